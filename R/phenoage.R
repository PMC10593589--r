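#' Constants of the PhenoAge model
#'
#' Returns the full constant set of the phenotypic-age model: the linear
#' predictor intercept and per-marker coefficients, the Gompertz mortality
#' parameters, and the constants mapping the 10-year mortality score onto the
#' years scale. The coefficients were estimated in the PhenoAge source
#' literature by a penalized Cox mortality model on nine clinical biomarkers
#' plus chronological age; they are held here as data so a variant constant
#' (see `pheno_denom` below) can be swapped with a single argument.
#'
#' Units expected by the linear predictor: albumin g/L, creatinine umol/L,
#' glucose mmol/L, CRP mg/dL (log is taken internally), lymphocyte percent
#' 0-100, mean cell volume fL, red cell distribution width percent, alkaline
#' phosphatase U/L, white blood cell count 10^3 cells/uL, age years. CRP is
#' the only marker entered on the log scale.
#'
#' @param pheno_denom Denominator constant of the years-scale transform.
#'   The default 0.09165 follows the equation as adopted in the NHANES
#'   re-analyses; some of the source literature prints 0.090165 instead.
#'   Either can be supplied.
#' @return A list with elements `intercept_xb`, `coefs` (named numeric vector
#'   of 10 coefficients), `gompertz_scale`, `gamma`, `pheno_intercept`,
#'   `pheno_inner`, `pheno_denom`.
#' @examples
#' phenoage_constants()$coefs[["rdw"]]  # 0.3306
#' @export
phenoage_constants <- function(pheno_denom = 0.09165) {
  stopifnot(is.numeric(pheno_denom), length(pheno_denom) == 1L, pheno_denom > 0)
  list(
    intercept_xb = -19.907,
    coefs = c(
      albumin        = -0.0336,
      creatinine     =  0.0095,
      glucose        =  0.1953,
      log_crp        =  0.0954,
      lymphocyte_pct = -0.0120,
      mcv            =  0.0268,
      rdw            =  0.3306,
      alp            =  0.00188,
      wbc            =  0.0554,
      chron_age      =  0.0804
    ),
    gompertz_scale  = 1.51714,
    gamma           = 0.0076927,
    pheno_intercept = 141.50,
    pheno_inner     = -0.00553,
    pheno_denom     = pheno_denom
  )
}

#' Names of the nine PhenoAge biomarkers
#'
#' Column names (in model order) of the biomarker panel consumed by
#' [compute_xb()], excluding chronological age.
#' @return Character vector of length 9.
#' @export
biomarker_names <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
    "mcv", "rdw", "alp", "wbc")
}

check_panel <- function(panel, crp_floor) {
  need <- c(biomarker_names(), "chron_age")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("biomarker panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in need) {
    v <- panel[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-finite or non-numeric value in biomarker '", nm, "'",
           call. = FALSE)
  }
  if (any(panel$lymphocyte_pct < 0 | panel$lymphocyte_pct > 100))
    stop("lymphocyte_pct must lie in [0, 100]", call. = FALSE)
  if (any(panel$chron_age < 0))
    stop("chron_age must be non-negative", call. = FALSE)
  if (any(pmax(panel$crp, crp_floor) <= 0))
    stop("crp must be positive after flooring", call. = FALSE)
  invisible(panel)
}

#' Linear predictor of the PhenoAge mortality model
#'
#' Computes `xb`, the weighted sum of the nine biomarkers and chronological
#' age. CRP enters as its natural log; all other markers enter linearly.
#' CRP values at or below `crp_floor` are raised to the floor first, since
#' assay detection limits can report zero and `log(0)` is undefined.
#'
#' @param panel A data.frame (or list) with numeric columns `albumin`,
#'   `creatinine`, `glucose`, `crp`, `lymphocyte_pct`, `mcv`, `rdw`, `alp`,
#'   `wbc`, `chron_age`, in the units documented in [phenoage_constants()].
#' @param constants Constant set, from [phenoage_constants()].
#' @param crp_floor Positive lower floor applied to CRP (mg/dL) before the
#'   log. Default 0.01.
#' @return Numeric vector of linear-predictor values (dimensionless).
#' @export
compute_xb <- function(panel, constants = phenoage_constants(),
                       crp_floor = 0.01) {
  check_panel(panel, crp_floor)
  k <- constants$coefs
  constants$intercept_xb +
    k[["albumin"]]        * panel$albumin +
    k[["creatinine"]]     * panel$creatinine +
    k[["glucose"]]        * panel$glucose +
    k[["log_crp"]]        * log(pmax(panel$crp, crp_floor)) +
    k[["lymphocyte_pct"]] * panel$lymphocyte_pct +
    k[["mcv"]]            * panel$mcv +
    k[["rdw"]]            * panel$rdw +
    k[["alp"]]            * panel$alp +
    k[["wbc"]]            * panel$wbc +
    k[["chron_age"]]      * panel$chron_age
}

#' Ten-year mortality score from the linear predictor
#'
#' Maps `xb` to the Gompertz model's 10-year mortality probability
#' `M = 1 - exp(-scale * exp(xb) / gamma)`. The scale constant satisfies
#' `scale = exp(120 * gamma) - 1` (120 months), which identifies the
#' expression as the Gompertz CDF over a 10-year horizon.
#'
#' Overflow is guarded: for very large `xb` the result approaches but never
#' equals 1 (it is capped just below 1 in double precision), so the
#' downstream `log(1 - M)` stays defined.
#'
#' @param xb Numeric vector of linear-predictor values (finite).
#' @param constants Constant set, from [phenoage_constants()].
#' @return Mortality scores strictly inside (0, 1), increasing in `xb`.
#' @export
compute_mortality_score <- function(xb, constants = phenoage_constants()) {
  if (!is.numeric(xb) || any(!is.finite(xb)))
    stop("xb must be finite numeric", call. = FALSE)
  m <- -expm1(-constants$gompertz_scale * exp(xb) / constants$gamma)
  pmin(pmax(m, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' PhenoAge (years) from the mortality score
#'
#' Maps the 10-year mortality score onto the years scale:
#' `PhenoAge = 141.50 + log(-0.00553 * log(1 - M)) / 0.09165`.
#'
#' @param m Mortality scores, strictly inside (0, 1).
#' @param constants Constant set, from [phenoage_constants()].
#' @return Phenotypic age in years, strictly increasing in `m`.
#' @export
compute_phenoage <- function(m, constants = phenoage_constants()) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0) || any(m >= 1))
    stop("mortality score must lie strictly in (0, 1)", call. = FALSE)
  constants$pheno_intercept +
    log(constants$pheno_inner * log1p(-m)) / constants$pheno_denom
}

#' PhenoAge from a biomarker panel
#'
#' Composition of [compute_xb()], [compute_mortality_score()] and
#' [compute_phenoage()]: the full chain from raw biomarkers to phenotypic
#' age in years. Deterministic and vectorized over rows.
#'
#' @inheritParams compute_xb
#' @return Numeric vector of phenotypic ages (years).
#' @examples
#' healthy40 <- data.frame(albumin = 43, creatinine = 80, glucose = 5,
#'   crp = 0.1, lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70,
#'   wbc = 6.5, chron_age = 40)
#' phenoage_from_panel(healthy40)  # about 35.8 y: younger than 40
#' @export
phenoage_from_panel <- function(panel, constants = phenoage_constants(),
                                crp_floor = 0.01) {
  compute_phenoage(
    compute_mortality_score(compute_xb(panel, constants, crp_floor), constants),
    constants)
}

#' Exact inverse: linear predictor achieving a target PhenoAge
#'
#' Algebraic inverse of the forward chain. Composing the two transforms
#' gives `xb = denom * (P - 141.50) + log(gamma / (scale * 0.00553))`, so
#' the inverse is exact (no root finding) and round-trips with
#' [compute_phenoage()] to machine precision. Used to calibrate the
#' synthetic cohort generator: any target PhenoAge can be implanted exactly
#' by emitting a biomarker panel whose `xb` equals this value.
#'
#' @param target Target phenotypic age(s) in years. Must be finite; the
#'   mathematical inverse is total, so only targets extreme enough that
#'   the implied mortality quantity under- or overflows double precision
#'   are rejected. (Round-tripping through [compute_mortality_score()]
#'   additionally requires `1 - M` to be representable, which holds for
#'   targets up to roughly 120 years.)
#' @param constants Constant set, from [phenoage_constants()].
#' @return Linear-predictor values `xb`.
#' @export
invert_phenoage <- function(target, constants = phenoage_constants()) {
  if (!is.numeric(target) || any(!is.finite(target)))
    stop("target PhenoAge must be finite numeric", call. = FALSE)
  xb <- constants$pheno_denom * (target - constants$pheno_intercept) +
    log(constants$gamma / (constants$gompertz_scale * (-constants$pheno_inner)))
  # implied -log(1 - M); the target is achievable iff this is a positive
  # finite double (it underflows for extremely negative targets and
  # overflows for absurdly large ones)
  q <- exp(constants$pheno_denom * (target - constants$pheno_intercept)) /
    (-constants$pheno_inner)
  bad <- q <= 0 | !is.finite(q) | !is.finite(xb)
  if (any(bad))
    stop("target PhenoAge outside the invertible range at index ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  xb
}

#' Batch-score PhenoAge over a participant table
#'
#' Appends `phenoage` (and a convenience `phenoage_accel = phenoage -
#' chron_age` column) to a table holding the nine biomarker columns and
#' `chron_age`. Rows with any missing biomarker get `NA`.
#'
#' @param data A data.frame containing the panel columns.
#' @param constants Constant set, from [phenoage_constants()].
#' @param crp_floor CRP floor (mg/dL) applied before the log.
#' @return `data` with `phenoage` and `phenoage_accel` columns appended.
#' @export
score_phenoage <- function(data, constants = phenoage_constants(),
                           crp_floor = 0.01) {
  need <- c(biomarker_names(), "chron_age")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("input table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- stats::complete.cases(data[need])
  out <- rep(NA_real_, nrow(data))
  if (any(ok))
    out[ok] <- phenoage_from_panel(data[ok, need, drop = FALSE],
                                   constants, crp_floor)
  data$phenoage <- out
  data$phenoage_accel <- out - data$chron_age
  data
}
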
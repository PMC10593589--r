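#' Centered percentile of an intake z-score
#'
#' The dietary inflammatory index maps each intake z-score through the
#' standard-normal CDF, doubled and shifted: `2 * pnorm(z) - 1`. This bounds
#' every nutrient's contribution in (-1, 1) and makes the median intake
#' contribute exactly zero.
#'
#' @param z Numeric vector of standard scores (finite).
#' @return Values in (-1, 1); an odd, strictly increasing function of `z`.
#' @examples
#' centered_percentile(0)     # 0
#' centered_percentile(1.96)  # ~0.95
#' @export
centered_percentile <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("z must be finite numeric", call. = FALSE)
  2 * stats::pnorm(z) - 1
}

#' Load and validate a DII parameter table
#'
#' Reads a tab-delimited parameter file with columns `name`, `unit`,
#' `global_mean`, `global_sd`, `effect_score`: one row per dietary
#' parameter, giving the global reference mean and standard deviation of
#' daily intake and the literature-derived inflammatory effect score
#' (positive = pro-inflammatory). The packaged default covers the 26
#' nutrient parameters used here, transcribed from the 2014
#' literature-derived DII reference database; verify against the original
#' publication (and override via `path`) before production use.
#'
#' @param path Path to the parameter file; default is the packaged table.
#' @param n_required Required row count (26 for this analysis; `NA` skips
#'   the check, e.g. for toy tables in examples).
#' @return A data.frame with the five columns above plus attributes
#'   `version` (tag derived from the file name) and `checksum`
#'   (sum of the numeric columns, logged for provenance).
#' @export
load_dii_parameters <- function(path = system.file("extdata",
                                                   "dii_parameters.tsv",
                                                   package = "phenodii"),
                                n_required = 26L) {
  if (!nzchar(path) || !file.exists(path))
    stop("DII parameter file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "unit", "global_mean", "global_sd", "effect_score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.na(n_required) && nrow(tab) != n_required)
    stop("parameter table must have ", n_required, " rows, found ",
         nrow(tab), call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate parameter names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tab$global_sd)) || any(tab$global_sd <= 0))
    stop("global_sd must be strictly positive for every parameter",
         call. = FALSE)
  if (any(!is.finite(tab$global_mean)) || any(!is.finite(tab$effect_score)))
    stop("non-finite mean or effect score in parameter table", call. = FALSE)
  attr(tab, "version") <- sub("\\.tsv$", "", basename(path))
  attr(tab, "checksum") <-
    sum(tab$global_mean) + sum(tab$global_sd) + sum(tab$effect_score)
  tab
}

#' Dietary inflammatory index of one or more intake records
#'
#' For each record, sums over non-missing nutrients the product of the
#' nutrient's inflammatory effect score and the centered percentile of its
#' intake z-score `(intake - global_mean) / global_sd`. Missing nutrients
#' contribute zero (the index tolerates fewer than the full parameter set);
#' the count of nutrients actually used is returned alongside.
#'
#' @param intake A data.frame (or single-row list) whose columns are named
#'   exactly as `params$name`; daily intake amounts, non-negative, `NA`
#'   for missing. Columns not present in `params` raise an error.
#' @param params Parameter table, from [load_dii_parameters()].
#' @return A data.frame with columns `dii` and `n_used` (nutrients that
#'   entered the sum), one row per record.
#' @examples
#' params <- data.frame(name = c("A", "B"), unit = "g",
#'   global_mean = c(10, 1), global_sd = c(2, 1),
#'   effect_score = c(-0.5, 0.4))
#' dii_score(data.frame(A = 10, B = 2.96), params)  # dii = 0.38
#' @export
dii_score <- function(intake, params) {
  intake <- as.data.frame(intake)
  unknown <- setdiff(names(intake), params$name)
  if (length(unknown))
    stop("unknown nutrient column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  have <- params$name[params$name %in% names(intake)]
  if (!length(have))
    stop("no nutrient columns present", call. = FALSE)
  x <- as.matrix(intake[have])
  if (any(x < 0, na.rm = TRUE))
    stop("negative intake amounts are not allowed", call. = FALSE)
  idx <- match(have, params$name)
  z <- sweep(sweep(x, 2L, params$global_mean[idx]), 2L,
             params$global_sd[idx], "/")
  contrib <- (2 * stats::pnorm(z) - 1) *
    rep(params$effect_score[idx], each = nrow(z))
  n_used <- rowSums(!is.na(contrib))
  if (any(n_used == 0L))
    stop("record(s) with all nutrients missing: ",
         paste(utils::head(which(n_used == 0L), 5L), collapse = ", "),
         call. = FALSE)
  data.frame(dii = rowSums(contrib, na.rm = TRUE), n_used = n_used)
}

#' Dichotomize diets at a DII of zero
#'
#' Diets with a strictly negative index are anti-inflammatory; an index of
#' zero or above is pro-inflammatory (the zero boundary belongs to the
#' pro-inflammatory class).
#'
#' @param dii Finite numeric DII values.
#' @return Factor with levels `anti_inflammatory`, `pro_inflammatory`
#'   (anti first, so it is the reference level in model fits).
#' @export
classify_diet <- function(dii) {
  if (!is.numeric(dii) || any(!is.finite(dii)))
    stop("dii must be finite numeric", call. = FALSE)
  factor(ifelse(dii < 0, "anti_inflammatory", "pro_inflammatory"),
         levels = c("anti_inflammatory", "pro_inflammatory"))
}

#' Batch-score the DII over a participant table
#'
#' Appends `dii`, `dii_n_used` and `diet_class` columns. Nutrient columns
#' are located by the parameter-table names; any listed nutrient absent
#' from the table is treated as missing for every record.
#'
#' @param data A data.frame with nutrient intake columns.
#' @param params Parameter table, from [load_dii_parameters()].
#' @return `data` with the three columns appended.
#' @export
score_dii <- function(data, params = load_dii_parameters()) {
  have <- intersect(params$name, names(data))
  if (!length(have))
    stop("none of the parameter-table nutrients found in the input table",
         call. = FALSE)
  sc <- dii_score(data[have], params)
  data$dii <- sc$dii
  data$dii_n_used <- sc$n_used
  data$diet_class <- classify_diet(sc$dii)
  data
}
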
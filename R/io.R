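#' Default column dictionary
#'
#' Maps the pipeline's canonical field names onto input column names.
#' The default is the identity mapping over every canonical field: the
#' participant id, demographics and covariates, the nine PhenoAge
#' biomarkers, the 26 DII nutrients, and the survey design triple
#' (`stratum`, `psu`, `weight`). Edit the `column` entries to ingest a
#' table with different headers, or set a `column` to `NA` to mark a
#' non-required field absent.
#'
#' @return Data.frame with columns `canonical`, `column`, `type`
#'   (`numeric` / `character`), `required`.
#' @export
default_column_dictionary <- function() {
  nutr <- load_dii_parameters()$name
  canonical <- c("id", "chron_age", "sex", "race", "education",
                 "income_poverty_ratio", "exercise", "smoking",
                 "drinking", "bmi", "energy", biomarker_names(), nutr,
                 "stratum", "psu", "weight")
  chr <- c("sex", "race", "education", "exercise", "smoking", "drinking",
           "stratum", "psu")
  data.frame(
    canonical = canonical,
    column = canonical,
    type = ifelse(canonical %in% chr, "character", "numeric"),
    required = canonical %in% c("id", "chron_age", "stratum", "psu",
                                "weight"))
}

#' Read a participant table through a column dictionary
#'
#' Reads a delimited text file with a header, renames mapped columns to
#' their canonical names, and coerces types: unparseable numeric cells
#' become missing flags, counted per column in the `parse_log` attribute.
#'
#' @param path Path to a delimited text file.
#' @param dictionary A dictionary from [default_column_dictionary()].
#' @param sep Field separator (default tab).
#' @return Data.frame of typed records; attribute `parse_log` holds
#'   per-column counts of cells coerced to `NA`.
#' @export
read_cohort <- function(path, dictionary = default_column_dictionary(),
                        sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""),
                           colClasses = "character",
                           check.names = FALSE)
  mapped <- dictionary[!is.na(dictionary$column), ]
  miss <- setdiff(mapped$column[mapped$required], names(raw))
  if (length(miss))
    stop("input is missing required mapped column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  present <- mapped[mapped$column %in% names(raw), ]
  out <- raw[present$column]
  names(out) <- present$canonical
  parse_log <- integer(0)
  for (i in seq_len(nrow(present))) {
    nm <- present$canonical[i]
    if (present$type[i] == "numeric") {
      was_na <- is.na(out[[nm]])
      out[[nm]] <- suppressWarnings(as.numeric(out[[nm]]))
      n_bad <- sum(is.na(out[[nm]]) & !was_na)
      if (n_bad) parse_log[nm] <- n_bad
    }
  }
  if (anyDuplicated(out$id))
    stop("duplicate participant id(s): ",
         paste(utils::head(unique(out$id[duplicated(out$id)]), 5L),
               collapse = ", "), call. = FALSE)
  attr(out, "parse_log") <- parse_log
  out
}

#' Write a participant table
#'
#' Tab-delimited, header, no row names; the inverse of [read_cohort()]
#' under the identity dictionary.
#'
#' @param records Data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Divide multi-cycle survey weights
#'
#' When several 2-year survey cycles are pooled, each cycle's weight is
#' divided by the number of cycles combined. Point estimates are
#' invariant to this global rescaling; totals are not, so the helper is
#' provided for users who need population-scale weights.
#'
#' @param weights Positive weights.
#' @param n_cycles Number of pooled cycles.
#' @return Rescaled weights.
#' @export
combine_cycle_weights <- function(weights, n_cycles) {
  stopifnot(n_cycles >= 1)
  weights / n_cycles
}

#' Write the analysis bundle as delimited text
#'
#' Writes the exclusion log, descriptive table, univariate screen,
#' adjusted-model table, stratified forest table and run metadata to
#' `out_dir`, one tab-delimited file each, in deterministic order.
#'
#' @param bundle Result of [run_cohort_analysis()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parts <- list(exclusion_log = bundle$exclusion_log,
                table1 = bundle$table1,
                table2 = bundle$table2,
                table3 = bundle$table3,
                forest = bundle$forest,
                meta = bundle$meta)
  paths <- character(0)
  for (nm in names(parts)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(parts[[nm]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}
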
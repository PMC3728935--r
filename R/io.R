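PHENO_COLS <- c("individual_id", "cross_id", "population", "stream",
                "experiment", "length")
SURV_COLS <- c("cross_id", "population", "stream", "n_stocked",
               "n_recaptured")

validate_phenotypes <- function(df) {
  probs <- character()
  row_of <- function(i) i + 1L  # header line
  bad <- which(!is.finite(df$length) | df$length <= 0)
  if (length(bad))
    probs <- c(probs, sprintf("line %d: non-positive or non-numeric length",
                              row_of(bad)))
  if (!all(df$experiment %in% c(1L, 2L))) {
    bad <- which(!df$experiment %in% c(1L, 2L))
    probs <- c(probs, sprintf("line %d: experiment must be 1 or 2", row_of(bad)))
  }
  probs
}

validate_survival <- function(df) {
  probs <- character()
  row_of <- function(i) i + 1L
  bad <- which(!is.finite(df$n_stocked) | !is.finite(df$n_recaptured) |
                 df$n_stocked < 0 | df$n_recaptured < 0)
  if (length(bad))
    probs <- c(probs, sprintf("line %d: counts must be non-negative numbers",
                              row_of(bad)))
  bad <- which(df$n_recaptured > df$n_stocked)
  if (length(bad))
    probs <- c(probs, sprintf("line %d: n_recaptured exceeds n_stocked",
                              row_of(bad)))
  probs
}

read_table_checked <- function(path, required, validator) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  probs <- validator(df)
  if (length(probs))
    stop("invalid rows in ", path, ":\n  ", paste(probs, collapse = "\n  "))
  df
}

#' Read and write phenotype tables
#'
#' Phenotype tables are plain CSV with columns \code{individual_id},
#' \code{cross_id}, \code{population}, \code{stream}, \code{experiment},
#' \code{length} (plus optional \code{sire_id}/\code{dam_id} for diallel
#' designs). Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return \code{read_phenotypes}: a data frame of records.
#' @export
read_phenotypes <- function(path) {
  df <- read_table_checked(path, PHENO_COLS, validate_phenotypes)
  df$experiment <- as.integer(df$experiment)
  df
}

#' @rdname read_phenotypes
#' @param table Data frame of phenotype records.
#' @export
write_phenotypes <- function(table, path) {
  missing <- setdiff(PHENO_COLS, names(table))
  if (length(missing))
    stop("table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write survival (egg-to-recapture) tables
#'
#' CSV with columns \code{cross_id}, \code{population}, \code{stream},
#' \code{n_stocked}, \code{n_recaptured}; rows with more recaptures than
#' stocked eggs are rejected with their line numbers.
#'
#' @param path File path.
#' @export
read_survival <- function(path) {
  df <- read_table_checked(path, SURV_COLS, validate_survival)
  df$n_stocked <- as.integer(df$n_stocked)
  df$n_recaptured <- as.integer(df$n_recaptured)
  df
}

#' @rdname read_survival
#' @param table Data frame of survival records.
#' @export
write_survival <- function(table, path) {
  missing <- setdiff(SURV_COLS, names(table))
  if (length(missing))
    stop("table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' The format is chosen by extension: \code{.json} via jsonlite, anything
#' else via yaml. The result is passed to \code{\link{run_config}} by
#' \code{\link{run_pipeline}} callers; here it is returned as a plain list.
#'
#' @param path File path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
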
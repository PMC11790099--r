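## Readers and writers for the raw event tables (CSV or Parquet), the
## ground-truth sidecar, and YAML cohort specifications.  Ground truth is
## written to a distinct subdirectory so that estimation code pointed at the
## data directory can never read it by accident.

.TABLE_NAMES <- c("static", "measurements", "interventions", "outcomes")

#' Write raw event tables to disk
#'
#' @param tables an `event_tables` object.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"` (requires the arrow package).
#' @return `dir`, invisibly.
#' @export
write_event_tables <- function(tables, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in .TABLE_NAMES) .write_table(tables[[nm]], dir, nm, format)
  invisible(dir)
}

#' Read raw event tables from disk
#'
#' @param dir directory containing the four tables.
#' @param format `"csv"` or `"parquet"`; `NULL` autodetects.
#' @return a validated `event_tables` object.
#' @export
read_event_tables <- function(dir, format = NULL) {
  format <- format %||%
    (if (file.exists(file.path(dir, "static.csv"))) "csv" else "parquet")
  tables <- lapply(.TABLE_NAMES, function(nm) .read_table(dir, nm, format))
  names(tables) <- .TABLE_NAMES
  class(tables) <- "event_tables"
  validate_event_tables(tables)
}

#' Write the simulation ground truth sidecar
#'
#' Stored under `dir/ground_truth/`, never alongside the event tables, so
#' downstream estimation that reads the data directory cannot touch it.
#'
#' @param sim an `ehr_sim` object.
#' @param dir the data directory.
#' @param format `"csv"` or `"parquet"`.
#' @return the sidecar directory, invisibly.
#' @export
write_ground_truth <- function(sim, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(sim$truth)
  .write_table(df, gt_dir, "truth", format)
  writeLines(jsonlite::toJSON(list(true_ate = attr(sim$truth, "true_ate")),
                              auto_unbox = TRUE, digits = NA),
             file.path(gt_dir, "truth_meta.json"))
  invisible(gt_dir)
}

#' Read the simulation ground truth sidecar
#'
#' @param dir the data directory containing `ground_truth/`.
#' @param format `"csv"` or `"parquet"`; `NULL` autodetects.
#' @return the ground-truth data frame with its `true_ate` attribute.
#' @export
read_ground_truth <- function(dir, format = NULL) {
  gt_dir <- file.path(dir, "ground_truth")
  format <- format %||%
    (if (file.exists(file.path(gt_dir, "truth.csv"))) "csv" else "parquet")
  truth <- .read_table(gt_dir, "truth", format)
  meta <- jsonlite::fromJSON(file.path(gt_dir, "truth_meta.json"))
  attr(truth, "true_ate") <- meta$true_ate
  class(truth) <- c("ehr_truth", "data.frame")
  truth
}

.write_table <- function(df, dir, name, format) {
  if (format == "csv") {
    utils::write.csv(as.data.frame(df), file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      .stopf("parquet output requires the 'arrow' package")
    arrow::write_parquet(as.data.frame(df), file.path(dir, paste0(name, ".parquet")))
  }
}

.read_table <- function(dir, name, format) {
  if (format == "csv") {
    utils::read.csv(file.path(dir, paste0(name, ".csv")), stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      .stopf("parquet input requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(file.path(dir, paste0(name, ".parquet"))))
  }
}

#' Serialize a cohort specification to YAML
#'
#' @param spec a [cohort_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Read a cohort specification from YAML
#'
#' @param path a YAML file written by [write_cohort_spec()].
#' @return a validated [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(cohort_spec, x)
}
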
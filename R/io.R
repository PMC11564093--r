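#' Read a long-format longitudinal feature table
#'
#' Expects (TSV/CSV, optionally gzip-compressed) columns
#' `participant_id`, `visit_age`, `healthy`, `omics`, `feature_id`,
#' `value`. Types are validated; a malformed numeric cell is reported
#' with its row number.
#'
#' @param path path to the table.
#' @param metadata optional path to a participant metadata table
#'   (`participant_id`, `sex`, `ethnicity`, `bmi`, `iris_class`).
#' @return an `aging_cohort` (without ground truth).
#' @export
read_long_table <- function(path, metadata = NULL) {
  dt <- if (grepl("\\.gz$", path)) {
    # file() connections decompress transparently; avoids an extra dependency
    data.table::fread(text = readLines(path),
                      colClasses = list(character = "participant_id"))
  } else {
    data.table::fread(path, colClasses = list(character = "participant_id"))
  }
  need <- c("participant_id", "visit_age", "healthy", "omics", "feature_id",
            "value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  for (col in c("visit_age", "value")) {
    v <- dt[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) stop("non-numeric '", col, "' in ", path,
                            " at data row(s) ", paste(head(bad, 5),
                                                      collapse = ", "))
      data.table::set(dt, j = col, value = num)
    }
  }
  if (!is.logical(dt$healthy)) {
    h <- tolower(as.character(dt$healthy))
    hv <- h %in% c("true", "t", "1", "yes")
    bad <- which(!h %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
    if (length(bad)) stop("non-boolean 'healthy' in ", path,
                          " at data row(s) ", paste(head(bad, 5),
                                                    collapse = ", "))
    data.table::set(dt, j = "healthy", value = hv)
  }
  meta <- if (!is.null(metadata))
    as.data.frame(data.table::fread(metadata)) else NULL
  structure(list(samples = dt, metadata = meta, truth = NULL,
                 taxonomy = NULL, config = NULL), class = "aging_cohort")
}

#' Write cohort tables to a directory
#'
#' Emits `samples.tsv` (long format), `metadata.tsv` and, when present,
#' `ground_truth.tsv` and `taxonomy.tsv`.
#'
#' @param cohort an `aging_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t")
  if (!is.null(cohort$metadata))
    data.table::fwrite(cohort$metadata, file.path(dir, "metadata.tsv"),
                       sep = "\t")
  if (!is.null(cohort$truth))
    data.table::fwrite(cohort$truth, file.path(dir, "ground_truth.tsv"),
                       sep = "\t")
  if (!is.null(cohort$taxonomy))
    data.table::fwrite(cohort$taxonomy, file.path(dir, "taxonomy.tsv"),
                       sep = "\t")
  invisible(dir)
}

#' Write a cross-sectional matrix with a provenance sidecar
#'
#' The matrix goes to `<stem>.tsv` (features in rows) and a JSON
#' sidecar `<stem>.json` records ages, omics assignment and the
#' adjustment provenance.
#'
#' @param csm a `cross_sectional` matrix.
#' @param stem output path stem.
#' @return the stem, invisibly.
#' @export
write_cross_sectional <- function(csm, stem) {
  tab <- data.table::as.data.table(csm$values, keep.rownames = "feature_id")
  data.table::fwrite(tab, paste0(stem, ".tsv"), sep = "\t")
  jsonlite::write_json(
    list(age = as.list(csm$age), omics = as.list(csm$omics),
         adjusted = csm$adjusted,
         confounders = csm$confounders %||% character(0)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_cross_sectional
#' @export
read_cross_sectional <- function(stem) {
  tab <- data.table::fread(paste0(stem, ".tsv"))
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  side <- jsonlite::read_json(paste0(stem, ".json"))
  structure(list(values = m,
                 age = unlist(side$age)[colnames(m)],
                 omics = unlist(side$omics)[rownames(m)],
                 metadata = NULL,
                 adjusted = isTRUE(side$adjusted),
                 confounders = unlist(side$confounders)),
            class = "cross_sectional")
}
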
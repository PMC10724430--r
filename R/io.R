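# Delimited-table ingest and cohort round-trip. Dialect: UTF-8, comma by
# default, mandatory header row of marker names, cells as rows. Every
# written output gets a JSON metadata sidecar (transform, cofactor,
# subsample settings, dropped channels) so SD-based statistics stay
# auditable.

#' Read an expression matrix
#'
#' Reads one (patient, timepoint) cells x markers table from a delimited
#' file or an FCS 3.0/3.1 file. Values are loaded raw
#' (`transform = "raw"`); apply [arcsinh_transform] afterwards. Channels
#' not in the configured panel are dropped (reported), rows with missing
#' entries are dropped and counted (`n_dropped_rows` attribute).
#'
#' @param path file path.
#' @param format `"delimited"` or `"fcs"`.
#' @param panel optional character vector restricting the marker panel; a
#'   file sharing no names with the panel is an error.
#' @param sep field separator for delimited files.
#' @param cluster_column optional name of a cluster-label column in a
#'   delimited file.
#' @return A [dnb_expression] with `transform = "raw"`.
#' @export
read_expression <- function(path, format = c("delimited", "fcs"),
                            panel = NULL, sep = ",", cluster_column = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "fcs") {
    fcs <- read_fcs(path)
    values <- fcs$values
    clusters <- NULL
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    if (!ncol(df))
      stop("empty table: ", path, call. = FALSE)
    clusters <- NULL
    if (!is.null(cluster_column) && cluster_column %in% names(df)) {
      clusters <- as.character(df[[cluster_column]])
      df[[cluster_column]] <- NULL
    }
    non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(non_num))
      stop("non-numeric columns in ", path, ": ",
           paste(non_num, collapse = ", "), call. = FALSE)
    values <- as.matrix(df)
  }
  if (!is.null(panel)) {
    keep <- colnames(values) %in% panel
    if (!any(keep))
      stop("no panel overlap: none of the file's channels match the ",
           "configured marker panel", call. = FALSE)
    dropped <- colnames(values)[!keep]
    if (length(dropped))
      message("dropping channels outside the panel: ",
              paste(dropped, collapse = ", "))
    values <- values[, keep, drop = FALSE]
  } else dropped <- character(0)
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message(n_dropped, " row(s) with missing values dropped")
    values <- values[complete, , drop = FALSE]
    if (!is.null(clusters)) clusters <- clusters[complete]
  }
  m <- dnb_expression(values, colnames(values), transform = "raw",
                      cluster_labels = clusters)
  attr(m, "dropped_channels") <- dropped
  attr(m, "n_dropped_rows") <- n_dropped
  m
}

#' Write an expression matrix as a delimited table
#'
#' Cells as rows, header row of marker names; same dialect
#' [read_expression] reads, so a write/read round trip is value-identical.
#'
#' @param m a [dnb_expression].
#' @param path output file.
#' @param sep field separator.
#' @export
write_expression <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "dnb_expression"))
  df <- as.data.frame(m$values)
  if (!is.null(m$cluster_labels)) df$cluster <- m$cluster_labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a cohort to a directory
#'
#' Emits one delimited table per (patient, timepoint), a cohort manifest
#' (`manifest.csv`: patient_id, group, hour, file), the clinical table
#' (`clinical.csv`) and a JSON metadata sidecar (`metadata.json`).
#'
#' @param cohort a `dnb_cohort`.
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, sep = ",") {
  stopifnot(inherits(cohort, "dnb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in cohort$samples) {
    for (h in names(s$matrices)) {
      f <- sprintf("%s_t%s.csv", s$patient_id, gsub("[.]", "p", h))
      write_expression(s$matrices[[h]], file.path(dir, f), sep = sep)
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = s$patient_id, group = s$group, hour = h,
                   file = f, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.csv"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.csv"),
                     sep = sep, row.names = FALSE, quote = FALSE)
  m1 <- cohort$samples[[1]]$matrices[[1]]
  meta <- list(transform = m1$transform, cofactor = m1$cofactor,
               n_markers = length(m1$marker_names),
               simulated = !is.null(cohort$truth),
               seed = if (!is.null(cohort$truth)) cohort$truth$params$seed)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(file.path(dir, "manifest.csv"))
}

#' Read a cohort from a manifest
#'
#' Rebuilds [dnb_sample] objects from a cohort directory written by
#' [write_cohort] (or assembled by hand in the same dialect). Missing
#' timepoints are a hard error: the 2h-4h difference and the
#' baseline-relative ranking require the full course.
#'
#' @param manifest_path path to the manifest table.
#' @param sep field separator.
#' @param transform transform state recorded in the files (as written by
#'   [write_cohort] this is the metadata sidecar's `transform`; default
#'   reads the sidecar when present, else `"raw"`).
#' @return A `dnb_cohort` (with `truth = NULL`; see [planted_truth]) whose
#'   `clinical` table is read from `clinical.csv` when present.
#' @export
read_cohort <- function(manifest_path, sep = ",", transform = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  dir <- dirname(manifest_path)
  manifest <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE, colClasses = "character")
  if (is.null(transform)) {
    meta_path <- file.path(dir, "metadata.json")
    transform <- if (file.exists(meta_path))
      jsonlite::read_json(meta_path)$transform else "raw"
  }
  samples <- lapply(split(manifest, manifest$patient_id), function(mf) {
    mats <- lapply(seq_len(nrow(mf)), function(i) {
      m <- read_expression(file.path(dir, mf$file[i]), "delimited", sep = sep)
      m$transform <- transform
      if (transform == "arcsinh") m$cofactor <- 5
      m
    })
    names(mats) <- mf$hour
    dnb_sample(mf$patient_id[1], mf$group[1], mats)
  })
  clinical <- NULL
  clin_path <- file.path(dir, "clinical.csv")
  if (file.exists(clin_path)) {
    clinical <- utils::read.table(clin_path, header = TRUE, sep = sep,
                                  stringsAsFactors = FALSE)
    clinical <- validate_clinical(clinical)
  }
  samples <- samples[order(names(samples))]
  structure(list(samples = samples, clinical = clinical, truth = NULL),
            class = "dnb_cohort")
}
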
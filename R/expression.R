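#' Single-timepoint expression matrix
#'
#' Container for one (patient, timepoint) cells x markers intensity matrix,
#' together with its transform state. Mass-cytometry intensities are
#' conventionally analysed on the arcsinh scale; the container records whether
#' the values are raw or already transformed (and with which cofactor), so
#' that a double transform can be refused.
#'
#' @param values numeric matrix, cells in rows, markers in columns. No
#'   missing values are allowed; drop incomplete rows at ingest.
#' @param marker_names character vector of unique marker names, one per
#'   column. Defaults to the column names of `values`.
#' @param transform `"raw"` or `"arcsinh"`.
#' @param cofactor arcsinh cofactor used, when `transform = "arcsinh"`.
#' @param cluster_labels optional per-cell cluster labels (factor or
#'   character), length equal to the number of cells.
#' @return An object of class `dnb_expression`.
#' @export
dnb_expression <- function(values, marker_names = colnames(values),
                           transform = c("raw", "arcsinh"),
                           cofactor = NULL, cluster_labels = NULL) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric", call. = FALSE)
  if (nrow(values) < 1L)
    stop("an expression matrix needs at least one cell", call. = FALSE)
  if (anyNA(values))
    stop("expression values contain missing entries; drop incomplete rows at ingest",
         call. = FALSE)
  if (is.null(marker_names))
    marker_names <- sprintf("M%02d", seq_len(ncol(values)))
  marker_names <- as.character(marker_names)
  if (length(marker_names) != ncol(values))
    stop("marker_names length does not match the number of columns", call. = FALSE)
  if (anyDuplicated(marker_names))
    stop("marker names must be unique", call. = FALSE)
  colnames(values) <- marker_names
  if (!is.null(cluster_labels)) {
    if (length(cluster_labels) != nrow(values))
      stop("cluster_labels must have one entry per cell", call. = FALSE)
    cluster_labels <- as.character(cluster_labels)
  }
  structure(list(values = values, marker_names = marker_names,
                 transform = transform, cofactor = cofactor,
                 cluster_labels = cluster_labels),
            class = "dnb_expression")
}

#' @export
print.dnb_expression <- function(x, ...) {
  cat(sprintf("<dnb_expression> %d cells x %d markers (%s%s)\n",
              nrow(x$values), ncol(x$values), x$transform,
              if (!is.null(x$cofactor)) sprintf(", cofactor %g", x$cofactor) else ""))
  cat("markers:", paste(utils::head(x$marker_names, 8L), collapse = ", "),
      if (length(x$marker_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.dnb_expression <- function(x) dim(x$values)

#' Arcsinh transform of raw intensities
#'
#' Applies `asinh(x / cofactor)` element-wise, the standard variance-
#' stabilising transform for mass-cytometry data (cofactor 5 by convention).
#' Negative raw values (possible after compensation) are retained; the
#' transform is odd, so sign and within-marker ranks are preserved.
#' Transforming an already-transformed matrix is an error.
#'
#' @param m a [dnb_expression] with `transform == "raw"`.
#' @param cofactor positive divisor applied before `asinh`.
#' @return The transformed [dnb_expression].
#' @export
arcsinh_transform <- function(m, cofactor = 5) {
  stopifnot(inherits(m, "dnb_expression"))
  if (!identical(m$transform, "raw"))
    stop("matrix is already arcsinh-transformed; refusing a double transform",
         call. = FALSE)
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number", call. = FALSE)
  m$values <- asinh(m$values / cofactor)
  m$transform <- "arcsinh"
  m$cofactor <- cofactor
  m
}

#' Uniform cell subsampling
#'
#' Draws a seeded uniform sample of cells without replacement so that
#' cell-level standard deviations are comparable across timepoints measured
#' at unequal depth. Matrices already at or below the target size pass
#' through unchanged (with a message).
#'
#' @param m a [dnb_expression].
#' @param n target number of cells; at least 50 (cell-level SD and
#'   correlation below that are too unstable to rank modules).
#' @param seed integer seed for the draw.
#' @return A [dnb_expression] with at most `n` cells.
#' @export
subsample_cells <- function(m, n, seed = 1L) {
  stopifnot(inherits(m, "dnb_expression"))
  if (!is.numeric(n) || length(n) != 1L || n < 50)
    stop("subsample size must be at least 50 cells", call. = FALSE)
  n_cells <- nrow(m$values)
  if (n_cells <= n) {
    message(sprintf("matrix has %d cells <= n = %d; left unchanged", n_cells, n))
    return(m)
  }
  set.seed(as.integer(seed))
  keep <- sort(sample.int(n_cells, n))
  m$values <- m$values[keep, , drop = FALSE]
  if (!is.null(m$cluster_labels)) m$cluster_labels <- m$cluster_labels[keep]
  m
}

#' Collapse cells to per-cluster medians
#'
#' Optional ingest switch: replaces the cells x markers matrix by one row of
#' per-marker medians per cluster. Off by default in the pipeline, where
#' cells within one (patient, timepoint) are the replicate unit.
#'
#' @param m a [dnb_expression] with `cluster_labels`.
#' @return A [dnb_expression] with one row per cluster.
#' @export
collapse_to_cluster_medians <- function(m) {
  stopifnot(inherits(m, "dnb_expression"))
  if (is.null(m$cluster_labels))
    stop("no cluster labels present", call. = FALSE)
  labs <- sort(unique(m$cluster_labels))
  med <- t(vapply(labs, function(l) {
    apply(m$values[m$cluster_labels == l, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(m$values))))
  dnb_expression(med, m$marker_names, transform = m$transform,
                 cofactor = m$cofactor, cluster_labels = labs)
}

#' Cluster abundance
#'
#' Frequency of each cell cluster among total cells of one matrix. Clusters
#' in `reference` that are absent from the matrix are reported with
#' frequency 0; without a reference list only observed clusters appear.
#'
#' @param m a [dnb_expression] carrying `cluster_labels`.
#' @param reference optional character vector of cluster names to report.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
cluster_abundance <- function(m, reference = NULL) {
  stopifnot(inherits(m, "dnb_expression"))
  if (is.null(m$cluster_labels))
    stop("cluster_abundance requires per-cell cluster labels", call. = FALSE)
  tab <- table(m$cluster_labels)
  freq <- as.numeric(tab) / length(m$cluster_labels)
  names(freq) <- names(tab)
  if (!is.null(reference)) {
    out <- stats::setNames(numeric(length(reference)), as.character(reference))
    seen <- intersect(names(freq), names(out))
    out[seen] <- freq[seen]
    extra <- setdiff(names(freq), names(out))
    if (length(extra))
      warning("clusters observed but absent from the reference list: ",
              paste(extra, collapse = ", "), call. = FALSE)
    out <- c(out, freq[extra])
    return(out)
  }
  freq
}

#' Ratio of group means
#'
#' Mean of a per-patient statistic in one group divided by its mean in
#' another, e.g. a cluster-abundance fold change between remission patients
#' and healthy controls.
#'
#' @param per_patient_values named numeric vector (names are patient ids).
#' @param groups named character vector mapping patient id to group.
#' @param g1,g2 group labels for the numerator and denominator.
#' @return The ratio `mean(g1) / mean(g2)`.
#' @export
group_ratio <- function(per_patient_values, groups, g1, g2) {
  if (is.null(names(per_patient_values)) || is.null(names(groups)))
    stop("per_patient_values and groups must be named by patient id", call. = FALSE)
  v1 <- per_patient_values[names(groups)[groups == g1]]
  v2 <- per_patient_values[names(groups)[groups == g2]]
  v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
  if (length(v1) == 0L)
    stop(sprintf("group '%s' is empty", g1), call. = FALSE)
  if (length(v2) == 0L)
    stop(sprintf("group '%s' is empty", g2), call. = FALSE)
  m2 <- mean(v2)
  if (m2 == 0)
    stop(sprintf("denominator group '%s' has zero mean", g2), call. = FALSE)
  mean(v1) / m2
}
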
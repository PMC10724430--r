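# Core DNB statistics: member SD, intra-module and module-to-background
# absolute Pearson correlation, and the composite index combining the three
# early-warning conditions of an impending critical transition.

# Absolute Pearson correlation matrix with the zero-variance convention:
# pairs involving a constant marker contribute r = 0 (their count is
# returned as an attribute), keeping pair-average denominators stable
# across timepoints instead of silently shrinking them.
.abs_cor <- function(values) {
  sds <- apply(values, 2, stats::sd)
  C <- suppressWarnings(stats::cor(values))
  n_zero <- sum(is.na(C[upper.tri(C)]))
  C[is.na(C)] <- 0
  diag(C) <- 1
  structure(abs(C), sds = sds, zero_var_pairs = n_zero)
}

# Shared summariser: module statistics from a precomputed |r| matrix and SD
# vector. Used both on cell-level data and on noiseless population
# correlation structures.
.stats_from_summary <- function(absC, sds, idx, epsilon = 1e-6) {
  sub <- absC[idx, idx, drop = FALSE]
  pcc_in <- mean(sub[upper.tri(sub)])
  pcc_out <- mean(absC[idx, -idx, drop = FALSE])
  sd_in <- mean(sds[idx])
  list(sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out,
       I = sd_in * pcc_in / (pcc_out + epsilon))
}

#' DNB module statistics at one timepoint
#'
#' For a candidate marker subset, computes over the cells of one
#' (patient, timepoint) matrix: `sd_in`, the mean member standard
#' deviation; `pcc_in`, the mean absolute pairwise Pearson correlation
#' among members; `pcc_out`, the mean absolute correlation between each
#' member and each non-member; and the composite index `I`. Pairs in which
#' either marker is constant contribute `r = 0` (count reported in the
#' `zero_var_pairs` field).
#'
#' @param m a [dnb_expression] with at least 50 cells.
#' @param members character vector of at least 2 marker names (at least 2
#'   markers must remain outside the module).
#' @param epsilon guard added to `pcc_out` in the composite index.
#' @return An object of class `dnb_module_stats`.
#' @export
module_stats <- function(m, members, epsilon = 1e-6) {
  stopifnot(inherits(m, "dnb_expression"))
  members <- as.character(members)
  missing <- setdiff(members, m$marker_names)
  if (length(missing))
    stop("markers not in panel: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(members) < 2L)
    stop("a module needs at least 2 members", call. = FALSE)
  if (length(m$marker_names) - length(members) < 2L)
    stop("at least 2 non-member markers are required", call. = FALSE)
  if (nrow(m$values) < 50L)
    warning("fewer than 50 cells; module statistics are unstable",
            call. = FALSE)
  absC <- .abs_cor(m$values)
  idx <- match(members, m$marker_names)
  s <- .stats_from_summary(absC, attr(absC, "sds"), idx, epsilon)
  structure(c(list(members = members), s,
              list(epsilon = epsilon,
                   zero_var_pairs = attr(absC, "zero_var_pairs"))),
            class = "dnb_module_stats")
}

#' @export
print.dnb_module_stats <- function(x, ...) {
  cat(sprintf("<dnb_module_stats> {%s}: sd_in %.4f, pcc_in %.4f, pcc_out %.4f, I %.4f\n",
              paste(x$members, collapse = ","), x$sd_in, x$pcc_in, x$pcc_out, x$I))
  invisible(x)
}

#' DNB composite index
#'
#' The single scalar folding the three DNB conditions into one score:
#' `I = sd_in * pcc_in / (pcc_out + epsilon)`. It rises when member
#' variance rises, when members become more mutually correlated, and when
#' they decouple from the rest of the network; `epsilon` guards the
#' `pcc_out -> 0` limit.
#'
#' @param s a `dnb_module_stats`, or a list with `sd_in`, `pcc_in`,
#'   `pcc_out` fields.
#' @param epsilon small positive guard (default 1e-6).
#' @return The index value.
#' @export
composite_index <- function(s, epsilon = 1e-6) {
  s$sd_in * s$pcc_in / (s$pcc_out + epsilon)
}

# All clusters appearing at any cut of an average-linkage dendrogram over
# distance 1 - |r|, as index sets, sizes within [min_size, max_size].
.dendrogram_clusters <- function(absC, min_size, max_size) {
  p <- ncol(absC)
  D <- stats::as.dist(1 - absC)
  h <- stats::hclust(D, method = "average")
  nodes <- vector("list", p - 1L)
  for (i in seq_len(p - 1L)) {
    left <- h$merge[i, 1]; right <- h$merge[i, 2]
    a <- if (left < 0) -left else nodes[[left]]
    b <- if (right < 0) -right else nodes[[right]]
    nodes[[i]] <- c(a, b)
  }
  keep <- Filter(function(s) length(s) >= min_size && length(s) <= max_size,
                 nodes)
  lapply(keep, sort)
}

#' Candidate DNB modules of one expression matrix
#'
#' Builds the candidate module list by average-linkage hierarchical
#' clustering on the distance `1 - |r|`: every cluster appearing at any
#' cut height whose size lies in `[min_size, max_size]` is a candidate
#' (deduplicated; ordered by size then lexicographically by marker names).
#' Exhaustive subset search is infeasible beyond ~20 markers; on small
#' panels this search is validated against exhaustive enumeration.
#'
#' @param m a [dnb_expression] with at least 4 markers.
#' @param min_size,max_size candidate size bounds (defaults 2 and 8; the
#'   effective upper bound also leaves at least 2 non-members).
#' @return List of character vectors of marker names (possibly empty, with
#'   a warning, when all markers are constant).
#' @export
candidate_modules <- function(m, min_size = 2, max_size = 8) {
  stopifnot(inherits(m, "dnb_expression"))
  p <- length(m$marker_names)
  if (p < 4L)
    stop("candidate search needs a panel of at least 4 markers", call. = FALSE)
  absC <- .abs_cor(m$values)
  if (all(attr(absC, "sds") == 0)) {
    warning("all markers are constant; no candidate modules", call. = FALSE)
    return(list())
  }
  sets <- .dendrogram_clusters(absC, min_size, min(max_size, p - 2L))
  .order_candidates(sets, m$marker_names)
}

# deduplicate and order index sets by size, then lexicographic marker names
.order_candidates <- function(sets, marker_names) {
  if (!length(sets)) return(list())
  named <- lapply(sets, function(s) marker_names[s])
  keys <- vapply(named, function(s) paste(sort(s), collapse = "\r"), "")
  named <- named[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  sizes <- lengths(named)
  named[order(sizes, keys)]
}

#' Rank candidate modules of one patient across the time course
#'
#' Pools candidate modules from every timepoint's correlation structure,
#' computes the composite index of each candidate at every timepoint, and
#' ranks candidates by the surge of the index relative to the unstimulated
#' baseline: `max over t > baseline of I(t) / (I(baseline) + epsilon)`.
#' Ties break by larger peak index, then lexicographically. Ranking
#' against baseline makes scores comparable across patients with different
#' resting variance and targets the dynamic response to stimulation rather
#' than static correlation.
#'
#' The per-sample ranked marker list takes the best module's members
#' ordered by their SD fold change at the module's peak hour, extended
#' with members of the next-ranked modules (same ordering, duplicates
#' skipped) to exactly `k` markers.
#'
#' @param sample a [dnb_sample].
#' @param baseline_hour hour used as reference (default 0).
#' @param min_size,max_size candidate size bounds passed to the search.
#' @param k length of the ranked marker list (default 5).
#' @param epsilon guard for both the composite index and the fold change.
#' @return An object of class `dnb_result`: list with `patient_id`,
#'   `group`, `modules` (data.frame, one row per candidate, ranked),
#'   `best_members`, `best_trajectory` (index of the best module per hour),
#'   `marker_order`, `k`.
#' @export
rank_modules <- function(sample, baseline_hour = 0, min_size = 2,
                         max_size = 8, k = 5, epsilon = 1e-6) {
  stopifnot(inherits(sample, "dnb_sample"))
  hours <- names(sample$matrices)
  base_key <- .hour_key(baseline_hour)
  if (!base_key %in% hours)
    stop("baseline hour ", base_key, " not present", call. = FALSE)
  panel <- sample_panel(sample)
  p <- length(panel)
  summ <- lapply(sample$matrices, function(m) .abs_cor(m$values))
  cand_idx <- list()
  for (s in summ) {
    if (all(attr(s, "sds") == 0)) next
    cand_idx <- c(cand_idx, .dendrogram_clusters(s, min_size, min(max_size, p - 2L)))
  }
  candidates <- .order_candidates(cand_idx, panel)
  if (!length(candidates))
    stop("no candidate modules (degenerate panel)", call. = FALSE)

  I <- matrix(NA_real_, length(candidates), length(hours),
              dimnames = list(NULL, hours))
  for (j in seq_along(hours)) {
    sds <- attr(summ[[j]], "sds")
    for (i in seq_along(candidates)) {
      idx <- match(candidates[[i]], panel)
      I[i, j] <- .stats_from_summary(summ[[j]], sds, idx, epsilon)$I
    }
  }
  post <- setdiff(hours, base_key)
  fold <- I[, post, drop = FALSE] / (I[, base_key] + epsilon)
  key_fold <- apply(fold, 1, max)
  peak_hour <- post[apply(fold, 1, which.max)]
  max_I <- apply(I[, post, drop = FALSE], 1, max)
  labels <- vapply(candidates, function(s) paste(sort(s), collapse = ","), "")
  ord <- order(-key_fold, -max_I, labels)

  modules <- data.frame(rank = seq_along(ord),
                        members = labels[ord],
                        size = lengths(candidates)[ord],
                        fold_change = key_fold[ord],
                        peak_hour = peak_hour[ord],
                        stringsAsFactors = FALSE)
  modules <- cbind(modules,
                   stats::setNames(as.data.frame(I[ord, , drop = FALSE]),
                                   paste0("I_", hours)))
  rownames(modules) <- NULL

  # ranked marker list: members by SD fold change at each module's peak hour
  sd_base <- attr(summ[[base_key]], "sds")
  marker_order <- character(0)
  for (r in ord) {
    mem <- candidates[[r]]
    sd_pk <- attr(summ[[peak_hour[r]]], "sds")[match(mem, panel)]
    sd_b <- sd_base[match(mem, panel)]
    fc <- sd_pk / pmax(sd_b, .Machine$double.eps)
    mem <- mem[order(-fc, mem)]
    marker_order <- c(marker_order, setdiff(mem, marker_order))
    if (length(marker_order) >= min(k, p)) break
  }
  structure(list(patient_id = sample$patient_id, group = sample$group,
                 modules = modules,
                 best_members = strsplit(modules$members[1], ",")[[1]],
                 best_trajectory = stats::setNames(as.numeric(I[ord[1], ]), hours),
                 marker_order = marker_order,
                 k = as.integer(k), baseline_hour = baseline_hour),
            class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat(sprintf("<dnb_result> %s (%s): best module {%s}, fold change %.2f at %s h\n",
              x$patient_id, x$group, x$modules$members[1],
              x$modules$fold_change[1], x$modules$peak_hour[1]))
  cat(" top markers:", paste(top_markers(x), collapse = ", "), "\n")
  invisible(x)
}

#' Top dynamical markers of one sample
#'
#' The first `k` markers of the sample's ranked marker list (see
#' [rank_modules]). When the panel holds fewer than `k` markers, all are
#' returned with a warning.
#'
#' @param result a `dnb_result`.
#' @param k number of markers (default, the `k` the result was ranked with).
#' @return Character vector of marker names, length `k` (or panel size).
#' @export
top_markers <- function(result, k = result$k) {
  stopifnot(inherits(result, "dnb_result"))
  if (length(result$marker_order) < k) {
    warning(sprintf("only %d markers available; returning all",
                    length(result$marker_order)), call. = FALSE)
    return(result$marker_order)
  }
  result$marker_order[seq_len(k)]
}

#' Marker-permutation null of the composite index
#'
#' Null distribution of the best candidate module's composite index under
#' independent permutation of each marker's cells, which preserves
#' marginals while destroying inter-marker correlation. Used to judge
#' whether an observed candidate index exceeds chance coupling.
#'
#' @param m a [dnb_expression].
#' @param n_perm number of permutations (default 100).
#' @param min_size,max_size candidate size bounds.
#' @param seed integer seed.
#' @param epsilon index guard.
#' @return Numeric vector of `n_perm` null maximum index values.
#' @export
dnb_null_index <- function(m, n_perm = 100, min_size = 2, max_size = 8,
                           seed = 1L, epsilon = 1e-6) {
  stopifnot(inherits(m, "dnb_expression"))
  set.seed(as.integer(seed))
  p <- length(m$marker_names)
  vapply(seq_len(n_perm), function(b) {
    V <- apply(m$values, 2, sample)
    absC <- .abs_cor(V)
    sets <- .dendrogram_clusters(absC, min_size, min(max_size, p - 2L))
    if (!length(sets)) return(0)
    max(vapply(sets, function(idx)
      .stats_from_summary(absC, attr(absC, "sds"), idx, epsilon)$I, numeric(1)))
  }, numeric(1))
}
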
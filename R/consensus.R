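# Consensus DNB core: pool each patient's top dynamical markers and keep
# the recurrent ones. Recurrence across patients is what separates a
# cohort-level biomarker set from per-sample noise.

#' Cross-sample frequency of top dynamical markers
#'
#' Counts, for every marker, the number of samples in whose top-`k` list it
#' appears. Optionally restricted to a subset of clinical groups (e.g. the
#' SLE samples only).
#'
#' @param results list of `dnb_result` objects, all ranked with the same `k`.
#' @param k the top-list length (must match every result's `k`).
#' @param restrict_to_group optional character vector of groups to count.
#' @return Named integer vector, sorted by decreasing count then marker
#'   name; attribute `n_samples` records how many samples were pooled.
#' @export
marker_frequency <- function(results, k = 5, restrict_to_group = NULL) {
  if (!length(results))
    stop("need at least one sample result", call. = FALSE)
  ks <- vapply(results, `[[`, 0L, "k")
  if (any(ks != k))
    stop("results were ranked with mixed k; refusing to pool", call. = FALSE)
  if (!is.null(restrict_to_group)) {
    keep <- vapply(results, `[[`, "", "group") %in% restrict_to_group
    results <- results[keep]
    if (!length(results)) {
      warning("no samples in the requested group(s); empty frequency map",
              call. = FALSE)
      return(structure(stats::setNames(integer(0), character(0)),
                       n_samples = 0L))
    }
  }
  tops <- lapply(results, top_markers, k = k)
  tab <- table(unlist(tops))
  freq <- stats::setNames(as.integer(tab), names(tab))
  freq <- freq[order(-freq, names(freq))]
  attr(freq, "n_samples") <- length(results)
  freq
}

#' Select the consensus DNB core set
#'
#' Two selection rules mirror the two readings of a recurrence analysis:
#' `top_m` keeps the `m` most frequent markers (the fixed-size scoring
#' core, default m = 4), `min_frequency` keeps every marker appearing in at
#' least `f_min` samples' top lists (default 5). Frequency ties at the
#' selection boundary break lexicographically and are always reported.
#'
#' @param freq named frequency vector from [marker_frequency].
#' @param rule `"top_m"` or `"min_frequency"`.
#' @param m core size for `top_m`.
#' @param f_min count threshold for `min_frequency`.
#' @return An object of class `dnb_core`: list with `markers` (ordered by
#'   frequency, ties lexicographic), `frequency`, `rule`, `parameter`.
#' @export
select_core <- function(freq, rule = c("top_m", "min_frequency"),
                        m = 4, f_min = 5) {
  rule <- match.arg(rule)
  if (!length(freq))
    stop("empty frequency map", call. = FALSE)
  freq <- freq[order(-freq, names(freq))]
  if (rule == "top_m") {
    if (m > length(freq)) {
      warning(sprintf("m = %d exceeds the %d distinct markers; keeping all",
                      m, length(freq)), call. = FALSE)
      m <- length(freq)
    }
    cut_count <- freq[m]
    if (m < length(freq) && freq[m + 1L] == cut_count)
      message("frequency tie at the selection boundary (count ", cut_count,
              "): ", paste(names(freq)[freq == cut_count], collapse = ", "),
              "; resolved lexicographically")
    markers <- names(freq)[seq_len(m)]
    parameter <- c(m = m)
  } else {
    markers <- names(freq)[freq >= f_min]
    parameter <- c(f_min = f_min)
    if (!length(markers))
      warning(sprintf("no marker reaches frequency %d; empty core", f_min),
              call. = FALSE)
  }
  structure(list(markers = markers, frequency = freq, rule = rule,
                 parameter = parameter),
            class = "dnb_core")
}

#' @export
print.dnb_core <- function(x, ...) {
  cat(sprintf("<dnb_core> rule %s (%s = %d): %s\n", x$rule,
              names(x$parameter), x$parameter,
              if (length(x$markers)) paste(x$markers, collapse = ", ") else "<empty>"))
  invisible(x)
}
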
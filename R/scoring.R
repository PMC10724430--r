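# Per-patient DNB scoring on a fixed cohort-wide core set, the 2h-4h score
# difference, clinical correlations and the trajectory-level outcome call.

#' DNB score trajectory of one patient
#'
#' Scores the fixed consensus core at every timepoint of one patient:
#' `score(t) = composite_index(module_stats(matrix_t, core))`. No
#' re-ranking happens here -- the core is fixed cohort-wide, which is what
#' makes trajectories comparable across patients. The score difference
#' `delta = score(2 h) - score(4 h)` is precomputed.
#'
#' @param sample a [dnb_sample].
#' @param core a `dnb_core` or character vector of at least 2 marker names,
#'   all present in the sample's panel.
#' @param epsilon composite-index guard.
#' @return An object of class `dnb_trajectory`: `patient_id`, `group`,
#'   `score` (named by hour), `delta`, `prediction` (`NA` until
#'   [predict_outcome]), `threshold_used`.
#' @export
score_trajectory <- function(sample, core, epsilon = 1e-6) {
  stopifnot(inherits(sample, "dnb_sample"))
  markers <- if (inherits(core, "dnb_core")) core$markers else as.character(core)
  if (length(markers) < 2L)
    stop("the scoring core needs at least 2 markers", call. = FALSE)
  missing <- setdiff(markers, sample_panel(sample))
  if (length(missing))
    stop(sprintf("core marker(s) absent from the panel of %s: %s",
                 sample$patient_id, paste(missing, collapse = ", ")),
         call. = FALSE)
  score <- vapply(sample$matrices, function(m)
    composite_index(module_stats(m, markers, epsilon), epsilon), numeric(1))
  traj <- structure(list(patient_id = sample$patient_id, group = sample$group,
                         core = markers,
                         score = score,
                         delta = NA_real_,
                         prediction = NA_character_,
                         threshold_used = NA_real_),
                    class = "dnb_trajectory")
  traj$delta <- delta_score(traj)
  traj
}

#' @export
print.dnb_trajectory <- function(x, ...) {
  cat(sprintf("<dnb_trajectory> %s (%s): %s; delta(2h-4h) = %.4f%s\n",
              x$patient_id, x$group,
              paste(sprintf("%s h: %.3f", names(x$score), x$score),
                    collapse = ", "),
              x$delta,
              if (!is.na(x$prediction)) paste0("; ", x$prediction) else ""))
  invisible(x)
}

#' DNB score difference between two hours
#'
#' `score(t_a) - score(t_b)`, by default the 2 h minus 4 h difference --
#' the prognostic quantity: a prompt surge that has already relaxed by 4 h
#' gives a positive difference, a delayed or blunted response a small or
#' negative one.
#'
#' @param traj a `dnb_trajectory`.
#' @param t_a,t_b hours (defaults 2 and 4).
#' @return The score difference.
#' @export
delta_score <- function(traj, t_a = 2, t_b = 4) {
  stopifnot(inherits(traj, "dnb_trajectory"))
  ka <- .hour_key(t_a); kb <- .hour_key(t_b)
  miss <- setdiff(c(ka, kb), names(traj$score))
  if (length(miss))
    stop("hour(s) missing from the trajectory: ", paste(miss, collapse = ", "),
         call. = FALSE)
  unname(traj$score[ka] - traj$score[kb])
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 in practice
.permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  for (m in 2:n) {
    out <- matrix(0L, nrow(P) * m, m)
    for (pos in seq_len(m)) {
      block <- (pos - 1L) * nrow(P) + seq_len(nrow(P))
      if (pos > 1L) out[block, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L)]
      out[block, pos] <- m
      if (pos < m) out[block, (pos + 1L):m] <- P[, pos:(m - 1L), drop = FALSE]
    }
    P <- out
  }
  P
}

#' Spearman correlation of score differences with a clinical variable
#'
#' Spearman rank correlation (midranks under ties) between per-patient
#' score differences and a clinical activity measure, with a two-sided
#' p-value: exact by full permutation enumeration for n <= 9 (cohort arms
#' sit at that boundary), large-sample t approximation otherwise.
#'
#' @param deltas named numeric vector (patient id -> score difference).
#' @param clinical clinical data.frame with `patient_id` and the variable.
#' @param variable `"SLEDAI"` or `"ESR"`.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
clinical_correlation <- function(deltas, clinical,
                                 variable = c("SLEDAI", "ESR")) {
  variable <- match.arg(variable)
  idx <- match(names(deltas), clinical$patient_id)
  v <- clinical[[variable]][idx]
  keep <- !is.na(v) & !is.na(deltas)
  x <- unname(deltas[keep]); y <- as.numeric(v[keep])
  n <- length(x)
  if (n < 5L)
    stop("fewer than 5 paired observations", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    warning(structure(class = c("dnb_undefined_correlation", "warning", "condition"),
                      list(message = paste0("constant ", variable,
                                            " (or deltas); correlation undefined"),
                           call = sys.call(-1))))
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    P <- .permutations(n)
    # rho is monotone in sum(rx * ry_perm); permute one rank vector
    s_perm <- as.numeric(matrix(ry[P], nrow(P), n) %*% rx)
    rho_perm <- (s_perm - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Trajectory-level outcome call from the score difference
#'
#' Classifies one trajectory by the sign of its 2h-4h score difference:
#' at or above the threshold (default 0) is a remission trajectory, below
#' it a flare trajectory; differences within `band` of the threshold are
#' indeterminate. The direction is fixed by the negative correlation of
#' the score difference with disease activity: a prompt, already-relaxed
#' response (positive difference) marks the resilient, remission-bound
#' state.
#'
#' @param traj a `dnb_trajectory`.
#' @param threshold decision cutoff on the score difference (default 0).
#' @param band half-width of the indeterminate zone (default 0).
#' @return The trajectory with `prediction` (`"remission"`, `"flare"` or
#'   `"indeterminate"`) and `threshold_used` filled in.
#' @export
predict_outcome <- function(traj, threshold = 0, band = 0) {
  stopifnot(inherits(traj, "dnb_trajectory"))
  d <- traj$delta
  traj$prediction <-
    if (band > 0 && abs(d - threshold) < band) "indeterminate"
    else if (d >= threshold) "remission" else "flare"
  traj$threshold_used <- threshold
  traj
}

#' Cohort-level DNB report
#'
#' Deterministic summary of a scored cohort: one row per patient (scores,
#' score difference, outcome call, clinical outcome when known), the mean
#' score trajectory per clinical group (mean of patient-level scores), and
#' the Spearman correlation of the score difference with SLEDAI and ESR.
#' Input order never affects the report (patients sort by id).
#'
#' @param trajectories list of `dnb_trajectory` (run [predict_outcome]
#'   first to include calls).
#' @param clinical optional clinical data.frame.
#' @return An object of class `dnb_report`: list with `patients`,
#'   `group_means`, `correlations`.
#' @export
cohort_report <- function(trajectories, clinical = NULL) {
  if (!length(trajectories))
    stop("need at least one trajectory", call. = FALSE)
  ids <- vapply(trajectories, `[[`, "", "patient_id")
  trajectories <- trajectories[order(ids)]
  hours <- names(trajectories[[1]]$score)
  pat <- data.frame(patient_id = sort(ids),
                    group = vapply(trajectories, `[[`, "", "group"),
                    stringsAsFactors = FALSE)
  S <- t(vapply(trajectories, `[[`, numeric(length(hours)), "score"))
  colnames(S) <- paste0("score_", hours)
  pat <- cbind(pat, S)
  pat$delta <- vapply(trajectories, `[[`, 0, "delta")
  pat$prediction <- vapply(trajectories, `[[`, "", "prediction")
  if (!is.null(clinical)) {
    pat$outcome <- clinical$outcome[match(pat$patient_id, clinical$patient_id)]
  }
  rownames(pat) <- NULL
  gm <- stats::aggregate(S, by = list(group = pat$group), FUN = mean)
  gm <- gm[order(gm$group), , drop = FALSE]
  rownames(gm) <- NULL
  correlations <- NULL
  if (!is.null(clinical)) {
    deltas <- stats::setNames(pat$delta, pat$patient_id)
    rows <- lapply(c("SLEDAI", "ESR"), function(v) {
      res <- tryCatch(clinical_correlation(deltas, clinical, v),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(variable = v, rho = res$rho, p = res$p, n = res$n,
                 method = res$method, stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) correlations <- do.call(rbind, rows)
  }
  structure(list(patients = pat, group_means = gm,
                 correlations = correlations),
            class = "dnb_report")
}

#' @export
print.dnb_report <- function(x, ...) {
  cat("<dnb_report>\n\nPer-patient score differences (2 h - 4 h):\n")
  print(x$patients[, c("patient_id", "group", "delta", "prediction",
                       intersect("outcome", names(x$patients)))],
        row.names = FALSE, digits = 4)
  cat("\nGroup mean trajectories:\n")
  print(x$group_means, row.names = FALSE, digits = 4)
  if (!is.null(x$correlations)) {
    cat("\nSpearman correlation of the score difference with clinical activity:\n")
    print(x$correlations, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
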
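#' Run the full DNB pipeline on a cohort
#'
#' Convenience wrapper chaining the four analysis stages: per-sample module
#' ranking ([rank_modules]), cross-sample marker frequencies
#' ([marker_frequency]), consensus core selection ([select_core]), and
#' per-patient score trajectories with outcome calls and the cohort report
#' ([score_trajectory], [predict_outcome], [cohort_report]).
#'
#' @param cohort a `dnb_cohort` (simulated or read from disk).
#' @param k top-marker list length per sample (default 5).
#' @param rule,m,f_min core selection rule and parameter (see
#'   [select_core]); default `top_m` with `m = 4`.
#' @param restrict_to_group optional group restriction for the frequency
#'   count (default: all samples).
#' @param threshold,band outcome-call settings (see [predict_outcome]).
#' @param min_size,max_size candidate module size bounds.
#' @return List with `results`, `frequency`, `core`, `trajectories`,
#'   `report`.
#' @export
run_dnb <- function(cohort, k = 5, rule = c("top_m", "min_frequency"),
                    m = 4, f_min = 5, restrict_to_group = NULL,
                    threshold = 0, band = 0, min_size = 2, max_size = 8) {
  stopifnot(inherits(cohort, "dnb_cohort"))
  rule <- match.arg(rule)
  results <- lapply(cohort$samples, rank_modules, k = k,
                    min_size = min_size, max_size = max_size)
  freq <- marker_frequency(results, k = k,
                           restrict_to_group = restrict_to_group)
  core <- select_core(freq, rule = rule, m = m, f_min = f_min)
  trajectories <- lapply(cohort$samples, function(s)
    predict_outcome(score_trajectory(s, core), threshold = threshold,
                    band = band))
  report <- cohort_report(trajectories, cohort$clinical)
  list(results = results, frequency = freq, core = core,
       trajectories = trajectories, report = report)
}

#' Outcome-call accuracy against recorded outcomes
#'
#' Fraction of patients with a known follow-up outcome whose trajectory
#' call matches it. Indeterminate calls count as errors.
#'
#' @param report a `dnb_report` whose patient table carries `outcome`.
#' @return Accuracy in [0, 1] (`NA` if no outcomes are known).
#' @export
prediction_accuracy <- function(report) {
  stopifnot(inherits(report, "dnb_report"))
  pat <- report$patients
  if (is.null(pat$outcome)) return(NA_real_)
  known <- !is.na(pat$outcome) & pat$outcome != "unknown"
  if (!any(known)) return(NA_real_)
  mean(pat$prediction[known] == pat$outcome[known])
}
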
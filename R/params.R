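#' Simulation parameters for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a marker panel of
#' CyTOF scale, a planted DNB module whose member standard deviations and
#' intra-module correlations surge toward a transition timepoint while the
#' module-to-background correlation drops, and an outcome link tying the
#' latent 2h-4h score difference to remission versus flare.
#'
#' Correlation and SD trajectories are literal per-timepoint vectors (one
#' value per hour in `timepoints`), which keeps the planted truth
#' unambiguous. Every implied block correlation matrix must be positive
#' semi-definite; infeasible specifications are rejected at construction
#' with the offending timepoint named. With `rho_bg = 0.05` and a 4-member
#' module in a 25-marker panel the feasible uniform module-to-background
#' correlation at a timepoint where `rho_in = rho_bg` is bounded near 0.165,
#' which is why the default `rho_out` starts at 0.15 and falls to 0.10 at
#' the transition.
#'
#' @param n_markers panel size (default 25, the scale of a CyTOF functional
#'   panel).
#' @param module_markers indices of the planted DNB members (default 1:4).
#' @param n_cells cells per (patient, timepoint) (default 2000).
#' @param timepoints stimulation hours, strictly increasing (fixed design
#'   `c(0, 0.5, 1, 2, 4)`).
#' @param rho_in intra-module correlation per timepoint, each in [0, 1).
#' @param rho_bg background pairwise correlation (default 0.05).
#' @param sigma_in module-member SD per timepoint (arcsinh units).
#' @param sigma_bg background SD (default 1).
#' @param rho_out module-to-background correlation per timepoint.
#' @param transition_time hour at which `rho_in` / `sigma_in` peak
#'   (default 2).
#' @param outcome_link list with `slope` and `noise_sd`: the probability of
#'   a remission outcome is `plogis(slope * latent_delta + noise)`;
#'   `slope = Inf` gives the deterministic sign link.
#' @param location constant added to every simulated value so intensities
#'   sit on the nonnegative part of the arcsinh scale (default 2).
#' @param marker_names optional marker names (default `M01`, `M02`, ...).
#' @param seed integer master seed; per-(patient, timepoint) substreams are
#'   derived from it (see [simulate_sample]).
#' @return An object of class `dnb_sim_params`.
#' @export
simulation_params <- function(n_markers = 25,
                              module_markers = 1:4,
                              n_cells = 2000,
                              timepoints = DNB_TIMEPOINTS,
                              rho_in = c(0.05, 0.20, 0.45, 0.85, 0.25),
                              rho_bg = 0.05,
                              sigma_in = c(1, 1.4, 2.1, 3, 1.4),
                              sigma_bg = 1,
                              rho_out = c(0.15, 0.14, 0.12, 0.10, 0.14),
                              transition_time = 2,
                              outcome_link = list(slope = 3, noise_sd = 0.2),
                              location = 2,
                              marker_names = NULL,
                              seed = 1L) {
  nt <- length(timepoints)
  if (nt < 2L || any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (length(rho_in) == 1L) rho_in <- rep(rho_in, nt)
  if (length(sigma_in) == 1L) sigma_in <- rep(sigma_in, nt)
  if (length(rho_out) == 1L) rho_out <- rep(rho_out, nt)
  if (length(rho_in) != nt || length(sigma_in) != nt || length(rho_out) != nt)
    stop("rho_in, sigma_in and rho_out must have one value per timepoint",
         call. = FALSE)
  if (n_markers < 4)
    stop("need at least 4 markers", call. = FALSE)
  module_markers <- sort(unique(as.integer(module_markers)))
  if (length(module_markers) < 2L || any(module_markers < 1L) ||
      any(module_markers > n_markers))
    stop("module_markers must be >= 2 indices within 1..n_markers", call. = FALSE)
  if (n_markers - length(module_markers) < 2L)
    stop("need at least 2 background markers", call. = FALSE)
  if (any(rho_in < 0) || any(rho_in >= 1) || any(abs(rho_out) >= 1) ||
      rho_bg < 0 || rho_bg >= 1)
    stop("correlations must lie in [0, 1) (rho_out in (-1, 1))", call. = FALSE)
  if (any(sigma_in <= 0) || sigma_bg <= 0)
    stop("SDs must be positive", call. = FALSE)
  if (!transition_time %in% timepoints)
    stop("transition_time must be one of the timepoints", call. = FALSE)
  if (is.null(marker_names))
    marker_names <- sprintf("M%02d", seq_len(n_markers))
  if (length(marker_names) != n_markers || anyDuplicated(marker_names))
    stop("marker_names must be n_markers unique names", call. = FALSE)
  p <- structure(list(n_markers = as.integer(n_markers),
                      module_markers = module_markers,
                      n_cells = as.integer(n_cells),
                      timepoints = timepoints,
                      rho_in = rho_in, rho_bg = rho_bg,
                      sigma_in = sigma_in, sigma_bg = sigma_bg,
                      rho_out = rho_out,
                      transition_time = transition_time,
                      outcome_link = outcome_link,
                      location = location,
                      marker_names = as.character(marker_names),
                      seed = as.integer(seed)),
                 class = "dnb_sim_params")
  for (k in seq_len(nt)) {
    R <- block_correlation(n_markers, module_markers,
                           rho_in[k], rho_out[k], rho_bg)
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(sprintf(paste0("correlation specification at timepoint %s h is not ",
                          "positive semi-definite (min eigenvalue %.4f)"),
                   .hour_key(timepoints[k]), ev), call. = FALSE)
  }
  p
}

#' @export
print.dnb_sim_params <- function(x, ...) {
  cat(sprintf("<dnb_sim_params> %d markers, module {%s}, %d cells, seed %d\n",
              x$n_markers, paste(x$marker_names[x$module_markers], collapse = ","),
              x$n_cells, x$seed))
  cat(" hours:   ", paste(.hour_key(x$timepoints), collapse = " "), "\n")
  cat(" rho_in:  ", paste(format(x$rho_in), collapse = " "), "\n")
  cat(" sigma_in:", paste(format(x$sigma_in), collapse = " "), "\n")
  cat(" rho_out: ", paste(format(x$rho_out), collapse = " "), "\n")
  invisible(x)
}

#' Block correlation matrix of the planted-module model
#'
#' Exchangeable three-block structure: `rho_in` among module members,
#' `rho_out` between members and background, `rho_bg` elsewhere.
#'
#' @param p panel size.
#' @param members member indices.
#' @param rho_in,rho_out,rho_bg the three correlation levels.
#' @return A `p x p` correlation matrix.
#' @export
block_correlation <- function(p, members, rho_in, rho_out, rho_bg) {
  R <- matrix(rho_bg, p, p)
  R[members, ] <- rho_out
  R[, members] <- rho_out
  R[members, members] <- rho_in
  diag(R) <- 1
  R
}
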
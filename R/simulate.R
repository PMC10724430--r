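#' @keywords internal
#' Deterministic substream seed for one (patient, timepoint) draw.
#' Derived from the master seed by a fixed counter scheme so that adding a
#' patient to a cohort never perturbs the cells of another patient:
#' seed * 7919 + patient_index * 104729 + timepoint_index * 7907 (mod 2^31-1).
.substream_seed <- function(seed, patient_index, timepoint_index) {
  s <- (as.double(seed) * 7919 + as.double(patient_index) * 104729 +
          as.double(timepoint_index) * 7907) %% 2147483647
  as.integer(s)
}

.draw_mvn <- function(n, R, sds, location) {
  U <- chol(R + diag(1e-10, nrow(R)))   # jitter admits exactly singular specs
  Z <- matrix(stats::rnorm(n * nrow(R)), n, nrow(R))
  sweep(Z %*% U, 2, sds, `*`) + location
}

#' Simulate one patient's stimulation time course
#'
#' Draws, for each timepoint, `n_cells` cells from a multivariate normal on
#' the arcsinh scale with the block correlation and SD structure of
#' `params` at that timepoint, shifted by `params$location`. Matrices are
#' reproducible from the master seed via per-(patient, timepoint)
#' substreams, keyed by `patient_index`.
#'
#' @param params a [simulation_params] object.
#' @param patient_id character id recorded in the sample.
#' @param group clinical group label.
#' @param patient_index integer key of this patient in the substream
#'   scheme (default 1).
#' @return A [dnb_sample].
#' @export
simulate_sample <- function(params, patient_id, group = "HC",
                            patient_index = 1L) {
  stopifnot(inherits(params, "dnb_sim_params"))
  mats <- vector("list", length(params$timepoints))
  names(mats) <- .hour_key(params$timepoints)
  for (k in seq_along(params$timepoints)) {
    R <- block_correlation(params$n_markers, params$module_markers,
                           params$rho_in[k], params$rho_out[k], params$rho_bg)
    sds <- rep(params$sigma_bg, params$n_markers)
    sds[params$module_markers] <- params$sigma_in[k]
    set.seed(.substream_seed(params$seed, patient_index, k))
    X <- .draw_mvn(params$n_cells, R, sds, params$location)
    mats[[k]] <- dnb_expression(X, params$marker_names, transform = "arcsinh",
                                cofactor = 5)
  }
  dnb_sample(patient_id, group, mats)
}

# One-step delay of a per-timepoint trajectory: the surge reaches each level
# one timepoint later, so a peak at 2 h moves to 4 h.
.delay_one_step <- function(v) c(v[1], v[-length(v)])

# Patient-level parameter object: canonical (early-peak) trajectories scaled
# by a group amplitude, then mixed with their one-step-delayed variant with
# weight w (the response delay). Both endpoints are PSD-checked by
# simulation_params, and the mixture of two PSD block structures is PSD.
.patient_params <- function(params, amplitude, w) {
  early_rho <- params$rho_bg + amplitude * (params$rho_in - params$rho_bg)
  early_sig <- params$sigma_bg + amplitude * (params$sigma_in - params$sigma_bg)
  early_out <- params$rho_out
  rho_in <- (1 - w) * early_rho + w * .delay_one_step(early_rho)
  sigma_in <- (1 - w) * early_sig + w * .delay_one_step(early_sig)
  rho_out <- (1 - w) * early_out + w * .delay_one_step(early_out)
  simulation_params(n_markers = params$n_markers,
                    module_markers = params$module_markers,
                    n_cells = params$n_cells,
                    timepoints = params$timepoints,
                    rho_in = pmin(rho_in, 0.999), rho_bg = params$rho_bg,
                    sigma_in = sigma_in, sigma_bg = params$sigma_bg,
                    rho_out = rho_out,
                    transition_time = params$transition_time,
                    outcome_link = params$outcome_link,
                    location = params$location,
                    marker_names = params$marker_names,
                    seed = params$seed)
}

# Latent (noiseless) DNB score difference between 2 h and 4 h for one
# patient, computed by the real scoring formula on the population block
# correlation and SDs -- truth independent of cell sampling noise.
.latent_delta <- function(pp, epsilon = 1e-6) {
  idx <- match(c(2, 4), pp$timepoints)
  I <- vapply(idx, function(k) {
    R <- block_correlation(pp$n_markers, pp$module_markers,
                           pp$rho_in[k], pp$rho_out[k], pp$rho_bg)
    sds <- rep(pp$sigma_bg, pp$n_markers)
    sds[pp$module_markers] <- pp$sigma_in[k]
    s <- .stats_from_summary(abs(R), sds, pp$module_markers, epsilon)
    s$I
  }, numeric(1))
  I[1] - I[2]
}

#' Default per-group response heterogeneity
#'
#' Each patient receives a response-delay weight `w` drawn uniformly from the
#' group's `delay` range: `w = 0` is the canonical early (2 h) surge, `w = 1`
#' the fully delayed (4 h) surge characteristic of a blunted late response.
#' `amplitude` scales the `rho_in` / `sigma_in` surge above background.
#' Healthy controls respond promptly; active SLE is shifted toward delayed,
#' blunted responses; remission SLE sits in between.
#'
#' @return Named list of per-group effect settings.
#' @export
default_group_effects <- function() {
  list(HC   = list(amplitude = 1, delay = c(0.00, 0.25)),
       aSLE = list(amplitude = 1, delay = c(0.35, 0.95)),
       rSLE = list(amplitude = 1, delay = c(0.05, 0.65)))
}

#' Simulate a cohort with planted tipping-point structure
#'
#' Generates one [dnb_sample] per patient across healthy controls (HC),
#' active SLE (aSLE) and remission SLE (rSLE), a clinical table (SLEDAI,
#' ESR, follow-up outcome) and a truth record. Disease activity is tied to
#' the response-delay weight `w` (see [default_group_effects]); the latent
#' 2h-4h score difference is computed from each patient's noiseless
#' population covariance, and for SLE patients the follow-up outcome is
#' drawn with probability `plogis(slope * latent_delta + noise)`
#' (`slope = Inf`: deterministic sign link).
#'
#' @param params a [simulation_params] object (cohort-level defaults).
#' @param n_per_group named counts for HC / aSLE / rSLE, each >= 1.
#' @param group_effects per-group amplitude and delay ranges; default
#'   [default_group_effects()].
#' @return An object of class `dnb_cohort`: list with `samples`, `clinical`
#'   (data.frame) and `truth`.
#' @export
simulate_cohort <- function(params,
                            n_per_group = c(HC = 4, aSLE = 6, rSLE = 6),
                            group_effects = default_group_effects()) {
  stopifnot(inherits(params, "dnb_sim_params"))
  if (!all(c("HC", "aSLE", "rSLE") %in% names(n_per_group)) ||
      any(n_per_group < 1))
    stop("n_per_group must name HC, aSLE and rSLE with counts >= 1", call. = FALSE)
  slope <- params$outcome_link$slope
  noise_sd <- params$outcome_link$noise_sd
  groups <- rep(c("HC", "aSLE", "rSLE"),
                times = n_per_group[c("HC", "aSLE", "rSLE")])
  ids <- unlist(lapply(c("HC", "aSLE", "rSLE"), function(g)
    sprintf("%s%02d", g, seq_len(n_per_group[[g]]))))
  n <- length(ids)
  samples <- vector("list", n); names(samples) <- ids
  clin <- data.frame(patient_id = ids, group = groups,
                     SLEDAI = NA_integer_, ESR = NA_real_,
                     outcome = "unknown", stringsAsFactors = FALSE)
  delay <- stats::setNames(numeric(n), ids)
  latent <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n)) {
    g <- groups[i]
    eff <- group_effects[[g]]
    # patient-level randomness (delay, clinical noise, outcome) uses its own
    # substream so cell draws are unaffected
    set.seed(.substream_seed(params$seed, i, 99L))
    w <- stats::runif(1, eff$delay[1], eff$delay[2])
    delay[i] <- w
    pp <- .patient_params(params, eff$amplitude, w)
    latent[i] <- .latent_delta(pp)
    raw_sledai <- 2 + 18 * w + stats::rnorm(1, 0, 1)
    if (g == "HC") {
      clin$SLEDAI[i] <- sample(0:2, 1)
    } else if (g == "aSLE") {
      clin$SLEDAI[i] <- as.integer(min(24, max(6, round(raw_sledai))))
    } else {
      clin$SLEDAI[i] <- as.integer(min(5, max(0, round(raw_sledai - 6))))
    }
    clin$ESR[i] <- max(2, round(8 + 80 * w + stats::rnorm(1, 0, 6)))
    if (g != "HC") {
      if (is.infinite(slope)) {
        clin$outcome[i] <- if (latent[i] >= 0) "remission" else "flare"
      } else {
        p_rem <- stats::plogis(slope * latent[i] + stats::rnorm(1, 0, noise_sd))
        clin$outcome[i] <- if (stats::runif(1) < p_rem) "remission" else "flare"
      }
    }
    samples[[i]] <- simulate_sample(pp, ids[i], g, patient_index = i)
  }
  truth <- structure(list(params = params,
                          module_markers = params$module_markers,
                          module_names = params$marker_names[params$module_markers],
                          delay = delay,
                          latent_delta = latent,
                          group_effects = group_effects),
                     class = "dnb_truth")
  structure(list(samples = samples, clinical = clin, truth = truth),
            class = "dnb_cohort")
}

#' @export
print.dnb_cohort <- function(x, ...) {
  cat(sprintf("<dnb_cohort> %d patients (%s)\n", length(x$samples),
              paste(sprintf("%s=%d", names(table(x$clinical$group)),
                            table(x$clinical$group)), collapse = ", ")))
  if (!is.null(x$truth))
    cat(" planted module:", paste(x$truth$module_names, collapse = ", "), "\n")
  invisible(x)
}

#' Planted truth of a simulated cohort
#'
#' Read-only access to the generator's ground truth: planted module
#' membership, per-patient response delays and latent 2h-4h score
#' differences. Cohorts built from real data carry no truth; asking for it
#' raises a classed error (`dnb_absent_truth_error`) rather than returning
#' an empty record.
#'
#' @param cohort a `dnb_cohort`.
#' @return The `dnb_truth` record.
#' @export
planted_truth <- function(cohort) {
  stopifnot(inherits(cohort, "dnb_cohort"))
  if (is.null(cohort$truth))
    stop(structure(class = c("dnb_absent_truth_error", "error", "condition"),
                   list(message = "cohort carries no planted truth (real data?)",
                        call = sys.call(-1))))
  cohort$truth
}
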
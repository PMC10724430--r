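# Synthetic cohort generator: planted block-correlation structure,
# determinism, PSD guards, truth record and outcome link.

test_that("null scenario shows no module/background separation", {
  p <- simulation_params(n_markers = 10, module_markers = 1:3, n_cells = 5000,
                         rho_in = 0.05, rho_bg = 0.05, sigma_in = 1,
                         sigma_bg = 1, rho_out = 0.05, seed = 11)
  s <- simulate_sample(p, "null01")
  V <- s$matrices[["2"]]$values
  C <- cor(V)
  mem <- p$module_markers
  in_cor <- mean(C[mem, mem][upper.tri(C[mem, mem])])
  bg <- setdiff(seq_len(10), mem)
  bg_cor <- mean(C[bg, bg][upper.tri(C[bg, bg])])
  expect_lt(abs(in_cor - bg_cor), 0.02)
})

test_that("empirical intra-module correlation matches the generating value", {
  p <- simulation_params(n_markers = 10, module_markers = 1:4, n_cells = 5000,
                         rho_in = c(0.05, 0.2, 0.4, 0.8, 0.3),
                         rho_out = c(0.1, 0.1, 0.1, 0.1, 0.1), seed = 3)
  s <- simulate_sample(p, "x")
  C <- cor(s$matrices[["2"]]$values[, 1:4])
  expect_lt(abs(mean(C[upper.tri(C)]) - 0.8), 0.03)
  # and member SD tracks sigma_in at the transition
  sds <- apply(s$matrices[["2"]]$values[, 1:4], 2, sd)
  expect_lt(abs(mean(sds) - 3), 0.15)
})

test_that("samples are reproducible from seed and substreams are independent", {
  p <- simulation_params(n_markers = 8, module_markers = 1:3, n_cells = 200,
                         seed = 42)
  a <- simulate_sample(p, "a", patient_index = 1L)
  b <- simulate_sample(p, "a", patient_index = 1L)
  expect_identical(a$matrices, b$matrices)
  # distinct seeds differ
  p2 <- simulation_params(n_markers = 8, module_markers = 1:3, n_cells = 200,
                          seed = 43)
  expect_false(identical(simulate_sample(p2, "a")$matrices[[1]]$values,
                         a$matrices[[1]]$values))
  # a patient's cells do not depend on how many other patients exist
  c1 <- simulate_cohort(p, n_per_group = c(HC = 1, aSLE = 1, rSLE = 1))
  c2 <- simulate_cohort(p, n_per_group = c(HC = 1, aSLE = 1, rSLE = 2))
  expect_identical(c1$samples[["aSLE01"]]$matrices,
                   c2$samples[["aSLE01"]]$matrices)
})

test_that("non-PSD correlation specifications are rejected naming the timepoint", {
  expect_error(
    simulation_params(n_markers = 25, module_markers = 1:4,
                      rho_in = 0.9, rho_bg = 0, rho_out = 0.9),
    "positive semi-definite.*0 h|0 h.*positive semi-definite")
  # infeasible only at one timepoint: that hour is named
  expect_error(
    simulation_params(n_markers = 25, module_markers = 1:4,
                      rho_out = c(0.15, 0.14, 0.12, 0.9, 0.14)),
    "timepoint 2 h")
})

test_that("sample covariance converges to the block covariance with n_cells", {
  dist_at <- function(n) {
    # averaged over a few seeds: the Frobenius error of a single draw is
    # itself random
    mean(vapply(5:7, function(sd_) {
      p <- simulation_params(n_markers = 8, module_markers = 1:3, n_cells = n,
                             seed = sd_)
      k <- match(2, p$timepoints)
      R <- block_correlation(8, 1:3, p$rho_in[k], p$rho_out[k], p$rho_bg)
      sds <- rep(p$sigma_bg, 8); sds[1:3] <- p$sigma_in[k]
      Sigma <- diag(sds) %*% R %*% diag(sds)
      S <- cov(simulate_sample(p, "x")$matrices[["2"]]$values)
      sqrt(sum((S - Sigma)^2))
    }, 0))
  }
  d <- vapply(c(500, 2000, 8000), dist_at, 0)
  expect_true(all(diff(d) < 0))
})

test_that("planted truth records module, delays and one latent delta per patient", {
  p <- simulation_params(n_markers = 8, module_markers = c(2, 5, 7),
                         n_cells = 100, seed = 9)
  co <- simulate_cohort(p, n_per_group = c(HC = 1, aSLE = 1, rSLE = 1))
  tr <- planted_truth(co)
  expect_identical(tr$module_markers, c(2L, 5L, 7L))
  expect_length(tr$latent_delta, 3L)
  expect_named(co$samples, names(tr$latent_delta))
  # real-data path carries no truth: classed error, not an empty record
  d <- withr::local_tempdir()
  write_cohort(co, d)
  real <- read_cohort(file.path(d, "manifest.csv"))
  expect_error(planted_truth(real), class = "dnb_absent_truth_error")
})

test_that("deterministic outcome link labels by the sign of the latent delta", {
  p <- simulation_params(n_markers = 8, module_markers = 1:3, n_cells = 100,
                         outcome_link = list(slope = Inf, noise_sd = 0),
                         seed = 21)
  co <- simulate_cohort(p, n_per_group = c(HC = 1, aSLE = 4, rSLE = 4))
  tr <- planted_truth(co)
  sle <- co$clinical$group != "HC"
  expect_identical(co$clinical$outcome[sle],
                   unname(ifelse(tr$latent_delta[co$clinical$patient_id[sle]] >= 0,
                                 "remission", "flare")))
})

test_that("zero-slope outcome link decouples labels from the latent delta", {
  ps <- lapply(101:112, function(s)
    simulation_params(n_markers = 8, module_markers = 1:3, n_cells = 100,
                      outcome_link = list(slope = 0, noise_sd = 0.2), seed = s))
  pvals <- vapply(ps, function(p) {
    co <- simulate_cohort(p, n_per_group = c(HC = 1, aSLE = 6, rSLE = 6))
    tr <- planted_truth(co)
    sle <- co$clinical$group != "HC"
    sgn <- tr$latent_delta[co$clinical$patient_id[sle]] >= 0
    out <- co$clinical$outcome[sle]
    if (length(unique(out)) < 2L || length(unique(sgn)) < 2L) return(NA_real_)
    fisher.test(table(sgn, out))$p.value
  }, 0)
  pvals <- pvals[!is.na(pvals)]
  expect_gt(length(pvals), 5L)
  expect_gt(mean(pvals), 0.2)   # no systematic association
})

test_that("cohort clinical table honours the SLEDAI group convention", {
  p <- simulation_params(n_markers = 8, module_markers = 1:3, n_cells = 100,
                         seed = 13)
  co <- simulate_cohort(p, n_per_group = c(HC = 2, aSLE = 5, rSLE = 5))
  cl <- co$clinical
  expect_true(all(cl$SLEDAI[cl$group == "aSLE"] > 5))
  expect_true(all(cl$SLEDAI[cl$group == "rSLE"] <= 5))
  expect_silent(suppressMessages(validate_clinical(cl)))
  expect_true(all(cl$outcome[cl$group == "HC"] == "unknown"))
})
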
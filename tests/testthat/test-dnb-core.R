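# Module statistics, the composite index and its laws, candidate search,
# per-sample ranking and the top-marker list.

test_that("module statistics agree with the brute-force pairwise oracle", {
  X <- toy_matrix()
  m <- dnb_expression(X)
  s <- suppressWarnings(module_stats(m, c("A", "B")))
  # frozen values, computed with an independent numpy script before the build
  expect_equal(s$sd_in, 1.8708286933869707, tolerance = 1e-12)
  expect_equal(s$pcc_in, 0.8285714285714287, tolerance = 1e-12)
  expect_equal(s$pcc_out, 0.42388225985369216, tolerance = 1e-12)
  expect_equal(s$I, 3.656938949717195, tolerance = 1e-10)
  # and with the in-suite loop oracle, on several random member subsets
  set.seed(10)
  V <- matrix(rnorm(100 * 6), 100, 6, dimnames = list(NULL, LETTERS[1:6]))
  mm <- dnb_expression(V)
  for (mem in list(c("A", "B"), c("B", "D", "F"), c("A", "C", "E", "F"))) {
    got <- module_stats(mm, mem)
    want <- oracle_module_stats(V, mem)
    expect_equal(got$sd_in, want$sd_in, tolerance = 1e-12)
    expect_equal(got$pcc_in, want$pcc_in, tolerance = 1e-12)
    expect_equal(got$pcc_out, want$pcc_out, tolerance = 1e-12)
    expect_equal(got$I, want$I, tolerance = 1e-10)
  }
})

test_that("perfect correlation and anti-correlation both give pcc_in = 1", {
  set.seed(11)
  x <- rnorm(100)
  V <- cbind(A = x, B = x, C = rnorm(100), D = rnorm(100))
  expect_equal(module_stats(dnb_expression(V), c("A", "B"))$pcc_in, 1)
  W <- cbind(A = x, B = -x, C = rnorm(100), D = rnorm(100))
  expect_equal(module_stats(dnb_expression(W), c("A", "B"))$pcc_in, 1)
})

test_that("zero-variance markers contribute r = 0 and are counted, not dropped", {
  set.seed(12)
  V <- cbind(A = rnorm(100), B = rnorm(100), C = rep(1, 100), D = rnorm(100))
  s <- module_stats(dnb_expression(V), c("A", "C"))
  expect_identical(s$zero_var_pairs, 3L)      # C against each other marker
  # C contributes |r| = 0 to both averages; denominators keep all pairs
  o <- oracle_module_stats(V, c("A", "C"))
  expect_equal(s$pcc_in, o$pcc_in)
  expect_equal(s$pcc_out, o$pcc_out)
})

test_that("module_stats enforces its contracts", {
  m <- dnb_expression(toy_matrix())
  expect_error(suppressWarnings(module_stats(m, c("A", "Z"))), "not in panel")
  expect_error(suppressWarnings(module_stats(m, "A")), "at least 2 members")
  expect_error(suppressWarnings(module_stats(m, c("A", "B", "C"))),
               "non-member")
  expect_warning(module_stats(m, c("A", "B")), "fewer than 50")
})

test_that("composite index follows its closed form", {
  mk <- function(sd_in, pcc_in, pcc_out)
    list(sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out)
  expect_equal(composite_index(mk(0, 0.5, 0.5)), 0)
  expect_equal(composite_index(mk(1, 1, 0)), 1e6)
  expect_equal(composite_index(mk(0.5, 0.8, 0.2)), 0.4 / 0.200001)
})

test_that("composite index is monotone in each argument on a grid", {
  g <- seq(0.05, 0.95, by = 0.15)
  mk <- function(sd_in, pcc_in, pcc_out)
    list(sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out)
  for (a in g) for (b in g) {
    I_sd <- vapply(g, function(s) composite_index(mk(s, a, b)), 0)
    I_in <- vapply(g, function(s) composite_index(mk(a, s, b)), 0)
    I_out <- vapply(g, function(s) composite_index(mk(a, b, s)), 0)
    expect_true(all(diff(I_sd) > 0))
    expect_true(all(diff(I_in) > 0))
    expect_true(all(diff(I_out) < 0))
  }
})

test_that("index is scale-equivariant in members and affine-invariant overall", {
  set.seed(14)
  V <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, LETTERS[1:6]))
  mem <- c("A", "B", "C")
  base <- module_stats(dnb_expression(V), mem)
  for (cc in c(2, 5, 17.3)) {
    W <- V
    W[, mem] <- W[, mem] * cc
    sc <- module_stats(dnb_expression(W), mem)
    expect_equal(sc$sd_in, cc * base$sd_in, tolerance = 1e-10)
    expect_equal(sc$pcc_in, base$pcc_in, tolerance = 1e-10)
    expect_equal(sc$pcc_out, base$pcc_out, tolerance = 1e-10)
    expect_equal(sc$I, cc * base$I, tolerance = 1e-8)
  }
  W <- sweep(V, 2, c(3, -1, 0.5, 100, -40, 7), `+`)
  sh <- module_stats(dnb_expression(W), mem)
  for (f in c("sd_in", "pcc_in", "pcc_out", "I"))
    expect_lt(abs(sh[[f]] - base[[f]]), 1e-10)
})

test_that("a planted perfectly correlated triple appears among candidates", {
  set.seed(15)
  x <- rnorm(500)
  V <- cbind(A = x, B = x + rnorm(500, sd = 1e-8), C = x,
             D = rnorm(500), E = rnorm(500), F = rnorm(500))
  cand <- candidate_modules(dnb_expression(V))
  expect_true(any(vapply(cand, function(s) setequal(s, c("A", "B", "C")),
                         logical(1))))
  # ordering: by size, then lexicographic
  sizes <- lengths(cand)
  expect_true(all(diff(sizes) >= 0))
  # all-constant panel: empty candidate list with a warning
  K <- matrix(1, 100, 4, dimnames = list(NULL, LETTERS[1:4]))
  expect_warning(empty <- candidate_modules(dnb_expression(K)), "constant")
  expect_length(empty, 0L)
})

test_that("pipeline best module equals the exhaustive-search best module", {
  for (seed in 1:5) {
    p <- oracle_fixture_params(seed, n_cells = 1000)
    s <- simulate_sample(p, sprintf("fx%02d", seed))
    res <- rank_modules(s)
    expect_identical(sort(res$best_members), oracle_best_module(s),
                     label = sprintf("seed %d", seed))
  }
})

test_that("the rank-1 module recovers planted members, never background", {
  # Baseline intra-module correlation sits at the background level, so the
  # fold-change key may prefer a lucky sub-pair of the planted module over
  # the full set; the stable per-sample property is containment (no
  # background contamination). The consensus stage restores the full
  # module by pooling across samples (tested in test-consensus.R).
  contained <- 0L
  for (seed in 1:25) {
    p <- simulation_params(n_cells = 2000, seed = 300 + seed)
    s <- simulate_sample(p, "x")
    res <- rank_modules(s)
    if (all(res$best_members %in% p$marker_names[1:4])) contained <- contained + 1L
  }
  expect_gte(contained, 22L)    # >= ~90% of 25 seeds
})

test_that("planted samples show far larger index surges than null samples", {
  pf <- nf <- numeric(10)
  for (seed in 1:10) {
    p <- simulation_params(n_cells = 2000, seed = 400 + seed)
    pf[seed] <- rank_modules(simulate_sample(p, "x"))$modules$fold_change[1]
    pn <- simulation_params(n_cells = 2000, rho_in = 0.05, sigma_in = 1,
                            rho_out = 0.05, seed = 400 + seed)
    nf[seed] <- rank_modules(simulate_sample(pn, "x"))$modules$fold_change[1]
  }
  # paired comparison: median best fold change at least 4x the null's
  expect_gte(median(pf) / median(nf), 4)
  expect_true(all(pf > 20))
})

test_that("identical matrices across timepoints degrade to deterministic ties", {
  set.seed(16)
  V <- matrix(rnorm(300 * 6), 300, 6, dimnames = list(NULL, LETTERS[1:6]))
  mats <- lapply(dnbsle::DNB_TIMEPOINTS, function(h) dnb_expression(V))
  names(mats) <- c("0", "0.5", "1", "2", "4")
  s <- dnb_sample("flat", "HC", mats)
  r1 <- rank_modules(s)
  r2 <- rank_modules(s)
  expect_equal(r1$modules$fold_change, rep(1, nrow(r1$modules)),
               tolerance = 1e-6)
  expect_identical(r1$modules, r2$modules)      # tie-break is deterministic
})

test_that("top markers follow the documented order and extension rule", {
  p <- oracle_fixture_params(1, n_cells = 1000)
  s <- simulate_sample(p, "x")
  res <- rank_modules(s)
  tm <- top_markers(res)
  expect_length(tm, 5L)
  expect_identical(anyDuplicated(tm), 0L)
  # best module is the planted triple; its members come first, ordered by
  # SD fold change at the peak hour, then members of the next-ranked module
  expect_setequal(tm[1:3], p$marker_names[1:3])
  sd0 <- apply(s$matrices[["0"]]$values[, tm[1:3]], 2, sd)
  sd2 <- apply(s$matrices[[res$modules$peak_hour[1]]]$values[, tm[1:3]], 2, sd)
  fc <- sd2 / sd0
  expect_true(all(diff(fc[tm[1:3]]) <= 0))
  expect_identical(top_markers(res, 1), tm[1])
  expect_warning(all_m <- top_markers(res, 99), "returning all")
  expect_lte(length(all_m), 8L)
})

test_that("independent panels stay below the marker-permutation null", {
  set.seed(17)
  V <- matrix(rnorm(5000 * 8), 5000, 8, dimnames = list(NULL, LETTERS[1:8]))
  m <- dnb_expression(V)
  cand <- candidate_modules(m)
  obs <- max(vapply(cand, function(mem) oracle_module_stats(V, mem)$I, 0))
  null <- dnb_null_index(m, n_perm = 60, seed = 18)
  expect_lte(obs, quantile(null, 0.95))
})
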
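# Independent brute-force oracles. Everything here is written as explicit
# loops over sums, sharing no code path with the package internals, so
# agreement is a genuine dual-route check.

oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) 0 else num / den   # zero-variance convention: r = 0
}

# (sd_in, pcc_in, pcc_out, I) by explicit enumeration of all pairs
oracle_module_stats <- function(values, members, epsilon = 1e-6) {
  all_names <- colnames(values)
  nonmem <- setdiff(all_names, members)
  sd_in <- mean(vapply(members, function(m) oracle_sd(values[, m]), 0))
  pin <- c()
  for (i in seq_along(members)) for (j in seq_along(members)) {
    if (i < j)
      pin <- c(pin, abs(oracle_pearson(values[, members[i]], values[, members[j]])))
  }
  pout <- c()
  for (a in members) for (b in nonmem)
    pout <- c(pout, abs(oracle_pearson(values[, a], values[, b])))
  pcc_in <- mean(pin); pcc_out <- mean(pout)
  list(sd_in = sd_in, pcc_in = pcc_in, pcc_out = pcc_out,
       I = sd_in * pcc_in / (pcc_out + epsilon))
}

# Exhaustive all-subsets best module of one sample, under the identical
# ranking key: max over t > 0 of I(t) / (I(0) + eps), ties by larger peak
# I, then lexicographic member label.
oracle_best_module <- function(sample, min_size = 2, max_size = 8,
                               epsilon = 1e-6) {
  panel <- sample$matrices[[1]]$marker_names
  p <- length(panel)
  sizes <- min_size:min(max_size, p - 2L)
  subsets <- unlist(lapply(sizes, function(s)
    utils::combn(panel, s, simplify = FALSE)), recursive = FALSE)
  hours <- names(sample$matrices)
  I <- matrix(NA_real_, length(subsets), length(hours))
  for (j in seq_along(hours)) {
    V <- sample$matrices[[j]]$values
    for (i in seq_along(subsets))
      I[i, j] <- oracle_module_stats(V, subsets[[i]], epsilon)$I
  }
  fold <- I[, -1, drop = FALSE] / (I[, 1] + epsilon)
  key <- apply(fold, 1, max)
  peak <- apply(I[, -1, drop = FALSE], 1, max)
  labels <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  best <- order(-key, -peak, labels)[1]
  sort(subsets[[best]])
}

# the toy 6-cell x 4-marker fixture used for the frozen module-stats values
toy_matrix <- function() {
  X <- matrix(c(1, 2, 1, 5,
                2, 1, 1, 3,
                3, 4, 2, 1,
                4, 3, 2, 4,
                5, 6, 3, 2,
                6, 5, 9, 6), nrow = 6, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  X
}

# small planted-module sample for core tests: 8-marker panel, 3-marker
# module surging at 2 h over a correlated background
oracle_fixture_params <- function(seed, n_cells = 2000) {
  simulation_params(n_markers = 8, module_markers = 1:3, n_cells = n_cells,
                    rho_in = c(0.2, 0.3, 0.5, 0.9, 0.3), rho_bg = 0.2,
                    sigma_in = c(1, 1.2, 1.6, 3, 1.2), sigma_bg = 1,
                    rho_out = 0.2, seed = seed)
}
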
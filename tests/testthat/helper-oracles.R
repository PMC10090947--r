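# Independent brute-force oracles, coded from first principles so they never
# share a code path with the package implementation.

# Welch two-sided t-test p-value from the textbook formulas.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Benjamini-Hochberg step-up by direct definition: q_i = min over j with
# p_(j) >= p_(i) of m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by enumeration of the probability mass function.
oracle_hyper_upper <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Mean silhouette width from the definition, given a full distance matrix
# and an integer cluster vector.
oracle_mean_silhouette <- function(d, cl) {
  d <- as.matrix(d)
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# PCA explained-variance ratios via eigendecomposition of the covariance of
# the column-centered matrix (rows = observations).
oracle_pca_ratios <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  ev / sum(ev)
}

# Planted-module recovery on one seed: simulate, preprocess, split, cluster,
# and score against the planted labels (each trace matched to the planted
# module whose apex is nearest, which resolves multi-assembly proteins).
recover_planted_modules <- function(seed, noise_sd = 0.2, n_modules = 9) {
  truth <- default_complex_truth(n_modules = n_modules, seed = seed)
  sim <- simulate_bnpage(truth, noise_sd = noise_sd, seed = seed)
  suppressWarnings({
    prep <- preprocess_profiles(sim$profiles, sim$irt, bait = sim$bait)
    traces <- split_profile(prep, detect_peaks(prep))
    cl <- cluster_modules(traces)
  })
  asg <- cl$assignments
  planted <- vapply(seq_len(nrow(asg)), function(i) {
    cand <- sim$truth[sim$truth$entity_id == asg$entity_id[i], ]
    cand$module_id[which.min(abs(cand$apex_fraction - asg$apex[i]))]
  }, character(1))
  list(ari = mclust::adjustedRandIndex(asg$module, planted),
       k = cl$k, clusters = cl, traces = traces, sim = sim, truth = truth)
}

# Single noiseless Gaussian profile tibble for peak-level tests.
gaussian_profile <- function(apexes, heights = rep(1, length(apexes)),
                             fwhm = 2, n = 64, id = "P1", kind = "protein") {
  sigma <- fwhm / 2.355
  x <- Reduce(`+`, Map(function(a, h) h * exp(-((1:n - a)^2) / (2 * sigma^2)),
                       apexes, heights))
  tibble::tibble(entity_id = id, entity_kind = kind, fraction = 1:n,
                 intensity = x / max(x), loc_score = NA_real_)
}
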
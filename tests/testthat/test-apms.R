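test_that("top-n peptide summarization sums the brightest observed peptides", {
  expect_equal(protein_from_top_peptides(100), 100)
  expect_equal(protein_from_top_peptides(c(30, 20, 10), top_n = 2), 50)
  expect_true(is.na(protein_from_top_peptides(numeric(0))))
  expect_true(is.na(protein_from_top_peptides(c(NA_real_, NA_real_))))
  expect_equal(protein_from_top_peptides(c(5, NA), top_n = 2), 5)
})

test_that("top-n summarization is permutation-invariant and monotone", {
  set.seed(42)
  for (i in 1:50) {
    x <- stats::runif(sample(1:6, 1), 0, 100)
    expect_equal(protein_from_top_peptides(x[sample.int(length(x))], 2),
                 protein_from_top_peptides(x, 2))
    j <- sample(seq_along(x), 1)
    bumped <- x
    bumped[j] <- bumped[j] + 1
    expect_gte(protein_from_top_peptides(bumped, 2),
               protein_from_top_peptides(x, 2))
  }
})

two_run_table <- function(bait_a = 2, bait_b = 1) {
  tibble::tibble(
    protein = rep(c("BAIT", "X"), 2),
    condition = "c",
    replicate = rep(1:2, each = 2),
    intensity = c(bait_a, 10, bait_b, 10))
}

test_that("bait normalization equalizes the bait and rescales runs", {
  same <- normalize_to_bait(two_run_table(1, 1), "BAIT")
  expect_equal(same$intensity, two_run_table(1, 1)$intensity)
  norm <- normalize_to_bait(two_run_table(2, 1), "BAIT")
  x <- norm$intensity[norm$protein == "X"]
  expect_equal(x[1] / x[2], 0.5)  # run with 2x bait is halved relative to the other
  bait_vals <- norm$intensity[norm$protein == "BAIT"]
  expect_equal(stats::sd(bait_vals) / mean(bait_vals), 0)  # bait CV = 0
  broken <- two_run_table()
  broken$intensity[broken$protein == "BAIT" & broken$replicate == 2] <- NA
  expect_error(normalize_to_bait(broken, "BAIT"), "c/2")
})

test_that("single-missing replicates are imputed with the condition median", {
  tb <- tibble::tibble(protein = "A", condition = "c", replicate = 1:3,
                       intensity = c(4, NA, 6))
  out <- impute_missing(tb, seed = 1)
  expect_equal(out$intensity[2], 5)
  expect_true(out$imputed[2])
  full <- tibble::tibble(protein = "A", condition = "c", replicate = 1:3,
                         intensity = c(4, 5, 6))
  expect_identical(impute_missing(full, seed = 1)$intensity, full$intensity)
})

test_that("heavily missing conditions draw from the censored low tail", {
  set.seed(11)
  n_prot <- 300
  mu <- stats::rnorm(n_prot, 20, 2)  # protein abundances span the dynamic range
  obs <- tibble::tibble(
    protein = rep(sprintf("P%03d", seq_len(n_prot)), each = 3),
    condition = "obs", replicate = rep(1:3, n_prot),
    intensity = 2^(rep(mu, each = 3) + stats::rnorm(3 * n_prot, 0, 0.2)))
  # exactly two of three replicates missing per protein: the median rule
  # cannot apply, every imputed cell comes from the censored tail
  keep_rep <- sample(1:3, n_prot, replace = TRUE)
  gap <- dplyr::mutate(obs, condition = "gap",
                       intensity = ifelse(
                         .data$replicate == keep_rep[match(
                           .data$protein, sprintf("P%03d", seq_len(n_prot)))],
                         .data$intensity, NA))
  out <- impute_missing(dplyr::bind_rows(obs, gap), percentile = 5, seed = 4)
  imp <- out[out$imputed, ]
  expect_equal(nrow(imp), 2 * n_prot)
  # compare each draw with the 10th percentile of its own run's observed values
  below <- vapply(seq_len(nrow(imp)), function(i) {
    run_obs <- gap$intensity[gap$replicate == imp$replicate[i] &
                               !is.na(gap$intensity)]
    log2(imp$intensity[i]) < stats::quantile(log2(run_obs), 0.10)
  }, logical(1))
  expect_gte(mean(below), 0.99)
})

test_that("differential statistics match hand-computable cases", {
  same <- tibble::tibble(protein = "A", condition = rep(c("t", "r"), each = 3),
                         replicate = rep(1:3, 2), intensity = rep(2^5, 6))
  res <- differential(same, "t", "r")
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)

  tb <- tibble::tibble(protein = "A", condition = rep(c("t", "r"), each = 3),
                       replicate = rep(1:3, 2),
                       intensity = 2^c(1, 1.1, 0.9, 3, 3.1, 2.9))
  res <- differential(tb, "t", "r")
  expect_equal(res$log2fc, -2, tolerance = 1e-12)
  expect_equal(res$p, oracle_welch_p(c(1, 1.1, 0.9), c(3, 3.1, 2.9)),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up rule", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  tb <- tibble::tibble(
    protein = rep(c("A", "B", "C"), each = 6),
    condition = rep(rep(c("t", "r"), each = 3), 3),
    replicate = rep(1:3, 6),
    intensity = 2^(c(1, 1.2, 0.8, 3, 3.1, 2.9,
                     5, 5.05, 4.95, 5.2, 5.1, 5.3,
                     2, 2.5, 1.5, 2.1, 2.6, 1.6)))
  res <- differential(tb, "t", "r")
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$q >= res$p))
})

test_that("proteins with too few replicates are skipped with a warning", {
  tb <- tibble::tibble(protein = "A", condition = c("t", "r", "r"),
                       replicate = c(1L, 1L, 2L), intensity = c(4, 5, 6))
  expect_warning(res <- differential(tb, "t", "r"), "fewer than 2")
  expect_equal(nrow(res), 0)
})

test_that("interactor filtering is strict at the score threshold", {
  sc <- tibble::tibble(protein = c("A", "B", "C"), score = c(0.95, 0.90, 0.10))
  expect_equal(filter_interactors(sc, 0.90)$protein, "A")
  expect_equal(nrow(filter_interactors(sc, 0)), 3)
  empty <- tibble::tibble(protein = character(), score = numeric())
  expect_equal(nrow(filter_interactors(empty)), 0)
})
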
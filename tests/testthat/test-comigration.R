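flat_profile <- function(id = "P1", value = 1, n = 8, kind = "protein",
                         loc = NA_real_) {
  tibble::tibble(entity_id = id, entity_kind = kind, fraction = 1:n,
                 intensity = value, loc_score = loc)
}

unit_irt <- function(n = 8) tibble::tibble(fraction = 1:n, intensity = 1)

test_that("preprocessing keeps profile shape and fills interior gaps", {
  prof <- tibble::tibble(entity_id = "P1", entity_kind = "protein",
                         fraction = 1:5, intensity = c(1, 2, NA, 4, 2),
                         loc_score = NA_real_)
  out <- preprocess_profiles(prof, unit_irt(5))
  expect_equal(out$intensity, c(1, 2, 3, 4, 2) / 4)  # gap = mean of neighbors, max = 1
  # constant iRT only rescales: argmax unchanged under a scaled iRT vector
  out2 <- preprocess_profiles(prof,
                              tibble::tibble(fraction = 1:5, intensity = 7))
  expect_equal(out2$intensity, out$intensity)
  # edge gap uses the single available neighbor
  edge <- dplyr::mutate(prof, intensity = c(NA, 2, 4, 4, 2))
  out3 <- preprocess_profiles(edge, unit_irt(5))
  expect_equal(out3$intensity[1], 2 / 4)
})

test_that("the two-level localization filter keeps confident phosphopeptides only", {
  keep <- tibble::tibble(entity_id = "pS1", entity_kind = "bait_phosphopeptide",
                         fraction = 1:5, intensity = c(1, 2, 3, 2, 1),
                         loc_score = c(0.6, 0.85, 0.6, 0.55, 0.5))
  drop <- dplyr::mutate(keep, entity_id = "pS2",
                        loc_score = rep(0.7, 5))  # never above 0.8
  out <- preprocess_profiles(dplyr::bind_rows(keep, drop), unit_irt(5))
  expect_setequal(unique(out$entity_id), "pS1")
  # fractions under the per-fraction floor are masked before imputation
  low_frac <- dplyr::mutate(keep, loc_score = c(0.6, 0.85, 0.6, 0.4, 0.5))
  out2 <- preprocess_profiles(low_frac, unit_irt(5))
  expect_equal(out2$intensity[4], mean(c(3, 1)) / 3)
})

test_that("invalid iRT vectors are rejected with the offending fraction", {
  prof <- flat_profile(n = 3)
  bad_irt <- tibble::tibble(fraction = 1:3, intensity = c(1, 0, 1))
  expect_error(preprocess_profiles(prof, bad_irt), "fraction 2")
})

test_that("bait-phosphopeptide profiles are divided by the bait protein", {
  phos <- tibble::tibble(entity_id = "pS1", entity_kind = "bait_phosphopeptide",
                         fraction = 1:4, intensity = c(2, 4, 8, 4),
                         loc_score = 0.9)
  bait <- tibble::tibble(fraction = 1:4, intensity = c(2, 2, 4, 4))
  out <- preprocess_profiles(phos, unit_irt(4), bait = bait)
  expect_equal(out$intensity, c(1, 2, 2, 1) / 2)
})

test_that("peak detection finds planted Gaussians and respects thresholds", {
  one <- gaussian_profile(30)
  pk <- detect_peaks(one)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex - 30), 1)

  two <- gaussian_profile(c(10, 40), heights = c(1, 0.8))
  pk2 <- detect_peaks(two)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$apex, c(10, 40), tolerance = 1)
  expect_true(all(pk2$left <= pk2$apex & pk2$apex <= pk2$right))

  flat <- dplyr::mutate(flat_profile(n = 64), intensity = 0.1)
  expect_equal(nrow(detect_peaks(flat)), 0)
  # the phosphopeptide threshold is stricter than the protein threshold
  # (a 0.35-high peak smooths to ~0.25, between the 0.2 and 0.3 gates)
  dim_peak <- dplyr::mutate(gaussian_profile(30), intensity = intensity * 0.35)
  expect_equal(nrow(detect_peaks(dim_peak)), 1)
  dim_phos <- dplyr::mutate(dim_peak, entity_kind = "bait_phosphopeptide",
                            loc_score = 0.9)
  expect_equal(nrow(detect_peaks(dim_phos)), 0)
})

test_that("nearby maxima are merged within the peak width", {
  x <- gaussian_profile(c(30, 31))
  pk <- detect_peaks(x)
  expect_equal(nrow(pk), 1)
})

test_that("split traces partition the profile exactly", {
  one <- gaussian_profile(20)
  tr <- split_profile(one, detect_peaks(one))
  expect_equal(tr$intensity, one$intensity)  # single peak keeps the profile

  two <- gaussian_profile(c(10, 40), heights = c(1, 0.8))
  tr2 <- split_profile(two, detect_peaks(two))
  recon <- tr2 |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(total = sum(.data$intensity))
  expect_equal(recon$total, two$intensity, tolerance = 1e-12)
  # valley rule: the left trace owns the valley fraction and is zero after it
  valley <- which.min(two$intensity[10:40]) + 9
  left <- dplyr::filter(tr2, .data$peak == 1)
  expect_true(all(left$intensity[left$fraction > valley] == 0))
  expect_equal(left$intensity[left$fraction == valley],
               two$intensity[valley])
})

test_that("peak correlation distance behaves at its boundary cases", {
  a <- c(0, 1, 2, 1, 0, 0, 0)
  expect_equal(peak_distance(a, a), 0)
  # anti-correlated on the shared support: b = -a + constant
  expect_equal(peak_distance(c(0, 1, 2, 1, 3, 0, 0), c(0, 3, 2, 3, 1, 0, 0)),
               2, tolerance = 1e-12)
  expect_equal(peak_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 2)  # disjoint
  expect_equal(peak_distance(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)  # constant
  # matches a directly coded correlation on the union support
  set.seed(5)
  for (i in 1:20) {
    x <- pmax(stats::rnorm(10), 0)
    y <- pmax(stats::rnorm(10), 0)
    if (sum(x > 0 & y > 0) == 0 || length(unique(x[x > 0 | y > 0])) < 2 ||
        length(unique(y[x > 0 | y > 0])) < 2) next
    sup <- x > 0 | y > 0
    expect_equal(peak_distance(x, y), 1 - stats::cor(x[sup], y[sup]),
                 tolerance = 1e-12)
  }
})

test_that("planted complexes are recovered as modules and the bait is excluded", {
  truth <- complex_truth(
    tibble::tibble(module_id = c("M1", "M2"), apex_fraction = c(10, 40),
                   fwhm = 2),
    tibble::tibble(module_id = rep(c("M1", "M2"), each = 5),
                   protein = sprintf("P%02d", 1:10), weight = 1))
  sim <- simulate_bnpage(truth, noise_sd = 0.05, dropout_rate = 0, seed = 3)
  prep <- preprocess_profiles(sim$profiles, sim$irt, bait = sim$bait)
  traces <- split_profile(prep, detect_peaks(prep))
  bait_traces <- split_profile(
    preprocess_profiles(sim$bait, sim$irt), detect_peaks(
      preprocess_profiles(sim$bait, sim$irt)))
  cl <- cluster_modules(dplyr::bind_rows(traces, bait_traces),
                        k_min = 2, k_max = 6, bait = "BAIT")
  expect_equal(cl$k, 2)
  expect_false("BAIT" %in% cl$assignments$entity_id)
  truth_lab <- cl$assignments$entity_id %in% sprintf("P%02d", 1:5)
  expect_equal(mclust::adjustedRandIndex(cl$assignments$module, truth_lab), 1)
})

test_that("degenerate and undersized clustering inputs are handled", {
  one <- gaussian_profile(20, id = "P1")
  two <- gaussian_profile(20, id = "P2")
  traces <- split_profile(dplyr::bind_rows(one, two),
                          detect_peaks(dplyr::bind_rows(one, two)))
  expect_warning(cl <- cluster_modules(traces, k_min = 2, k_max = 10),
                 "clamped")
  expect_lte(cl$k, 2)
  expect_error(cluster_modules(traces[traces$entity_id == "P1", ]),
               "at least 2")
})

test_that("modules are assembled with members, signatures and weighted apex", {
  prof <- dplyr::bind_rows(
    gaussian_profile(10, id = "P1"),
    gaussian_profile(10, id = "P2"),
    gaussian_profile(10, id = "pS367", kind = "bait_phosphopeptide"),
    gaussian_profile(40, id = "P3"),
    gaussian_profile(c(10, 40), id = "P4"))
  prof$loc_score[prof$entity_kind == "bait_phosphopeptide"] <- 0.9
  traces <- split_profile(prof, detect_peaks(prof))
  cl <- cluster_modules(traces, k_min = 2, k_max = 4)
  mods <- assemble_modules(cl, traces)
  m10 <- mods[which.min(abs(mods$apex - 10)), ]
  m40 <- mods[which.min(abs(mods$apex - 40)), ]
  expect_setequal(m10$members[[1]], c("P1", "P2", "P4"))
  expect_equal(m10$phosphosignature[[1]], "pS367")
  expect_equal(m40$phosphosignature[[1]], character(0))  # may be empty
  expect_setequal(m40$members[[1]], c("P3", "P4"))       # multi-assembly
  expect_true(all(diff(mods$apex) >= 0))                 # high mass first
})

test_that("molecular weights interpolate log-linearly and flag extrapolation", {
  cal <- tibble::tibble(fraction = c(10, 20), kda = c(1000, 100))
  at_point <- estimate_mw(10, tibble::tibble(fraction = c(10, 20, 30),
                                             kda = c(1048, 100, 10)))
  expect_equal(at_point$mw_kda, 1048)
  mid <- estimate_mw(15, cal)
  expect_equal(mid$mw_kda, 10^2.5, tolerance = 1e-9)
  expect_false(mid$extrapolated)
  expect_true(estimate_mw(5, cal)$extrapolated)
  expect_error(estimate_mw(10, tibble::tibble(fraction = c(10, 20),
                                              kda = c(100, 1000))),
               "decrease")
  # monotone decreasing in apex fraction
  mw <- estimate_mw(seq(8, 25, by = 0.5), cal)$mw_kda
  expect_true(all(diff(mw) < 0))
})

test_that("fractionation preserves stoichiometry of the planted interactome", {
  # stoichiometry weights spanning an order of magnitude, as in a real
  # interactome, so the fraction sums must track the unfractionated amounts
  set.seed(6)
  mods <- tibble::tibble(module_id = sprintf("M%d", 1:5),
                         apex_fraction = c(8, 20, 32, 44, 56), fwhm = 2)
  members <- tibble::tibble(
    module_id = rep(mods$module_id, each = 4),
    protein = sprintf("P%02d", 1:20),
    weight = 10^stats::runif(20, -0.5, 0.5))
  truth <- complex_truth(mods, members)
  sim <- simulate_bnpage(truth, seed = 6)
  sigma <- 2 / 2.355
  expected <- members |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(total = sum(.data$weight) * sqrt(2 * pi) * sigma)
  observed <- sim$profiles |>
    dplyr::filter(.data$entity_kind == "protein") |>
    dplyr::group_by(entity_id) |>
    dplyr::summarise(total = sum(.data$intensity, na.rm = TRUE))
  both <- dplyr::inner_join(expected, observed,
                            by = c(protein = "entity_id"))
  expect_gt(stats::cor(both$total.x, both$total.y), 0.9)
})
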
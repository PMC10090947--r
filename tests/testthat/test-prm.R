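lib_entry <- function(rel = c(y1 = 1, y2 = 0.5, y3 = 0.25), rt = 45) {
  list(library_rt = rt, rel_intensity = rel)
}

test_that("spectral dot product is cosine similarity on shared fragments", {
  lib <- c(y1 = 0.2, y2 = 0.5, y3 = 1)
  expect_equal(dot_product(lib * 37, lib), 1.0, tolerance = 1e-12)
  expect_equal(dot_product(c(y1 = 1, y2 = 0, y3 = 1),
                           c(y1 = 1, y2 = 1, y3 = 0)), 0.5)
  expect_equal(dot_product(c(y1 = 1, y2 = 0), c(y1 = 0, y2 = 1)), 0)
  expect_equal(dot_product(c(y1 = 0, y2 = 0), lib[1:2]), 0)  # convention
  expect_error(dot_product(c(y1 = 1), lib), "shared")
  # scale invariance and bounds on random non-negative vectors
  set.seed(1)
  for (i in 1:50) {
    o <- stats::setNames(stats::runif(5), paste0("y", 1:5))
    l <- stats::setNames(stats::runif(5), paste0("y", 1:5))
    d <- dot_product(o, l)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(dot_product(o * 100, l / 3), d, tolerance = 1e-12)
  }
})

test_that("peak groups are gated on retention time and dot product", {
  lib <- lib_entry()
  obs <- lib$rel_intensity * 50
  ok <- accept_peak_group(45, obs, lib, gradient_length = 90)
  expect_true(ok$accepted)
  # 5 min off on a 90-min gradient exceeds the 4.5-min window
  late <- accept_peak_group(50, obs, lib, gradient_length = 90)
  expect_false(late$accepted)
  expect_false(late$rt_ok)
  expect_true(late$dotp_ok)
  # dot product exactly at the threshold is rejected (strict >)
  half <- c(y1 = 1, y2 = 0, y3 = 1)
  liber <- lib_entry(rel = c(y1 = 1, y2 = 1, y3 = 0))
  stopifnot(abs(dot_product(half, liber$rel_intensity) - 0.5) < 1e-12)
  exact <- accept_peak_group(45, half, liber, 90,
                             prm_params(min_dotp = 0.5))
  expect_false(exact$accepted)
  expect_error(accept_peak_group(45, obs, list(library_rt = NA), 90),
               "library RT")
})

test_that("quantification filters by signal-to-noise then sums the top three", {
  q <- quantify_peptide(c(10, 20, 30), sn = c(10, 10, 10))
  expect_equal(q$intensity, 60)
  expect_false(q$low_fragment)
  # the brightest fragment fails the S/N gate and is excluded
  q2 <- quantify_peptide(c(40, 30, 20, 10), sn = c(4, 10, 10, 10))
  expect_equal(q2$intensity, 60)
  q3 <- quantify_peptide(c(40, 30), sn = c(4, 4))
  expect_true(is.na(q3$intensity))
  # fewer than three surviving fragments is flagged
  q4 <- quantify_peptide(c(40, 30), sn = c(10, 10))
  expect_equal(q4$intensity, 70)
  expect_true(q4$low_fragment)
  # monotone in any area above the gate
  set.seed(2)
  for (i in 1:25) {
    a <- stats::runif(5, 0, 100)
    s <- stats::runif(5, 5, 30)
    j <- sample(5, 1)
    a2 <- a; a2[j] <- a2[j] + 10
    expect_gte(quantify_peptide(a2, s)$intensity,
               quantify_peptide(a, s)$intensity)
  }
})

test_that("light/heavy ratios are log2 and guard the heavy channel", {
  expect_equal(light_heavy_ratio(100, 100), 0)
  expect_equal(light_heavy_ratio(400, 100), 2)
  expect_true(is.na(light_heavy_ratio(NA, 100)))
  expect_error(light_heavy_ratio(100, 0), "heavy")
})

test_that("panel normalization divides runs by their reference level", {
  panel <- tibble::tibble(
    entity = rep(c("REF1", "REF2", "X"), 2),
    run = rep(c("r1", "r2"), each = 3),
    intensity = c(10, 40, 100, 10, 40, 100))
  out <- normalize_panel(panel, "housekeeping_irt", c("REF1", "REF2"))
  expect_equal(out$intensity, panel$intensity)  # equal references: unchanged
  doubled <- panel
  doubled$intensity[doubled$run == "r2"] <- doubled$intensity[doubled$run == "r2"] * 2
  out2 <- normalize_panel(doubled, "housekeeping_irt", c("REF1", "REF2"))
  x <- out2$intensity[out2$entity == "X"]
  expect_equal(x[2] / x[1], 1, tolerance = 1e-12)  # 2x references halve the run
  missing_ref <- panel[panel$entity != "REF2" | panel$run != "r2", ]
  expect_error(normalize_panel(missing_ref, "tag_peptide", c("REF2")),
               "REF2.*r2")
})

test_that("bait-peptide mode separates phosphorylation from bait abundance", {
  panel <- tibble::tibble(
    entity = rep(c("BAITPEP", "pS1"), 2),
    run = rep(c("r1", "r2"), each = 2),
    intensity = c(10, 50, 20, 50),
    is_phospho = rep(c(FALSE, TRUE), 2))
  out <- normalize_panel(panel, "bait_peptides", "BAITPEP")
  ph <- out$intensity[out$entity == "pS1"]
  # equal raw phospho signal on 2x bait means half the phosphorylation level
  expect_equal(ph[1] / ph[2], 2, tolerance = 1e-12)
})

test_that("knockout-panel PCA explains variance like an eigendecomposition", {
  set.seed(7)
  lines <- c("parental", "ko1", "ko2", "ko3")
  panel <- tidyr::expand_grid(entity = sprintf("E%02d", 1:8),
                              cell_line = lines, replicate = 1:3) |>
    dplyr::mutate(intensity = 2^(15 + stats::rnorm(dplyr::n(), 0, 0.3)))
  ps <- panel_summary(panel, "parental", ko_targets = "E01")
  expect_equal(sum(ps$explained_variance), 1, tolerance = 1e-9)
  expect_false("E01" %in% rownames(ps$pca$rotation))  # KO target removed
  fcm <- tidyr::pivot_wider(ps$fold_changes[ps$fold_changes$entity != "E01", ],
                            id_cols = "entity", names_from = "cell_line",
                            values_from = "log2fc")
  ratios <- oracle_pca_ratios(t(as.matrix(fcm[, -1])))
  expect_equal(unname(ps$explained_variance[seq_along(ratios)]), ratios,
               tolerance = 1e-9)
  expect_s3_class(autoplot(ps), "ggplot")
  expect_error(panel_summary(panel, "nope"), "parental")
})

test_that("a rank-one fold-change structure loads entirely on PC1", {
  lines <- c("parental", "ko1", "ko2", "ko3")
  base <- c(ko1 = 1, ko2 = 2, ko3 = 3)
  panel <- tidyr::expand_grid(entity = sprintf("E%02d", 1:6),
                              cell_line = lines, replicate = 1:3) |>
    dplyr::mutate(effect = ifelse(.data$cell_line == "parental", 0,
                                  base[.data$cell_line] *
                                    as.integer(sub("E", "", .data$entity))),
                  intensity = 2^(15 + .data$effect))
  ps <- panel_summary(panel, "parental")
  expect_equal(unname(ps$explained_variance[1]), 1, tolerance = 1e-9)
})

test_that("scored synthetic runs separate true targets from decoys", {
  a <- prm_assay(n_peptides = 8, seed = 4)
  pr <- simulate_prm(a, seed = 4, decoy_fraction = 1)
  sc <- score_peak_groups(dplyr::filter(pr$peak_groups, .data$channel == "light"),
                          pr$library, a$gradient_length)
  sc <- dplyr::left_join(sc,
                         dplyr::distinct(pr$peak_groups, .data$group_id,
                                         .data$is_decoy),
                         by = "group_id")
  expect_true(all(sc$accepted[!sc$is_decoy]))
  expect_true(all(!is.na(sc$intensity[sc$accepted])))
})
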
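#' Protein intensity from its most intense peptides
#'
#' Summarizes one protein in one run as the sum of its `top_n` most intense
#' observed peptides (default 2, i.e. a top-2 unique-peptide quantification).
#' With fewer than `top_n` observed peptides the sum runs over all observed;
#' with none the result is missing, never zero.
#'
#' @param intensities Numeric vector of peptide intensities for one
#'   protein/run; `NA` marks unobserved peptides.
#' @param top_n Number of peptides to sum (default 2).
#' @return A single intensity, or `NA` when no peptide was observed.
#' @examples
#' protein_from_top_peptides(c(30, 20, 10))  # 50
#' @export
protein_from_top_peptides <- function(intensities, top_n = 2) {
  abort_if(top_n < 1, "top_n must be >= 1")
  x <- intensities[!is.na(intensities)]
  if (length(x) == 0) return(NA_real_)
  sum(sort(x, decreasing = TRUE)[seq_len(min(top_n, length(x)))])
}

#' Roll a peptide table up to protein intensities
#'
#' Applies [protein_from_top_peptides()] per (protein, condition, replicate).
#'
#' @param peptides Long peptide tibble (`protein`, `peptide`, `condition`,
#'   `replicate`, `intensity`).
#' @param top_n Number of peptides to sum per run.
#' @return Protein-level tibble (`protein`, `condition`, `replicate`,
#'   `intensity`).
#' @export
quantify_proteins <- function(peptides, top_n = 2) {
  peptides |>
    dplyr::group_by(.data$protein, .data$condition, .data$replicate) |>
    dplyr::summarise(intensity = protein_from_top_peptides(.data$intensity, top_n),
                     .groups = "drop")
}

#' Normalize a protein table to the bait
#'
#' Divides every run's intensities by that run's bait intensity, then rescales
#' by the mean bait intensity so values keep their original magnitude. After
#' normalization the bait is equal across runs (coefficient of variation 0).
#'
#' @param quant Protein-level tibble (`protein`, `condition`, `replicate`,
#'   `intensity`).
#' @param bait Bait protein identifier; must be observed in every run.
#' @return The normalized tibble.
#' @export
normalize_to_bait <- function(quant, bait) {
  runs <- dplyr::distinct(quant, .data$condition, .data$replicate)
  bt <- quant |>
    dplyr::filter(.data$protein == bait, !is.na(.data$intensity)) |>
    dplyr::select("condition", "replicate", bait_intensity = "intensity")
  missing_runs <- dplyr::anti_join(runs, bt, by = c("condition", "replicate"))
  abort_if(nrow(missing_runs) > 0,
           paste0("bait '", bait, "' missing in run ",
                  paste(paste0(missing_runs$condition, "/",
                               missing_runs$replicate), collapse = ", ")))
  scale <- mean(bt$bait_intensity)
  quant |>
    dplyr::left_join(bt, by = c("condition", "replicate")) |>
    dplyr::mutate(intensity = .data$intensity / .data$bait_intensity * scale) |>
    dplyr::select(-"bait_intensity")
}

#' Impute missing replicate intensities
#'
#' Two-tier left-censored imputation on log2 intensities, per protein and
#' condition: a condition with exactly one missing replicate (and at least
#' `max_single_missing + 1` observed) gets the median of its observed
#' replicates; a condition with more missing replicates gets draws from a
#' normal distribution centered at the `percentile` quantile of the run's
#' observed log2-intensity distribution (5 for label-free AP-MS, 1 for
#' DIA-style workflows), with standard deviation equal to the median
#' within-condition replicate standard deviation. Imputed cells are flagged.
#'
#' @param quant Protein-level tibble with possible `NA` intensities.
#' @param percentile Down-shift percentile (default 5).
#' @param max_single_missing Maximum missing replicates repaired by the
#'   median rule (default 1).
#' @param seed Optional seed for the random draws.
#' @return The tibble with missing intensities filled and a logical
#'   `imputed` column.
#' @export
impute_missing <- function(quant, percentile = 5, max_single_missing = 1,
                           seed = NULL) {
  abort_if(percentile <= 0 || percentile >= 100, "percentile must be in (0,100)")
  cond_obs <- quant |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$intensity)), .groups = "drop")
  abort_if(any(cond_obs$n_obs == 0),
           paste0("condition fully missing: ",
                  paste(cond_obs$condition[cond_obs$n_obs == 0], collapse = ", ")))
  # per-run distribution of observed log2 intensities defines the censoring tail
  run_stats <- quant |>
    dplyr::filter(!is.na(.data$intensity), .data$intensity > 0) |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::summarise(q_low = stats::quantile(log2(.data$intensity),
                                             percentile / 100, names = FALSE),
                     .groups = "drop")
  sd_rep <- quant |>
    dplyr::filter(!is.na(.data$intensity), .data$intensity > 0) |>
    dplyr::group_by(.data$protein, .data$condition) |>
    dplyr::summarise(s = stats::sd(log2(.data$intensity)), .groups = "drop")
  sigma <- stats::median(sd_rep$s, na.rm = TRUE)
  if (!is.finite(sigma) || sigma == 0) sigma <- 0.3

  with_seed(seed, {
    out <- quant |>
      dplyr::group_by(.data$protein, .data$condition) |>
      dplyr::mutate(.n_miss = sum(is.na(.data$intensity)),
                    .med = stats::median(.data$intensity, na.rm = TRUE)) |>
      dplyr::ungroup() |>
      dplyr::mutate(imputed = is.na(.data$intensity))
    median_fix <- out$imputed & out$.n_miss <= max_single_missing
    out$intensity[median_fix] <- out$.med[median_fix]
    tail_fix <- which(out$imputed & out$.n_miss > max_single_missing)
    if (length(tail_fix) > 0) {
      qlow <- dplyr::left_join(out[tail_fix, c("condition", "replicate")],
                               run_stats, by = c("condition", "replicate"))$q_low
      # run entirely unobserved: fall back to the global intensity distribution
      if (anyNA(qlow)) {
        global_q <- stats::quantile(
          log2(quant$intensity[!is.na(quant$intensity) & quant$intensity > 0]),
          percentile / 100, names = FALSE)
        qlow[is.na(qlow)] <- global_q
      }
      out$intensity[tail_fix] <-
        2^(stats::rnorm(length(tail_fix), mean = qlow, sd = sigma))
    }
    dplyr::select(out, -".n_miss", -".med")
  })
}

#' Differential interactor statistics
#'
#' Per protein, a two-sided t test on log2 intensities between a condition
#' and a reference (Welch by default), with the log2 fold change as the
#' difference of group means and Benjamini-Hochberg adjustment across the
#' tested protein set.
#'
#' @param quant Protein-level tibble (imputed; no missing values in the two
#'   groups compared).
#' @param condition,reference Condition labels to compare.
#' @param var_equal Use the pooled-variance t test instead of Welch
#'   (default `FALSE`).
#' @return Tibble (`protein`, `log2fc`, `p`, `q`, `n_condition`,
#'   `n_reference`), BH-adjusted within this contrast.
#' @export
differential <- function(quant, condition, reference, var_equal = FALSE) {
  df <- dplyr::filter(quant, .data$condition %in% c(!!condition, !!reference),
                      !is.na(.data$intensity))
  res <- df |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_map(function(g, key) {
      x <- log2(g$intensity[g$condition == condition])
      y <- log2(g$intensity[g$condition == reference])
      if (length(x) < 2 || length(y) < 2) {
        rlang::warn(paste0("protein ", key$protein,
                           " skipped: fewer than 2 replicates per group"))
        return(NULL)
      }
      lfc <- mean(x) - mean(y)
      p <- if (stats::sd(c(x, y)) == 0) 1 else {
        tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
                 error = function(e) 1)
      }
      tibble::tibble(protein = key$protein, log2fc = lfc, p = p,
                     n_condition = length(x), n_reference = length(y))
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) return(tibble::tibble(protein = character(),
                                            log2fc = numeric(), p = numeric(),
                                            q = numeric(),
                                            n_condition = integer(),
                                            n_reference = integer()))
  res$q <- stats::p.adjust(res$p, method = "BH")
  dplyr::select(res, "protein", "log2fc", "p", "q", "n_condition", "n_reference")
}

#' Filter high-confidence interactors by probability score
#'
#' Retains candidates whose SAINT-style confidence score strictly exceeds the
#' threshold (default > 0.90).
#'
#' @param scores Tibble (`protein`, `score`).
#' @param threshold Probability threshold in `[0, 1]` (default 0.90).
#' @return Tibble of retained rows.
#' @export
filter_interactors <- function(scores, threshold = 0.90) {
  abort_if(threshold < 0 || threshold > 1, "threshold must be in [0,1]")
  dplyr::filter(tibble::as_tibble(scores), .data$score > threshold)
}
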
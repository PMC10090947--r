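#' Module recall against a protein-protein interaction reference
#'
#' For each module with at least two protein members, the recall is the
#' fraction of its unordered member pairs present in the reference edge set.
#' The background is the recall over all unordered pairs of the interactor
#' universe (the bait excluded). For the comparison, per-module-size random
#' subsets of the universe are resampled to form a background recall
#' distribution; module recalls are tested against it with a two-sided
#' unpaired t test, and normality of the module recalls is assessed with the
#' Shapiro-Wilk test.
#'
#' @param modules Output of [assemble_modules()] (needs `module`, `members`).
#' @param reference Edge tibble (`protein_a`, `protein_b`) from [read_ppi()].
#' @param universe Character vector of interactor ids (bait excluded).
#' @param n_samples Background subsets drawn per module (default 100).
#' @param seed Optional seed for the resampling.
#' @return A `module_evaluation` object: `module_recall` tibble,
#'   `background_recall` (all-pairs value), `background_samples`,
#'   `shapiro_p`, `comparison_p`.
#' @export
recall_vs_background <- function(modules, reference, universe,
                                 n_samples = 100, seed = NULL) {
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  edges <- unique(edge_key(reference$protein_a, reference$protein_b))
  pair_recall <- function(members) {
    members <- intersect(members, universe)
    if (length(members) < 2) return(NA_real_)
    pr <- utils::combn(members, 2)
    mean(edge_key(pr[1, ], pr[2, ]) %in% edges)
  }
  mr <- modules |>
    dplyr::mutate(recall = vapply(.data$members, pair_recall, numeric(1)),
                  size = vapply(.data$members,
                                function(m) length(intersect(m, universe)),
                                numeric(1))) |>
    dplyr::select("module", "size", "recall")
  dropped <- mr$module[is.na(mr$recall)]
  if (length(dropped) > 0) {
    rlang::warn(paste0("module(s) with < 2 members excluded: ",
                       paste(dropped, collapse = ", ")))
  }
  mr <- dplyr::filter(mr, !is.na(.data$recall))
  abort_if(nrow(mr) == 0, "no module with >= 2 members in the universe")
  all_pairs <- utils::combn(universe, 2)
  background <- mean(edge_key(all_pairs[1, ], all_pairs[2, ]) %in% edges)
  bg_samples <- with_seed(seed, {
    unlist(lapply(mr$size, function(k) {
      vapply(seq_len(n_samples), function(i) {
        pair_recall(sample(universe, k))
      }, numeric(1))
    }))
  })
  shapiro_p <- if (nrow(mr) >= 3 && stats::sd(mr$recall) > 0)
    stats::shapiro.test(mr$recall)$p.value else NA_real_
  comparison_p <- if (stats::sd(c(mr$recall, bg_samples)) == 0) {
    1
  } else if (nrow(mr) < 2) {
    # a single module: compare the background distribution to its recall
    stats::t.test(bg_samples, mu = mr$recall)$p.value
  } else {
    stats::t.test(mr$recall, bg_samples)$p.value
  }
  structure(list(module_recall = mr, background_recall = background,
                 background_samples = bg_samples,
                 shapiro_p = shapiro_p, comparison_p = comparison_p),
            class = "module_evaluation")
}

#' @export
print.module_evaluation <- function(x, ...) {
  cat("Module PPI recall:", nrow(x$module_recall), "modules, mean recall",
      format(mean(x$module_recall$recall), digits = 3),
      "vs background", format(x$background_recall, digits = 3), "\n")
  cat("comparison p =", format(x$comparison_p, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.module_evaluation <- function(x, ...) {
  dplyr::mutate(x$module_recall, background_recall = x$background_recall)
}

#' @export
glance.module_evaluation <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x$module_recall),
                 mean_recall = mean(x$module_recall$recall),
                 background_recall = x$background_recall,
                 shapiro_p = x$shapiro_p,
                 comparison_p = x$comparison_p)
}

#' Hypergeometric compartment enrichment of a module
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` module
#' members annotated to a term, with population size `N = |universe|`,
#' `K = |term set|` annotated successes and `n = |module|` draws. Flagged
#' significant at `p < 0.05` (no multiple-testing correction by default,
#' switchable to Benjamini-Hochberg across the tested terms).
#'
#' @param members Character vector of module member proteins (subset of the
#'   universe).
#' @param annotation Named list of term membership vectors (see
#'   [read_gmt()]).
#' @param term Term name; must exist in `annotation`.
#' @param universe Background protein universe.
#' @return Upper-tail p-value.
#' @export
term_enrichment <- function(members, annotation, term, universe) {
  abort_if(!term %in% names(annotation),
           paste0("term not in annotation: ", term))
  members <- intersect(members, universe)
  term_set <- intersect(annotation[[term]], universe)
  k <- length(intersect(members, term_set))
  stats::phyper(k - 1, length(term_set),
                length(universe) - length(term_set),
                length(members), lower.tail = FALSE)
}

#' Compartment enrichment across modules and terms
#'
#' @param modules Output of [assemble_modules()].
#' @param annotation Named list of term membership vectors.
#' @param universe Background protein universe.
#' @param terms Terms to test (default: all in `annotation`).
#' @param adjust Apply Benjamini-Hochberg across all (module, term) tests
#'   (default `FALSE`, matching the uncorrected convention).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Tibble (`module`, `term`, `k`, `n`, `p`, `significant`).
#' @export
enrich_modules <- function(modules, annotation, universe,
                           terms = names(annotation), adjust = FALSE,
                           alpha = 0.05) {
  res <- tidyr::expand_grid(module = modules$module, term = terms) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      k = length(intersect(
        intersect(modules$members[[which(modules$module == .data$module)]],
                  universe),
        intersect(annotation[[.data$term]], universe))),
      n = length(intersect(
        modules$members[[which(modules$module == .data$module)]], universe)),
      p = term_enrichment(
        modules$members[[which(modules$module == .data$module)]],
        annotation, .data$term, universe)) |>
    dplyr::ungroup()
  if (adjust) res$p <- stats::p.adjust(res$p, method = "BH")
  dplyr::mutate(res, significant = .data$p < alpha)
}
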
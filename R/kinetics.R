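#' Kinetic response profiles relative to the unstimulated condition
#'
#' For each protein and treatment time point, computes
#' `log2(mean(condition) / mean(reference))`; the reference condition itself
#' is identically zero. Proteins not observed in the reference are excluded
#' with a warning.
#'
#' @param quant Protein-level tibble (`protein`, `condition`, `replicate`,
#'   `intensity`).
#' @param reference Unstimulated condition label (default `"untreated"`).
#' @param timepoints Optional character vector fixing the column order of the
#'   profile; defaults to all non-reference conditions in first-appearance
#'   order.
#' @return Tibble (`protein`, `condition`, `log2fc`) with `condition` an
#'   ordered factor over the time points.
#' @export
kinetic_profiles <- function(quant, reference = "untreated", timepoints = NULL) {
  abort_if(!reference %in% quant$condition,
           paste0("reference condition '", reference, "' not present"))
  timepoints <- timepoints %||% setdiff(unique(quant$condition), reference)
  means <- quant |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::group_by(.data$protein, .data$condition) |>
    dplyr::summarise(m = mean(.data$intensity), .groups = "drop")
  ref <- dplyr::filter(means, .data$condition == reference)
  no_ref <- setdiff(unique(means$protein), ref$protein)
  if (length(no_ref) > 0) {
    rlang::warn(paste0("excluded (missing in ", reference, "): ",
                       paste(no_ref, collapse = ", ")))
  }
  means |>
    dplyr::filter(.data$condition %in% timepoints,
                  .data$protein %in% ref$protein) |>
    dplyr::left_join(dplyr::select(ref, "protein", ref_m = "m"), by = "protein") |>
    dplyr::transmute(protein = .data$protein,
                     condition = factor(.data$condition, levels = timepoints),
                     log2fc = log2(.data$m / .data$ref_m)) |>
    dplyr::arrange(.data$protein, .data$condition)
}

#' Fuzzy c-means clustering of kinetic profiles
#'
#' Groups fold-change time courses by response shape with the fuzzy c-means
#' algorithm: memberships `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))`, centers
#' as membership-weighted means, iterated until the largest center shift
#' falls below `tol`. Profiles are z-scored per protein before clustering so
#' only the shape matters. Initialization is by seeded random membership with
#' multiple restarts, keeping the solution with the lowest objective.
#'
#' @param profiles Output of [kinetic_profiles()] (long tibble) or a numeric
#'   matrix with one row per protein.
#' @param c Number of clusters (default 3).
#' @param m Fuzzifier, > 1 (default 2).
#' @param tol Convergence tolerance on the maximum center shift
#'   (default 1e-6).
#' @param max_iter Iteration cap per restart (default 200).
#' @param seed Seed for the random initializations.
#' @param restarts Number of random restarts (default 10).
#' @param standardize z-score profiles before clustering (default `TRUE`).
#' @return A `fuzzy_cmeans` object: `membership` (n x c matrix, rows sum
#'   to 1), `centers` (c x timepoints), `objective`, `objective_trace`,
#'   `cluster` (hard argmax assignment), `data` (the clustered matrix).
#' @export
fuzzy_cmeans <- function(profiles, c = 3, m = 2, tol = 1e-6, max_iter = 200,
                         seed = NULL, restarts = 10, standardize = TRUE) {
  x <- if (is.matrix(profiles)) profiles else {
    wide <- tidyr::pivot_wider(profiles, id_cols = "protein",
                               names_from = "condition",
                               values_from = "log2fc")
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide$protein
    mat
  }
  abort_if(any(!is.finite(x)), "profiles must be finite")
  abort_if(m <= 1, "fuzzifier m must be > 1")
  abort_if(c < 1, "c must be >= 1")
  abort_if(c > nrow(x), "more clusters than profiles")
  z <- if (standardize) t(apply(x, 1, zscore)) else x
  dimnames(z) <- list(rownames(x),
                      colnames(x) %||% paste0("T", seq_len(ncol(x))))
  n <- nrow(z)

  run_once <- function() {
    u <- matrix(stats::runif(n * c), n, c)
    u <- u / rowSums(u)
    trace <- numeric(0)
    centers <- matrix(0, c, ncol(z))
    for (iter in seq_len(max_iter)) {
      w <- u^m
      centers_new <- (t(w) %*% z) / colSums(w)
      d2 <- outer(rowSums(z^2), rep(1, c)) - 2 * z %*% t(centers_new) +
        outer(rep(1, n), rowSums(centers_new^2))
      d2 <- pmax(d2, 1e-12)
      u <- 1 / (d2^(1 / (m - 1)) * rowSums((1 / d2)^(1 / (m - 1))))
      trace <- c(trace, sum(u^m * d2))
      shift <- if (iter == 1) Inf else max(abs(centers_new - centers))
      centers <- centers_new
      if (shift < tol) break
    }
    list(u = u, centers = centers, objective = trace[length(trace)],
         trace = trace)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, restarts))) {
      fit <- run_once()
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    dimnames(best$u) <- list(rownames(z), paste0("C", seq_len(c)))
    dimnames(best$centers) <- list(paste0("C", seq_len(c)), colnames(z))
    structure(list(membership = best$u, centers = best$centers,
                   objective = best$objective,
                   objective_trace = best$trace,
                   cluster = stats::setNames(max.col(best$u), rownames(z)),
                   m = m, c = c, data = z),
              class = "fuzzy_cmeans")
  })
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat("Fuzzy c-means clustering: c =", x$c, ", m =", x$m,
      ",", nrow(x$membership), "profiles\n")
  cat("objective:", format(x$objective, digits = 6),
      "after", length(x$objective_trace), "iterations\n")
  cat("hard cluster sizes:", paste(tabulate(x$cluster, x$c), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a fuzzy clustering into long memberships
#'
#' @param x A `fuzzy_cmeans` object.
#' @param ... Unused.
#' @return Tibble (`protein`, `cluster`, `membership`, `hard`).
#' @export
tidy.fuzzy_cmeans <- function(x, ...) {
  tibble::as_tibble(x$membership, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "cluster",
                        values_to = "membership") |>
    dplyr::mutate(hard = paste0("C", x$cluster[.data$protein]) == .data$cluster)
}

#' One-row summary of a fuzzy clustering
#'
#' @param x A `fuzzy_cmeans` object.
#' @param ... Unused.
#' @return One-row tibble (`c`, `m`, `n`, `objective`, `iterations`,
#'   `mean_max_membership`).
#' @export
glance.fuzzy_cmeans <- function(x, ...) {
  tibble::tibble(c = x$c, m = x$m, n = nrow(x$membership),
                 objective = x$objective,
                 iterations = length(x$objective_trace),
                 mean_max_membership = mean(apply(x$membership, 1, max)))
}

#' Plot fuzzy cluster centers and member profiles
#'
#' @param object A `fuzzy_cmeans` object.
#' @param ... Unused.
#' @return A ggplot: one facet per cluster, member profiles shaded by
#'   membership, center overlaid.
#' @export
autoplot.fuzzy_cmeans <- function(object, ...) {
  members <- tibble::as_tibble(object$data, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "timepoint", values_to = "z") |>
    dplyr::mutate(cluster = paste0("C", object$cluster[.data$protein]),
                  membership = apply(object$membership, 1, max)[.data$protein],
                  timepoint = factor(.data$timepoint,
                                     levels = colnames(object$data)))
  centers <- tibble::as_tibble(object$centers, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint", values_to = "z") |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = colnames(object$data)))
  ggplot2::ggplot(members,
                  ggplot2::aes(.data$timepoint, .data$z, group = .data$protein)) +
    ggplot2::geom_line(ggplot2::aes(alpha = .data$membership), colour = "grey40") +
    ggplot2::geom_line(data = centers,
                       ggplot2::aes(group = .data$cluster),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized log2 fold change",
                  alpha = "membership") +
    ggplot2::theme_minimal()
}
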
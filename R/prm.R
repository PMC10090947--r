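#' PRM acceptance and quantification parameters
#'
#' Defaults follow the targeted-analysis record: retention time within 5% of
#' the gradient length of the library value, spectral dot product strictly
#' above 0.75, fragments below signal-to-noise 5 removed, and quantification
#' as the sum of the top three surviving fragment areas.
#'
#' @param rt_tolerance_fraction RT window as a fraction of the gradient
#'   (default 0.05).
#' @param min_dotp Minimum (exclusive) spectral dot product (default 0.75).
#' @param min_sn Minimum signal-to-noise for a fragment to be quantified
#'   (default 5; strict `<` filters).
#' @param quant_top_fragments Fragments summed for quantification (default 3).
#' @return A `prm_params` list.
#' @export
prm_params <- function(rt_tolerance_fraction = 0.05, min_dotp = 0.75,
                       min_sn = 5, quant_top_fragments = 3) {
  abort_if(rt_tolerance_fraction <= 0, "rt_tolerance_fraction must be > 0")
  abort_if(min_dotp <= 0 || min_dotp > 1, "min_dotp must be in (0,1]")
  abort_if(min_sn <= 0 || quant_top_fragments < 1, "invalid PRM parameters")
  structure(list(rt_tolerance_fraction = rt_tolerance_fraction,
                 min_dotp = min_dotp, min_sn = min_sn,
                 quant_top_fragments = quant_top_fragments),
            class = "prm_params")
}

#' Normalized spectral dot product
#'
#' Cosine similarity between observed fragment areas and library relative
#' intensities, over their shared fragments (at least two required). An
#' all-zero observed vector gives 0 by convention. Scale-invariant in both
#' arguments and bounded in `[0, 1]` for non-negative input.
#'
#' @param observed Named numeric vector of observed fragment areas.
#' @param library_intensities Named numeric vector of library relative
#'   intensities.
#' @return Value in `[0, 1]`.
#' @examples
#' dot_product(c(y1 = 1, y2 = 0, y3 = 1), c(y1 = 1, y2 = 1, y3 = 0))  # 0.5
#' @export
dot_product <- function(observed, library_intensities) {
  shared <- intersect(names(observed), names(library_intensities))
  abort_if(length(shared) < 2, "need >= 2 shared fragments")
  o <- observed[shared]
  l <- library_intensities[shared]
  if (all(o == 0) || all(l == 0)) return(0)
  sum(o * l) / sqrt(sum(o^2) * sum(l^2))
}

#' Accept or reject a PRM peak group
#'
#' A peak group is accepted when its apex retention time matches the library
#' value within `rt_tolerance_fraction` of the gradient length AND its
#' spectral dot product strictly exceeds `min_dotp`. Both criteria are
#' reported.
#'
#' @param rt Observed apex retention time (minutes).
#' @param observed Named vector of observed fragment areas.
#' @param library_entry List/row with `library_rt` and named
#'   `rel_intensity` vector (see [prm_assay()] library rows).
#' @param gradient_length Gradient length in minutes.
#' @param params A [prm_params()] list.
#' @return List (`accepted`, `rt_ok`, `dotp_ok`, `rt_delta`, `dotp`).
#' @export
accept_peak_group <- function(rt, observed, library_entry, gradient_length,
                              params = prm_params()) {
  abort_if(is.null(library_entry$library_rt) || is.na(library_entry$library_rt),
           "library RT missing")
  rt_delta <- abs(rt - library_entry$library_rt)
  dotp <- dot_product(observed, library_entry$rel_intensity)
  rt_ok <- rt_delta <= params$rt_tolerance_fraction * gradient_length
  dotp_ok <- dotp > params$min_dotp
  list(accepted = rt_ok && dotp_ok, rt_ok = rt_ok, dotp_ok = dotp_ok,
       rt_delta = rt_delta, dotp = dotp)
}

#' Quantify an accepted peak group
#'
#' Drops fragments with signal-to-noise below `min_sn` (strict `<`), then
#' sums the `quant_top_fragments` largest remaining areas. With fewer
#' surviving fragments than requested, all remaining areas are summed and the
#' quantification flagged low-fragment; with none, the result is missing.
#'
#' @param areas Numeric vector of fragment areas.
#' @param sn Numeric vector of fragment signal-to-noise ratios.
#' @param params A [prm_params()] list.
#' @return List (`intensity`, `n_fragments`, `low_fragment`).
#' @export
quantify_peptide <- function(areas, sn, params = prm_params()) {
  keep <- !is.na(areas) & !is.na(sn) & sn >= params$min_sn
  a <- areas[keep]
  if (length(a) == 0) {
    return(list(intensity = NA_real_, n_fragments = 0L, low_fragment = TRUE))
  }
  top <- sort(a, decreasing = TRUE)[seq_len(min(params$quant_top_fragments,
                                                length(a)))]
  list(intensity = sum(top), n_fragments = length(top),
       low_fragment = length(a) < params$quant_top_fragments)
}

#' Light/heavy log2 ratio
#'
#' Endogenous (light) over stable-isotope reference (heavy) intensity on the
#' log2 scale.
#'
#' @param light Light-channel intensity (may be `NA`).
#' @param heavy Heavy-channel intensity; must be positive.
#' @return `log2(light / heavy)`, or `NA` when light is missing.
#' @export
light_heavy_ratio <- function(light, heavy) {
  abort_if(any(is.na(heavy) | heavy <= 0), "heavy intensity must be > 0")
  log2(light / heavy)
}

#' Score and quantify a PRM run table
#'
#' Applies [accept_peak_group()] and [quantify_peptide()] to every
#' (peptide, group, channel) of a fragment-level table against an assay
#' library.
#'
#' @param peak_groups Fragment-level tibble (`peptide`, `group_id`,
#'   `channel`, `rt`, `fragment`, `area`, `sn`), e.g. from [simulate_prm()].
#' @param library Library tibble (`peptide`, `fragment`, `rel_intensity`,
#'   `library_rt`).
#' @param gradient_length Gradient length in minutes.
#' @param params A [prm_params()] list.
#' @return Tibble per (peptide, group, channel): `rt`, `dotp`, `rt_delta`,
#'   `accepted`, `intensity`, `n_fragments`, `low_fragment`.
#' @export
score_peak_groups <- function(peak_groups, library, gradient_length,
                              params = prm_params()) {
  peak_groups |>
    dplyr::group_by(.data$peptide, .data$group_id, .data$channel) |>
    dplyr::group_map(function(g, key) {
      le <- library[library$peptide == key$peptide, ]
      obs <- stats::setNames(g$area, g$fragment)
      entry <- list(library_rt = le$library_rt[1],
                    rel_intensity = stats::setNames(le$rel_intensity,
                                                    le$fragment))
      acc <- accept_peak_group(g$rt[1], obs, entry, gradient_length, params)
      q <- quantify_peptide(g$area, g$sn, params)
      tibble::tibble(peptide = key$peptide, group_id = key$group_id,
                     channel = key$channel, rt = g$rt[1],
                     dotp = acc$dotp, rt_delta = acc$rt_delta,
                     accepted = acc$accepted,
                     intensity = if (acc$accepted) q$intensity else NA_real_,
                     n_fragments = q$n_fragments,
                     low_fragment = q$low_fragment)
    }) |>
    dplyr::bind_rows()
}

#' Normalize a targeted panel across runs
#'
#' Divides every run by the geometric mean of its reference intensities,
#' rescaled by the grand mean so equal references leave the table unchanged.
#' Modes: `"housekeeping_irt"` (housekeeping plus iRT reference peptides),
#' `"tag_peptide"` (a shared affinity-tag peptide present in every bait
#' construct), and `"bait_peptides"` (a set of bait peptides; phosphopeptide
#' rows, marked by `is_phospho`, are additionally divided by the run's bait
#' level so phosphorylation changes are separated from bait-abundance
#' changes).
#'
#' @param panel Tibble (`entity`, `run`, `intensity`, optional logical
#'   `is_phospho`).
#' @param mode One of `"bait_peptides"`, `"housekeeping_irt"`,
#'   `"tag_peptide"`.
#' @param reference_ids Entities forming the reference set; each must be
#'   observed in every run.
#' @return The normalized tibble.
#' @export
normalize_panel <- function(panel, mode = c("bait_peptides",
                                            "housekeeping_irt",
                                            "tag_peptide"),
                            reference_ids) {
  mode <- match.arg(mode)
  abort_if(length(reference_ids) == 0, "reference_ids must be non-empty")
  runs <- unique(panel$run)
  refs <- dplyr::filter(panel, .data$entity %in% reference_ids,
                        !is.na(.data$intensity))
  per_run <- refs |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(n_ref = dplyr::n_distinct(.data$entity),
                     gm = geom_mean(.data$intensity), .groups = "drop")
  incomplete <- c(setdiff(runs, per_run$run),
                  per_run$run[per_run$n_ref < length(reference_ids)])
  abort_if(length(incomplete) > 0,
           paste0("reference peptide(s) ",
                  paste(reference_ids, collapse = ", "),
                  " missing in run ", paste(incomplete, collapse = ", ")))
  scale <- mean(per_run$gm)
  out <- panel |>
    dplyr::left_join(dplyr::select(per_run, "run", "gm"), by = "run") |>
    dplyr::mutate(intensity = .data$intensity / .data$gm * scale) |>
    dplyr::select(-"gm")
  if (mode == "bait_peptides" && "is_phospho" %in% names(panel)) {
    bait_level <- out |>
      dplyr::filter(.data$entity %in% reference_ids) |>
      dplyr::group_by(.data$run) |>
      dplyr::summarise(bait = geom_mean(.data$intensity), .groups = "drop")
    out <- out |>
      dplyr::left_join(bait_level, by = "run") |>
      dplyr::mutate(intensity = dplyr::if_else(
        .data$is_phospho, .data$intensity / .data$bait, .data$intensity)) |>
      dplyr::select(-"bait")
  }
  out
}

#' Knockout-panel fold changes and principal component analysis
#'
#' Per entity and cell line: log2 fold change versus the parental line with a
#' two-sided t test across replicates. A principal component analysis is run
#' on the centered entity-by-line fold-change matrix with the knockout target
#' entities removed (their loss is trivially the dominant signal); explained
#' variance ratios sum to 1.
#'
#' @param panel Normalized tibble (`entity`, `cell_line`, `replicate`,
#'   `intensity`).
#' @param parental Parental cell-line label.
#' @param ko_targets Entities removed from the PCA input (default none).
#' @param scale. Scale entities to unit variance before PCA (default `FALSE`;
#'   log2 fold changes are already on a comparable scale).
#' @return A `panel_summary` object: `fold_changes` tibble (`entity`,
#'   `cell_line`, `log2fc`, `p`), `pca` (the `prcomp` fit),
#'   `explained_variance` (named ratios summing to 1).
#' @export
panel_summary <- function(panel, parental, ko_targets = character(),
                          scale. = FALSE) {
  abort_if(!parental %in% panel$cell_line,
           paste0("parental line '", parental, "' not present"))
  ref <- dplyr::filter(panel, .data$cell_line == parental)
  fc <- panel |>
    dplyr::filter(.data$cell_line != parental, !is.na(.data$intensity)) |>
    dplyr::group_by(.data$entity, .data$cell_line) |>
    dplyr::group_map(function(g, key) {
      r <- ref$intensity[ref$entity == key$entity & !is.na(ref$intensity)]
      if (length(r) < 2 || nrow(g) < 2) return(NULL)
      x <- log2(g$intensity)
      y <- log2(r)
      tibble::tibble(entity = key$entity, cell_line = key$cell_line,
                     log2fc = mean(x) - mean(y),
                     p = if (stats::sd(x) == 0 && stats::sd(y) == 0) 1 else
                       tryCatch(stats::t.test(x, y)$p.value,
                                error = function(e) 1))
    }) |>
    dplyr::bind_rows()
  mat <- fc |>
    dplyr::filter(!.data$entity %in% ko_targets) |>
    tidyr::pivot_wider(id_cols = "entity", names_from = "cell_line",
                       values_from = "log2fc") |>
    tibble::column_to_rownames("entity") |>
    as.matrix()
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  pca <- stats::prcomp(t(mat), center = TRUE, scale. = scale.)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  names(ev) <- colnames(pca$x)
  structure(list(fold_changes = fc, pca = pca, explained_variance = ev,
                 ko_targets = ko_targets, parental = parental),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("Knockout-panel summary vs", x$parental, ":",
      dplyr::n_distinct(x$fold_changes$cell_line), "lines,",
      dplyr::n_distinct(x$fold_changes$entity), "entities\n")
  cat("PC1 explains", sprintf("%.1f%%", 100 * x$explained_variance[1]), "\n")
  invisible(x)
}

#' @export
tidy.panel_summary <- function(x, ...) {
  tibble::as_tibble(x$fold_changes)
}

#' @export
glance.panel_summary <- function(x, ...) {
  tibble::tibble(n_lines = dplyr::n_distinct(x$fold_changes$cell_line),
                 n_entities = dplyr::n_distinct(x$fold_changes$entity),
                 pc1_variance = x$explained_variance[1],
                 pc2_variance = if (length(x$explained_variance) > 1)
                   x$explained_variance[2] else NA_real_)
}

#' Knockout-panel PCA score plot
#'
#' @param object A `panel_summary` object.
#' @param ... Unused.
#' @return A ggplot of the cell lines in the first two principal components.
#' @export
autoplot.panel_summary <- function(object, ...) {
  sc <- tibble::as_tibble(object$pca$x[, 1:2, drop = FALSE],
                          rownames = "cell_line")
  ev <- object$explained_variance
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1,
                                   if ("PC2" %in% names(sc)) .data$PC2 else 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell_line),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = if (length(ev) > 1)
                    sprintf("PC2 (%.1f%%)", 100 * ev[2]) else "PC2") +
    ggplot2::theme_minimal()
}
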
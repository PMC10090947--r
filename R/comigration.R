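#' Peak detection and preprocessing parameters
#'
#' Defaults follow the analysis record: minimum normalized peak intensity 0.2
#' for proteins and 0.3 for phosphopeptides, smoothing/merge width 2 fractions
#' (read as the FWHM of the Gaussian smoothing kernel, sigma = 2/2.355), and
#' the two-level phosphopeptide localization filter (score > 0.8 in at least
#' one fraction to keep the peptide; fractions kept only where the score is
#' >= 0.5).
#'
#' @param min_norm_intensity_protein,min_norm_intensity_phospho Minimum
#'   normalized smoothed peak height, in (0, 1).
#' @param width Smoothing kernel FWHM and peak-merge radius, in fractions.
#' @param loc_any_fraction Localization score required somewhere (default 0.8).
#' @param loc_per_fraction Per-fraction localization score floor (default 0.5).
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_norm_intensity_protein = 0.2,
                        min_norm_intensity_phospho = 0.3,
                        width = 2,
                        loc_any_fraction = 0.8,
                        loc_per_fraction = 0.5) {
  abort_if(min_norm_intensity_protein <= 0 || min_norm_intensity_protein >= 1,
           "min_norm_intensity_protein must be in (0,1)")
  abort_if(min_norm_intensity_phospho <= 0 || min_norm_intensity_phospho >= 1,
           "min_norm_intensity_phospho must be in (0,1)")
  abort_if(width <= 0, "width must be > 0")
  abort_if(loc_any_fraction < 0 || loc_any_fraction > 1 ||
             loc_per_fraction < 0 || loc_per_fraction > 1,
           "localization thresholds must be in [0,1]")
  structure(list(min_norm_intensity_protein = min_norm_intensity_protein,
                 min_norm_intensity_phospho = min_norm_intensity_phospho,
                 width = width,
                 loc_any_fraction = loc_any_fraction,
                 loc_per_fraction = loc_per_fraction),
            class = "peak_params")
}

#' Preprocess raw migration profiles
#'
#' Applies, in order: (1) per-fraction iRT normalization (divide each
#' fraction's intensities by that fraction's iRT intensity); (2) for bait
#' phosphopeptides only, division by the bait protein profile, so changes in
#' phosphorylation are separated from changes in bait abundance; (3) the
#' two-level localization filter on phosphopeptides; (4) imputation of
#' interior missing values with the mean of the two flanking fractions (edge
#' fractions use the single available neighbor); (5) scaling of each profile
#' to maximum 1.
#'
#' @param profiles Long profile tibble (`entity_id`, `entity_kind`,
#'   `fraction`, `intensity`, `loc_score`).
#' @param irt Tibble (`fraction`, `intensity`) of iRT standard intensities;
#'   must be positive in every fraction.
#' @param bait Optional bait profile tibble (`fraction`, `intensity`) used in
#'   step (2); skipped when `NULL`.
#' @param params A [peak_params()] list.
#' @return Preprocessed long tibble; all-missing profiles are dropped with a
#'   warning and failing phosphopeptides removed.
#' @export
preprocess_profiles <- function(profiles, irt, bait = NULL,
                                params = peak_params()) {
  fracs <- sort(unique(profiles$fraction))
  irt <- dplyr::arrange(tibble::as_tibble(irt), .data$fraction)
  bad <- irt$fraction[is.na(irt$intensity) | irt$intensity <= 0]
  abort_if(length(bad) > 0,
           paste0("iRT intensity missing or non-positive in fraction ",
                  paste(bad, collapse = ", ")))
  abort_if(!all(fracs %in% irt$fraction), "iRT must cover every fraction")

  df <- profiles |>
    dplyr::left_join(dplyr::select(irt, "fraction", irt_i = "intensity"),
                     by = "fraction") |>
    dplyr::mutate(intensity = .data$intensity / .data$irt_i) |>
    dplyr::select(-"irt_i")

  if (!is.null(bait)) {
    bait <- dplyr::select(tibble::as_tibble(bait), "fraction",
                          bait_i = "intensity")
    df <- df |>
      dplyr::left_join(bait, by = "fraction") |>
      dplyr::mutate(intensity = dplyr::if_else(
        .data$entity_kind == "bait_phosphopeptide" & !is.na(.data$bait_i) &
          .data$bait_i > 0,
        .data$intensity / .data$bait_i, .data$intensity)) |>
      dplyr::select(-"bait_i")
  }

  # two-level localization filter (phosphopeptides only)
  df <- df |>
    dplyr::group_by(.data$entity_id) |>
    dplyr::filter(.data$entity_kind[1] != "bait_phosphopeptide" |
                    any(.data$loc_score > params$loc_any_fraction,
                        na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(intensity = dplyr::if_else(
      .data$entity_kind == "bait_phosphopeptide" &
        (is.na(.data$loc_score) | .data$loc_score < params$loc_per_fraction),
      NA_real_, .data$intensity))

  impute_neighbors <- function(x) {
    miss <- which(is.na(x))
    for (i in miss) {
      left <- if (i > 1) x[i - 1] else NA_real_
      right <- if (i < length(x)) x[i + 1] else NA_real_
      nb <- c(left, right)
      if (any(!is.na(nb))) x[i] <- mean(nb, na.rm = TRUE)
    }
    x
  }

  out <- df |>
    dplyr::arrange(.data$entity_id, .data$fraction) |>
    dplyr::group_by(.data$entity_id, .data$entity_kind) |>
    dplyr::group_map(function(g, key) {
      x <- impute_neighbors(g$intensity)
      x[is.na(x)] <- 0
      mx <- max(x)
      if (!is.finite(mx) || mx <= 0) {
        rlang::warn(paste0("profile dropped (no signal): ", key$entity_id))
        return(NULL)
      }
      dplyr::mutate(g, entity_id = key$entity_id,
                    entity_kind = key$entity_kind,
                    intensity = x / mx)
    }) |>
    dplyr::bind_rows()
  dplyr::select(out, "entity_id", "entity_kind", "fraction", "intensity",
                dplyr::any_of("loc_score"))
}

# Peak detection on a single normalized intensity vector. Returns a tibble of
# apex/boundary fractions with smoothed heights and an FWHM estimate from the
# half-maximum crossings of the smoothed trace.
detect_peaks_vector <- function(x, min_height, width) {
  n <- length(x)
  s <- gaussian_smooth(x, width)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) s[i - 1] else -Inf
    right <- if (i < n) s[i + 1] else -Inf
    s[i] > left && s[i] >= right
  }, logical(1))
  apex <- which(is_max & s >= min_height)
  if (length(apex) == 0) {
    return(tibble::tibble(peak = integer(), apex = integer(),
                          left = integer(), right = integer(),
                          height = numeric(), fwhm = numeric()))
  }
  # merge apexes closer than `width` fractions, keeping the higher
  apex <- apex[order(s[apex], decreasing = TRUE)]
  kept <- integer(0)
  for (a in apex) {
    if (all(abs(a - kept) >= width)) kept <- c(kept, a)
  }
  kept <- sort(kept)
  bounds <- function(a) {
    l <- a
    while (l > 1 && s[l - 1] < s[l]) l <- l - 1
    r <- a
    while (r < n && s[r + 1] < s[r]) r <- r + 1
    c(l, r)
  }
  half_width <- function(a) {
    half <- s[a] / 2
    l <- a
    while (l > 1 && s[l] > half) l <- l - 1
    r <- a
    while (r < n && s[r] > half) r <- r + 1
    max(r - l, 1)
  }
  purrr::map_dfr(seq_along(kept), function(i) {
    b <- bounds(kept[i])
    tibble::tibble(peak = i, apex = kept[i], left = b[1], right = b[2],
                   height = s[kept[i]], fwhm = half_width(kept[i]))
  })
}

#' Detect migration peaks in preprocessed profiles
#'
#' Smooths each profile with a Gaussian kernel (FWHM = `width` fractions,
#' sigma = width/2.355), finds local maxima of the smoothed trace whose
#' smoothed height reaches the kind-specific minimum normalized intensity,
#' merges maxima closer than `width` fractions (keeping the higher), and sets
#' boundaries at the nearest local minima or range ends.
#'
#' @param profiles Preprocessed long profile tibble (max of each profile = 1).
#' @param params A [peak_params()] list.
#' @return Tibble (`entity_id`, `entity_kind`, `peak`, `apex`, `left`,
#'   `right`, `height`, `fwhm`); entities with no peak above threshold
#'   contribute no rows.
#' @export
detect_peaks <- function(profiles, params = peak_params()) {
  profiles |>
    dplyr::arrange(.data$entity_id, .data$fraction) |>
    dplyr::group_by(.data$entity_id, .data$entity_kind) |>
    dplyr::group_map(function(g, key) {
      thr <- if (key$entity_kind == "bait_phosphopeptide")
        params$min_norm_intensity_phospho else params$min_norm_intensity_protein
      pk <- detect_peaks_vector(g$intensity, thr, params$width)
      if (nrow(pk) == 0) return(NULL)
      dplyr::mutate(pk, entity_id = key$entity_id,
                    entity_kind = key$entity_kind, .before = 1)
    }) |>
    dplyr::bind_rows()
}

#' Split profiles into single-peak traces
#'
#' Produces one trace per detected peak. Traces of the same entity partition
#' the profile exactly: interior cut points are the minima of the profile
#' between adjacent apexes (the valley fraction goes to the left trace) and
#' the outermost traces extend to the range ends, so that the sum of an
#' entity's split traces equals its profile at every fraction.
#'
#' @param profiles Preprocessed long profile tibble.
#' @param peaks Output of [detect_peaks()].
#' @return Long tibble (`trace_id`, `entity_id`, `entity_kind`, `peak`,
#'   `apex`, `fraction`, `intensity`).
#' @export
split_profile <- function(profiles, peaks) {
  profiles |>
    dplyr::arrange(.data$entity_id, .data$fraction) |>
    dplyr::group_by(.data$entity_id, .data$entity_kind) |>
    dplyr::group_map(function(g, key) {
      pk <- peaks[peaks$entity_id == key$entity_id, ]
      if (nrow(pk) == 0) return(NULL)
      pk <- dplyr::arrange(pk, .data$apex)
      n <- nrow(g)
      cuts <- integer(0)
      if (nrow(pk) > 1) {
        cuts <- vapply(seq_len(nrow(pk) - 1), function(i) {
          lo <- pk$apex[i]
          hi <- pk$apex[i + 1]
          seg <- g$intensity[lo:hi]
          lo + which.min(seg) - 1L
        }, integer(1))
      }
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, n)
      purrr::map_dfr(seq_len(nrow(pk)), function(i) {
        v <- numeric(n)
        v[starts[i]:ends[i]] <- g$intensity[starts[i]:ends[i]]
        tibble::tibble(
          trace_id = sprintf("%s.%d", key$entity_id, pk$peak[i]),
          entity_id = key$entity_id, entity_kind = key$entity_kind,
          peak = pk$peak[i], apex = pk$apex[i],
          fraction = g$fraction, intensity = v)
      })
    }) |>
    dplyr::bind_rows()
}

#' Correlation distance between two split traces
#'
#' `1 - Pearson correlation` computed over the union of the two supports
#' (fractions where either trace is nonzero). Traces with disjoint supports
#' are maximally dissimilar (distance 2); a constant trace on the union gives
#' distance 1 by convention.
#'
#' @param a,b Numeric intensity vectors on the same fraction axis.
#' @return Distance in `[0, 2]`.
#' @export
peak_distance <- function(a, b) {
  abort_if(length(a) != length(b), "traces must share the fraction axis")
  sup <- which(a > 0 | b > 0)
  if (length(sup) == 0) return(1)
  if (!any(a > 0 & b > 0)) return(2)
  av <- a[sup]
  bv <- b[sup]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(1)
  1 - stats::cor(av, bv)
}

#' Pairwise distance matrix over split traces
#'
#' @param traces Output of [split_profile()].
#' @return A `dist` object over trace ids (ordered as in `traces`).
#' @export
trace_distance_matrix <- function(traces) {
  wide <- tidyr::pivot_wider(traces, id_cols = "trace_id",
                             names_from = "fraction",
                             values_from = "intensity")
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$trace_id
  k <- nrow(mat)
  d <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- peak_distance(mat[i, ], mat[j, ])
    }
  }
  stats::as.dist(d)
}

#' Cluster split traces into co-migration modules
#'
#' Excludes the bait's own traces (the bait migrates in every fraction and
#' would bridge all groups), runs agglomerative hierarchical clustering on
#' the peak correlation distance, and picks the number of clusters in
#' `[k_min, k_max]` that maximizes the mean silhouette width (ties resolved
#' toward the smaller k).
#'
#' @param traces Output of [split_profile()].
#' @param k_min,k_max Candidate range for the number of modules.
#' @param bait Bait entity id to exclude (default `"BAIT"`).
#' @param linkage Agglomeration method (default `"average"`).
#' @param silhouette_on `"distance"` (silhouette on the correlation-distance
#'   matrix, default) or `"euclidean"` (on the trace vectors).
#' @return A `comigration_clusters` object: `assignments` tibble
#'   (`trace_id`, `entity_id`, `entity_kind`, `apex`, `module`), chosen `k`,
#'   `silhouette` curve tibble, the `hclust` tree, and the distance matrix.
#' @export
cluster_modules <- function(traces, k_min = 2, k_max = 15, bait = "BAIT",
                            linkage = "average",
                            silhouette_on = c("distance", "euclidean")) {
  silhouette_on <- match.arg(silhouette_on)
  traces <- dplyr::filter(traces, .data$entity_id != bait)
  info <- dplyr::distinct(traces, .data$trace_id, .data$entity_id,
                          .data$entity_kind, .data$apex)
  abort_if(nrow(info) < 2, "need at least 2 non-bait traces")
  d <- trace_distance_matrix(traces)
  if (k_max > nrow(info)) {
    rlang::warn("k_max larger than trace count; clamped")
    k_max <- nrow(info)
  }
  k_min <- min(k_min, k_max)
  tree <- stats::hclust(d, method = linkage)
  d_sil <- if (silhouette_on == "distance") d else {
    wide <- tidyr::pivot_wider(traces, id_cols = "trace_id",
                               names_from = "fraction",
                               values_from = "intensity")
    stats::dist(as.matrix(wide[, -1]))
  }
  sil_curve <- purrr::map_dfr(seq(k_min, k_max), function(k) {
    cl <- stats::cutree(tree, k = k)
    msw <- if (k == 1 || k == nrow(info)) NA_real_ else
      mean(cluster::silhouette(cl, d_sil)[, "sil_width"])
    tibble::tibble(k = k, mean_silhouette = msw)
  })
  ok <- which(!is.na(sil_curve$mean_silhouette))
  k_best <- if (length(ok) == 0) k_min else
    sil_curve$k[ok[which.max(sil_curve$mean_silhouette[ok])]]
  cl <- stats::cutree(tree, k = k_best)
  assignments <- dplyr::mutate(
    info[match(names(cl), info$trace_id), ],
    module = sprintf("module_%02d", unname(cl)))
  structure(list(assignments = assignments, k = k_best,
                 silhouette = sil_curve, tree = tree, dist = d),
            class = "comigration_clusters")
}

#' @export
print.comigration_clusters <- function(x, ...) {
  cat("Co-migration clustering:", nrow(x$assignments), "split traces in",
      x$k, "modules\n")
  best <- x$silhouette$mean_silhouette[x$silhouette$k == x$k]
  if (length(best) == 1 && !is.na(best))
    cat("mean silhouette at k =", x$k, ":", format(best, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.comigration_clusters <- function(x, ...) {
  tibble::as_tibble(x$assignments)
}

#' @export
glance.comigration_clusters <- function(x, ...) {
  best <- x$silhouette$mean_silhouette[x$silhouette$k == x$k]
  tibble::tibble(k = x$k, n_traces = nrow(x$assignments),
                 mean_silhouette = if (length(best)) best else NA_real_)
}

#' Silhouette model-selection curve
#'
#' @param object A `comigration_clusters` object.
#' @param ... Unused.
#' @return A ggplot of mean silhouette width against the number of modules.
#' @export
autoplot.comigration_clusters <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(.data$k, .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of modules",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Estimate native molecular weight from an apex fraction
#'
#' Linear interpolation of `log10(kDa)` against fraction index through the
#' calibration points; apexes outside the calibrated range are linearly
#' extrapolated from the nearest segment and flagged.
#'
#' @param apex_fraction Numeric vector of apex fractions.
#' @param calibration Tibble/data frame (`fraction`, `kda`) with kDa strictly
#'   decreasing as fraction increases (gel top = high mass).
#' @return Tibble (`apex_fraction`, `mw_kda`, `extrapolated`).
#' @export
estimate_mw <- function(apex_fraction, calibration) {
  calibration <- dplyr::arrange(tibble::as_tibble(calibration), .data$fraction)
  abort_if(nrow(calibration) < 2, "need >= 2 calibration points")
  abort_if(any(diff(calibration$kda) >= 0),
           "calibration kDa must strictly decrease with fraction")
  lk <- log10(calibration$kda)
  fr <- calibration$fraction
  interp <- function(a) {
    if (a <= fr[1]) {
      s <- (lk[2] - lk[1]) / (fr[2] - fr[1])
      lk[1] + s * (a - fr[1])
    } else if (a >= fr[length(fr)]) {
      nn <- length(fr)
      s <- (lk[nn] - lk[nn - 1]) / (fr[nn] - fr[nn - 1])
      lk[nn] + s * (a - fr[nn])
    } else {
      stats::approx(fr, lk, xout = a)$y
    }
  }
  tibble::tibble(
    apex_fraction = apex_fraction,
    mw_kda = 10^vapply(apex_fraction, interp, numeric(1)),
    extrapolated = apex_fraction < fr[1] | apex_fraction > fr[length(fr)])
}

#' Assemble annotated co-migration modules
#'
#' Per cluster: the unique interactor members, the phosphosignature (bait
#' phosphosites with a trace in the cluster; may be empty), the
#' intensity-weighted mean apex fraction, and, if a calibration is given, the
#' estimated native molecular weight. Modules are sorted by apex fraction
#' (highest native mass first).
#'
#' @param clusters A `comigration_clusters` object.
#' @param traces The split traces the clustering was run on.
#' @param calibration Optional (`fraction`, `kda`) calibration for
#'   [estimate_mw()].
#' @return Tibble (`module`, `n_members`, `members` list-col,
#'   `phosphosignature` list-col, `apex`, `mw_kda`, `mw_extrapolated`).
#' @export
assemble_modules <- function(clusters, traces, calibration = NULL) {
  tot <- traces |>
    dplyr::group_by(.data$trace_id) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  mods <- clusters$assignments |>
    dplyr::left_join(tot, by = "trace_id") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_members = dplyr::n_distinct(
        .data$entity_id[.data$entity_kind == "protein"]),
      members = list(sort(unique(
        .data$entity_id[.data$entity_kind == "protein"]))),
      phosphosignature = list(sort(unique(
        .data$entity_id[.data$entity_kind == "bait_phosphopeptide"]))),
      apex = stats::weighted.mean(.data$apex, .data$total),
      .groups = "drop") |>
    dplyr::arrange(.data$apex)
  if (!is.null(calibration)) {
    mw <- estimate_mw(mods$apex, calibration)
    mods$mw_kda <- mw$mw_kda
    mods$mw_extrapolated <- mw$extrapolated
  }
  mods
}
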
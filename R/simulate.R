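#' Ground-truth description of planted co-migration modules
#'
#' Defines the complexes a BN-PAGE simulation plants: each module has an apex
#' fraction, a peak full width at half maximum (FWHM, in fractions), member
#' proteins with stoichiometry weights, and attached bait phosphosites.
#' Multi-assembly proteins may appear in several modules.
#'
#' @param modules Tibble with columns `module_id`, `apex_fraction`, `fwhm`.
#' @param members Tibble with columns `module_id`, `protein`, `weight` (> 0).
#' @param phosphosites Tibble with columns `module_id`, `site` (may have zero
#'   rows: a module's phosphosignature can be empty).
#' @param n_fractions Number of native gel fractions (default 64).
#' @return A validated `complex_truth` object.
#' @export
complex_truth <- function(modules, members, phosphosites = NULL,
                          n_fractions = 64) {
  modules <- tibble::as_tibble(modules)
  members <- tibble::as_tibble(members)
  phosphosites <- tibble::as_tibble(
    phosphosites %||% tibble::tibble(module_id = character(), site = character()))
  abort_if(any(modules$apex_fraction < 1 | modules$apex_fraction > n_fractions),
           "apex_fraction outside the fraction range",
           class = "comigratr_validation_error")
  abort_if(any(modules$fwhm <= 0), "fwhm must be > 0")
  abort_if(any(members$weight <= 0), "member weights must be > 0")
  abort_if(!all(members$module_id %in% modules$module_id),
           "member refers to an unknown module")
  abort_if(!all(phosphosites$module_id %in% modules$module_id),
           "phosphosite attached to an unknown module")
  abort_if(any(!modules$module_id %in% members$module_id),
           "every module needs at least one member")
  structure(list(modules = modules, members = members,
                 phosphosites = phosphosites, n_fractions = n_fractions),
            class = "complex_truth")
}

#' Default planted-complex layout
#'
#' A nine-module layout with 3-8 members each, apexes spaced at least two FWHM
#' apart across the 64-fraction axis, one multi-assembly protein shared
#' between the two largest modules, and one or two phosphosites attached to
#' most modules (one module deliberately carries none). This mirrors the
#' structure of a bait interactome resolved into discrete native assemblies.
#'
#' @param n_modules Number of planted modules (default 9).
#' @param fwhm Peak FWHM in fractions (default 2).
#' @param seed Seed controlling member counts and weights.
#' @return A `complex_truth` object.
#' @export
default_complex_truth <- function(n_modules = 9, fwhm = 2, seed = 1) {
  with_seed(derive_seed(seed, "truth"), {
    apexes <- round(seq(6, 58, length.out = n_modules))
    mods <- tibble::tibble(
      module_id = sprintf("M%02d", seq_len(n_modules)),
      apex_fraction = apexes,
      fwhm = fwhm
    )
    sizes <- sample(3:8, n_modules, replace = TRUE)
    members <- purrr::map2_dfr(mods$module_id, sizes, function(id, k) {
      tibble::tibble(
        module_id = id,
        protein = sprintf("P_%s_%d", id, seq_len(k)),
        weight = stats::runif(k, 0.5, 1)
      )
    })
    # one multi-assembly protein shared between the first two modules
    shared <- members$protein[members$module_id == mods$module_id[1]][1]
    members <- dplyr::bind_rows(
      members,
      tibble::tibble(module_id = mods$module_id[2], protein = shared,
                     weight = 0.8))
    sites <- purrr::map_dfr(seq_len(n_modules), function(i) {
      if (i == 3) return(NULL)  # a module with an empty phosphosignature
      k <- sample(1:2, 1)
      tibble::tibble(module_id = mods$module_id[i],
                     site = sprintf("S%d", 100 * i + seq_len(k)))
    })
    complex_truth(mods, members, sites)
  })
}

#' Simulate BN-PAGE migration profiles from planted complexes
#'
#' Each member protein's profile is the sum, over the modules it belongs to,
#' of `weight * exp(-(f - apex)^2 / (2 sigma^2))` with `sigma = fwhm / 2.355`,
#' perturbed by multiplicative log-normal noise and clipped at zero. Attached
#' phosphopeptides inherit their module's peak. Dropout replaces intensities
#' with missing values. Phosphopeptide localization scores are drawn high
#' (> 0.8 somewhere, >= 0.5 per signal fraction) for true sites so that the
#' two-level localization filter is exercised.
#'
#' @param truth A [complex_truth()] object.
#' @param noise_sd Log-scale standard deviation of the multiplicative noise
#'   (default 0.2, a realistic MS1 intensity CV of about 20%).
#' @param dropout_rate Probability that a measured value is missing
#'   (default 0.05).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `profiles` (long tibble: `entity_id`, `entity_kind`,
#'   `fraction`, `intensity`, `loc_score`), `irt` (per-fraction iRT
#'   intensities), `bait` (bait profile tibble), and `truth` (entity-level
#'   labels for tests only).
#' @export
simulate_bnpage <- function(truth, noise_sd = 0.2, dropout_rate = 0.05,
                            seed = 1) {
  abort_if(!inherits(truth, "complex_truth"), "truth must be a complex_truth")
  abort_if(noise_sd < 0, "noise_sd must be >= 0")
  abort_if(dropout_rate < 0 || dropout_rate >= 1, "dropout_rate must be in [0,1)")
  n <- truth$n_fractions
  fr <- seq_len(n)
  mod_tab <- truth$modules

  shape <- function(apex, fwhm, weight) {
    sigma <- fwhm / 2.355
    weight * exp(-((fr - apex)^2) / (2 * sigma^2))
  }

  with_seed(seed, {
    noisy <- function(base) {
      v <- base * exp(stats::rnorm(n, 0, noise_sd))
      v[base < 1e-12] <- base[base < 1e-12]  # no noise floor outside the peak
      v <- pmax(v, 0)
      if (dropout_rate > 0) v[stats::runif(n) < dropout_rate] <- NA_real_
      v
    }

    prot_profiles <- truth$members |>
      dplyr::left_join(mod_tab, by = "module_id") |>
      dplyr::group_by(.data$protein) |>
      dplyr::group_map(function(g, key) {
        base <- Reduce(`+`, purrr::pmap(
          list(g$apex_fraction, g$fwhm, g$weight), shape))
        tibble::tibble(entity_id = key$protein, entity_kind = "protein",
                       fraction = fr, intensity = noisy(base),
                       loc_score = NA_real_)
      }) |>
      dplyr::bind_rows()

    phos_profiles <- if (nrow(truth$phosphosites) == 0) NULL else
      truth$phosphosites |>
      dplyr::left_join(mod_tab, by = "module_id") |>
      dplyr::group_by(.data$site) |>
      dplyr::group_map(function(g, key) {
        base <- Reduce(`+`, purrr::pmap(
          list(g$apex_fraction, g$fwhm, rep(1, nrow(g))), shape))
        loc <- stats::runif(n, 0.5, 1)            # per-fraction placement score
        loc[which.max(base)] <- stats::runif(1, 0.85, 1)  # confident somewhere
        tibble::tibble(entity_id = key$site, entity_kind = "bait_phosphopeptide",
                       fraction = fr, intensity = noisy(base), loc_score = loc)
      }) |>
      dplyr::bind_rows()

    # bait protein migrates in every module, so it spans most fractions
    bait_base <- Reduce(`+`, purrr::pmap(
      list(mod_tab$apex_fraction, mod_tab$fwhm * 2, rep(1, nrow(mod_tab))),
      shape)) + 0.2
    bait <- tibble::tibble(entity_id = "BAIT", entity_kind = "protein",
                           fraction = fr,
                           intensity = pmax(bait_base * exp(stats::rnorm(n, 0, noise_sd)), 1e-6),
                           loc_score = NA_real_)

    irt <- tibble::tibble(fraction = fr,
                          intensity = exp(stats::rnorm(n, 0, noise_sd / 2)))

    truth_labels <- dplyr::bind_rows(
      dplyr::left_join(truth$members, mod_tab, by = "module_id") |>
        dplyr::transmute(entity_id = .data$protein, entity_kind = "protein",
                         module_id = .data$module_id,
                         apex_fraction = .data$apex_fraction),
      dplyr::left_join(truth$phosphosites, mod_tab, by = "module_id") |>
        dplyr::transmute(entity_id = .data$site,
                         entity_kind = "bait_phosphopeptide",
                         module_id = .data$module_id,
                         apex_fraction = .data$apex_fraction))

    list(profiles = dplyr::bind_rows(prot_profiles, phos_profiles),
         irt = irt, bait = bait, truth = truth_labels)
  })
}

#' AP-MS simulation design
#'
#' Describes a replicated AP-MS experiment: conditions, planted per-protein
#' log2 fold changes versus the reference condition, which proteins are true
#' interactors versus nonspecific background, and the missingness rate.
#'
#' @param n_interactors,n_background Number of true interactors and background
#'   proteins.
#' @param conditions Character vector of condition labels; the first is the
#'   reference.
#' @param replicates Replicates per condition (>= 2; default 3, matching a
#'   triplicate design).
#' @param log2fc Tibble `(protein, condition, log2fc)` of planted effects;
#'   unlisted pairs default to 0.
#' @param missingness Probability an intensity is missing, in `[0, 1)`.
#' @param noise_sd Log2-scale replicate noise standard deviation (default 0.2).
#' @return An `apms_design` object.
#' @export
apms_design <- function(n_interactors = 20, n_background = 30,
                        conditions = c("untreated", "treated"),
                        replicates = 3, log2fc = NULL,
                        missingness = 0.05, noise_sd = 0.2) {
  abort_if(replicates < 2, "replicates must be >= 2")
  abort_if(missingness < 0 || missingness >= 1, "missingness must be in [0,1)")
  log2fc <- tibble::as_tibble(
    log2fc %||% tibble::tibble(protein = character(), condition = character(),
                               log2fc = numeric()))
  abort_if(any(!is.finite(log2fc$log2fc)), "planted log2fc must be finite")
  structure(list(
    interactors = sprintf("INT%03d", seq_len(n_interactors)),
    background = sprintf("BG%03d", seq_len(n_background)),
    conditions = conditions, replicates = replicates,
    log2fc = log2fc, missingness = missingness, noise_sd = noise_sd),
    class = "apms_design")
}

#' Simulate replicate AP-MS peptide tables with planted fold changes
#'
#' Each protein gets 2-5 peptides with log-normal intensities; condition means
#' are offset by the planted log2 fold change; true interactors receive
#' SAINT-style confidence scores >= 0.95 and background proteins < 0.5. The
#' bait protein `"BAIT"` is added at a constant high level in every run.
#'
#' @param design An [apms_design()] object.
#' @param seed Integer seed.
#' @return List with `peptides` (long peptide tibble), `scores` (protein
#'   confidence scores), and `truth` (planted effects).
#' @export
simulate_apms <- function(design, seed = 1) {
  abort_if(!inherits(design, "apms_design"), "design must be an apms_design")
  proteins <- c(design$interactors, design$background)
  with_seed(seed, {
    base_log2 <- stats::setNames(stats::runif(length(proteins), 18, 24), proteins)
    n_pep <- stats::setNames(sample(2:5, length(proteins), replace = TRUE), proteins)
    runs <- tidyr::expand_grid(condition = design$conditions,
                               replicate = seq_len(design$replicates))
    peptides <- purrr::map_dfr(proteins, function(prot) {
      k <- n_pep[[prot]]
      # peptide-specific response factors, constant across runs of a protein
      pep_offset <- stats::rnorm(k, 0, 1)
      lfc <- design$log2fc[design$log2fc$protein == prot, ]
      purrr::pmap_dfr(runs, function(condition, replicate) {
        planted <- lfc$log2fc[lfc$condition == condition]
        mu <- base_log2[[prot]] + (if (length(planted)) planted[1] else 0) +
          pep_offset
        tibble::tibble(
          protein = prot, condition = condition, replicate = replicate,
          peptide = sprintf("%s_pep%d", prot, seq_len(k)),
          intensity = 2^(mu + stats::rnorm(k, 0, design$noise_sd)))
      })
    })
    if (design$missingness > 0) {
      drop <- stats::runif(nrow(peptides)) < design$missingness
      peptides$intensity[drop] <- NA_real_
    }
    bait <- tidyr::expand_grid(protein = "BAIT",
                               condition = design$conditions,
                               replicate = seq_len(design$replicates)) |>
      dplyr::mutate(peptide = "BAIT_pep1",
                    intensity = 2^(25 + stats::rnorm(dplyr::n(), 0, design$noise_sd / 2)))
    scores <- tibble::tibble(
      protein = proteins,
      score = ifelse(proteins %in% design$interactors,
                     stats::runif(length(proteins), 0.95, 1),
                     stats::runif(length(proteins), 0, 0.5)))
    list(peptides = dplyr::bind_rows(peptides, bait),
         scores = scores,
         truth = design$log2fc)
  })
}

#' PRM assay description
#'
#' A targeted assay: peptides with library relative fragment intensities
#' (>= 4 fragments each), a library retention time within the gradient, the
#' heavy-reference spike level, and the noise model.
#'
#' @param n_peptides Number of target peptides.
#' @param n_fragments Fragments per peptide (default 6, the number picked per
#'   peak group).
#' @param gradient_length Gradient length in minutes (default 90).
#' @param heavy_level Heavy-channel spike intensity (default 1000).
#' @param noise_sd Log-scale multiplicative noise on fragment areas
#'   (default 0.1).
#' @param seed Seed for library generation.
#' @return A `prm_assay` object with a `library` tibble
#'   `(peptide, fragment, rel_intensity, library_rt)`.
#' @export
prm_assay <- function(n_peptides = 10, n_fragments = 6, gradient_length = 90,
                      heavy_level = 1000, noise_sd = 0.1, seed = 1) {
  abort_if(n_fragments < 4, "assay needs >= 4 fragments per peptide")
  with_seed(derive_seed(seed, "assay"), {
    # fragment series with a dominant ion and roughly geometric decay, the
    # shape a spectral library entry typically has
    lib <- tidyr::expand_grid(peptide = sprintf("pep%02d", seq_len(n_peptides)),
                              fragment = sprintf("y%d", seq_len(n_fragments))) |>
      dplyr::group_by(.data$peptide) |>
      dplyr::mutate(rel_intensity = {
        decay <- stats::runif(1, 0.35, 0.6)
        r <- decay^(seq_len(dplyr::n()) - 1) *
          exp(stats::rnorm(dplyr::n(), 0, 0.3))
        r / max(r)
      }) |>
      dplyr::ungroup()
    rts <- tibble::tibble(peptide = unique(lib$peptide),
                          library_rt = stats::runif(n_peptides,
                                                    0.1 * gradient_length,
                                                    0.9 * gradient_length))
    lib <- dplyr::left_join(lib, rts, by = "peptide")
    abort_if(any(rts$library_rt <= 0 | rts$library_rt >= gradient_length),
             "library RT must lie inside the gradient")
    structure(list(library = lib, gradient_length = gradient_length,
                   heavy_level = heavy_level, noise_sd = noise_sd),
              class = "prm_assay")
  })
}

#' Simulate PRM peak groups from an assay library
#'
#' Light-channel fragment areas are proportional to peptide abundance times
#' the library relative intensity, with multiplicative log-normal noise; the
#' heavy channel sits at the spike level. Decoy peak groups are planted either
#' at retention-time offsets larger than 5% of the gradient or with shuffled
#' fragment ratios, so acceptance gates can be benchmarked.
#'
#' @param assay A [prm_assay()] object.
#' @param true_abundances Named numeric vector of light-channel abundances per
#'   peptide (defaults to 100 for all assay peptides).
#' @param seed Integer seed.
#' @param decoy_fraction Fraction of peptides that additionally get a decoy
#'   peak group (default 0.5).
#' @param sn Signal-to-noise assigned to true fragments (default 20; decoys
#'   get the same so only RT and ratio gates separate them).
#' @return List with `peak_groups` (tibble: `peptide`, `group_id`, `channel`,
#'   `rt`, `fragment`, `area`, `sn`, `is_decoy`) and `library`.
#' @export
simulate_prm <- function(assay, true_abundances = NULL, seed = 1,
                         decoy_fraction = 0.5, sn = 20) {
  abort_if(!inherits(assay, "prm_assay"), "assay must be a prm_assay")
  lib <- assay$library
  peptides <- unique(lib$peptide)
  true_abundances <- true_abundances %||%
    stats::setNames(rep(100, length(peptides)), peptides)
  with_seed(seed, {
    derangement <- function(n) {
      repeat {
        p <- sample.int(n)
        if (all(p != seq_len(n))) return(p)
      }
    }
    make_group <- function(pep, abundance, rt, shuffle, decoy) {
      le <- lib[lib$peptide == pep, ]
      rel <- le$rel_intensity
      # a wrong peak group misassigns every fragment, so shuffle with no
      # fixed points
      if (shuffle) rel <- rel[derangement(length(rel))]
      light <- tibble::tibble(
        peptide = pep,
        group_id = paste0(pep, if (decoy) "_decoy" else "_true"),
        channel = "light", rt = rt, fragment = le$fragment,
        area = abundance * rel * exp(stats::rnorm(nrow(le), 0, assay$noise_sd)),
        sn = sn, is_decoy = decoy)
      heavy <- dplyr::mutate(light, channel = "heavy",
                             area = assay$heavy_level * le$rel_intensity *
                               exp(stats::rnorm(nrow(le), 0, assay$noise_sd / 2)))
      dplyr::bind_rows(light, heavy)
    }
    jitter_rt <- function(rt) rt + stats::rnorm(1, 0, 0.01 * assay$gradient_length)
    groups <- purrr::map_dfr(peptides, function(pep) {
      rt0 <- lib$library_rt[lib$peptide == pep][1]
      out <- make_group(pep, true_abundances[[pep]], jitter_rt(rt0),
                        shuffle = FALSE, decoy = FALSE)
      if (stats::runif(1) < decoy_fraction) {
        if (stats::runif(1) < 0.5) {
          off <- stats::runif(1, 0.08, 0.3) * assay$gradient_length *
            sample(c(-1, 1), 1)
          dec <- make_group(pep, true_abundances[[pep]], rt0 + off,
                            shuffle = FALSE, decoy = TRUE)
        } else {
          dec <- make_group(pep, true_abundances[[pep]], jitter_rt(rt0),
                            shuffle = TRUE, decoy = TRUE)
        }
        out <- dplyr::bind_rows(out, dec)
      }
      out
    })
    list(peak_groups = groups, library = lib)
  })
}
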
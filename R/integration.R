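#' Association-classification thresholds
#'
#' Fold-change and probability gates for calling a phosphosite-interactor
#' association phosphorylation-dependent from the matching phospho-null
#' mutant AP-MS: binding lost below `fc_down` log2 (strictly), gained above
#' `fc_up` (strictly), both at raw `p < p_max`.
#'
#' @param fc_down,fc_up Log2 fold-change gates (defaults -1 and +1).
#' @param p_max Probability gate (default 0.05).
#' @return An `integration_params` list.
#' @export
integration_params <- function(fc_down = -1, fc_up = 1, p_max = 0.05) {
  abort_if(!(fc_down < 0 && fc_up > 0), "need fc_down < 0 < fc_up")
  abort_if(p_max <= 0 || p_max >= 1, "p_max must be in (0,1)")
  structure(list(fc_down = fc_down, fc_up = fc_up, p_max = p_max),
            class = "integration_params")
}

#' Co-migration associations between interactors and phosphosites
#'
#' A pair (interactor, phosphosite) is associated when some module contains
#' both the interactor and the phosphosite in its phosphosignature; the
#' supporting modules are recorded (a pair may be supported by several).
#'
#' @param modules Output of [assemble_modules()] (needs `module`, `members`,
#'   `phosphosignature`).
#' @return Tibble (`interactor`, `site`, `modules` list-col, `n_modules`).
#' @export
comigration_associations <- function(modules) {
  pairs <- purrr::pmap_dfr(
    list(modules$module, modules$members, modules$phosphosignature),
    function(id, members, sites) {
      if (length(members) == 0 || length(sites) == 0) return(NULL)
      tidyr::expand_grid(interactor = members, site = sites) |>
        dplyr::mutate(module = id)
    })
  if (nrow(pairs) == 0) {
    return(tibble::tibble(interactor = character(), site = character(),
                          modules = list(), n_modules = integer()))
  }
  pairs |>
    dplyr::group_by(.data$interactor, .data$site) |>
    dplyr::summarise(modules = list(sort(unique(.data$module))),
                     n_modules = dplyr::n_distinct(.data$module),
                     .groups = "drop")
}

#' Classify associations against phospho-null mutant fold changes
#'
#' For each co-migration association, looks up the interactor's differential
#' result in the alanine mutant of that site versus wild type and assigns:
#' `phospho_required` when `log2fc < fc_down` and `p < p_max` (binding lost
#' without the phosphate), `phospho_inhibitory` when `log2fc > fc_up` and
#' `p < p_max`, otherwise `unaffected`; pairs whose site has no mutant
#' measurement are `untested`. All inequalities are strict.
#'
#' @param associations Output of [comigration_associations()].
#' @param mutant_results Tibble (`site`, `protein`, `log2fc`, `p`): per-site
#'   mutant-vs-wild-type differential results (single-site mutants only;
#'   multi-site constructs are reported separately, not classified here).
#' @param params An [integration_params()] list.
#' @return The associations tibble with `log2fc`, `p`, and `class` columns
#'   (`class` in `phospho_required`, `phospho_inhibitory`, `unaffected`,
#'   `untested`).
#' @export
classify_association <- function(associations, mutant_results,
                                 params = integration_params()) {
  mutant_results <- dplyr::select(tibble::as_tibble(mutant_results),
                                  "site", interactor = "protein",
                                  "log2fc", "p")
  associations |>
    dplyr::left_join(mutant_results, by = c("interactor", "site")) |>
    dplyr::mutate(class = dplyr::case_when(
      is.na(.data$log2fc) | is.na(.data$p) ~ "untested",
      .data$log2fc < params$fc_down & .data$p < params$p_max ~ "phospho_required",
      .data$log2fc > params$fc_up & .data$p < params$p_max ~ "phospho_inhibitory",
      TRUE ~ "unaffected"))
}

#' Association matrix heatmap
#'
#' @param associations Output of [classify_association()].
#' @return A ggplot tile map of interactors by phosphosites colored by class.
#' @export
plot_association_matrix <- function(associations) {
  ggplot2::ggplot(associations,
                  ggplot2::aes(.data$site, .data$interactor,
                               fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      phospho_required = "#2c7fb8", phospho_inhibitory = "#d95f02",
      unaffected = "grey70", untested = "grey90")) +
    ggplot2::labs(x = "bait phosphosite", y = "interactor", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
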
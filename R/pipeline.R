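#' Pipeline configuration
#'
#' One block of parameters per stage, every threshold exposed with the
#' analysis-record value as its default. A fixed seed makes every stochastic
#' stage byte-identical between runs.
#'
#' @param seed Integer run seed.
#' @param fraction_count Number of native gel fractions (default 64).
#' @param n_modules Planted modules when simulating (default 9).
#' @param noise_sd,dropout_rate BN-PAGE simulation noise (defaults 0.2, 0.05).
#' @param peak [peak_params()] block.
#' @param apms Named list: `saint_threshold` (0.90), `impute_percentile` (5),
#'   `max_single_missing` (1), `top_n_peptides` (2).
#' @param cluster Named list: `k_min`, `k_max`, `linkage`, `bait`.
#' @param integration [integration_params()] block.
#' @param prm [prm_params()] block.
#' @param paths Named list of input/output locations (`out_dir` required by
#'   [run_pipeline()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, fraction_count = 64, n_modules = 9,
                            noise_sd = 0.2, dropout_rate = 0.05,
                            peak = peak_params(),
                            apms = list(saint_threshold = 0.90,
                                        impute_percentile = 5,
                                        max_single_missing = 1,
                                        top_n_peptides = 2),
                            cluster = list(k_min = 2, k_max = 15,
                                           linkage = "average", bait = "BAIT"),
                            integration = integration_params(),
                            prm = prm_params(),
                            paths = list(out_dir = tempfile("comigratr_run_"))) {
  cfg <- structure(list(seed = seed, fraction_count = fraction_count,
                        n_modules = n_modules, noise_sd = noise_sd,
                        dropout_rate = dropout_rate, peak = peak,
                        apms = apms, cluster = cluster,
                        integration = integration, prm = prm, paths = paths),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or plain list, e.g. from
#'   [read_config()]).
#' @return The config, invisibly; errors on the first invalid field.
#' @export
validate_config <- function(config) {
  abort_if(!is.numeric(config$fraction_count) || config$fraction_count < 2,
           "fraction_count must be an integer >= 2",
           class = "comigratr_validation_error")
  abort_if(!is.numeric(config$seed) || length(config$seed) != 1,
           "seed must be a single integer")
  abort_if(config$noise_sd < 0, "noise_sd must be >= 0")
  abort_if(config$dropout_rate < 0 || config$dropout_rate >= 1,
           "dropout_rate must be in [0,1)")
  with(config$apms, {
    abort_if(saint_threshold < 0 || saint_threshold > 1,
             "saint_threshold must be in [0,1]")
    abort_if(top_n_peptides < 1, "top_n_peptides must be >= 1")
    abort_if(impute_percentile <= 0 || impute_percentile >= 100,
             "impute_percentile must be in (0,100)")
  })
  if (!inherits(config$peak, "peak_params"))
    do.call(peak_params, config$peak)
  if (!inherits(config$integration, "integration_params"))
    do.call(integration_params, config$integration)
  if (!inherits(config$prm, "prm_params"))
    do.call(prm_params, config$prm)
  invisible(config)
}

#' Read a YAML pipeline configuration
#'
#' Unspecified fields fall back to the [pipeline_config()] defaults.
#'
#' @param path YAML (or JSON) config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  abort_if(!file.exists(path), paste0("config not found: ", path))
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- pipeline_config()
  merged <- utils::modifyList(unclass(defaults), raw)
  for (block in c("peak", "integration", "prm")) {
    if (!inherits(merged[[block]], paste0(block, "_params")) &&
        is.list(merged[[block]])) {
      ctor <- switch(block, peak = peak_params,
                     integration = integration_params, prm = prm_params)
      merged[[block]] <- do.call(ctor, merged[[block]][
        intersect(names(merged[[block]]), names(formals(ctor)))])
    }
  }
  cfg <- structure(merged, class = "pipeline_config")
  validate_config(cfg)
  cfg
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  invisible(line)
}

#' Run the simulate / co-migrate / evaluate / integrate pipeline
#'
#' Executes the stages in order on seeded synthetic data: generates BN-PAGE
#' profiles and mutant AP-MS tables from a planted ground truth, preprocesses
#' and splits the migration profiles, clusters them into modules, evaluates
#' the modules against a reference built from the planted complexes, and
#' classifies phosphosite-interactor associations against the mutant fold
#' changes. Every output table is written to the run directory with a
#' provenance header (config hash, seed, package version); a failing stage
#' aborts with its name and the log records how far the run got.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory, the module table, the
#'   classified associations, and the evaluation object.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  prov <- c(paste0("comigratr ", as.character(utils::packageVersion("comigratr"))),
            paste0("seed ", config$seed),
            paste0("config_hash ",
                   sum(utf8ToInt(paste(deparse(
                     unclass(config)[setdiff(names(config), "paths")]),
                     collapse = "")))),
            paste0("R ", R.version.string))
  stage <- function(name, expr) {
    log_line(log_con, name, "start")
    res <- tryCatch(expr, error = function(e) {
      log_line(log_con, name, paste("FAILED:", conditionMessage(e)))
      rlang::abort(paste0("stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "comigratr_stage_error")
    })
    log_line(log_con, name, "done")
    res
  }

  sim <- stage("simulate", {
    truth <- default_complex_truth(n_modules = config$n_modules,
                                   seed = config$seed)
    sim <- simulate_bnpage(truth, noise_sd = config$noise_sd,
                           dropout_rate = config$dropout_rate,
                           seed = config$seed)
    write_table(sim$profiles, file.path(out_dir, "profiles.tsv"), prov)
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"))
    list(truth = truth, data = sim)
  })

  clusters <- stage("comigrate", {
    prep <- preprocess_profiles(sim$data$profiles, sim$data$irt,
                                bait = sim$data$bait, params = config$peak)
    peaks <- detect_peaks(prep, config$peak)
    traces <- split_profile(prep, peaks)
    cl <- cluster_modules(traces, k_min = config$cluster$k_min,
                          k_max = config$cluster$k_max,
                          bait = config$cluster$bait,
                          linkage = config$cluster$linkage)
    write_table(tidy(cl), file.path(out_dir, "trace_assignments.tsv"), prov)
    list(clusters = cl, traces = traces)
  })

  modules <- stage("assemble", {
    mods <- assemble_modules(clusters$clusters, clusters$traces)
    flat <- dplyr::mutate(mods,
                          members = purrr::map_chr(.data$members, paste,
                                                   collapse = ";"),
                          phosphosignature = purrr::map_chr(
                            .data$phosphosignature, paste, collapse = ";"))
    write_table(flat, file.path(out_dir, "modules.tsv"), prov)
    mods
  })

  evaluation <- stage("evaluate", {
    # reference edges: cliques of the planted complexes (what a curated PPI
    # database would contain for genuinely interacting members)
    ref <- sim$truth$members |>
      dplyr::group_by(.data$module_id) |>
      dplyr::reframe({
        if (dplyr::n() < 2) tibble::tibble(protein_a = character(),
                                           protein_b = character())
        else {
          pr <- utils::combn(sort(unique(.data$protein)), 2)
          tibble::tibble(protein_a = pr[1, ], protein_b = pr[2, ])
        }
      }) |>
      dplyr::distinct(.data$protein_a, .data$protein_b) |>
      dplyr::mutate(evidence = 1L)
    universe <- sort(unique(sim$truth$members$protein))
    ev <- recall_vs_background(modules, ref, universe,
                               seed = derive_seed(config$seed, "recall"))
    write_table(tidy(ev), file.path(out_dir, "module_evaluation.tsv"), prov)
    ev
  })

  associations <- stage("integrate", {
    assoc <- comigration_associations(modules)
    # mutant AP-MS: members of each phosphosite's module suppressed in the
    # matching alanine mutant
    mutant <- simulate_mutant_panel(sim$truth, seed = config$seed)
    cls <- classify_association(assoc, mutant, config$integration)
    flat <- dplyr::mutate(cls, modules = purrr::map_chr(.data$modules, paste,
                                                        collapse = ";"))
    write_table(flat, file.path(out_dir, "associations.tsv"), prov)
    cls
  })

  log_line(log_con, "run", "complete")
  invisible(list(dir = out_dir, modules = modules,
                 associations = associations, evaluation = evaluation,
                 clusters = clusters$clusters))
}

#' Simulate a phospho-null mutant AP-MS differential panel
#'
#' For each phosphosite in the planted truth, generates mutant-versus-wild-
#' type differential results in which the members of the site's module lose
#' binding (planted log2 fold change -2.5 at p < 0.01) and all other
#' interactors are unchanged. Used by the pipeline's integrate stage and by
#' planted-recovery tests.
#'
#' @param truth A [complex_truth()] object.
#' @param seed Integer seed.
#' @param suppressed_log2fc Planted loss for module members (default -2.5).
#' @return Tibble (`site`, `protein`, `log2fc`, `p`).
#' @export
simulate_mutant_panel <- function(truth, seed = 1, suppressed_log2fc = -2.5) {
  proteins <- sort(unique(truth$members$protein))
  with_seed(derive_seed(seed, "mutant"), {
    purrr::map_dfr(seq_len(nrow(truth$phosphosites)), function(i) {
      site <- truth$phosphosites$site[i]
      mod <- truth$phosphosites$module_id[i]
      hit <- truth$members$protein[truth$members$module_id == mod]
      tibble::tibble(
        site = site, protein = proteins,
        log2fc = ifelse(proteins %in% hit,
                        suppressed_log2fc + stats::rnorm(length(proteins), 0, 0.2),
                        stats::rnorm(length(proteins), 0, 0.2)),
        p = ifelse(proteins %in% hit,
                   stats::runif(length(proteins), 1e-5, 0.01),
                   stats::runif(length(proteins), 0.1, 1)))
    })
  })
}
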
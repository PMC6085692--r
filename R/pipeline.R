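#' Pipeline configuration
#'
#' One object driving [run_pipeline()] end to end, for either synthetic
#' data (a [sim_config()]) or on-disk inputs laid out as written by
#' [write_sim_truth()]: `chronogram.nwk`, `within_trees/<clade>.nwk`,
#' `localities.csv`, `sample_map.csv`, optionally `ecomorph.csv`
#' (columns clade, ecomorph).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param sim A [sim_config()] (synthetic mode).
#' @param input_dir Input directory (files mode).
#' @param out_dir Output directory; `NULL` disables writing.
#' @param alpha Significance level of the backward stepwise (default 0.05).
#' @param k_axes PCA axes retained for environmental dissimilarity.
#' @param age_mode `"stem"` or `"crown"`.
#' @param covariance_source `"chronogram"` (Brownian covariance from the
#'   chronogram pruned to the analysed clades) or a path to a
#'   species-by-species distance matrix CSV (first column = clade id),
#'   ultrametrized by UPGMA.
#' @param weighting Locality-pair weighting for the divergence average; see
#'   [locality_mean_divergence()].
#' @param formula Optional model formula; default: divergence on geographic
#'   distance, age, environmental heterogeneity and (when estimable)
#'   ecomorph, plus all geographic-distance interactions.
#' @param rules A [clade_rules()] object applied to the sample map.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), sim = sim_config(),
                            input_dir = NULL, out_dir = NULL, alpha = 0.05,
                            k_axes = 5, age_mode = "stem",
                            covariance_source = "chronogram",
                            weighting = "locality-pair", formula = NULL,
                            rules = clade_rules()) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (mode == "files") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      abort("files mode needs an existing input_dir")
    }
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, alpha = alpha, k_axes = k_axes,
                 age_mode = age_mode, covariance_source = covariance_source,
                 weighting = weighting, formula = formula, rules = rules),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (config$mode == "synthetic") {
    truth <- simulate_clade_dataset(config$sim)
    list(chronogram = truth$chronogram, within_trees = truth$within_trees,
         localities = truth$locality_table, sample_map = truth$sample_map,
         ecomorph = truth$clade_summary[c("clade", "ecomorph")], truth = truth)
  } else {
    d <- config$input_dir
    chron <- read_newick(file.path(d, "chronogram.nwk"))
    tree_files <- list.files(file.path(d, "within_trees"), pattern = "\\.nwk$",
                             full.names = TRUE)
    within <- lapply(tree_files, read_newick)
    names(within) <- sub("\\.nwk$", "", basename(tree_files))
    loc <- readr::read_csv(file.path(d, "localities.csv"),
                           show_col_types = FALSE)
    sm <- readr::read_csv(file.path(d, "sample_map.csv"),
                          show_col_types = FALSE)
    eco_path <- file.path(d, "ecomorph.csv")
    eco <- if (file.exists(eco_path)) {
      readr::read_csv(eco_path, show_col_types = FALSE)
    } else NULL
    list(chronogram = chron, within_trees = within, localities = loc,
         sample_map = sm, ecomorph = eco, truth = NULL)
  }
}

default_full_formula <- function(n_clades, ecomorph) {
  terms <- c("avg_geodist", "age", "env_het",
             "avg_geodist:age", "avg_geodist:env_het")
  if (!is.null(ecomorph)) {
    nlev <- length(unique(ecomorph))
    p_full <- 6 + 2 * (nlev - 1)
    if (nlev >= 2 && n_clades > p_full + 2) {
      terms <- c(terms[1:3], "ecomorph", terms[4:5], "avg_geodist:ecomorph")
    }
  }
  stats::reformulate(terms, "avg_divergence")
}

#' Run the full comparative analysis
#'
#' Orchestrates every stage: clade rules on the sample map, patristic
#' distances and per-clade average divergence from the within-species
#' trees, great-circle geographic means, environmental PCA heterogeneity,
#' species ages from the chronogram, Brownian covariance, the full PGLS
#' model, and backward likelihood-ratio model reduction. All intermediate
#' tables are materialised as CSV/TSV when `out_dir` is set, so any single
#' stage can be re-run and checked from the written files.
#'
#' @param config A [pipeline_config()] (or a [sim_config()], wrapped into a
#'   synthetic-mode pipeline config).
#' @return List: `clade_summary`, `divergence`, `sample_map`, `exclusions`,
#'   `full` and `final` (`pgls_fit`s), `trace`, `cov`, `truth` (synthetic
#'   mode only).
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "sim_config")) config <- pipeline_config(sim = config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out)) {
        q <- file.path(out, "quarantine")
        dir.create(q, showWarnings = FALSE, recursive = TRUE)
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(q, "error.txt"))
      }
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  inp <- stage("load", load_pipeline_inputs(config))
  sm <- stage("clade-rules", apply_clade_rules(inp$sample_map, config$rules))
  exclusions <- sm[sm$excluded, c("sample", "clade", "locality", "reason")]

  dmats <- stage("patristic", lapply(inp$within_trees, patristic_matrix))
  div <- stage("divergence", clade_divergence(dmats, sm, config$weighting))

  geo <- stage("geodesy", geographic_matrix(inp$localities))
  scores <- stage("environment-pca", pca_scores(inp$localities, k = config$k_axes))
  envd <- env_dissimilarity(scores)

  clade_locs <- sm |>
    dplyr::filter(!.data$excluded) |>
    dplyr::distinct(.data$clade, .data$locality)
  per_clade_geo <- stage("geodesy-means", clade_locs |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(avg_geodist = mean_pairwise(geo, .data$locality),
                     env_het = clade_env_heterogeneity(envd, .data$locality),
                     .groups = "drop"))

  clades <- retained_clades(sm)
  chron_map <- tibble::tibble(tip = intersect(inp$chronogram$tip.label, clades)) |>
    dplyr::mutate(clade = .data$tip)
  if (!all(clades %in% chron_map$tip)) {
    abort(paste("clades absent from chronogram:",
                paste(setdiff(clades, chron_map$tip), collapse = ", ")))
  }
  ages <- stage("ages", species_age(inp$chronogram, chron_map, config$age_mode))

  summary_tbl <- div |>
    dplyr::left_join(per_clade_geo, by = "clade") |>
    dplyr::left_join(ages[c("clade", "age")], by = "clade")
  if (!is.null(inp$ecomorph)) {
    summary_tbl <- dplyr::left_join(summary_tbl, inp$ecomorph, by = "clade")
  }

  cov <- stage("covariance", {
    if (identical(config$covariance_source, "chronogram")) {
      pruned <- ape::keep.tip(inp$chronogram, clades)
      brownian_covariance_tree(pruned)
    } else {
      dm <- as.data.frame(readr::read_csv(config$covariance_source,
                                          show_col_types = FALSE))
      m <- as.matrix(dm[-1]); rownames(m) <- dm[[1]]
      brownian_covariance(m[clades, clades])
    }
  })

  form <- config$formula %||%
    default_full_formula(nrow(summary_tbl),
                         if ("ecomorph" %in% names(summary_tbl))
                           summary_tbl$ecomorph else NULL)
  sel <- stage("pgls", backward_stepwise(summary_tbl, form, cov,
                                         alpha = config$alpha))

  if (!is.null(out)) {
    readr::write_csv(summary_tbl, file.path(out, "clade_summary.csv"))
    readr::write_csv(div, file.path(out, "divergence.csv"))
    readr::write_csv(exclusions, file.path(out, "exclusions.csv"))
    readr::write_tsv(tidy(sel$full), file.path(out, "full_model_coefficients.tsv"))
    readr::write_tsv(pgls_anova(sel$full), file.path(out, "full_model_anova.tsv"))
    readr::write_tsv(tidy(sel$final), file.path(out, "final_model_coefficients.tsv"))
    readr::write_tsv(pgls_anova(sel$final), file.path(out, "final_model_anova.tsv"))
    readr::write_tsv(sel$trace, file.path(out, "elimination_trace.tsv"))
    meta <- list(mode = config$mode, alpha = config$alpha,
                 k_axes = config$k_axes, age_mode = config$age_mode,
                 covariance = cov$method, formula = deparse(form),
                 seed = if (config$mode == "synthetic") config$sim$seed else NA,
                 r_version = as.character(getRversion()))
    yaml::write_yaml(meta, file.path(out, "run_metadata.yaml"))
    sink(file.path(out, "summary.txt")); print(sel$final); sink()
  }

  list(clade_summary = summary_tbl, divergence = div, sample_map = sm,
       exclusions = exclusions, full = sel$full, final = sel$final,
       trace = sel$trace, cov = cov, truth = inp$truth)
}

#' Write a small worked example dataset (and its expected outputs)
#'
#' Generates a compact synthetic dataset (8 clades, 3-4 localities each),
#' writes its inputs under `<dir>/input` and the pipeline outputs under
#' `<dir>/expected`. Regeneration with the same seed is idempotent, which
#' is what the end-to-end determinism tests rely on.
#'
#' @param dir Target directory.
#' @param seed Integer seed (default 42).
#' @return List with `input` and `expected` paths and the pipeline result.
#' @export
make_fixtures <- function(dir, seed = 42) {
  cfg <- sim_config(n_species = 8, n_localities_range = c(3, 4), seed = seed)
  truth <- simulate_clade_dataset(cfg)
  input <- file.path(dir, "input")
  write_sim_truth(truth, input)
  res <- run_pipeline(pipeline_config(mode = "files", input_dir = input,
                                      out_dir = file.path(dir, "expected")))
  list(input = input, expected = file.path(dir, "expected"), result = res)
}
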
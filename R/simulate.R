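#' Simulate an ultrametric chronogram
#'
#' Pure-birth (Yule) tree with `n_species` tips, node heights rescaled so
#' every root-to-tip path equals `root_age`. Tips are labelled
#' `sp01, sp02, ...`.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate (1/Myr); affects relative node heights
#'   only, since the depth is rescaled.
#' @param root_age Tree depth in Myr.
#' @param seed Optional integer seed.
#' @return Ultrametric `phylo`.
#' @export
simulate_chronogram <- function(n_species, birth_rate = 0.1, root_age = 95,
                                seed = NULL) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (root_age <= 0) abort("root_age must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_age / depth)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate a locality table with environments
#'
#' Localities are placed uniformly in a square region of edge `extent_km`
#' centred at `center`. Twenty environmental variables (stylised bioclim
#' variables `env01..env19` plus `tree_cover` in percent) are generated as
#' fixed linear functions of the coordinates mixed with white noise:
#' `env_autocorr = 1` gives purely spatial (deterministic in the
#' coordinates) environments, `0` gives pure noise.
#'
#' @param n_localities Number of localities (>= 1).
#' @param extent_km Edge of the sampling square in km (> 0).
#' @param env_autocorr Spatial-trend weight in \[0, 1\].
#' @param seed Optional integer seed.
#' @param center Named or positional pair c(lat, lon) of the region centre.
#' @param prefix Locality id prefix (ids are `prefix1, prefix2, ...`).
#' @return Tibble: `locality`, `lat`, `lon`, `env01..env19`, `tree_cover`.
#' @export
simulate_localities <- function(n_localities, extent_km = 1100,
                                env_autocorr = 0.8, seed = NULL,
                                center = c(21.5, -79.5), prefix = "L") {
  if (n_localities < 1) abort("n_localities must be >= 1")
  if (extent_km <= 0) abort("extent_km must be > 0")
  if (env_autocorr < 0 || env_autocorr > 1) abort("env_autocorr must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  km_per_deg <- pi * 6371.0088 / 180
  dlat <- extent_km / km_per_deg
  dlon <- extent_km / (km_per_deg * cos(center[1] * pi / 180))
  lat <- center[1] + runif(n_localities, -dlat / 2, dlat / 2)
  lon <- center[2] + runif(n_localities, -dlon / 2, dlon / 2)
  lat <- pmin(pmax(lat, -90), 90)
  lon <- pmin(pmax(lon, -180), 180)

  # fixed (seed-independent) spatial gradients per variable
  k <- 1:20
  a <- cos(k)          # latitudinal gradient weight
  b <- sin(1.7 * k)    # longitudinal gradient weight
  mu <- c(15 + 2 * (1:19), 50)       # variable means (stylised bioclim scales)
  sdev <- c(2 + 0.5 * (1:19), 20)    # variable sds

  env <- matrix(NA_real_, n_localities, 20)
  for (j in k) {
    trend <- a[j] * (lat - center[1]) * km_per_deg +
      b[j] * (lon - center[2]) * km_per_deg * cos(center[1] * pi / 180)
    tsd <- stats::sd(trend)
    trend_std <- if (n_localities > 1 && tsd > 0) (trend - mean(trend)) / tsd else
      rep(0, n_localities)
    noise <- rnorm(n_localities)
    env[, j] <- mu[j] + sdev[j] *
      (env_autocorr * trend_std + (1 - env_autocorr) * noise)
  }
  colnames(env) <- c(sprintf("env%02d", 1:19), "tree_cover")
  env[, "tree_cover"] <- pmin(pmax(env[, "tree_cover"], 0), 100)
  tibble::tibble(locality = paste0(prefix, seq_len(n_localities)),
                 lat = lat, lon = lon) |>
    dplyr::bind_cols(tibble::as_tibble(env))
}

#' Simulate a complete clade dataset with known ground truth
#'
#' Generates every input the comparative pipeline consumes, under the
#' linear model it is meant to recover: a Yule chronogram rescaled to the
#' configured root age; per-species localities with environments; expected
#' divergence `mu = beta_age * stem_age + beta_geo * mean_geo_km +
#' beta_env * env_het`; residuals that are a `lambda_signal`-weighted blend
#' of a Brownian draw on the chronogram and white noise, both scaled to
#' `noise_sd`, with the realised divergence truncated at zero; and a
#' within-species star tree per species whose between-locality patristic
#' distances all equal the realised divergence, so the tree-based response
#' recovers the truth exactly.
#'
#' Geographic and environmental summaries are computed with the package's
#' own geodesy and PCA modules (a single PCA over all localities, axes
#' 1..5), so the generated predictors are exactly what the analysis stage
#' will see.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `config`, `chronogram`, `clade_summary`
#'   (tibble with clade, age, avg_geodist, env_het, ecomorph, mu, resid,
#'   divergence), `locality_table`, `sample_map`, `within_trees` (named
#'   list of `phylo`).
#' @export
simulate_clade_dataset <- function(config) {
  validate_sim_config(config)
  n <- config$n_species
  chron <- simulate_chronogram(n, config$birth_rate, config$root_age,
                               seed = sub_seed(config$seed, 1))
  sp <- chron$tip.label
  ages <- species_age(chron, tibble::tibble(tip = sp, clade = sp), "stem")

  ecomorph_levels <- c("crown-giant", "grass-bush", "trunk-crown",
                       "trunk-ground", "twig", "unique-1", "unique-2")
  set.seed(sub_seed(config$seed, 2))
  ecomorph <- sample(ecomorph_levels, n, replace = TRUE)

  # per-species localities, each species in its own sub-range of the region
  loc_list <- vector("list", n)
  km_per_deg <- pi * 6371.0088 / 180
  half <- (config$extent_km / km_per_deg) / 2
  for (i in seq_len(n)) {
    set.seed(sub_seed(config$seed, 100 + i))
    lo <- config$n_localities_range[1]; hi <- config$n_localities_range[2]
    n_loc <- if (lo == hi) lo else sample(lo:hi, 1)
    range_km <- runif(1, config$range_km_limits[1], config$range_km_limits[2])
    ctr <- c(21.5 + runif(1, -half, half) * 0.5,
             -79.5 + runif(1, -half, half) * 2)
    loc_list[[i]] <- simulate_localities(
      n_loc, extent_km = range_km, env_autocorr = config$env_autocorr,
      seed = sub_seed(config$seed, 500 + i), center = ctr,
      prefix = paste0(sp[i], "_L"))
  }
  locality_table <- dplyr::bind_rows(loc_list)

  geo <- geographic_matrix(locality_table)
  scores <- pca_scores(locality_table, k = 5)
  envd <- env_dissimilarity(scores)
  avg_geo <- vapply(loc_list, function(lt) mean_pairwise(geo, lt$locality),
                    numeric(1))
  env_het <- vapply(loc_list, function(lt) mean_pairwise(envd, lt$locality),
                    numeric(1))

  # residual: Brownian component on the chronogram blended with white noise
  set.seed(sub_seed(config$seed, 3))
  bm <- ape::rTraitCont(chron, model = "BM", sigma = 1)
  bm <- bm[sp] * config$noise_sd / sqrt(config$root_age)
  white <- vapply(seq_len(n), function(i) {
    set.seed(sub_seed(config$seed, 1000 + i))
    rnorm(1, 0, config$noise_sd)
  }, numeric(1))
  resid <- unname(sqrt(config$lambda_signal) * bm +
                    sqrt(1 - config$lambda_signal) * white)

  mu <- config$beta_age * ages$age[match(sp, ages$clade)] +
    config$beta_geo * avg_geo + config$beta_env * env_het
  if (mean(mu < 0) > 0.5) {
    warn("expected divergence negative for >50% of species; truncating at 0")
  }
  divergence <- pmax(mu + resid, 0)

  within_trees <- purrr::map(seq_len(n), function(i) {
    locality_star_tree(loc_list[[i]]$locality, divergence[i],
                       config$samples_per_locality)
  })
  names(within_trees) <- sp

  sample_map <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(sample = within_trees[[i]]$tip.label, clade = sp[i]) |>
      dplyr::mutate(locality = sub("_s[0-9]+$", "", .data$sample),
                    excluded = FALSE, reason = NA_character_)
  })

  structure(list(
    config = config, chronogram = chron,
    clade_summary = tibble::tibble(
      clade = sp, age = ages$age[match(sp, ages$clade)],
      avg_geodist = avg_geo, env_het = env_het, ecomorph = ecomorph,
      mu = mu, resid = resid, divergence = divergence),
    locality_table = locality_table, sample_map = sample_map,
    within_trees = within_trees
  ), class = "sim_truth")
}

# star tree over localities: each locality hangs off the root at length
# divergence/2 and carries its samples on zero-length branches, so every
# between-locality patristic distance equals `divergence` exactly
locality_star_tree <- function(localities, divergence, samples_per_locality) {
  stopifnot(divergence >= 0)
  subtrees <- vapply(localities, function(lc) {
    tips <- paste0(lc, "_s", seq_len(samples_per_locality))
    if (samples_per_locality == 1) {
      sprintf("%s:%.12g", tips, divergence / 2)
    } else {
      sprintf("(%s):%.12g", paste0(tips, ":0", collapse = ","), divergence / 2)
    }
  }, character(1))
  txt <- paste0("(", paste(subtrees, collapse = ","), ");")
  read_newick(txt)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic clade dataset:", x$config$n_species, "species,",
      nrow(x$locality_table), "localities,",
      nrow(x$sample_map), "samples\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Materialises all inputs as plain-text files: Newick chronogram and
#' within-species trees, CSV locality table, sample map, and ground-truth
#' clade summary, plus the configuration as a key: value file.
#'
#' @param truth A `sim_truth` from [simulate_clade_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(truth$chronogram, file.path(dir, "chronogram.nwk"))
  trees_dir <- file.path(dir, "within_trees")
  dir.create(trees_dir, showWarnings = FALSE)
  for (sp in names(truth$within_trees)) {
    ape::write.tree(truth$within_trees[[sp]],
                    file.path(trees_dir, paste0(sp, ".nwk")))
  }
  readr::write_csv(truth$locality_table, file.path(dir, "localities.csv"))
  readr::write_csv(truth$sample_map, file.path(dir, "sample_map.csv"))
  readr::write_csv(truth$clade_summary, file.path(dir, "clade_summary_truth.csv"))
  write_sim_config(truth$config, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
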
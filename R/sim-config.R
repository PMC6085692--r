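#' Configuration for the synthetic clade dataset
#'
#' Bundles the generating conditions for [simulate_clade_dataset()]: a Yule
#' chronogram with a fixed root age, per-species locality sampling, and
#' divergence generated as a linear function of stem age, mean geographic
#' distance and environmental heterogeneity, with residual noise that can be
#' partly phylogenetically structured.
#'
#' @param n_species Number of species (tips of the chronogram), >= 3.
#' @param birth_rate Per-lineage speciation rate (1/Myr) of the Yule
#'   process; only the topology/relative node order depend on it because
#'   node heights are rescaled to `root_age`.
#' @param root_age Depth of the chronogram in Myr (default 95, a deep
#'   island-radiation root calibration).
#' @param n_localities_range Integer pair: min and max localities per
#'   species (localities drawn uniformly in this range).
#' @param beta_age Effect of stem age on divergence (substitutions/site per
#'   Myr).
#' @param beta_geo Effect of mean geographic distance (per km).
#' @param beta_env Effect of environmental heterogeneity (per PCA-distance
#'   unit).
#' @param noise_sd Residual standard deviation of divergence.
#' @param lambda_signal Fraction (in \[0, 1\]) of residual variance that is
#'   phylogenetically structured (Brownian motion on the chronogram).
#' @param seed Integer seed; the whole dataset is reproducible bit-for-bit
#'   from it.
#' @param extent_km Edge of the overall sampling region (km).
#' @param range_km_limits Min/max spatial extent of a single species' range
#'   (km); per-species extents are drawn uniformly in this interval.
#' @param env_autocorr In \[0, 1\]: weight of the spatial trend (vs. white
#'   noise) in the generated environmental variables.
#' @param samples_per_locality Tips generated per locality in the
#'   within-species trees.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species = 26, birth_rate = 0.1, root_age = 95,
                       n_localities_range = c(3, 10),
                       beta_age = 0.0015, beta_geo = 2e-5, beta_env = 0,
                       noise_sd = 0.005, lambda_signal = 0.5, seed = 1,
                       extent_km = 1100, range_km_limits = c(100, 600),
                       env_autocorr = 0.8, samples_per_locality = 2) {
  cfg <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
              root_age = root_age,
              n_localities_range = as.integer(n_localities_range),
              beta_age = beta_age, beta_geo = beta_geo, beta_env = beta_env,
              noise_sd = noise_sd, lambda_signal = lambda_signal,
              seed = as.integer(seed), extent_km = extent_km,
              range_km_limits = range_km_limits, env_autocorr = env_autocorr,
              samples_per_locality = as.integer(samples_per_locality))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_species < 3) abort("n_species must be >= 3")
  if (cfg$birth_rate <= 0) abort("birth_rate must be > 0")
  if (cfg$root_age <= 0) abort("root_age must be > 0")
  if (length(cfg$n_localities_range) != 2 ||
      any(cfg$n_localities_range < 1) ||
      cfg$n_localities_range[1] > cfg$n_localities_range[2]) {
    abort("n_localities_range must be an increasing pair of positive integers")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$lambda_signal < 0 || cfg$lambda_signal > 1) {
    abort("lambda_signal must be in [0, 1]")
  }
  if (cfg$extent_km <= 0) abort("extent_km must be > 0")
  if (cfg$samples_per_locality < 1) abort("samples_per_locality must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic clade dataset configuration\n")
  cat(sprintf("  %d species, Yule(%g), root age %g Myr, seed %d\n",
              x$n_species, x$birth_rate, x$root_age, x$seed))
  cat(sprintf("  effects: age %g, geo %g, env %g; noise sd %g, lambda %g\n",
              x$beta_age, x$beta_geo, x$beta_env, x$noise_sd, x$lambda_signal))
  invisible(x)
}

#' Read / write a sim_config as a key: value text file
#' @param path File path.
#' @return For `read_sim_config`, a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic sub-seed derivation: a fixed offset scheme so per-species
# draws are independent of how many species follow
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483629)
}
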
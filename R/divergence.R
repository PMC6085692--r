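#' Average between-locality genetic divergence of one clade
#'
#' The response variable of the comparative analysis. For each unordered
#' pair of localities (p, q) sampled for the clade, the mean patristic
#' distance over all cross-locality sample pairs i in p, j in q is taken;
#' the clade's average divergence is the unweighted mean of these
#' locality-pair means. Within-locality sample pairs never enter the
#' average, and locality pairs are weighted equally regardless of how many
#' samples each locality contributed (see `weighting`).
#'
#' @param d Patristic (or other genetic) distance matrix whose dimnames are
#'   sample ids.
#' @param sample_map Processed sample map (see [apply_clade_rules()]).
#' @param clade_id Clade to summarise; must be retained (no
#'   exclusion flags on all its samples).
#' @param weighting `"locality-pair"` (default: equal weight per locality
#'   pair) or `"sample-pair"` (equal weight per cross-locality sample pair).
#' @return A `clade_divergence` list: `clade`, `n_localities`, `n_pairs`
#'   (locality pairs), `pair_means` (symmetric locality-by-locality matrix of
#'   locality-pair mean distances), `avg_divergence`.
#' @export
locality_mean_divergence <- function(d, sample_map, clade_id,
                                     weighting = c("locality-pair", "sample-pair")) {
  weighting <- match.arg(weighting)
  stopifnot(is.matrix(d), is.data.frame(sample_map))
  rows <- sample_map[sample_map$clade == clade_id, , drop = FALSE]
  if (!nrow(rows)) abort(paste("unknown clade:", clade_id))
  if (all(rows$excluded)) {
    abort(paste0("clade '", clade_id, "' is excluded (",
                 paste(unique(rows$reason), collapse = "; "), ")"))
  }
  rows <- rows[!rows$excluded, , drop = FALSE]
  missing <- setdiff(rows$sample, rownames(d))
  if (length(missing)) {
    abort(paste("samples absent from distance matrix:",
                paste(missing, collapse = ", ")))
  }
  locs <- sort(unique(rows$locality))
  if (length(locs) < 2) abort("need at least 2 localities with retained samples")

  pair_means <- matrix(NA_real_, length(locs), length(locs),
                       dimnames = list(locs, locs))
  diag(pair_means) <- 0
  pair_n <- pair_means
  for (a in seq_along(locs)) {
    for (b in seq_len(a - 1)) {
      ia <- rows$sample[rows$locality == locs[a]]
      ib <- rows$sample[rows$locality == locs[b]]
      block <- d[ia, ib, drop = FALSE]
      pair_means[a, b] <- pair_means[b, a] <- mean(block)
      pair_n[a, b] <- pair_n[b, a] <- length(block)
    }
  }
  ut <- upper.tri(pair_means)
  avg <- if (weighting == "locality-pair") {
    mean(pair_means[ut])
  } else {
    sum(pair_means[ut] * pair_n[ut]) / sum(pair_n[ut])
  }
  structure(list(clade = clade_id,
                 n_localities = length(locs),
                 n_pairs = sum(ut),
                 pair_means = pair_means,
                 avg_divergence = avg),
            class = "clade_divergence")
}

#' @export
print.clade_divergence <- function(x, ...) {
  cat(sprintf("Clade %s: %d localities, %d locality pairs, avg divergence %.6g\n",
              x$clade, x$n_localities, x$n_pairs, x$avg_divergence))
  invisible(x)
}

#' Per-clade divergence table
#'
#' Maps [locality_mean_divergence()] over every retained clade of a sample
#' map and returns the tidy summary used downstream as the response.
#'
#' @param d Distance matrix over samples, or a named list of matrices (one
#'   per clade; each clade's samples looked up in its own matrix — the usual
#'   case when each species has its own gene tree).
#' @inheritParams locality_mean_divergence
#' @param sample_map Processed sample map.
#' @return Tibble: `clade`, `n_localities`, `n_pairs`, `avg_divergence`.
#' @export
clade_divergence <- function(d, sample_map,
                             weighting = c("locality-pair", "sample-pair")) {
  weighting <- match.arg(weighting)
  clades <- retained_clades(sample_map)
  purrr::map_dfr(clades, function(cl) {
    dm <- if (is.list(d) && !is.matrix(d)) d[[cl]] else d
    if (is.null(dm)) abort(paste("no distance matrix for clade", cl))
    cd <- locality_mean_divergence(dm, sample_map, cl, weighting)
    tibble::tibble(clade = cd$clade, n_localities = cd$n_localities,
                   n_pairs = cd$n_pairs, avg_divergence = cd$avg_divergence)
  })
}
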
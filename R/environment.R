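#' Principal-component scores of locality environments
#'
#' Summarises the per-locality environmental variables (19 bioclim-style
#' variables plus percent tree cover, or any numeric columns supplied) by
#' PCA, by default on the correlation matrix (each variable centred and
#' scaled to unit variance, so variables with large units such as annual
#' precipitation do not dominate). The first `k` axes are retained for the
#' downstream Euclidean dissimilarity.
#'
#' Constant columns carry no information on the correlation scale and are
#' dropped with a warning. The sign of each axis is fixed so that the
#' largest-magnitude loading on that axis is positive, making scores
#' reproducible across platforms.
#'
#' @param localities Data frame with a `locality` id column and numeric
#'   environment columns. Columns named `lat`/`lon` are ignored.
#' @param k Number of axes to retain (default 5).
#' @param env_cols Optional character vector naming the environment columns;
#'   default: all numeric columns except `lat` and `lon`.
#' @param use_correlation Scale variables to unit variance (default TRUE).
#'   FALSE gives covariance-matrix PCA.
#' @return An object of class `env_scores`: list with `scores` (tibble:
#'   locality, PC1..PCk), `loadings`, `center`, `scale`, `var_explained`
#'   (fraction per retained axis), `k`, and `dropped` (constant columns).
#' @export
pca_scores <- function(localities, k = 5, env_cols = NULL, use_correlation = TRUE) {
  stopifnot(is.data.frame(localities))
  if (!"locality" %in% names(localities)) abort("locality column required")
  if (nrow(localities) < 2) abort("need at least 2 localities for PCA")
  if (is.null(env_cols)) {
    num <- vapply(localities, is.numeric, logical(1))
    env_cols <- setdiff(names(localities)[num], c("lat", "lon"))
  }
  if (!length(env_cols)) abort("no environment columns found")
  x <- as.matrix(localities[env_cols])
  if (anyNA(x)) abort("missing values in environment columns")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warn(paste("dropping constant environment variables:",
               paste(dropped, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!ncol(x)) abort("all environment columns constant")
  k <- min(k, ncol(x), nrow(x) - 1)
  pc <- prcomp(x, center = TRUE, scale. = use_correlation)
  rot <- pc$rotation
  # sign convention: largest-|loading| entry of each axis is positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(
    scores = tibble::tibble(locality = as.character(localities$locality)) |>
      dplyr::bind_cols(tibble::as_tibble(scores[, seq_len(k), drop = FALSE])),
    loadings = rot[, seq_len(k), drop = FALSE],
    center = pc$center,
    scale = if (use_correlation) pc$scale else rep(1, ncol(x)),
    var_explained = ve[seq_len(k)],
    k = k,
    dropped = dropped
  )
  class(out) <- "env_scores"
  out
}

#' @export
print.env_scores <- function(x, ...) {
  cat("Environmental PCA scores:", nrow(x$scores), "localities,",
      x$k, "axes retained\n")
  cat("Variance explained:",
      paste0(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Euclidean environmental dissimilarity between localities
#'
#' Distance between locality score vectors on the retained PCA axes.
#'
#' @param scores An `env_scores` object from [pca_scores()], or a data frame
#'   with a `locality` column and numeric score columns.
#' @return Symmetric matrix with locality ids as dimnames.
#' @export
env_dissimilarity <- function(scores) {
  if (inherits(scores, "env_scores")) scores <- scores$scores
  stopifnot(is.data.frame(scores))
  if (!"locality" %in% names(scores)) abort("locality column required")
  m <- as.matrix(scores[setdiff(names(scores), "locality")])
  if (!is.numeric(m)) abort("score columns must be numeric")
  d <- as.matrix(dist(m))
  dimnames(d) <- list(scores$locality, scores$locality)
  d
}

#' Environmental heterogeneity of a clade's range
#'
#' Mean pairwise environmental dissimilarity over the clade's localities.
#' Low values mean a homogeneous range; the value grows with environmental
#' differences among localities.
#'
#' @param env_dist Environmental dissimilarity matrix from
#'   [env_dissimilarity()].
#' @param localities Character vector of the clade's locality ids (>= 2).
#' @return Scalar mean dissimilarity.
#' @export
clade_env_heterogeneity <- function(env_dist, localities) {
  mean_pairwise(env_dist, localities)
}

#' Average point values on a square grid
#'
#' Replaces each point's value with the mean over all points falling in the
#' same cell of a `cell_km` square grid anchored at the lower-left corner of
#' the data bounding box (an equirectangular local approximation; adequate
#' at the sub-degree cell sizes this is meant for, e.g. smoothing 1-km
#' tree-cover values to a 5-km grid).
#'
#' @param points Data frame with `lat`, `lon` and a numeric `value` column.
#' @param cell_km Grid cell edge in km (default 5).
#' @return The input tibble with added `cell_x`, `cell_y` indices and
#'   `value_avg`, the cell mean.
#' @export
grid_average <- function(points, cell_km = 5) {
  stopifnot(is.data.frame(points))
  if (!nrow(points)) abort("empty input")
  need <- c("lat", "lon", "value")
  if (!all(need %in% names(points))) {
    abort(paste("points must have columns:", paste(need, collapse = ", ")))
  }
  check_coords(points$lat, points$lon)
  km_per_deg <- pi * 6371.0088 / 180
  lat0 <- min(points$lat); lon0 <- min(points$lon)
  y_km <- (points$lat - lat0) * km_per_deg
  x_km <- (points$lon - lon0) * km_per_deg * cos(lat0 * pi / 180)
  out <- tibble::as_tibble(points)
  out$cell_x <- as.integer(floor(x_km / cell_km))
  out$cell_y <- as.integer(floor(y_km / cell_km))
  out |>
    dplyr::group_by(.data$cell_x, .data$cell_y) |>
    dplyr::mutate(value_avg = mean(.data$value)) |>
    dplyr::ungroup()
}
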
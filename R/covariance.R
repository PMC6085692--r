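#' UPGMA cophenetic (ultrametric) distances
#'
#' Average-linkage agglomerative clustering returning the implied
#' ultrametric (cophenetic) distance matrix directly. Written in-package so
#' the tie-break is explicit and deterministic: when several pairs are at
#' the minimum distance, the pair whose sorted label pair is
#' lexicographically smallest is merged first.
#'
#' @param d Symmetric distance matrix with dimnames, zero diagonal.
#' @return Ultrametric matrix on the same labels; `u[i, j]` is twice the
#'   height at which i and j first join.
#' @export
upgma_cophenetic <- function(d) {
  stopifnot(is.matrix(d))
  if (is.null(rownames(d))) abort("distance matrix needs dimnames")
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d)))) {
    abort("distance matrix is not symmetric")
  }
  labs <- rownames(d)
  n <- length(labs)
  if (n < 2) abort("need at least 2 taxa")
  u <- matrix(0, n, n, dimnames = list(labs, labs))
  # active clusters: list of member index vectors, keyed by a representative
  members <- as.list(seq_len(n))
  key <- vapply(members, function(m) min(labs[m]), character(1))
  dc <- d  # between-cluster average distances, rows/cols track clusters
  active <- seq_len(n)
  while (length(active) > 1) {
    # find minimum off-diagonal among active clusters
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        a <- active[ii]; b <- active[jj]
        dd <- dc[a, b]
        kk <- paste(sort(c(key[a], key[b])), collapse = "\r")
        if (dd < best_d - 1e-15 ||
            (abs(dd - best_d) <= 1e-15 && (is.null(best_key) || kk < best_key))) {
          best <- c(a, b); best_d <- dd; best_key <- kk
        }
      }
    }
    a <- best[1]; b <- best[2]
    ma <- members[[a]]; mb <- members[[b]]
    u[ma, mb] <- best_d
    u[mb, ma] <- best_d
    # UPGMA average linkage: size-weighted update
    na <- length(ma); nb <- length(mb)
    for (c_ in setdiff(active, best)) {
      dn <- (na * dc[a, c_] + nb * dc[b, c_]) / (na + nb)
      dc[a, c_] <- dc[c_, a] <- dn
    }
    members[[a]] <- c(ma, mb)
    key[a] <- min(key[a], key[b])
    active <- setdiff(active, b)
  }
  u
}

#' Brownian-motion covariance from a species distance matrix
#'
#' PGLS under Brownian motion needs, for every pair of clades, the length of
#' evolutionary history they share from the root. A plain genetic distance
#' matrix does not carry that structure, so it is first ultrametrized by
#' UPGMA; with cophenetic distances `u` and tree depth `T = max(u)/2`, the
#' shared path length is `C_ij = T - u_ij/2` and `C_ii = T`.
#'
#' @param d Symmetric species-by-species distance matrix (dimnames = clade
#'   ids).
#' @return A `cov_spec` object: list with `C` (covariance matrix), `order`
#'   (clade ids), `depth` (T), and `method` metadata.
#' @seealso [brownian_covariance_tree()] for the tree-input route.
#' @export
brownian_covariance <- function(d) {
  u <- upgma_cophenetic(d)
  T_ <- max(u) / 2
  C <- T_ - u / 2
  diag(C) <- T_
  new_cov_spec(C, method = "distance-upgma")
}

#' Brownian-motion covariance from an ultrametric tree
#'
#' `C_ij` = shared branch length from the root to the MRCA of i and j
#' (computed by [ape::vcv()]); the natural route when a chronogram for the
#' analysed clades is available.
#'
#' @param tree Ultrametric `phylo`; tip labels are the clade ids.
#' @return A `cov_spec` object.
#' @export
brownian_covariance_tree <- function(tree) {
  validate_tree(tree)
  node_heights(tree)  # errors if not ultrametric
  C <- ape::vcv(tree)
  ord <- sort(rownames(C))
  new_cov_spec(C[ord, ord], method = "tree-vcv")
}

new_cov_spec <- function(C, method) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    abort("covariance matrix is not positive semi-definite")
  }
  structure(list(C = C, order = rownames(C), depth = max(diag(C)),
                 method = method),
            class = "cov_spec")
}

#' @export
print.cov_spec <- function(x, ...) {
  cat(sprintf("Brownian covariance over %d clades (depth %.6g, method %s)\n",
              nrow(x$C), x$depth, x$method))
  invisible(x)
}
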
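# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force path enumeration instead of cophenetic
# distances, the spherical law of cosines instead of the haversine, literal
# formula transcriptions instead of dist.dna.

# patristic distance by explicit root-to-tip path enumeration: for each tip
# record the multiset of edges to the root, then d(i,j) = sum of edge
# lengths not shared by both paths
brute_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    p <- integer(0)
    while (parent[node] != 0) {
      p <- c(p, node)
      node <- parent[node]
    }
    p
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(i - 1)) {
      shared <- intersect(paths[[i]], paths[[j]])
      uniq <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
      d[i, j] <- d[j, i] <- sum(elen[uniq])
    }
  }
  ord <- sort(tree$tip.label)
  d[ord, ord]
}

# spherical law of cosines, same radius convention as haversine_km
slc_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  ang <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  r * acos(pmin(pmax(ang, -1), 1))
}

# literal K2P transcription for one pair of gap-free sequences
k2p_pair <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  purines <- c("A", "G")
  ts <- mean((a != b) & ((a %in% purines) == (b %in% purines)))  # transitions
  tv <- mean((a != b) & ((a %in% purines) != (b %in% purines)))  # transversions
  -0.5 * log((1 - 2 * ts - tv) * sqrt(1 - 2 * tv))
}

# random non-ultrametric tree with uniform branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr
}

# small clade-style regression dataset with an ultrametric tree
random_pgls_data <- function(n, seed, sigma = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- sprintf("c%02d", seq_len(n))
  d <- data.frame(clade = tr$tip.label,
                  x1 = rnorm(n), x2 = rnorm(n),
                  g = sample(c("low", "mid", "high"), n, replace = TRUE))
  d$y <- 0.5 + 1.2 * d$x1 - 0.7 * d$x2 + sigma * rnorm(n)
  list(tree = tr, data = d)
}
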
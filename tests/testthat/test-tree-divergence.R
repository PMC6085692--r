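test_that("read_newick parses lengths exactly and validates structure", {
  tr <- read_newick("(A:1.0,B:2.0):0.0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))
  tr2 <- read_newick("((A:1,B:1):1,C:2);")
  depth <- ape::node.depth.edgelength(tr2)[1:3]
  expect_equal(unname(depth), c(2, 2, 2))
  expect_error(read_newick("(A:1,A:2);"), "duplicate tip")
  expect_error(read_newick("((A:1,B:2);"), "malformed")
  expect_error(read_newick("(A:1,B);"), "lengths missing")
})

test_that("patristic distances match definition and brute-force enumeration", {
  expect_equal(patristic_matrix("(A:1.0,B:2.0);")["A", "B"], 3.0)
  zero <- read_newick("((A:0,B:0):0,C:0);")
  expect_true(all(patristic_matrix(zero) == 0))
  # brute-force path-enumeration oracle on random trees
  for (s in 1:6) {
    tr <- random_tree(12, seed = 100 + s)
    expect_equal(patristic_matrix(tr), brute_patristic(tr), tolerance = 1e-12)
  }
  expect_error(patristic_matrix(ape::read.tree(text = "(A:1);")), "at least 2 tips")
})

test_that("patristic distances satisfy the four-point condition", {
  tr <- random_tree(15, seed = 202)
  d <- patristic_matrix(tr)
  set.seed(7)
  for (k in 1:30) {
    q <- sample(rownames(d), 4)
    s1 <- d[q[1], q[2]] + d[q[3], q[4]]
    s2 <- d[q[1], q[3]] + d[q[2], q[4]]
    s3 <- d[q[1], q[4]] + d[q[2], q[3]]
    ss <- sort(c(s1, s2, s3))
    expect_lt(ss[3] - ss[2], 1e-9)  # two largest sums equal on a tree metric
  }
})

test_that("uniform branch scaling scales all divergences linearly", {
  tr <- random_tree(10, seed = 303)
  tr2 <- tr; tr2$edge.length <- 3 * tr$edge.length
  expect_equal(patristic_matrix(tr2), 3 * patristic_matrix(tr), tolerance = 1e-12)
})

test_that("clade rules: identity, splits, exclusions and the min-locality rule", {
  sm <- tibble::tibble(
    sample = sprintf("s%02d", 1:12),
    clade = rep(c("spA", "spB"), each = 6),
    locality = c(paste0("A", rep(1:3, each = 2)), paste0("B", 1:6)))
  id <- apply_clade_rules(sm, clade_rules())
  expect_equal(id$clade, sm$clade)
  expect_false(any(id$excluded))

  # split spB's 6 localities into two clades of 3: both retained
  rules <- clade_rules(splits = list(
    spB = list(spB_east = paste0("B", 1:3), spB_west = paste0("B", 4:6))))
  out <- apply_clade_rules(sm, rules)
  expect_setequal(retained_clades(out), c("spA", "spB_east", "spB_west"))

  # excluding one sample leaves spA with 2 localities -> min-localities flag
  out2 <- apply_clade_rules(sm, clade_rules(exclude_samples = c("s01", "s02")))
  expect_true(all(out2$excluded[out2$clade == "spA"]))
  expect_true("min-localities" %in% out2$reason[out2$clade == "spA"])
  expect_setequal(retained_clades(out2), "spB")
  # every exclusion carries a reason
  expect_true(all(nzchar(out2$reason[out2$excluded])))

  expect_error(apply_clade_rules(sm, clade_rules(splits = list(spZ = list(z = "A1")))),
               "unknown species")
  expect_error(
    apply_clade_rules(sm, clade_rules(splits = list(spA = list(x = "B9")))),
    "unknown localities")
})

test_that("locality mean divergence: simple arithmetic and brute-force oracle", {
  # 2 localities, 1 sample each
  d <- matrix(c(0, 0.04, 0.04, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sm <- tibble::tibble(sample = c("a", "b"), clade = "sp",
                       locality = c("p", "q"), excluded = FALSE, reason = NA)
  cd <- locality_mean_divergence(d, sm, "sp")
  expect_equal(cd$avg_divergence, 0.04)
  expect_equal(cd$n_pairs, 1L)

  # p = {a, b}, q = {c}; mean of 0.02, 0.04
  d2 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d2["a", "c"] <- d2["c", "a"] <- 0.02
  d2["b", "c"] <- d2["c", "b"] <- 0.04
  sm2 <- tibble::tibble(sample = c("a", "b", "c"), clade = "sp",
                        locality = c("p", "p", "q"), excluded = FALSE, reason = NA)
  expect_equal(locality_mean_divergence(d2, sm2, "sp")$avg_divergence, 0.03)

  # brute-force double loop over cross-locality sample pairs, 5 localities x 2
  tr <- random_tree(10, seed = 404)
  d3 <- patristic_matrix(tr)
  sm3 <- tibble::tibble(sample = rownames(d3), clade = "sp",
                        locality = rep(paste0("L", 1:5), each = 2),
                        excluded = FALSE, reason = NA)
  got <- locality_mean_divergence(d3, sm3, "sp")
  pairs <- combn(paste0("L", 1:5), 2)
  pm <- apply(pairs, 2, function(pq) {
    ii <- sm3$sample[sm3$locality == pq[1]]
    jj <- sm3$sample[sm3$locality == pq[2]]
    vals <- c()
    for (i in ii) for (j in jj) vals <- c(vals, d3[i, j])
    mean(vals)
  })
  expect_equal(got$avg_divergence, mean(pm), tolerance = 1e-12)
  # bounded by locality-pair means
  expect_gte(got$avg_divergence, min(pm))
  expect_lte(got$avg_divergence, max(pm))
  # invariant to sample order
  got2 <- locality_mean_divergence(d3, sm3[sample(nrow(sm3)), ], "sp")
  expect_equal(got2$avg_divergence, got$avg_divergence)
  # sample-pair weighting equals the raw cross-pair mean
  gotw <- locality_mean_divergence(d3, sm3, "sp", weighting = "sample-pair")
  allv <- c()
  for (k in seq_len(ncol(pairs))) {
    ii <- sm3$sample[sm3$locality == pairs[1, k]]
    jj <- sm3$sample[sm3$locality == pairs[2, k]]
    for (i in ii) for (j in jj) allv <- c(allv, d3[i, j])
  }
  expect_equal(gotw$avg_divergence, mean(allv), tolerance = 1e-12)

  sm4 <- sm3; sm4$excluded <- TRUE; sm4$reason <- "excluded-clade"
  expect_error(locality_mean_divergence(d3, sm4, "sp"), "excluded")
})

test_that("sequence distances: closed forms, complete deletion, K2P oracle", {
  aln <- c(s1 = "AAAA", s2 = "AAAA")
  for (m in c("p", "JC69", "K2P")) {
    expect_equal(sequence_distance(aln, m)["s1", "s2"], 0)
  }
  aln2 <- c(s1 = "AAAA", s2 = "AAAT")
  expect_equal(sequence_distance(aln2, "p")["s1", "s2"], 0.25)
  expect_equal(sequence_distance(aln2, "JC69")["s1", "s2"],
               -0.75 * log(1 - 4 * 0.25 / 3), tolerance = 1e-9)
  # gap columns removed for all sequences (complete deletion)
  aln3 <- c(s1 = "A-CGT", s2 = "ATCGA", s3 = "ANCGT")
  d <- sequence_distance(aln3, "p")  # column 2 has a gap and an N: dropped
  expect_equal(d["s1", "s3"], 0)     # identical after deletion
  expect_equal(d["s1", "s2"], 0.25)  # 4 clean columns, one mismatch (T vs A)
  # K2P literal-formula oracle on random pairs
  set.seed(55)
  for (k in 1:10) {
    s1 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    ch <- strsplit(s1, "")[[1]]
    mut <- sample(300, 40)
    ch[mut] <- sample(c("A", "C", "G", "T"), 40, TRUE)
    s2 <- paste(ch, collapse = "")
    if (s1 == s2) next
    got <- sequence_distance(c(a = s1, b = s2), "K2P")["a", "b"]
    expect_equal(got, k2p_pair(s1, s2), tolerance = 1e-9)
  }
  expect_error(sequence_distance(c(a = "A-", b = "-A")), "no shared")
  expect_error(sequence_distance(c(a = "ACGT", b = "ACG")), "equal length")
  # JC69 undefined when p >= 3/4
  expect_error(sequence_distance(c(a = "AAAA", b = "CCCC"), "JC69"), "undefined")
})
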
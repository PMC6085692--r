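test_that("chronograms are ultrametric binary trees of the requested depth", {
  tr2 <- simulate_chronogram(2, root_age = 95, seed = 1)
  expect_equal(sort(tr2$edge.length), c(95, 95))
  for (s in 1:5) {
    tr <- simulate_chronogram(10, seed = s)
    depths <- ape::node.depth.edgelength(tr)[1:10]
    expect_lt(max(abs(depths - 95)), 1e-9)
    expect_equal(tr$Nnode, 9)  # binary: n - 1 internal nodes
  }
  t1 <- simulate_chronogram(12, seed = 7)
  t2 <- simulate_chronogram(12, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_chronogram(1), ">= 2")
})

test_that("locality simulation honours seeding, bounds and the autocorrelation knob", {
  a <- simulate_localities(30, seed = 5)
  b <- simulate_localities(30, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(simulate_localities(1, seed = 1)), 1)
  expect_true(all(a$tree_cover >= 0 & a$tree_cover <= 100))
  expect_true(all(abs(a$lat) <= 90))
  expect_true(all(abs(a$lon) <= 180))
  # env_autocorr = 1: every variable is an exact linear function of the
  # coordinates, so regression residuals on (lat, lon) vanish
  det <- simulate_localities(25, env_autocorr = 1, seed = 9)
  for (v in c("env01", "env07", "env19")) {
    res <- stats::resid(stats::lm(stats::reformulate(c("lat", "lon"), v), det))
    expect_lt(max(abs(res)), 1e-8)
  }
  expect_error(simulate_localities(0), ">= 1")
  expect_error(simulate_localities(5, extent_km = -1), "> 0")
})

test_that("null configuration yields zero divergence recovered through the tree stage", {
  cfg <- sim_config(n_species = 4, beta_age = 0, beta_geo = 0, beta_env = 0,
                    noise_sd = 0, seed = 11)
  truth <- simulate_clade_dataset(cfg)
  expect_true(all(truth$clade_summary$divergence == 0))
  dmats <- lapply(truth$within_trees, patristic_matrix)
  div <- clade_divergence(dmats, truth$sample_map)
  expect_true(all(div$avg_divergence == 0))
})

test_that("deterministic chain: divergence equals beta_age x stem age, and round-trips", {
  cfg <- sim_config(n_species = 6, beta_age = 0.001, beta_geo = 0, beta_env = 0,
                    noise_sd = 0, seed = 12)
  truth <- simulate_clade_dataset(cfg)
  expect_equal(truth$clade_summary$divergence,
               0.001 * truth$clade_summary$age, tolerance = 1e-9)
  dmats <- lapply(truth$within_trees, patristic_matrix)
  div <- clade_divergence(dmats, truth$sample_map)
  m <- dplyr::left_join(div, truth$clade_summary, by = "clade")
  expect_equal(m$avg_divergence, m$divergence, tolerance = 1e-9)
})

test_that("identical configurations reproduce the dataset bit-for-bit", {
  cfg <- sim_config(n_species = 5, seed = 13)
  t1 <- simulate_clade_dataset(cfg)
  t2 <- simulate_clade_dataset(cfg)
  expect_identical(t1$clade_summary, t2$clade_summary)
  expect_identical(t1$locality_table, t2$locality_table)
  expect_identical(lapply(t1$within_trees, ape::write.tree),
                   lapply(t2$within_trees, ape::write.tree))
})

test_that("adding a species leaves earlier species' locality draws untouched", {
  t5 <- simulate_clade_dataset(sim_config(n_species = 5, seed = 14))
  t6 <- simulate_clade_dataset(sim_config(n_species = 6, seed = 14))
  for (sp in sprintf("sp%02d", 1:5)) {
    a <- t5$locality_table[startsWith(t5$locality_table$locality, sp), ]
    b <- t6$locality_table[startsWith(t6$locality_table$locality, sp), ]
    expect_identical(a[c("locality", "lat", "lon")], b[c("locality", "lat", "lon")])
  }
})

test_that("with no phylogenetic signal, residuals are exchangeable on the tree", {
  # correlation between species residuals and phylogenetic distance to the
  # nearest neighbour should be null; count significant tests across reps
  reps <- 60; sig <- 0
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_species = 12, beta_age = 0, beta_geo = 0, beta_env = 0,
                      noise_sd = 0.005, lambda_signal = 0, seed = 80000 + i)
    truth <- simulate_clade_dataset(cfg)
    pd <- patristic_matrix(truth$chronogram)
    diag(pd) <- NA
    nn <- apply(pd[truth$clade_summary$clade, truth$clade_summary$clade], 1,
                min, na.rm = TRUE)
    p <- stats::cor.test(truth$clade_summary$resid, nn)$p.value
    if (p < 0.05) sig <- sig + 1
  }
  expect_lte(sig / reps, 0.15)
})

test_that("configuration validation and truncation warning fire", {
  expect_error(sim_config(n_species = 2), ">= 3")
  expect_error(sim_config(lambda_signal = 1.5), "lambda")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  cfg <- sim_config(n_species = 4, beta_age = -0.01, beta_geo = 0,
                    noise_sd = 0.001, seed = 15)
  expect_warning(truth <- simulate_clade_dataset(cfg), "truncating")
  expect_true(all(truth$clade_summary$divergence >= 0))
})

test_that("config files round-trip through the key-value format", {
  cfg <- sim_config(n_species = 7, beta_age = 0.002, seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
})
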
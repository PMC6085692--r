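test_that("PGLS with identity covariance reproduces OLS exactly", {
  for (s in 1:8) {
    rd <- random_pgls_data(15, seed = 800 + s)
    f <- pgls_fit(rd$data, y ~ x1 + x2 + g, cov = NULL)
    ols <- stats::lm(y ~ x1 + x2 + g, rd$data)
    sm <- summary(ols)$coefficients
    td <- tidy(f)
    expect_equal(td$estimate, unname(sm[, 1]), tolerance = 1e-9)
    expect_equal(td$std.error, unname(sm[, 2]), tolerance = 1e-9)
    expect_equal(td$statistic, unname(sm[, 3]), tolerance = 1e-9)
    a <- stats::anova(ols)
    got <- pgls_anova(f)
    expect_equal(got$statistic[-1], a$`F value`[1:3], tolerance = 1e-9)
    expect_equal(got$p.value[-1], a$`Pr(>F)`[1:3], tolerance = 1e-9)
  }
})

test_that("hand-worked normal equations: n=3, y=(1,2,4), x=(0,1,2), C=I", {
  d <- data.frame(clade = c("a", "b", "c"), x = c(0, 1, 2), y = c(1, 2, 4))
  f <- pgls_fit(d, y ~ x, cov = NULL)
  # X'X = [[3,3],[3,5]], X'y = [7,10]; solve: intercept 5/6, slope 3/2
  expect_equal(unname(coef(f)), c(5 / 6, 3 / 2), tolerance = 1e-12)
})

test_that("PGLS matches nlme::gls under a Brownian correlation (ML)", {
  skip_if_not_installed("nlme")
  for (s in 1:5) {
    rd <- random_pgls_data(14, seed = 900 + s)
    cv <- brownian_covariance_tree(rd$tree)
    f <- pgls_fit(rd$data, y ~ x1 + x2, cv)
    dd <- rd$data; rownames(dd) <- dd$clade
    g <- nlme::gls(y ~ x1 + x2, data = dd,
                   correlation = ape::corBrownian(phy = rd$tree, form = ~clade),
                   method = "ML")
    expect_equal(unname(coef(f)), unname(stats::coef(g)), tolerance = 1e-8)
    expect_equal(tidy(f)$std.error, unname(sqrt(diag(g$varBeta))), tolerance = 1e-8)
    expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-8)
    expect_equal(pgls_anova(f)$statistic, stats::anova(g)$`F-value`, tolerance = 1e-8)
  }
})

test_that("refits are bit-reproducible and dropping a term never helps the likelihood", {
  rd <- random_pgls_data(16, seed = 1001)
  cv <- brownian_covariance_tree(rd$tree)
  f1 <- pgls_fit(rd$data, y ~ x1 + x2 + g, cv)
  f2 <- pgls_fit(rd$data, y ~ x1 + x2 + g, cv)
  expect_identical(f1$logLik, f2$logLik)
  for (drop in c("x1", "x2", "g")) {
    red <- pgls_fit(rd$data, stats::reformulate(setdiff(c("x1", "x2", "g"), drop), "y"), cv)
    expect_lte(red$logLik, f1$logLik + 1e-9)
    out <- lrt(f1, red)
    expect_gte(out$statistic, 0)
  }
})

test_that("likelihood-ratio mechanics: identity, chi-square quantile, recompute oracle", {
  rd <- random_pgls_data(15, seed = 1101)
  cv <- brownian_covariance_tree(rd$tree)
  f <- pgls_fit(rd$data, y ~ x1 + x2, cv)
  same <- lrt(f, f)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # chi-square quantile identity
  expect_equal(stats::pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  # statistic equals twice the difference of independently recomputed logLiks
  red <- pgls_fit(rd$data, y ~ x1, cv)
  out <- lrt(f, red)
  expect_equal(out$statistic, 2 * (f$logLik - red$logLik), tolerance = 1e-12)
  expect_equal(out$df, 1L)
  expect_error(lrt(red, f), "not nested")
})

test_that("changing the factor reference level changes coefficients but not F or LRT", {
  rd <- random_pgls_data(18, seed = 1201)
  cv <- brownian_covariance_tree(rd$tree)
  f1 <- pgls_fit(rd$data, y ~ x1 + g, cv)
  d2 <- rd$data
  d2$g <- stats::relevel(factor(d2$g), ref = "mid")
  f2 <- pgls_fit(d2, y ~ x1 + g, cv)
  expect_false(isTRUE(all.equal(sort(coef(f1)), sort(coef(f2)))))
  expect_equal(pgls_anova(f1)$statistic, pgls_anova(f2)$statistic, tolerance = 1e-9)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-9)
})

test_that("collinear designs are rejected with the offending term named", {
  rd <- random_pgls_data(12, seed = 1301)
  rd$data$x3 <- 2 * rd$data$x1
  expect_error(pgls_fit(rd$data, y ~ x1 + x3, cov = NULL), "collinear")
  expect_error(pgls_fit(rd$data[1:3, ], y ~ x1 + x2 + g, cov = NULL),
               "more parameters")
})

test_that("phylogenetic weighting is more efficient under Brownian residuals", {
  # GLS with the true covariance is BLUE: across replicates the sampling
  # spread of the age coefficient should be clearly smaller than OLS's
  reps <- 30
  ep <- eo <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_species = 20, beta_age = 0.0015, noise_sd = 0.005,
                      lambda_signal = 1, seed = 40000 + i)
    truth <- simulate_clade_dataset(cfg)
    cs <- truth$clade_summary
    cs$avg_divergence <- cs$divergence
    cv <- brownian_covariance_tree(truth$chronogram)
    tp <- tidy(pgls_fit(cs, avg_divergence ~ avg_geodist + age, cv))
    to <- tidy(pgls_fit(cs, avg_divergence ~ avg_geodist + age, cov = NULL))
    ep[i] <- tp$estimate[tp$term == "age"]
    eo[i] <- to$estimate[to$term == "age"]
  }
  rmse <- function(e) sqrt(mean((e - 0.0015)^2))
  expect_lt(rmse(ep), rmse(eo))
})
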
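test_that("PGLS with lambda = 0 on an ultrametric tree equals OLS", {
  cfg <- sim_config(n_tips = 40, lambda = 0, seed = 21)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  xy <- named_xy(tt)
  f <- fit_pgls(xy$x, xy$y, tr, lambda = 0)
  ols <- lm(xy$y ~ xy$x)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
  expect_equal(f$f_statistic, unname(summary(ols)$fstatistic[1]),
               tolerance = 1e-8)
})

test_that("coefficients equal the naive matrix-inversion oracle at n <= 6", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(4:6, 1)
    tr <- relabel_tips(simulate_tree(sim_config(n_tips = n)), "t")
    x <- stats::setNames(rnorm(n), tr$tip.label)
    y <- stats::setNames(rnorm(n), tr$tip.label)
    lam <- sample(c(0, 0.3, 0.7, 1), 1)
    f <- fit_pgls(x, y, tr, lambda = lam)
    beta <- naive_gls_beta(cbind(1, x[tr$tip.label]), y[tr$tip.label],
                           vcv_pagel(tr, lam))
    expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("fixed-lambda and REML fits agree with nlme::gls + corPagel", {
  skip_if_not_installed("nlme")
  cfg <- sim_config(n_tips = 40, lambda = 0.6, seed = 23)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  d <- data.frame(x = tt$log_mass, y = tt$log_lifespan, sp = tt$species)
  for (lam in c(0, 0.5, 1)) {
    f <- fit_pgls(stats::setNames(d$x, d$sp), stats::setNames(d$y, d$sp),
                  tr, lambda = lam)
    g <- nlme::gls(y ~ x, data = d, method = "REML",
                   correlation = ape::corPagel(lam, phy = tr, form = ~sp,
                                               fixed = TRUE))
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
  }
  f <- fit_pgls(stats::setNames(d$x, d$sp), stats::setNames(d$y, d$sp), tr)
  g <- nlme::gls(y ~ x, data = d, method = "REML",
                 correlation = ape::corPagel(0.5, phy = tr, form = ~sp))
  lam_nlme <- as.numeric(coef(g$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(f$lambda, lam_nlme, tolerance = 1e-3)
})

test_that("REML lambda beats a coarse grid, every fit", {
  set.seed(24)
  for (lam_true in c(0.2, 0.8)) {
    cfg <- sim_config(n_tips = 60, lambda = lam_true)
    tr <- simulate_tree(cfg)
    tt <- simulate_traits(tr, cfg)
    xy <- named_xy(tt)
    f <- fit_pgls(xy$x, xy$y, tr, fallback_threshold = 0)
    grid_ll <- vapply(c(0, 0.5, 1), function(l)
      fit_pgls(xy$x, xy$y, tr, lambda = l)$loglik_reml, numeric(1))
    expect_true(all(f$loglik_reml >= grid_ll - 1e-8))
  }
})

test_that("species mismatches and degenerate inputs error informatively", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  x <- c(A = 1, B = 2, D = 3)
  y <- c(A = 1, B = 2, D = 3)
  expect_error(fit_pgls(x, y, tr), "absent from tree: D")
  expect_error(fit_pgls(c(A = 1, B = 2), c(A = 1, B = 2), tr), "at least 3")
  expect_error(fit_pgls(unname(x), unname(y), tr), "named")
  expect_error(fit_pgls(x[1:2], y[1:2], tr, lambda = 2), "at least 3|\\[0, 1\\]")
})

test_that("plain GLS matches PGLS at lambda zero and triggers as fallback", {
  cfg <- sim_config(n_tips = 30, lambda = 0, seed = 25)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  xy <- named_xy(tt)
  f0 <- fit_pgls(xy$x, xy$y, tr, lambda = 0)
  fp <- fit_gls_plain(as.numeric(xy$x), as.numeric(xy$y))
  expect_equal(unname(fp$coefficients), unname(f0$coefficients),
               tolerance = 1e-10)
  # estimated lambda below the threshold flips the fit to identity covariance
  ff <- fit_pgls(xy$x, xy$y, tr, fallback_threshold = 1.5)
  expect_true(ff$fallback_gls)
  expect_equal(unname(ff$coefficients), unname(fp$coefficients),
               tolerance = 1e-10)
})

test_that("tree selection maximizes F with first-index tie-breaking", {
  cfg <- sim_config(n_tips = 20, lambda = 1, seed = 26)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  xy <- named_xy(tt)
  single <- fit_over_trees(xy$x, xy$y, tr)
  expect_equal(single$index, 1)
  expect_equal(length(single$f_values), 1)

  copies <- fit_over_trees(xy$x, xy$y, list(tr, tr, tr))
  expect_equal(copies$index, 1)
  expect_lt(diff(range(copies$f_values)), 1e-8)
  expect_error(fit_over_trees(xy$x, xy$y, list()), "empty")
})

test_that("the generating tree tends to win the F comparison", {
  set.seed(27)
  wins <- vapply(1:25, function(i) {
    cfg <- sim_config(n_tips = 40, lambda = 1, sigma = 0.15)
    tr <- simulate_tree(cfg)
    tt <- simulate_traits(tr, cfg)
    xy <- named_xy(tt)
    decoys <- lapply(1:4, function(j) {
      d <- simulate_tree(sim_config(n_tips = 40))
      d$tip.label <- sample(tr$tip.label)
      d
    })
    fit_over_trees(xy$x, xy$y, c(list(tr), decoys))$index == 1
  }, logical(1))
  expect_gt(mean(wins), 1 / 5)  # far above the chance rate of one in five
})

test_that("confidence bands are narrowest at the predictor mean and PI contains CI", {
  cfg <- sim_config(n_tips = 50, lambda = 0.5, seed = 28)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  xy <- named_xy(tt)
  f <- fit_pgls(xy$x, xy$y, tr)
  grid <- seq(min(xy$x), max(xy$x), length.out = 41)
  pr <- predict_with_intervals(f, grid)
  widths <- pr$ci_upper - pr$ci_lower
  # whitened-space predictor mean minimizes the band width
  xw_mean <- -f$cov_beta[1, 2] / f$cov_beta[2, 2]
  expect_equal(grid[which.min(widths)], grid[which.min(abs(grid - xw_mean))])
  expect_true(all(pr$pi_lower <= pr$ci_lower & pr$pi_upper >= pr$ci_upper))

  # degenerate noise: PI collapses onto CI
  cfg0 <- sim_config(n_tips = 20, sigma = 1e-9, seed = 29,
                     intercepts = c(clade_a = 0.3, clade_b = 0.3))
  tr0 <- simulate_tree(cfg0)
  tt0 <- simulate_traits(tr0, cfg0)
  xy0 <- named_xy(tt0)
  f0 <- fit_pgls(xy0$x, xy0$y, tr0, lambda = 0)
  pr0 <- predict_with_intervals(f0, c(1, 3))
  expect_equal(pr0$pi_lower, pr0$ci_lower, tolerance = 1e-6)
})

test_that("the ANCOVA ladder is monotone in likelihood and finds true structure", {
  set.seed(30)
  cfg <- sim_config(n_tips = 20, lambda = 1,
                    intercepts = c(clade_a = 0.16, clade_b = 1.0))
  tra <- two_clade_tree(20, cfg)
  tt <- simulate_traits(tra, cfg)
  g <- stats::setNames(tt$clade, tt$species)
  xy <- named_xy(tt)
  lad <- phylo_ancova(xy$x, xy$y, g, tra)
  ll <- vapply(lad$fits, function(f) f$loglik_ml, numeric(1))
  expect_true(all(diff(ll[c("common", "intercept", "full")]) >= -1e-8))
  expect_true(all(diff(ll[c("common", "slope", "full")]) >= -1e-8))
  expect_true(all(lad$comparisons$F >= 0))
  expect_equal(lad$comparisons$df_extra, c(1, 1, 2))
  # partial eta squared is the proportional RSS reduction, in [0, 1]
  expect_true(all(lad$comparisons$partial_eta_sq >= 0 &
                    lad$comparisons$partial_eta_sq <= 1))

  expect_error(phylo_ancova(xy$x, xy$y,
                            stats::setNames(rep(c("A", "B"), c(2, 38)),
                                            names(xy$x)), tra),
               "at least 3 members")
})

test_that("published-coefficient fits project but refuse interval math", {
  pf <- published_fit(slope = -0.83, intercept = -0.31)
  expect_error(predict_with_intervals(pf, 1), "covariance")
  est <- project_trait(pf, 14)
  expect_true(is.na(est$lower))
  expect_equal(est$estimate, 10^(-0.83 * log10(14) - 0.31), tolerance = 1e-12)
})
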
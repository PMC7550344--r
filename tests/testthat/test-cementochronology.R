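make_table <- function(...) increment_table(data.frame(...))

test_that("increment tables are validated", {
  expect_error(increment_table(data.frame(specimen = "s")), "missing columns")
  expect_error(make_table(specimen = "s", element = "m1", observer = "o",
                          section = 1, count = 0), "positive integers")
  expect_error(make_table(specimen = "s", element = "m1", observer = "o",
                          section = c(1, 1), count = c(3, 4)), "duplicate")
  tab <- make_table(specimen = "s", element = c("m1", "m2"), observer = "o",
                    section = 1, count = c(3, 4))
  expect_s3_class(tab, "increment_table")
})

test_that("observer final counts take the maximum over sections", {
  tab <- make_table(specimen = "s1", element = "m2", observer = "o1",
                    section = 1:3, count = c(3, 4, 4))
  expect_equal(observer_final_count(tab, "s1", "o1"), 4)
  single <- make_table(specimen = "s1", element = "m2", observer = "o1",
                       section = 1, count = 7)
  expect_equal(observer_final_count(single, "s1", "o1"), 7)
  expect_error(observer_final_count(tab, "s1", "oX"), "no records")
})

test_that("taxon lifespan aggregates consensus across observers and specimens", {
  tab <- make_table(
    specimen = rep(c("s1", "s2"), each = 6),
    element = "m2",
    observer = rep(rep(c("o1", "o2", "o3"), each = 2), 2),
    section = rep(1:2, 6),
    count = c(5, 6, 6, 6, 4, 5,   8, 9, 9, 9, 7, 8))
  # s1 finals: 6,6,5 -> median 6; s2 finals: 9,9,8 -> median 9
  cons <- specimen_consensus(tab)
  expect_equal(sort(unique(cons$consensus)), c(6, 9))
  expect_equal(taxon_max_lifespan(tab), 9)
  expect_equal(taxon_max_lifespan(tab, consensus = "max"), 9)
  expect_equal(taxon_max_lifespan(tab, consensus = "min"), 8)

  # all observers agreeing everywhere reduces to the plain maximum
  agree <- make_table(specimen = rep(c("x", "y"), each = 3), element = "m1",
                      observer = rep(c("o1", "o2", "o3"), 2), section = 1,
                      count = c(4, 4, 4, 11, 11, 11))
  expect_equal(taxon_max_lifespan(agree), 11)

  # even observer count: median ties round half up
  even <- make_table(specimen = "s", element = "m1",
                     observer = c("o1", "o2"), section = 1, count = c(4, 5))
  expect_equal(taxon_max_lifespan(even), 5)
})

test_that("adding a specimen never decreases the lifespan estimate", {
  set.seed(31)
  base <- as.data.frame(simulate_increment_table(sim_config(), 2:9))
  est0 <- taxon_max_lifespan(increment_table(base))
  extra <- data.frame(specimen = "Z", element = "m2", observer = "o1",
                      section = 1, count = sample(1:20, 1))
  est1 <- taxon_max_lifespan(increment_table(rbind(base, extra)))
  expect_gte(est1, est0)
})

test_that("CV uses the sample standard deviation", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(4, 5)), 15.71348, tolerance = 1e-6)
  # two-value sample sd is |diff|/sqrt(2); this underpins the fossil CVs
  expect_equal(sd(c(9.32, 4.89)), abs(9.32 - 4.89) / sqrt(2), tolerance = 1e-12)
  expect_error(cv(3), "at least 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("one-way ANOVA summary path reconstructs the raw computation", {
  raw <- list(g1 = c(4.1, 5.3, 6.2, 5.5), g2 = c(7.9, 8.2, 9.1),
              g3 = c(3.3, 4.4, 5.1, 4.2, 3.9))
  a_raw <- one_way_anova(raw)
  summ <- data.frame(n = lengths(raw),
                     mean = vapply(raw, mean, numeric(1)),
                     sd = vapply(raw, sd, numeric(1)))
  a_sum <- one_way_anova(summ)
  expect_equal(a_sum$F, a_raw$F, tolerance = 1e-10)
  expect_equal(a_sum$df, a_raw$df)
  expect_equal(a_sum$p, a_raw$p, tolerance = 1e-10)

  ident <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_error(one_way_anova(list(1, 2)), "within-group")
  expect_error(one_way_anova(list(1:3)), "at least 2 groups")
})

test_that("Cohen's d pools variances unweighted", {
  expect_equal(cohens_d(5, 1, 5, 2), 0)
  expect_equal(cohens_d(3, 2, 7, 2), 2)  # equal sds reduce to |diff|/sd
  expect_equal(round(cohens_d(7.105, 3.132, 21.8, 5.87), 2), 3.12)
  expect_error(cohens_d(1, 0, 2, 0), "zero pooled")
})

test_that("agreement statistics summarize observer precision", {
  set.seed(32)
  tab <- simulate_increment_table(sim_config(p_miss = 0.15, p_accessory = 0.05),
                                  rep(c(6, 10, 14), each = 4))
  ag <- agreement_stats(tab)
  expect_equal(nrow(ag$per_specimen), 12)
  expect_true(all(ag$per_specimen$cv_inter >= 0, na.rm = TRUE))
  expect_equal(unname(ag$summary["cv_inter", "n"]), 12)
  expect_true(is.finite(ag$shapiro["cv_inter", "W"]))
  expect_true(ag$shapiro["cv_inter", "W"] > 0 &&
                ag$shapiro["cv_inter", "W"] <= 1)

  # fewer than 3 specimens: normality not computable, reported as NA
  two <- simulate_increment_table(sim_config(p_miss = 0.2, seed = 33), c(5, 9))
  expect_true(is.na(agreement_stats(two)$shapiro["cv_inter", "W"]))
})

test_that("sum-slices z-projection matches the per-pixel loop oracle", {
  ones <- array(1, dim = c(4, 5, 12))
  expect_equal(zproject_sum(ones, 1, 10), matrix(10, 4, 5))

  set.seed(34)
  a <- array(runif(4 * 5 * 12), dim = c(4, 5, 12))
  b <- array(runif(4 * 5 * 12), dim = c(4, 5, 12))
  # linearity
  expect_equal(zproject_sum(a, 2, 6) + zproject_sum(b, 2, 6),
               zproject_sum(a + b, 2, 6), tolerance = 1e-12)
  # brute-force loop
  oracle <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) for (k in 3:9) oracle[i, j] <- oracle[i, j] + a[i, j, k]
  expect_equal(zproject_sum(a, 3, 7), oracle, tolerance = 1e-12)
  expect_error(zproject_sum(a, 5, 10), "out of bounds")
  expect_error(zproject_sum(matrix(1, 2, 2)), "3-D")
})
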
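test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_tips = 1), "n_tips")
  expect_error(sim_config(lambda = 1.5), "lambda")
  expect_error(sim_config(sigma = -1), "sd")
  expect_error(sim_config(p_miss = 2), "p_miss")
  expect_error(simulate_increment_table(sim_config(), integer(0)), "non-empty")
  expect_error(simulate_increment_table(sim_config(), c(3, 0)), ">= 1")
})

test_that("identical seeds give bit-identical outputs", {
  cfg <- sim_config(n_tips = 50, seed = 1)
  t1 <- simulate_tree(cfg); t2 <- simulate_tree(cfg)
  expect_identical(write_newick(t1), write_newick(t2))
  tr1 <- simulate_traits(t1, cfg); tr2 <- simulate_traits(t2, cfg)
  expect_identical(tr1, tr2)
  i1 <- simulate_increment_table(cfg, 1:10)
  i2 <- simulate_increment_table(cfg, 1:10)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
})

test_that("simulated trees are binary, ultrametric, at the requested height", {
  tiny <- simulate_tree(sim_config(n_tips = 2, tree_height = 5, seed = 3))
  expect_equal(ape::Ntip(tiny), 2)
  expect_equal(unname(tip_depths(tiny)), c(5, 5), tolerance = 1e-9)

  big <- simulate_tree(sim_config(n_tips = 100, seed = 4))
  expect_equal(ape::Ntip(big), 100)
  d <- tip_depths(big)
  expect_lt(max(d) - min(d), 1e-9 * max(d))
  expect_true(ape::is.binary(big))
})

test_that("noise-free traits collapse exactly onto the generating lines", {
  cfg <- sim_config(n_tips = 30, sigma = 0, mssmr_sigma = 0, k_sigma = 0,
                    seed = 5)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  for (cl in levels(tt$clade)) {
    sub <- tt[tt$clade == cl, ]
    if (nrow(sub) < 2) next
    co <- coef(lm(log_lifespan ~ log_mass, data = sub))
    expect_equal(unname(co[2]), 0.26, tolerance = 1e-10)
    expect_equal(unname(co[1]), unname(cfg$intercepts[cl]), tolerance = 1e-10)
  }
  # downstream traits are exact linear functions of log lifespan
  expect_equal(tt$log_mssmr, cfg$mssmr_intercept + cfg$mssmr_slope * tt$log_lifespan,
               tolerance = 1e-10)
  expect_equal(tt$log_k, cfg$k_intercept + cfg$k_slope * tt$log_lifespan,
               tolerance = 1e-10)
})

test_that("lambda controls phylogenetic correlation of trait residuals", {
  # fixed balanced tree: two deep clades, shallow sister pairs inside
  tr <- read_newick(paste0(
    "(((a1:10,a2:10):90,(a3:10,a4:10):90):100,",
    "((b1:10,b2:10):90,(b3:10,b4:10):90):100);"))
  resid_of <- function(cfg) {
    tt <- simulate_traits(tr, cfg)
    r <- tt$log_lifespan - (cfg$intercepts[tt$clade] + cfg$slope * tt$log_mass)
    stats::setNames(r, tt$species)
  }
  set.seed(8)
  n_rep <- 300
  r0 <- t(replicate(n_rep, resid_of(sim_config(n_tips = 8, lambda = 0))))
  r1 <- t(replicate(n_rep, resid_of(sim_config(n_tips = 8, lambda = 1))))

  # lambda = 0: sister-pair residuals uncorrelated across replicates
  sister0 <- cor(r0[, "a1"], r0[, "a2"])
  expect_lt(abs(sister0), 0.15)
  expect_lt(abs(cor(r0[, "b1"], r0[, "b2"])), 0.15)

  # lambda = 1: within-clade correlation exceeds between-clade
  within1 <- cor(r1[, "a1"], r1[, "a3"])
  between1 <- cor(r1[, "a1"], r1[, "b1"])
  expect_gt(within1, between1)
  expect_gt(cor(r1[, "a1"], r1[, "a2"]), 0.5)
})

test_that("increment tables reflect the miss/accessory noise model", {
  clean <- sim_config(p_miss = 0, p_accessory = 0, seed = 9)
  tab <- simulate_increment_table(clean, c(4, 7, 12))
  truth <- attr(tab, "truth")
  for (i in seq_len(nrow(truth))) {
    counts <- tab$count[tab$specimen == truth$specimen[i]]
    expect_true(all(counts == truth$true_age[i]))
  }
  ag <- agreement_stats(tab)
  expect_true(all(ag$per_specimen$cv_inter == 0))

  # misses only: observer finals can never exceed the true age
  missy <- sim_config(p_miss = 0.2, p_accessory = 0, seed = 10)
  tab2 <- simulate_increment_table(missy, rep(14, 20))
  cons <- specimen_consensus(tab2)
  expect_true(all(cons$final <= 14))
  expect_true(all(tab2$count >= 1))
})

test_that("maximum lifespan is recovered from noisy tables at low miss rates", {
  set.seed(11)
  ages <- rep_len(1:15, 30)
  hits <- vapply(1:200, function(i) {
    tab <- simulate_increment_table(sim_config(p_miss = 0.1, p_accessory = 0),
                                    ages)
    taxon_max_lifespan(tab) == max(ages)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("simulation bundles round-trip through disk", {
  cfg <- sim_config(n_tips = 10, seed = 12)
  tr <- simulate_tree(cfg)
  tt <- simulate_traits(tr, cfg)
  inc <- simulate_increment_table(cfg, c(3, 9))
  dir <- tempfile("simout")
  paths <- write_simulation(dir, tree = tr, traits = tt, increments = inc)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "traits.csv",
                                               "increments.csv",
                                               "increments_truth.csv")))))
  back <- read_increment_table(file.path(dir, "increments.csv"))
  expect_equal(nrow(back), nrow(inc))
  expect_equal(ape::Ntip(read_newick(file = file.path(dir, "tree.nwk"))), 10)
})
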
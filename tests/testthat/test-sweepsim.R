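cfg_small <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275)

test_that("configuration validates its inputs and encodes the priors", {
  cfg <- sim_config()
  expect_equal(cfg$alpha_range, c(250, 2500))
  expect_equal(sim_config(scenario = "weak")$alpha_range, c(25, 250))
  expect_equal(sim_config(scenario = "strong")$alpha_range, c(2500, 25000))
  expect_equal(cfg$tau_range, c(0, 0.025))
  expect_equal(cfg$f_range, c(0, 0.2))
  expect_equal(sim_config(demography = growth_demography())$tau_range, c(0, 0.0004))
  expect_error(sim_config(n_chrom = 59), "even")
  expect_error(sim_config(n_chrom = 400, N = 100), "exceeds")
  expect_error(growth_demography(fold_change = 0.5), "fold_change")
  expect_error(growth_demography(duration = -1), "duration")
})

test_that("sweep models place hard/soft centrally and linked classes in flanks", {
  cfg <- sim_config()
  set.seed(71)
  expect_equal(draw_sweep_model("hard", cfg)$sweep_win, 6L)
  expect_equal(draw_sweep_model("soft", cfg)$sweep_win, 6L)
  expect_true(is.na(draw_sweep_model("neutral", cfg)$sweep_win))
  draws <- replicate(2000, draw_sweep_model("linkedHard", cfg)$sweep_win)
  expect_false(any(draws == 6L))
  tab <- table(factor(draws, levels = setdiff(1:11, 6)))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)  # uniform over the 10 flanks
  m <- draw_sweep_model("soft", cfg)
  expect_true(m$f0 > 0 && m$f0 <= 0.2)
  expect_true(m$alpha >= 250 && m$alpha <= 2500)
})

test_that("neutral replicates match the Watterson expectation for S", {
  set.seed(72)
  n_rep <- 30
  s_obs <- replicate(n_rep, simulate_replicate("neutral", cfg_small)$segsites)
  n <- cfg_small$n_chrom
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  expected <- cfg_small$theta * a1
  sd_s <- sqrt(a1 * cfg_small$theta + a2 * cfg_small$theta^2)
  se_mean <- sd_s / sqrt(n_rep)
  # mean S within 3 standard errors plus a finite-sites allowance
  expect_lt(abs(mean(s_obs) - expected), 3 * se_mean + 0.05 * expected)
})

test_that("neutral diversity is close to theta on average", {
  set.seed(73)
  pis <- replicate(25, theta_pi(diploidize(simulate_replicate("neutral", cfg_small))))
  expect_gt(mean(pis), 0.6 * cfg_small$theta)
  expect_lt(mean(pis), 1.4 * cfg_small$theta)
})

test_that("fresh hard sweeps carve a diversity valley at the center", {
  cfg <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275,
                    alpha_range = c(1000, 2500), tau_range = c(0, 0))
  set.seed(74)
  lay <- make_layout(c(0, 1), 11)
  pis <- t(replicate(40, {
    g <- diploidize(simulate_replicate("hard", cfg))
    compute_profile(g, lay)["pi", ]
  }))
  central <- colMeans(pis)[6]
  flank <- mean(colMeans(pis)[c(1, 2, 10, 11)])
  expect_lt(central, 0.5 * flank)
  # central subwindow carries the minimum mean diversity
  expect_equal(which.min(colMeans(pis)), 6L, ignore_attr = TRUE)
})

test_that("linked sweeps put the diversity minimum at the selected subwindow", {
  cfg <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275,
                    alpha_range = c(1000, 2500), tau_range = c(0, 0))
  set.seed(75)
  lay <- make_layout(c(0, 1), 11)
  for (win in c(2L, 9L)) {
    pis <- t(replicate(25, {
      m <- draw_sweep_model("linkedHard", cfg, sweep_win = win)
      g <- diploidize(simulate_replicate(m, cfg))
      compute_profile(g, lay)["pi", ]
    }))
    expect_equal(which.min(colMeans(pis)), win, ignore_attr = TRUE)
  }
})

test_that("soft sweeps retain more diplotype diversity at the center than hard sweeps", {
  cfg <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275,
                    alpha_range = c(1000, 2500), tau_range = c(0, 0),
                    f_range = c(0.1, 0.2))
  set.seed(76)
  lay <- make_layout(c(0, 1), 11)
  central_ndip <- function(lab) {
    mean(replicate(25, {
      g <- diploidize(simulate_replicate(lab, cfg))
      compute_profile(g, lay)["nDiplos", 6]
    }))
  }
  expect_gt(central_ndip("soft"), central_ndip("hard"))
})

test_that("a fixed seed reproduces the training set bit for bit", {
  set.seed(77)
  ts1 <- build_training_set(cfg_small, n_per_class = 3, n_test_per_class = 2)
  set.seed(77)
  ts2 <- build_training_set(cfg_small, n_per_class = 3, n_test_per_class = 2)
  expect_identical(ts1, ts2)
})

test_that("training sets are balanced with disjoint train/test splits", {
  set.seed(78)
  ts <- build_training_set(cfg_small, n_per_class = 10, n_test_per_class = 4)
  expect_equal(nrow(ts), 70L)
  expect_true(all(table(ts$label[ts$set == "train"]) == 10))
  expect_true(all(table(ts$label[ts$set == "test"]) == 4))
  expect_equal(ncol(ts[grep("_win[0-9]+$", names(ts))]), 132L)
})

test_that("30-fold growth skews the frequency spectrum toward rare variants", {
  cfg_const <- cfg_small
  cfg_growth <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275,
                           demography = growth_demography(fold_change = 30,
                                                          duration = 0.05))
  set.seed(79)
  d_const <- mean(replicate(20, tajimas_d(diploidize(
    simulate_replicate("neutral", cfg_const)))))
  d_growth <- mean(replicate(20, tajimas_d(diploidize(
    simulate_replicate("neutral", cfg_growth)))))
  expect_lt(d_growth, d_const)
  expect_lt(d_growth, 0)
})

test_that("fold_change 1 reduces to the constant-size model", {
  cfg_g1 <- sim_config(n_chrom = 20, N = 60, L = 1100, theta = 55, rho = 275,
                       demography = growth_demography(fold_change = 1,
                                                      duration = 0.05))
  set.seed(80)
  r <- simulate_replicate("neutral", cfg_g1)
  expect_gt(r$segsites, 0)
  # same population size throughout; S should sit near the Watterson mean
  n <- 20
  a1 <- sum(1 / seq_len(n - 1))
  expect_lt(abs(r$segsites - 55 * a1), 4 * sqrt(a1 * 55 + sum(1/seq_len(n-1)^2) * 55^2))
})

test_that("simulated replicates read back through the ms dialect unchanged", {
  set.seed(81)
  r <- simulate_replicate("hard", cfg_small)
  f <- withr::local_tempfile(fileext = ".ms")
  write_ms_replicates(list(r), f)
  back <- read_ms_replicates(f)[[1]]
  expect_equal(back$haplotypes, r$haplotypes, ignore_attr = TRUE)
  expect_equal(back$positions, r$positions, tolerance = 1e-5)
})
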
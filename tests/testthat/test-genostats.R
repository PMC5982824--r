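test_that("pi matches the pairwise-difference definition", {
  # one site, genotypes (0, 2): 4 implied chromosomes, alt count 2 ->
  # brute force over the 6 chromosome pairs: 4 differing pairs -> 2/3... but
  # per-site formula 2*2*2/(4*3) = 2/3; frozen from oracle_pi
  g <- matrix(c(0L, 2L), 2, 1)
  expect_equal(theta_pi(g), 2 / 3)
  expect_equal(theta_pi(g), oracle_pi(g))

  mono <- matrix(2L, 4, 6)
  expect_equal(theta_pi(mono), 0)

  set.seed(41)
  for (i in 1:10) {
    g <- random_geno(sample(2:8, 1), sample(1:20, 1))
    expect_equal(theta_pi(g), oracle_pi(g))
  }
})

test_that("pi and thetaW are preserved by diploidization", {
  set.seed(42)
  for (i in 1:8) {
    rep <- random_replicate(sample(c(6, 10, 16), 1), sample(4:20, 1))
    h <- rep$haplotypes
    nc <- nrow(h)
    cnt <- colSums(h)
    pi_hap <- sum(2 * cnt * (nc - cnt) / (nc * (nc - 1)))
    s_hap <- sum(cnt > 0 & cnt < nc)
    tw_hap <- s_hap / sum(1 / seq_len(nc - 1))
    g <- diploidize(rep)
    expect_equal(theta_pi(g), pi_hap)
    expect_equal(theta_w(g), tw_hap)
  }
})

test_that("thetaW follows the harmonic-number scaling", {
  g <- matrix(c(0L, 1L), 2, 1)  # S = 1, 4 chromosomes
  expect_equal(theta_w(g), 1 / (1 + 1/2 + 1/3))
  expect_equal(theta_w(matrix(0L, 3, 4)), 0)
  g2 <- matrix(1L, 1, 11)  # single diploid het at 11 sites: Nc = 2, a1 = 1
  expect_equal(theta_w(g2), 11)
})

test_that("Tajima's D matches a textbook implementation and has sane conventions", {
  expect_equal(tajimas_d(matrix(0L, 5, 4)), 0)  # S = 0 convention
  set.seed(43)
  for (i in 1:12) {
    g <- random_geno(sample(3:8, 1), sample(2:20, 1))
    expect_equal(tajimas_d(g), oracle_tajd(g), tolerance = 1e-12)
  }
})

test_that("genotype distances count mismatching sites", {
  g <- rbind(c(0L, 1L, 2L), c(0L, 2L, 2L))
  expect_equal(genotype_distances(g)$values, 1)
  gid <- rbind(c(1L, 0L, 2L), c(1L, 0L, 2L))
  expect_equal(genotype_distances(gid)$values, 0)
  gc <- rbind(c(0L, 0L, 1L, 2L), c(2L, 1L, 0L, 0L))
  expect_equal(genotype_distances(gc)$values, 4)
  expect_error(genotype_distances(matrix(0L, 1, 3)), "2 individuals")
})

test_that("the g matrix is a metric core: symmetric, zero diagonal, triangle inequality", {
  set.seed(44)
  for (i in 1:6) {
    g <- random_geno(sample(4:7, 1), sample(3:15, 1))
    d <- genotype_distances(g)$matrix
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    n <- nrow(d)
    for (a in 1:n) for (b in 1:n) for (c in 1:n) {
      expect_lte(d[a, c], d[a, b] + d[b, c])
    }
  }
})

test_that("gkl moments use population central moments with the constant convention", {
  expect_equal(gkl_moments(c(0, 0, 0)),
               c(variance = 0, skewness = 0, kurtosis = 0))
  expect_equal(gkl_moments(c(1, 2, 3)),
               c(variance = 2/3, skewness = 0, kurtosis = 1.5))
  sym <- c(1, 2, 2, 3, 3, 3, 4, 4, 5)
  expect_equal(unname(gkl_moments(sym)["skewness"]), 0)
  expect_error(gkl_moments(numeric(0)), "empty")
  set.seed(45)
  x <- rpois(20, 4)
  expect_equal(unname(gkl_moments(x)), oracle_moments(x), tolerance = 1e-12)
})

test_that("diplotype spectrum computes J1, J12, J2/J1", {
  # frequencies (1/2, 1/4, 1/4)
  g <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 0L), c(2L, 2L))
  ds <- diplotype_spectrum(g)
  expect_equal(ds$n_diplos, 3L)
  expect_equal(ds$J1, 0.375)
  expect_equal(ds$J12, 0.625)
  expect_equal(ds$J2J1, 1/3)

  same <- matrix(1L, 5, 3)
  ds2 <- diplotype_spectrum(same)
  expect_equal(ds2$n_diplos, 1L)
  expect_equal(ds2$J1, 1)
  expect_equal(ds2$J12, 1)
  expect_equal(ds2$J2J1, 0)

  distinct <- diag(2L, 4)
  ds3 <- diplotype_spectrum(distinct)
  expect_equal(ds3$n_diplos, 4L)
  expect_equal(ds3$J1, 1/4)
})

test_that("J12 >= J1 over random matrices", {
  set.seed(46)
  for (i in 1:20) {
    ds <- diplotype_spectrum(random_geno(sample(2:10, 1), sample(1:8, 1)))
    expect_gte(ds$J12, ds$J1)
    expect_gte(ds$J1, 0)
    expect_lte(ds$J1, 1)
    expect_gte(ds$J2J1, 0)
    expect_lt(ds$J2J1, 1)
  }
})

test_that("genotypic r2 is the squared Pearson correlation of genotype columns", {
  g <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  expect_equal(genotypic_r2(g, 1, 2), 1)
  g2 <- cbind(c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L))
  expect_equal(genotypic_r2(g2, 1, 2), 1)
  set.seed(47)
  for (i in 1:10) {
    g <- random_geno(sample(4:10, 1), 2, p_na = 0.1)
    expect_equal(genotypic_r2(g, 1, 2), oracle_r2(g[, 1], g[, 2]))
  }
})

test_that("ZnS averages retained pairs and degrades gracefully", {
  g <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  expect_equal(zns(g), 1)
  expect_equal(zns(cbind(c(0L, 1L, 2L))), 0)  # single site
  set.seed(48)
  for (i in 1:8) {
    g <- random_geno(sample(4:8, 1), sample(2:12, 1), p_na = 0.05)
    expect_equal(zns(g), oracle_zns(g))
  }
})

test_that("independent sites give small ZnS (r2 bias ~ 1/(n-1))", {
  set.seed(49)
  vals <- replicate(30, {
    g <- matrix(sample(0:2, 40 * 8, TRUE), 40, 8)
    zns(g)
  })
  expect_lt(mean(vals), 3 / 39)  # well below linkage, allowing sampling bias
})

test_that("omega-max matches split enumeration and respects the site floor", {
  expect_equal(omega_max(random_geno(6, 0)), 0)
  set.seed(50)
  g5 <- matrix(sample(0:1, 8 * 5, TRUE), 8, 5) * 2L
  expect_equal(omega_max(g5), 0)  # S = 5 < 6
  for (i in 1:8) {
    g <- random_geno(sample(5:9, 1), sample(6:14, 1))
    expect_equal(omega_max(g), oracle_omega(g), tolerance = 1e-10)
  }
})

test_that("two tight blocks with zero between-block LD maximize omega over valid splits", {
  # left block: 3 perfectly associated sites; right block: 3 perfectly
  # associated sites; between-block pairs uncorrelated by construction
  set.seed(51)
  a <- sample(0:2, 24, TRUE)
  b <- sample(0:2, 24, TRUE)
  g <- cbind(a, a, a, b, b, b)
  storage.mode(g) <- "integer"
  # at the true boundary the between sum is 0 -> that split is skipped;
  # the result comes from the remaining splits and is finite and >= 0
  om <- omega_max(g)
  expect_true(is.finite(om))
  expect_gte(om, 0)
})

test_that("all statistics are invariant to individual permutation; site order matters only for omega", {
  set.seed(52)
  g <- random_geno(8, 14)
  geno <- genotype_matrix(g, sort(runif(14)), span = c(0, 1))
  perm <- sample(8)
  gp <- genotype_matrix(g[perm, ], geno$positions, span = c(0, 1))
  expect_equal(window_stats(geno), window_stats(gp))

  sperm <- sample(14)
  gs <- g[, sperm]
  stats_orig <- window_stats(genotype_matrix(g, sort(runif(14)), c(0, 1)))
  stats_shuf <- window_stats(genotype_matrix(gs, sort(runif(14)), c(0, 1)))
  keep <- setdiff(stat_names(), "omegaMax")
  expect_equal(stats_orig[keep], stats_shuf[keep])
})

test_that("every statistic returns its degenerate value on an empty window", {
  empty <- genotype_matrix(matrix(integer(0), nrow = 4, ncol = 0), numeric(0),
                           span = c(0, 1))
  st <- window_stats(empty)
  expect_true(all(is.finite(st)))
  expect_equal(unname(st["pi"]), 0)
  expect_equal(unname(st["tajD"]), 0)
  expect_equal(unname(st["ZnS"]), 0)
  expect_equal(unname(st["omegaMax"]), 0)
  expect_equal(unname(st["nDiplos"]), 1)  # all individuals share the empty genotype
})

test_that("the compiled profile path agrees with the per-window R functions", {
  set.seed(53)
  for (i in 1:10) {
    n <- sample(3:9, 1); m <- sample(6:30, 1)
    g <- random_geno(n, m, p_na = ifelse(i %% 2, 0, 0.1))
    geno <- genotype_matrix(g, sort(runif(m)), span = c(0, 1))
    lay <- make_layout(c(0, 1), 5)
    expect_equal(unclass(compute_profile(geno, lay)),
                 unclass(sweepimage:::compute_profile_r(geno, lay)),
                 tolerance = 1e-10)
  }
})
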
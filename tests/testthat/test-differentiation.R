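two_pop_fixture <- function(a1, a2, n_per, marker = "snp") {
  rownames(a1) <- rownames(a2) <- sprintf("i%02d", seq_len(nrow(a1)))
  g <- genotype_matrix(a1, a2, marker)
  ids <- sprintf("pop%d", seq_along(n_per))
  locs <- locality_set(
    data.frame(id = ids, lat = 51 + seq_along(n_per), lon = 9),
    setNames(rep(ids, n_per), g$ind))
  list(g = g, locs = locs)
}

test_that("theta = 1 for populations fixed for alternate alleles", {
  a1 <- matrix(c(rep(0L, 10), rep(1L, 10)), ncol = 1)
  fx <- two_pop_fixture(a1, a1, c(10, 10))
  expect_equal(wc_fst_pair(fx$g, fx$locs, "pop1", "pop2")$theta, 1)
})

test_that("theta is near zero for a panmictic population split at random", {
  set.seed(3)
  reps <- vapply(1:20, function(r) {
    n <- 40; L <- 60
    p <- runif(L, 0.2, 0.8)
    a1 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
    a2 <- matrix(rbinom(n * L, 1, rep(p, each = n)), n, L)
    fx <- two_pop_fixture(a1, a2, c(20, 20))
    wc_fst_pair(fx$g, fx$locs, "pop1", "pop2")$theta
  }, 0)
  expect_lt(abs(mean(reps)), 0.01)      # unbiasedness across replicates
})

test_that("variance components equal the literal-formula oracle", {
  # 2 pops x 3 individuals x 2 loci worked toy, plus random SNP/msat toys
  a1 <- matrix(c(0L, 0L, 1L, 1L, 1L, 0L,
                 0L, 1L, 1L, 0L, 0L, 0L), 6, 2)
  a2 <- matrix(c(0L, 1L, 1L, 1L, 1L, 1L,
                 1L, 1L, 1L, 0L, 1L, 0L), 6, 2)
  fx <- two_pop_fixture(a1, a2, c(3, 3))
  got <- wc_fst_pair(fx$g, fx$locs, "pop1", "pop2")
  expect_equal(got$theta, oracle_wc_theta(fx$g, fx$locs, c("pop1", "pop2")),
               tolerance = 1e-12)

  for (seed in 1:3) {
    toy <- toy_dataset(c(4, 5, 3), n_loci = 5, seed = seed)
    toy$g$a1[2, 1] <- toy$g$a2[2, 1] <- NA_integer_
    ids <- locality_ids(toy$locs)
    got <- wc_fst(toy$g, toy$locs)$theta
    expect_equal(got, oracle_wc_theta(toy$g, toy$locs, ids),
                 tolerance = 1e-10)
    ms <- toy_dataset(c(5, 4), n_loci = 4, seed = seed + 10,
                      marker = "microsatellite")
    got_ms <- wc_fst(ms$g, ms$locs)$theta
    expect_equal(got_ms,
                 oracle_wc_theta(ms$g, ms$locs, locality_ids(ms$locs)),
                 tolerance = 1e-10)
  }
})

test_that("theta is undefined with reason when no locus is shared", {
  a1 <- matrix(c(0L, NA, NA, 1L), 2, 2)
  rownames(a1) <- c("i1", "i2"); colnames(a1) <- c("L1", "L2")
  g <- genotype_matrix(a1, a1, "snp")
  locs <- locality_set(data.frame(id = c("A", "B"), lat = 51:52, lon = 9),
                       c(i1 = "A", i2 = "B"))
  expect_error(wc_fst(g, locs), "undefined")
})

test_that("fst matrix is symmetric with zero diagonal and valid CIs", {
  cfg <- sim_config(n_pops = 4, n_per_pop = 15, n_snps = 300,
                    fst_target = 0.1, seed = 2)
  sim <- simulate_neutral(cfg)
  fm <- fst_matrix(sim$genotypes, sim$localities, n_boot = 50, seed = 1)
  expect_equal(fm$theta, t(fm$theta))
  expect_equal(unname(diag(fm$theta)), rep(0, 4))
  off <- upper.tri(fm$theta)
  expect_true(all(fm$lower[off] <= fm$theta[off] + 1e-9))
  expect_true(all(fm$upper[off] >= fm$theta[off] - 1e-9))
  expect_lt(abs(mean(fm$theta[off]) - 0.1), 0.03)
  # deterministic under seed
  fm2 <- fst_matrix(sim$genotypes, sim$localities, n_boot = 50, seed = 1)
  expect_identical(fm$lower, fm2$lower)
})

test_that("Rousset linearisation maps known values and is monotone", {
  m <- matrix(c(0, 0, 0.5, 0, 0, 1, 0.5, 1, 0), 3, 3)
  out <- rousset_linearise(m)
  expect_equal(out[1, 2], 0)
  expect_equal(out[1, 3], 1)
  expect_equal(out[2, 3], 1e6)          # capped sentinel at theta = 1
  th <- seq(-0.9, 0.9, by = 0.1)
  lin <- th / (1 - th)
  expect_true(all(diff(lin) > 0))
  neg <- matrix(c(0, -0.02, -0.02, 0), 2, 2)
  expect_equal(rousset_linearise(neg)[1, 2], -0.02 / 1.02)
  expect_equal(rousset_linearise(neg, floor_negative = TRUE)[1, 2], 0)
})

test_that("geographic distances obey metric basics", {
  locs <- locality_set(
    data.frame(id = c("a", "b", "c"), lat = c(51, 52, 51.5),
               lon = c(9, 9, 10)),
    c(x = "a"))
  d_deg <- geo_distances(locs, "euclidean_deg")
  expect_equal(unname(diag(d_deg)), rep(0, 3))
  expect_equal(d_deg["a", "b"], 1)      # one degree of latitude
  d_km <- geo_distances(locs, "great_circle_km")
  expect_equal(d_km["a", "b"], 111.2, tolerance = 0.005)
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(d_km[i, j], d_km[i, k] + d_km[k, j] + 1e-9)
})

test_that("Mantel statistic and exact p match enumeration", {
  set.seed(5)
  xy <- matrix(rnorm(8), 4, 2)
  d1 <- as.matrix(dist(xy))
  expect_equal(mantel_test(d1, d1, n_perm = 99)$r, 1)

  d2 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  got <- mantel_test(d1, d2, exact = TRUE)
  ref <- oracle_mantel_exact(d1, d2)
  expect_equal(got$r, ref$r, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)
  expect_equal(got$n_perm, 24)
})

test_that("Mantel r agrees with the vegan implementation", {
  set.seed(6)
  d1 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  d2 <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  got <- mantel_test(d1, d2, n_perm = 999, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(got$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(got$p - ref$signif), 0.12)
})

test_that("Mantel null p-values are roughly uniform", {
  set.seed(7)
  ps <- vapply(1:40, function(r) {
    d1 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    d2 <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
    mantel_test(d1, d2, n_perm = 199, seed = r)$p
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lt(mean(ps < 0.05), 0.2)
})
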
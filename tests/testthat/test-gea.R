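gea_toy <- function(n_pops = 6, n_per = 8, L = 60, seed = 50, beta = 0,
                    n_adaptive = 0, fst = 0.05) {
  cfg <- sim_config(n_pops = n_pops, n_per_pop = n_per, n_snps = L,
                    n_adaptive = n_adaptive, beta = beta,
                    fst_target = fst, missing_rate = 0, seed = seed)
  plant_adaptive_loci(cfg, simulate_neutral(cfg))
}

test_that("VIFs are unity for orthogonal predictors, duplicates dropped", {
  env <- env_table(data.frame(locality = letters[1:8],
                              p1 = c(1, -1, 1, -1, 1, -1, 1, -1),
                              p2 = c(1, 1, -1, -1, 1, 1, -1, -1)))
  out <- vif_screen(env, 5)
  expect_equal(unname(out$vif), c(1, 1))
  expect_equal(out$retained, c("p1", "p2"))

  env2 <- env_table(data.frame(locality = letters[1:6],
                               p1 = rnorm(6), p3 = rnorm(6)))
  env2$p2 <- env2$p1                      # exact duplicate
  out2 <- vif_screen(env2, 5)
  expect_equal(length(out2$dropped), 1)
  expect_true(out2$dropped %in% c("p1", "p2"))
})

test_that("VIFs match the direct regression oracle on a 4-predictor toy", {
  set.seed(51)
  n <- 12
  base <- rnorm(n)
  df <- data.frame(locality = sprintf("l%02d", 1:n),
                   q1 = base + rnorm(n, 0, 0.5),
                   q2 = base + rnorm(n, 0, 0.5),
                   q3 = rnorm(n), q4 = rnorm(n))
  env <- env_table(df)
  out <- vif_screen(env, threshold = 1e9)   # no dropping: raw VIFs
  for (j in c("q1", "q2", "q3", "q4")) {
    r2 <- summary(lm(df[[j]] ~ ., data = df[setdiff(names(df),
                                                    c("locality", j))]))$r.squared
    expect_equal(unname(out$vif[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
})

test_that("constrained variance hits 1 when Y = XB and the null band otherwise", {
  sim <- gea_toy(L = 30, seed = 52)
  X <- scale(env_per_individual(sim$env, sim$genotypes, sim$localities))
  set.seed(52)
  B <- matrix(rnorm(ncol(X) * 30), ncol(X), 30)
  o <- oracle_rda(X %*% B, X)            # noise-free: fully constrained
  expect_equal(o$prop, 1, tolerance = 1e-9)

  # genotype rows permuted across individuals (population structure and
  # environment decoupled): E[constrained proportion] ~ P / (n - 1)
  big <- gea_toy(n_pops = 8, n_per = 20, L = 800, seed = 62)
  set.seed(62)
  g0 <- big$genotypes
  perm <- sample.int(n_ind(g0))
  a1 <- g0$a1[perm, ]; a2 <- g0$a2[perm, ]
  rownames(a1) <- rownames(a2) <- g0$ind
  gp <- genotype_matrix(a1, a2, "snp")
  fit <- fit_rda(gp, big$env, big$localities)
  expected <- length(fit$eig) / (n_ind(big$genotypes) - 1)
  expect_gt(fit$prop_constrained, 0.4 * expected)
  expect_lt(fit$prop_constrained, 2.5 * expected)
})

test_that("rda fit equals the literal regression + eigen oracle", {
  for (seed in c(53, 54)) {
    sim <- gea_toy(n_pops = 6, n_per = 3, L = 8, seed = seed)
    fit <- fit_rda(sim$genotypes, sim$env, sim$localities)
    Y <- snp_dosage(sim$genotypes)
    X <- env_per_individual(sim$env, sim$genotypes, sim$localities)
    o <- oracle_rda(Y, X)
    k <- length(fit$eig)
    expect_equal(fit$eig, o$eig[seq_len(k)], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$prop_constrained, o$prop, tolerance = 1e-8)
    for (ax in seq_len(k))
      expect_equal(abs(unname(fit$loadings[, ax])),
                   abs(o$loadings[, ax]), tolerance = 1e-6)
  }
})

test_that("rda eigenvalues agree with vegan's rda", {
  sim <- gea_toy(n_pops = 5, n_per = 6, L = 40, seed = 55)
  fit <- fit_rda(sim$genotypes, sim$env, sim$localities)
  Y <- snp_dosage(sim$genotypes)
  X <- as.data.frame(scale(env_per_individual(sim$env, sim$genotypes,
                                              sim$localities)))
  vfit <- vegan::rda(Y ~ bio5 + bio18 + tri + cti, data = X)
  veig <- unname(vfit$CCA$eig)
  expect_equal(unname(fit$eig), veig[seq_along(fit$eig)],
               tolerance = 1e-8)
  expect_equal(fit$prop_constrained,
               unname(vfit$CCA$tot.chi / vfit$tot.chi), tolerance = 1e-8)
})

test_that("rank-deficient predictor sets are refused by name", {
  sim <- gea_toy(n_pops = 4, n_per = 4, L = 10, seed = 56)
  env <- as.data.frame(sim$env)
  env$dup <- env$bio5
  env <- env_table(env)
  expect_error(fit_rda(sim$genotypes, env, sim$localities),
               "collinear|rank")
})

test_that("candidate detection respects thresholds and truth", {
  sim <- gea_toy(n_pops = 8, n_per = 15, L = 500, n_adaptive = 10,
                 beta = 3, seed = 57)
  fit <- fit_rda(sim$genotypes, sim$env, sim$localities)
  cand <- detect_candidates(fit, sim$genotypes, sd_threshold = 2.5)
  truth <- sim$truth$adaptive
  expect_gt(mean(truth$locus %in% cand$locus), 0.8)
  hit <- cand[cand$locus %in% truth$locus, ]
  agree <- mean(hit$predictor ==
                  truth$predictor[match(hit$locus, truth$locus)])
  expect_gt(agree, 0.7)
  expect_true(all(abs(cand$z) > 2.5))
  none <- detect_candidates(fit, sim$genotypes, sd_threshold = Inf)
  expect_equal(nrow(none), 0)
})

test_that("categorisation thresholds and partitions behave", {
  sim <- gea_toy(n_pops = 6, n_per = 10, L = 300, n_adaptive = 20,
                 beta = 3, seed = 58)
  fit <- fit_rda(sim$genotypes, sim$env, sim$localities)
  cand <- detect_candidates(fit, sim$genotypes)
  calls <- categorise_individuals(sim$genotypes, sim$env, sim$localities,
                                  cand, c("bio5", "bio18"),
                                  threshold_t = Inf)
  expect_true(all(calls$category == "intermediate"))
  expect_equal(nrow(calls), n_ind(sim$genotypes))

  calls2 <- categorise_individuals(sim$genotypes, sim$env, sim$localities,
                                   cand, c("bio5", "bio18"),
                                   threshold_t = 0.5)
  expect_true(all(calls2$category %in% c("warm", "cold", "intermediate")))
  expect_equal(sum(table(calls2$category)), n_ind(sim$genotypes))

  expect_error(categorise_individuals(sim$genotypes, sim$env,
                                      sim$localities, cand[0, ],
                                      c("bio5", "bio18")),
               "fewer than 2")
})

test_that("extreme-temperature demes take opposite adaptive labels", {
  sim <- gea_toy(n_pops = 8, n_per = 15, L = 600, n_adaptive = 30,
                 beta = 3, seed = 59)
  fit <- fit_rda(sim$genotypes, sim$env, sim$localities)
  cand <- detect_candidates(fit, sim$genotypes)
  calls <- categorise_individuals(sim$genotypes, sim$env, sim$localities,
                                  cand, c("bio5", "bio18"),
                                  threshold_t = 0.5)
  bio5 <- sim$env$bio5[match(calls$locality, sim$env$locality)]
  warm_mean <- mean(bio5[calls$category == "warm"])
  cold_mean <- mean(bio5[calls$category == "cold"])
  expect_gt(warm_mean, cold_mean)
  hot <- sim$env$locality[which.max(sim$env$bio5)]
  cold <- sim$env$locality[which.min(sim$env$bio5)]
  maj <- function(loc) {
    tb <- table(calls$category[calls$locality == loc])
    names(tb)[which.max(tb)]
  }
  expect_true(maj(hot) %in% c("warm", "intermediate"))
  expect_true(maj(cold) %in% c("cold", "intermediate"))
  expect_false(identical(maj(hot), "cold"))
  expect_false(identical(maj(cold), "warm"))
})

test_that("locality proportions sum to one and match hand tallies", {
  calls <- data.frame(
    individual = sprintf("i%d", 1:10),
    locality = rep(c("A", "B", "C"), c(5, 4, 1)),
    category = c("warm", "warm", "cold", "intermediate", "warm",
                 "cold", "cold", "cold", "intermediate", "warm"),
    stringsAsFactors = FALSE)
  locs <- locality_set(
    data.frame(id = c("A", "B", "C"), lat = 51:53, lon = 9),
    setNames(calls$locality, calls$individual))
  pr <- locality_proportions(calls, locs)
  expect_equal(rowSums(pr[, -1]), rep(1, 3), ignore_attr = TRUE)
  expect_equal(pr$warm[pr$locality == "A"], 3 / 5)
  expect_equal(pr$cold[pr$locality == "B"], 3 / 4)
  expect_equal(pr$warm[pr$locality == "C"], 1)   # single individual
})
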
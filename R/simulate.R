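#' Simulation configuration
#'
#' Parameters of the island-model genotype simulator used for power
#' analysis and end-to-end testing. Population allele frequencies follow
#' the Balding-Nichols model: for ancestral frequency `p` and target
#' differentiation `F`, each deme draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, and genotypes are
#' `Binomial(2, p_deme)` — Hardy-Weinberg within demes by construction.
#'
#' @param n_pops number of demes.
#' @param n_per_pop individuals per deme; scalar or length-`n_pops`
#'   vector (uneven sampling as in real surveys, 1-35 per locality).
#' @param n_snps number of bi-allelic SNP loci.
#' @param n_adaptive number of environmentally driven ("adaptive") loci
#'   among the SNPs.
#' @param fst_target target multilocus differentiation, in (0, 1).
#' @param beta effect size: shift of the adaptive-locus allele-frequency
#'   logit per standard deviation of the driving predictor.
#' @param adaptive_predictors predictor names that drive adaptive loci,
#'   assigned round-robin; defaults to the primary member of each
#'   predictor pair (`bio5` for climate, `tri` for topography).
#' @param missing_rate fraction of genotypes set missing completely at
#'   random.
#' @param n_msat_loci number of microsatellite loci.
#' @param msat_alleles alleles per microsatellite locus (2-10).
#' @param env_sd_noise standard deviation of the off-gradient noise in
#'   the generated predictors (on the standardised gradient scale).
#' @param seed integer seed; every simulation is deterministic given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 10, n_per_pop = 30, n_snps = 2000,
                       n_adaptive = 0, fst_target = 0.10, beta = 0,
                       adaptive_predictors = c("bio5", "tri"),
                       missing_rate = 0.05, n_msat_loci = 9,
                       msat_alleles = 6, env_sd_noise = 0.5, seed = 1L) {
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  stopifnot(n_pops >= 2, all(n_per_pop >= 1), n_snps >= 1,
            n_adaptive >= 0, n_adaptive <= n_snps,
            missing_rate >= 0, missing_rate < 1,
            msat_alleles >= 2, msat_alleles <= 10)
  if (fst_target <= 0 || fst_target >= 1)
    stop("degenerate config: fst_target must lie strictly in (0, 1)")
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_snps = n_snps,
                 n_adaptive = n_adaptive, fst_target = fst_target,
                 beta = beta, adaptive_predictors = adaptive_predictors,
                 missing_rate = missing_rate, n_msat_loci = n_msat_loci,
                 msat_alleles = msat_alleles, env_sd_noise = env_sd_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Stable per-stage seed derivation
#'
#' Maps a base seed and a stage label to a reproducible 31-bit seed so
#' pipeline stages are individually re-runnable.
#'
#' @param seed integer base seed.
#' @param stage character stage label.
#' @return integer seed below `2^31`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Locality scaffold: a latitudinal gradient with longitudes shuffled so
# the two environmental gradients are close to orthogonal.
sim_localities <- function(cfg) {
  K <- cfg$n_pops
  lat <- seq(50.2, 52.8, length.out = K)
  lon_order <- sample.int(K)           # under caller's seed
  lon <- seq(6.5, 10.8, length.out = K)[lon_order]
  ids <- sprintf("P%02d", seq_len(K))
  ind_ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_i%03d", ids[k], seq_len(cfg$n_per_pop[k]))))
  membership <- stats::setNames(rep(ids, cfg$n_per_pop), ind_ids)
  locality_set(data.frame(id = ids, name = ids, lat = lat, lon = lon,
                          provenance = "autochthonous",
                          stringsAsFactors = FALSE),
               membership)
}

# Two predictor pairs on plausible scales: a climate pair following the
# latitudinal gradient (bio5 degC, bio18 mm) and a topographic pair on
# the orthogonal longitude gradient (tri, cti, unitless).
sim_env <- function(cfg, locs) {
  K <- cfg$n_pops
  z_lat <- as.numeric(scale(locs$localities$lat))
  z_lon <- as.numeric(scale(locs$localities$lon))
  ns <- cfg$env_sd_noise
  env_table(data.frame(
    locality = locality_ids(locs),
    bio5 = 22 + 3 * (-z_lat + stats::rnorm(K, 0, ns)),   # warmer southwards
    bio18 = 220 + 40 * (-0.25 * z_lat + stats::rnorm(K, 0, ns)),
    tri = 5 + 2 * (z_lon + stats::rnorm(K, 0, ns)),
    cti = 8 + 1.5 * (0.25 * z_lon + stats::rnorm(K, 0, ns)),
    stringsAsFactors = FALSE))
}

bn_pop_freqs <- function(p_anc, fst) {
  K <- length(p_anc)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  stats::rbeta(K, a, b)
}

#' Simulate neutral SNP genotypes under the Balding-Nichols island model
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset` with elements `genotypes`
#'   ([genotype_matrix()]), `localities` ([locality_set()]), `env`
#'   ([env_table()]) and `truth` (ancestral and per-deme allele
#'   frequencies, target F_ST, adaptive-locus table — empty here).
#' @export
simulate_neutral <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "neutral"))
  locs <- sim_localities(cfg)
  env <- sim_env(cfg, locs)
  K <- cfg$n_pops; L <- cfg$n_snps
  p_anc <- stats::runif(L, 0.1, 0.9)
  p_pop <- matrix(0, K, L, dimnames = list(locality_ids(locs), NULL))
  for (l in seq_len(L)) p_pop[, l] <- bn_pop_freqs(rep(p_anc[l], K),
                                                   cfg$fst_target)
  g <- draw_genotypes_from_freqs(cfg, locs, p_pop)
  truth <- list(p_anc = p_anc, p_pop = p_pop,
                fst_target = cfg$fst_target,
                adaptive = data.frame(locus = character(0),
                                      predictor = character(0),
                                      stringsAsFactors = FALSE))
  structure(list(genotypes = g, localities = locs, env = env,
                 truth = truth, config = cfg),
            class = "sim_dataset")
}

draw_genotypes_from_freqs <- function(cfg, locs, p_pop) {
  K <- cfg$n_pops; L <- ncol(p_pop); n <- sum(cfg$n_per_pop)
  d <- matrix(0L, n, L)
  row0 <- c(0L, cumsum(cfg$n_per_pop))
  for (k in seq_len(K)) {
    idx <- (row0[k] + 1L):row0[k + 1L]
    d[idx, ] <- matrix(stats::rbinom(length(idx) * L, 2,
                                     rep(p_pop[k, ], each = length(idx))),
                       length(idx), L)
  }
  if (cfg$missing_rate > 0)
    d[stats::runif(length(d)) < cfg$missing_rate] <- NA_integer_
  a1 <- ifelse(d == 2L, 1L, 0L)
  a2 <- ifelse(d >= 1L, 1L, 0L)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  rownames(a1) <- rownames(a2) <- names(locs$membership)
  colnames(a1) <- colnames(a2) <- sprintf("snp%05d", seq_len(L))
  genotype_matrix(a1, a2, "snp")
}

#' Plant environmentally driven loci into a neutral simulation
#'
#' For each adaptive locus the per-deme allele-frequency logit is
#' shifted by `beta` times the standardised value of its driving
#' predictor in that deme, and genotypes at those loci are redrawn.
#' `beta = 0` leaves the data distributionally neutral.
#'
#' @param cfg a [sim_config()] with `n_adaptive > 0` (or 0 for a no-op).
#' @param sim a `sim_dataset` from [simulate_neutral()].
#' @return the modified `sim_dataset`; `truth$adaptive` lists each
#'   adaptive locus id and its driving predictor.
#' @export
plant_adaptive_loci <- function(cfg, sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (cfg$n_adaptive == 0) return(sim)
  set.seed(derive_seed(cfg$seed, "adaptive"))
  g <- sim$genotypes
  L <- n_loci(g)
  adaptive_idx <- sort(sample.int(L, cfg$n_adaptive))
  preds <- rep_len(cfg$adaptive_predictors, cfg$n_adaptive)
  envm <- as.matrix(sim$env[setdiff(names(sim$env), "locality")])
  envz <- scale(envm)
  rownames(envz) <- sim$env$locality
  p_pop <- sim$truth$p_pop
  ids <- rownames(p_pop)
  for (m in seq_along(adaptive_idx)) {
    l <- adaptive_idx[m]
    z <- envz[ids, preds[m]]
    p_pop[, l] <- stats::plogis(stats::qlogis(p_pop[, l]) + cfg$beta * z)
  }
  # redraw genotypes at adaptive loci only, preserving missingness mask
  mask <- is.na(g$a1)
  memb <- sim$localities$membership[g$ind]
  for (m in seq_along(adaptive_idx)) {
    l <- adaptive_idx[m]
    p <- p_pop[memb, l]
    d <- stats::rbinom(n_ind(g), 2, p)
    a1 <- ifelse(d == 2L, 1L, 0L); a2 <- ifelse(d >= 1L, 1L, 0L)
    a1[mask[, l]] <- NA_integer_; a2[mask[, l]] <- NA_integer_
    g$a1[, l] <- as.integer(a1); g$a2[, l] <- as.integer(a2)
  }
  sim$genotypes <- g
  sim$truth$p_pop <- p_pop
  sim$truth$adaptive <- data.frame(
    locus = g$loci$id[adaptive_idx], predictor = preds,
    stringsAsFactors = FALSE)
  sim
}

#' Simulate a multi-allelic microsatellite panel
#'
#' Deme allele frequencies are Dirichlet-distributed around an ancestral
#' Dirichlet draw with concentration `(1 - F) / F`, so differentiation
#' matches the SNP island model; genotypes are two multinomial draws.
#'
#' @param cfg a [sim_config()].
#' @param locs optional [locality_set()] to reuse (so SNP and
#'   microsatellite panels share individuals); defaults to a fresh
#'   scaffold.
#' @return list with `genotypes` ([genotype_matrix()], microsatellite)
#'   and `truth` (per-deme allele frequencies).
#' @export
simulate_microsats <- function(cfg, locs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "msat"))
  if (is.null(locs)) locs <- sim_localities(cfg)
  K <- cfg$n_pops; L <- cfg$n_msat_loci; A <- cfg$msat_alleles
  conc <- (1 - cfg$fst_target) / cfg$fst_target
  alleles <- 100L + 2L * (seq_len(A) - 1L)   # fragment sizes
  n <- length(locs$membership)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  memb <- locs$membership
  truth <- vector("list", L)
  rdirichlet1 <- function(alpha) {
    x <- stats::rgamma(length(alpha), alpha)
    x / sum(x)
  }
  for (l in seq_len(L)) {
    p_anc <- rdirichlet1(rep(1, A))
    p_pop <- t(vapply(seq_len(K),
                      function(k) rdirichlet1(p_anc * conc),
                      numeric(A)))
    rownames(p_pop) <- locality_ids(locs)
    truth[[l]] <- p_pop
    for (k in locality_ids(locs)) {
      idx <- which(memb == k)
      a1[idx, l] <- alleles[sample.int(A, length(idx), replace = TRUE,
                                       prob = p_pop[k, ])]
      a2[idx, l] <- alleles[sample.int(A, length(idx), replace = TRUE,
                                       prob = p_pop[k, ])]
    }
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  rownames(a1) <- rownames(a2) <- names(memb)
  colnames(a1) <- colnames(a2) <- sprintf("msat%02d", seq_len(L))
  list(genotypes = genotype_matrix(a1, a2, "microsatellite"),
       localities = locs, truth = truth)
}

#' One-call simulation of a full study dataset
#'
#' Neutral island-model SNPs, planted adaptive loci and a microsatellite
#' panel over the same localities and individuals.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_dataset` with an extra `msat` element.
#' @export
simulate_dataset <- function(cfg) {
  sim <- plant_adaptive_loci(cfg, simulate_neutral(cfg))
  sim$msat <- simulate_microsats(cfg, sim$localities)$genotypes
  sim
}
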
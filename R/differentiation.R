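#' Weir & Cockerham (1984) variance components and multilocus theta
#'
#' Sample-size-corrected F_ST estimator. Per locus and allele the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) variance components are computed with the
#' n-bar / n_c corrections; the multilocus estimate is the ratio of sums
#' `theta = sum(a) / sum(a + b + c)` over alleles and loci. Missing
#' genotypes are excluded per locus; loci informative in fewer than two
#' populations (or with mean sample size <= 1) are skipped. Small
#' negative estimates are a property of the estimator and are preserved.
#'
#' @param g a [genotype_matrix()].
#' @param locs a [locality_set()].
#' @param localities optional subset of locality ids (default: all with
#'   at least one individual).
#' @return list with `theta` (multilocus), `per_locus` (data.frame of
#'   per-locus `a`, `abc` = a+b+c and `theta`), `n_loci_used`.
#' @export
wc_fst <- function(g, locs, localities = NULL) {
  idx <- locality_indices(g, locs)
  if (is.null(localities))
    localities <- names(idx)[vapply(idx, length, 0L) > 0]
  if (length(localities) < 2)
    stop("theta undefined: need at least two sampled localities")
  idx <- idx[localities]
  snp <- g$loci$marker_class == "snp"
  A <- ABC <- rep(NA_real_, n_loci(g))
  if (any(snp)) {
    comp <- wc_components_snp(g, idx, which(snp))
    A[snp] <- comp$a; ABC[snp] <- comp$abc
  }
  if (any(!snp)) {
    for (j in which(!snp)) {
      comp <- wc_components_multi(g, idx, j)
      A[j] <- comp$a; ABC[j] <- comp$abc
    }
  }
  use <- !is.na(A) & !is.na(ABC)
  if (!any(use) || sum(ABC[use]) == 0)
    stop("theta undefined: no informative polymorphic loci shared by ",
         "the requested localities")
  list(theta = sum(A[use]) / sum(ABC[use]),
       per_locus = data.frame(locus = g$loci$id, a = A, abc = ABC,
                              theta = ifelse(ABC != 0, A / ABC, NA_real_),
                              stringsAsFactors = FALSE),
       n_loci_used = sum(use))
}

# vectorised biallelic path: per-locality counts, ALT frequency and
# heterozygote frequency per locus; component sums over both alleles
# are twice the single-allele values, applied uniformly.
wc_components_snp <- function(g, idx, loci) {
  K <- length(idx); L <- length(loci)
  n <- p <- h <- matrix(0, K, L)
  for (k in seq_len(K)) {
    i <- idx[[k]]
    a1 <- g$a1[i, loci, drop = FALSE]; a2 <- g$a2[i, loci, drop = FALSE]
    ok <- !is.na(a1)
    n[k, ] <- colSums(ok)
    d <- a1 + a2
    p[k, ] <- ifelse(n[k, ] > 0, colSums(d, na.rm = TRUE) / (2 * n[k, ]), 0)
    h[k, ] <- ifelse(n[k, ] > 0, colSums(a1 != a2, na.rm = TRUE) / n[k, ], 0)
  }
  r <- colSums(n > 0)
  nsum <- colSums(n)
  nbar <- nsum / r
  valid <- r >= 2 & nbar > 1
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  pbar <- colSums(n * p) / nsum
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- NA_real_
  abc <- a + b + cc
  list(a = 2 * a, abc = 2 * abc)
}

# generic multi-allelic path (one locus), summing components per allele
wc_components_multi <- function(g, idx, j) {
  dat <- lapply(idx, function(i) {
    a1 <- g$a1[i, j]; a2 <- g$a2[i, j]
    ok <- !is.na(a1)
    list(a1 = a1[ok], a2 = a2[ok])
  })
  ni <- vapply(dat, function(d) length(d$a1), 0L)
  dat <- dat[ni > 0]; ni <- ni[ni > 0]
  r <- length(ni)
  if (r < 2) return(list(a = NA_real_, abc = NA_real_))
  nbar <- mean(ni)
  if (nbar <= 1) return(list(a = NA_real_, abc = NA_real_))
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  alleles <- sort(unique(unlist(lapply(dat, function(d) c(d$a1, d$a2)))))
  a_sum <- abc_sum <- 0
  for (al in alleles) {
    pi <- vapply(dat, function(d) mean(c(d$a1, d$a2) == al), 0)
    hi <- vapply(dat, function(d)
      mean((d$a1 == al) != (d$a2 == al)), 0)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  list(a = a_sum, abc = abc_sum)
}

#' Pairwise Weir-Cockerham theta
#'
#' @inheritParams wc_fst
#' @param loc_a,loc_b locality ids.
#' @return as [wc_fst()], restricted to the pair.
#' @export
wc_fst_pair <- function(g, locs, loc_a, loc_b) {
  wc_fst(g, locs, localities = c(loc_a, loc_b))
}

#' Pairwise F_ST matrix with bootstrap confidence intervals
#'
#' All pairwise Weir-Cockerham estimates among sampled localities; CIs
#' by bootstrap over loci (percentile interval on the ratio of sums).
#'
#' @inheritParams wc_fst
#' @param n_boot bootstrap replicates over loci (100 is a common
#'   reporting convention).
#' @param alpha two-sided CI level.
#' @param min_n localities with fewer individuals are excluded.
#' @param seed integer seed.
#' @return list of class `fst_matrix`: `theta` (symmetric matrix, zero
#'   diagonal), `lower`, `upper` (CI matrices), `localities`.
#' @export
fst_matrix <- function(g, locs, n_boot = 100, alpha = 0.05, min_n = 1,
                       seed = 1L) {
  idx <- locality_indices(g, locs)
  ids <- names(idx)[vapply(idx, length, 0L) >= min_n]
  K <- length(ids)
  if (K < 2) stop("need at least two localities with min_n individuals")
  set.seed(derive_seed(seed, "fst_boot"))
  th <- lo <- up <- matrix(0, K, K, dimnames = list(ids, ids))
  for (u in seq_len(K - 1)) for (v in (u + 1):K) {
    fit <- wc_fst_pair(g, locs, ids[u], ids[v])
    use <- !is.na(fit$per_locus$a)
    a <- fit$per_locus$a[use]; abc <- fit$per_locus$abc[use]
    bs <- replicate(n_boot, {
      b <- sample.int(length(a), replace = TRUE)
      s <- sum(abc[b])
      if (s == 0) NA_real_ else sum(a[b]) / s
    })
    ci <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                          names = FALSE)
    th[u, v] <- th[v, u] <- fit$theta
    lo[u, v] <- lo[v, u] <- ci[1]
    up[u, v] <- up[v, u] <- ci[2]
  }
  structure(list(theta = th, lower = lo, upper = up, localities = ids),
            class = "fst_matrix")
}

#' Rousset linearisation theta / (1 - theta)
#'
#' Linear with geographic distance under isolation-by-distance models.
#' Negative estimates are kept as computed by default (transparency over
#' convention); set `floor_negative` to clamp them to zero. Estimates at
#' or above 1 are capped at `cap` rather than returning infinity.
#'
#' @param f an `fst_matrix` or a numeric matrix of theta values.
#' @param floor_negative clamp negative theta to 0 before transforming.
#' @param cap sentinel replacing infinite values (theta -> 1).
#' @return numeric matrix of theta / (1 - theta).
#' @export
rousset_linearise <- function(f, floor_negative = FALSE, cap = 1e6) {
  th <- if (inherits(f, "fst_matrix")) f$theta else as.matrix(f)
  if (floor_negative) th <- pmax(th, 0)
  out <- th / (1 - th)
  out[th >= 1] <- cap
  diag(out) <- 0
  out
}

#' Geographic distance matrix between localities
#'
#' @param locs a [locality_set()].
#' @param metric `"euclidean_deg"` (plain Euclidean distance on decimal
#'   degrees, the convention used with locality coordinates in a small
#'   study region) or `"great_circle_km"` (haversine on a mean-radius
#'   sphere).
#' @return symmetric matrix with zero diagonal, locality ids as
#'   dimnames.
#' @export
geo_distances <- function(locs, metric = c("euclidean_deg",
                                           "great_circle_km")) {
  metric <- match.arg(metric)
  xy <- locs$localities[, c("lon", "lat")]
  ids <- locality_ids(locs)
  if (metric == "euclidean_deg") {
    d <- as.matrix(stats::dist(xy))
  } else {
    d <- geosphere::distm(as.matrix(xy),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2,
                                                     r = 6371008.8)) / 1000
  }
  dimnames(d) <- list(ids, ids)
  d
}

#' Mantel test for matrix correlation (isolation by distance)
#'
#' Pearson correlation of the lower-triangle vectors of two symmetric
#' distance matrices; significance by simultaneous row/column
#' permutation of one matrix. One-sided ("greater") by default, with the
#' +1 permutation correction; with `exact = TRUE` all `n!` permutations
#' are enumerated instead (feasible for up to ~8 localities).
#'
#' @param d_gen,d_geo symmetric numeric matrices over the same
#'   localities (e.g. linearised F_ST and geographic distance).
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param exact enumerate all permutations instead of sampling.
#' @return list: `r`, `p`, `n_perm`, `alternative`.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = 1L,
                        alternative = c("greater", "less", "two.sided"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  d_gen <- as.matrix(d_gen); d_geo <- as.matrix(d_geo)
  stopifnot(identical(dim(d_gen), dim(d_geo)))
  n <- nrow(d_gen)
  lt <- lower.tri(d_gen)
  r_obs <- stats::cor(d_gen[lt], d_geo[lt])
  stat <- function(perm) {
    dp <- d_geo[perm, perm]
    stats::cor(d_gen[lt], dp[lt])
  }
  side <- function(r_perm) {
    switch(alternative,
           greater = r_perm >= r_obs - 1e-12,
           less = r_perm <= r_obs + 1e-12,
           two.sided = abs(r_perm) >= abs(r_obs) - 1e-12)
  }
  if (exact) {
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, 0)
    p <- mean(side(rs))
    n_perm <- length(perms)
  } else {
    set.seed(derive_seed(seed, "mantel"))
    rs <- vapply(seq_len(n_perm), function(i) stat(sample.int(n)), 0)
    p <- (1 + sum(side(rs))) / (n_perm + 1)
  }
  list(r = r_obs, p = p, n_perm = n_perm, alternative = alternative)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  m <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    m <- m + 1L
    out[[m]] <- append(s, n, after = pos - 1L)
  }
  out
}
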
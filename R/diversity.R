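#' Per-locality observed and expected heterozygosity
#'
#' Per locus within a locality, `H_O` is the fraction of heterozygous
#' genotypes among non-missing calls and `H_E` is Nei's unbiased gene
#' diversity `(2n / (2n - 1)) (1 - sum p_i^2)` with `n` the number of
#' individuals called at the locus. The locality value is the mean over
#' loci with at least one call; loci monomorphic within the locality are
#' included unless `exclude_monomorphic = TRUE`. Localities sampled
#' below `min_n` individuals are flagged, not dropped (conventional
#' minima: 10 for microsatellites, 4 for RAD-seq SNPs).
#'
#' @param g a [genotype_matrix()].
#' @param locs a [locality_set()].
#' @param min_n minimum sample size before a locality is flagged.
#' @param exclude_monomorphic drop within-locality-monomorphic loci from
#'   the means.
#' @return data.frame: `locality`, `n`, `flagged`, `n_loci_used`, `ho`,
#'   `he` (`NA` where a locality has no callable locus).
#' @export
heterozygosity <- function(g, locs, min_n = 4, exclude_monomorphic = FALSE) {
  idx <- locality_indices(g, locs)
  out <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    st <- locality_het_by_locus(g, i, exclude_monomorphic)
    data.frame(locality = id, n = length(i),
               flagged = length(i) < min_n,
               n_loci_used = sum(!is.na(st$ho)),
               ho = if (all(is.na(st$ho))) NA_real_ else
                 mean(st$ho, na.rm = TRUE),
               he = if (all(is.na(st$he))) NA_real_ else
                 mean(st$he, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# per-locus H_O / H_E for the individuals in rows `i`
locality_het_by_locus <- function(g, i, exclude_monomorphic = FALSE) {
  L <- n_loci(g)
  ho <- he <- rep(NA_real_, L)
  if (length(i) == 0) return(list(ho = ho, he = he))
  a1 <- g$a1[i, , drop = FALSE]; a2 <- g$a2[i, , drop = FALSE]
  for (j in seq_len(L)) {
    ok <- !is.na(a1[, j])
    n <- sum(ok)
    if (n == 0) next
    het <- a1[ok, j] != a2[ok, j]
    av <- c(a1[ok, j], a2[ok, j])
    p <- tabulate(match(av, unique(av))) / (2 * n)
    if (exclude_monomorphic && length(p) < 2) next
    ho[j] <- mean(het)
    he[j] <- if (2 * n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else 0
  }
  list(ho = ho, he = he)
}

#' Multilocus inbreeding coefficient with bootstrap confidence interval
#'
#' `F_IS = 1 - mean(H_O) / mean(H_E)` over loci; the percentile CI is a
#' bootstrap over loci. Inbreeding is called significant when the CI
#' excludes zero.
#'
#' @inheritParams heterozygosity
#' @param n_boot bootstrap resamples over loci.
#' @param alpha two-sided CI level (default 0.05 gives a 95% CI).
#' @param seed integer seed for the bootstrap.
#' @return data.frame: `locality`, `n`, `fis`, `lower`, `upper`,
#'   `significant`. `F_IS` is `NA` where mean `H_E` is zero (undefined).
#' @export
inbreeding_fis <- function(g, locs, n_boot = 1000, alpha = 0.05,
                           min_n = 4, seed = 1L) {
  idx <- locality_indices(g, locs)
  set.seed(derive_seed(seed, "fis_boot"))
  out <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    st <- locality_het_by_locus(g, i)
    use <- !is.na(st$ho)
    res <- data.frame(locality = id, n = length(i), fis = NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      significant = NA, stringsAsFactors = FALSE)
    if (!any(use)) return(res)
    ho <- st$ho[use]; he <- st$he[use]
    if (mean(he) == 0) return(res)       # undefined: no diversity
    res$fis <- 1 - mean(ho) / mean(he)
    bs <- replicate(n_boot, {
      b <- sample.int(length(ho), replace = TRUE)
      heb <- mean(he[b])
      if (heb == 0) NA_real_ else 1 - mean(ho[b]) / heb
    })
    ci <- stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                          names = FALSE)
    res$lower <- ci[1]; res$upper <- ci[2]
    res$significant <- ci[1] > 0 || ci[2] < 0
    res
  })
  do.call(rbind, out)
}

#' Hardy-Weinberg equilibrium tests per locus and locality
#'
#' `chi2`: goodness of fit of observed genotype counts against
#' Hardy-Weinberg proportions computed from the observed allele
#' frequencies (df = number of possible genotypes minus number of
#' alleles). `mc_exact`: Monte-Carlo exact test — allele copies are
#' permuted among individuals within the locality and the p-value is the
#' proportion of permuted genotype tables whose conditional probability
#' given the allele counts is as small or smaller than the observed
#' table's (the usual exact-test ordering).
#'
#' @inheritParams heterozygosity
#' @param method `"chi2"` or `"mc_exact"`.
#' @param n_steps Monte-Carlo permutations for `mc_exact`.
#' @param seed integer seed (Monte-Carlo method is deterministic given it).
#' @return data.frame: `locality`, `locus`, `n`, `p` (`NA` where a locus
#'   is monomorphic in the locality or has no calls).
#' @export
hwe_test <- function(g, locs, method = c("chi2", "mc_exact"),
                     n_steps = 10000, seed = 1L) {
  method <- match.arg(method)
  idx <- locality_indices(g, locs)
  set.seed(derive_seed(seed, "hwe"))
  rows <- list()
  for (id in names(idx)) {
    i <- idx[[id]]
    for (j in seq_len(n_loci(g))) {
      a1 <- g$a1[i, j]; a2 <- g$a2[i, j]
      ok <- !is.na(a1)
      n <- sum(ok)
      p <- NA_real_
      if (n > 0) {
        al1 <- a1[ok]; al2 <- a2[ok]
        if (length(unique(c(al1, al2))) >= 2) {
          p <- if (method == "chi2") hwe_chi2(al1, al2)
               else hwe_mc_exact(al1, al2, n_steps)
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(locality = id, locus = g$loci$id[j], n = n, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

geno_key <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2))

hwe_chi2 <- function(a1, a2) {
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  pfreq <- (tabulate(match(a1, alleles), k) +
            tabulate(match(a2, alleles), k)) / (2 * n)
  # expected HWE genotype counts over all k(k+1)/2 genotype classes
  obs <- exp_ <- numeric(0)
  keys <- geno_key(a1, a2)
  for (u in seq_len(k)) for (v in u:k) {
    e <- if (u == v) n * pfreq[u]^2 else 2 * n * pfreq[u] * pfreq[v]
    o <- sum(keys == paste(alleles[u], alleles[v]))
    obs <- c(obs, o); exp_ <- c(exp_, e)
  }
  use <- exp_ > 0
  stat <- sum((obs[use] - exp_[use])^2 / exp_[use])
  df <- k * (k + 1) / 2 - k
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# conditional probability of a genotype table given allele counts
# (log scale); h = number of heterozygotes
log_cond_prob <- function(a1, a2) {
  n <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  ac <- tabulate(match(a1, alleles), length(alleles)) +
    tabulate(match(a2, alleles), length(alleles))
  h <- sum(a1 != a2)
  gt <- table(geno_key(a1, a2))
  lgamma(n + 1) - sum(lgamma(gt + 1)) + h * log(2) +
    sum(lgamma(ac + 1)) - lgamma(2 * n + 1)
}

hwe_mc_exact <- function(a1, a2, n_steps) {
  obs <- log_cond_prob(a1, a2)
  pool <- c(a1, a2)
  n <- length(a1)
  hits <- 0L
  for (s in seq_len(n_steps)) {
    perm <- sample(pool)
    b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
    if (log_cond_prob(b1, b2) <= obs + 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_steps + 1)
}

#' Rarefied allelic richness
#'
#' Hypergeometric expectation of the number of distinct alleles in a
#' standardised subsample of `g_size` gene copies: for a locus with `N`
#' copies sampled of which `N_i` carry allele `i`,
#' `A_g = sum_i [1 - C(N - N_i, g) / C(N, g)]`. The locality value is
#' the mean over loci. `g_size` is counted in gene copies (two per
#' diploid individual); localities with fewer than `g_size` copies at a
#' locus are flagged and that locus excluded from their mean.
#'
#' @inheritParams heterozygosity
#' @param g_size standardised subsample size in gene copies.
#' @return data.frame: `locality`, `n`, `min_copies`, `flagged`, `ar`.
#' @export
rarefied_allelic_richness <- function(g, locs, g_size = 2) {
  idx <- locality_indices(g, locs)
  out <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    ar <- rep(NA_real_, n_loci(g))
    min_copies <- Inf
    for (j in seq_len(n_loci(g))) {
      av <- c(g$a1[i, j], g$a2[i, j])
      av <- av[!is.na(av)]
      N <- length(av)
      if (N > 0) min_copies <- min(min_copies, N)
      if (N < g_size || N == 0) next
      Ni <- tabulate(match(av, unique(av)))
      ar[j] <- sum(1 - exp(lchoose(N - Ni, g_size) - lchoose(N, g_size)))
    }
    data.frame(locality = id, n = length(i),
               min_copies = if (is.finite(min_copies)) min_copies else 0,
               flagged = !all(!is.na(ar)),
               ar = if (all(is.na(ar))) NA_real_ else mean(ar, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rarefied private allele count
#'
#' Expected number of alleles present in a `g_size`-copy subsample of
#' the focal locality and absent from independent `g_size`-copy
#' subsamples of every other locality: per allele the presence
#' probability in the focal locality is multiplied by the product of
#' per-locality absence probabilities elsewhere (all hypergeometric),
#' summed over alleles and averaged over loci. The raw (unrarefied)
#' private-allele count is also reported.
#'
#' @inheritParams rarefied_allelic_richness
#' @return data.frame: `locality`, `n`, `flagged`, `pa` (rarefied mean
#'   over loci), `pa_raw` (count of alleles observed only there).
#' @export
rarefied_private_alleles <- function(g, locs, g_size = 2) {
  idx <- locality_indices(g, locs)
  ids <- names(idx)
  K <- length(ids); L <- n_loci(g)
  # per locus: allele copy counts per locality
  pa <- matrix(NA_real_, K, L, dimnames = list(ids, NULL))
  pa_raw <- stats::setNames(numeric(K), ids)
  for (j in seq_len(L)) {
    avs <- lapply(ids, function(id) {
      i <- idx[[id]]
      av <- c(g$a1[i, j], g$a2[i, j])
      av[!is.na(av)]
    })
    alleles <- sort(unique(unlist(avs)))
    if (length(alleles) == 0) next
    Nk <- vapply(avs, length, 0L)
    cnt <- vapply(avs, function(av) tabulate(match(av, alleles),
                                             length(alleles)),
                  integer(length(alleles)))
    cnt <- matrix(cnt, nrow = length(alleles))   # alleles x localities
    # raw private alleles
    present <- cnt > 0
    priv <- which(rowSums(present) == 1)
    for (a in priv) pa_raw[which(present[a, ])] <-
      pa_raw[which(present[a, ])] + 1
    # rarefied: absence probability per allele x locality
    usable <- Nk >= g_size
    if (!any(usable)) next
    qabs <- matrix(1, length(alleles), K)
    for (k in which(usable))
      qabs[, k] <- exp(lchoose(Nk[k] - cnt[, k], g_size) -
                         lchoose(Nk[k], g_size))
    for (k in which(usable)) {
      others <- setdiff(which(usable), k)
      contrib <- (1 - qabs[, k]) *
        apply(qabs[, others, drop = FALSE], 1, prod)
      pa[k, j] <- sum(contrib)
    }
  }
  data.frame(locality = ids,
             n = vapply(idx, length, 0L),
             flagged = apply(pa, 1, function(x) any(is.na(x))),
             pa = rowMeans(pa, na.rm = TRUE),
             pa_raw = pa_raw,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-locality diversity report
#'
#' Combines heterozygosity, inbreeding, rarefied allelic richness and
#' private alleles into one table (columns mirror a classical diversity
#' table: N, P_A, A_R, H_O, H_E, F_IS with CI).
#'
#' @inheritParams heterozygosity
#' @inheritParams inbreeding_fis
#' @inheritParams rarefied_allelic_richness
#' @return data.frame of class `diversity_report`; attribute `min_n`
#'   echoes the flagging rule applied.
#' @export
diversity_report <- function(g, locs, min_n = 4, g_size = 2,
                             n_boot = 1000, alpha = 0.05, seed = 1L) {
  het <- heterozygosity(g, locs, min_n = min_n)
  fis <- inbreeding_fis(g, locs, n_boot = n_boot, alpha = alpha,
                        min_n = min_n, seed = seed)
  ar <- rarefied_allelic_richness(g, locs, g_size = g_size)
  pa <- rarefied_private_alleles(g, locs, g_size = g_size)
  out <- data.frame(locality = het$locality, n = het$n,
                    flagged = het$flagged,
                    pa = pa$pa, pa_raw = pa$pa_raw, ar = ar$ar,
                    ho = het$ho, he = het$he,
                    fis = fis$fis, fis_lower = fis$lower,
                    fis_upper = fis$upper,
                    fis_significant = fis$significant,
                    stringsAsFactors = FALSE)
  attr(out, "min_n") <- min_n
  attr(out, "g_size") <- g_size
  class(out) <- c("diversity_report", "data.frame")
  out
}
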
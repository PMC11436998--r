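# Independent brute-force oracles. These deliberately re-derive each
# statistic with naive scalar loops / exhaustive enumeration, sharing no
# code with the package implementations they check.

# --- heterozygosity: per-genotype hand tally -------------------------
oracle_het <- function(g, rows) {
  ho_l <- he_l <- c()
  for (j in seq_len(n_loci(g))) {
    nh <- nn <- 0
    copies <- c()
    for (i in rows) {
      x <- g$a1[i, j]; y <- g$a2[i, j]
      if (is.na(x)) next
      nn <- nn + 1
      if (x != y) nh <- nh + 1
      copies <- c(copies, x, y)
    }
    if (nn == 0) next
    ho_l <- c(ho_l, nh / nn)
    sump2 <- 0
    for (al in unique(copies))
      sump2 <- sump2 + (sum(copies == al) / length(copies))^2
    he_l <- c(he_l, if (length(copies) > 1)
      (length(copies) / (length(copies) - 1)) * (1 - sump2) else 0)
  }
  list(ho = mean(ho_l), he = mean(he_l))
}

# --- Weir & Cockerham 1984: literal scalar transcription -------------
# per locus, summing components over every allele; pops given as a list
# of (a1, a2) vectors with missing already removed
oracle_wc_locus <- function(pops) {
  pops <- pops[vapply(pops, function(p) length(p$a1) > 0, TRUE)]
  r <- length(pops)
  if (r < 2) return(c(a = NA, abc = NA))
  ni <- vapply(pops, function(p) length(p$a1), 0)
  nbar <- sum(ni) / r
  if (nbar <= 1) return(c(a = NA, abc = NA))
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- unique(unlist(lapply(pops, function(p) c(p$a1, p$a2))))
  A <- ABC <- 0
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      cnt <- sum(pops[[k]]$a1 == al) + sum(pops[[k]]$a2 == al)
      p_i[k] <- cnt / (2 * ni[k])
      h_i[k] <- sum((pops[[k]]$a1 == al) != (pops[[k]]$a2 == al)) / ni[k]
    }
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a
    ABC <- ABC + a + b + cc
  }
  c(a = A, abc = ABC)
}

oracle_wc_theta <- function(g, locs, ids) {
  idx <- locality_indices(g, locs)[ids]
  A <- ABC <- 0
  for (j in seq_len(n_loci(g))) {
    pops <- lapply(idx, function(i) {
      ok <- !is.na(g$a1[i, j])
      list(a1 = g$a1[i, j][ok], a2 = g$a2[i, j][ok])
    })
    comp <- oracle_wc_locus(pops)
    if (!is.na(comp["a"])) {
      A <- A + comp["a"]; ABC <- ABC + comp["abc"]
    }
  }
  unname(A / ABC)
}

# --- rarefaction: exhaustive subset enumeration ----------------------
# expected distinct alleles among all C(N, g) subsets of gene copies
oracle_ar_locus <- function(copies, g_size) {
  N <- length(copies)
  if (N < g_size) return(NA_real_)
  subs <- utils::combn(N, g_size)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# presence probability of an allele in a size-g subsample, by
# enumeration; private-allele expectation for a focal pop among others
oracle_pa_locus <- function(copy_list, focal, g_size) {
  pres <- function(copies, al) {
    N <- length(copies)
    if (N < g_size) return(NA_real_)
    subs <- utils::combn(N, g_size)
    mean(apply(subs, 2, function(s) al %in% copies[s]))
  }
  alleles <- unique(unlist(copy_list))
  tot <- 0
  for (al in alleles) {
    term <- pres(copy_list[[focal]], al)
    for (k in seq_along(copy_list)) {
      if (k == focal) next
      term <- term * (1 - pres(copy_list[[k]], al))
    }
    tot <- tot + term
  }
  tot
}

# --- Mantel: exhaustive permutation p-value --------------------------
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  prev <- oracle_perms(n - 1L)
  out <- NULL
  for (r in seq_len(nrow(prev))) for (k in seq_len(n)) {
    row <- prev[r, ]
    out <- rbind(out, c(row[seq_len(k - 1)], n, row[seq(k, length.out = n - k)]))
  }
  out
}

oracle_mantel_exact <- function(d_gen, d_geo) {
  n <- nrow(d_gen)
  lt <- lower.tri(d_gen)
  r_obs <- cor(d_gen[lt], d_geo[lt])
  perms <- oracle_perms(n)
  rs <- apply(perms, 1, function(p) {
    dp <- d_geo[p, p]
    cor(d_gen[lt], dp[lt])
  })
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# --- RDA: literal normal-equations + eigen oracle --------------------
oracle_rda <- function(Y, X) {
  Y <- scale(Y, center = TRUE, scale = FALSE)
  X <- scale(X)
  B <- solve(t(X) %*% X) %*% t(X) %*% Y
  Yhat <- X %*% B
  ev <- eigen(t(Yhat) %*% Yhat, symmetric = TRUE)
  keep <- ev$values > max(ev$values, 0) * 1e-9
  list(eig = ev$values[keep] / (nrow(Y) - 1),
       loadings = ev$vectors[, keep, drop = FALSE],
       prop = sum(Yhat^2) / sum(Y^2))
}

# --- HWE: exact biallelic enumeration (Levene) -----------------------
oracle_hwe_exact_biallelic <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  lprob <- function(h) {   # h heterozygotes, allele count na fixed
    haa <- (na - h) / 2
    hbb <- n - haa - h
    if (h %% 2 != na %% 2 || haa < 0 || hbb < 0 ||
        haa != round(haa)) return(-Inf)
    lfactorial(n) - (lfactorial(haa) + lfactorial(h) + lfactorial(hbb)) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
      lfactorial(2 * n)
  }
  hs <- 0:min(na, 2 * n - na)
  lp <- vapply(hs, lprob, 0)
  p_obs <- lp[hs == n_ab]
  sum(exp(lp[lp <= p_obs + 1e-12]))
}

# --- misc fixtures ---------------------------------------------------
toy_matrix <- function(a1, a2, marker = "snp") {
  genotype_matrix(a1, a2, marker)
}

# small multi-locality dataset built by hand
toy_dataset <- function(n_per = c(3, 3), n_loci = 4, seed = 42,
                        marker = "snp") {
  set.seed(seed)
  n <- sum(n_per)
  if (marker == "snp") {
    a1 <- matrix(rbinom(n * n_loci, 1, 0.5), n, n_loci)
    a2 <- matrix(rbinom(n * n_loci, 1, 0.5), n, n_loci)
  } else {
    a1 <- matrix(sample(100:106, n * n_loci, TRUE), n, n_loci)
    a2 <- matrix(sample(100:106, n * n_loci, TRUE), n, n_loci)
  }
  rownames(a1) <- rownames(a2) <- sprintf("i%02d", 1:n)
  colnames(a1) <- colnames(a2) <- sprintf("L%d", 1:n_loci)
  g <- genotype_matrix(a1, a2, marker)
  ids <- sprintf("pop%d", seq_along(n_per))
  locs <- locality_set(
    data.frame(id = ids, lat = 51 + seq_along(n_per) * 0.5,
               lon = 9 + seq_along(n_per) * 0.3),
    setNames(rep(ids, n_per), g$ind))
  list(g = g, locs = locs)
}
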
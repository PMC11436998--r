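#' Principal component analysis of genotypes
#'
#' Genotypes are coded as allele counts (0/1/2 alternate-allele dosage
#' for SNPs; per-allele counts for microsatellite loci), missing values
#' mean-imputed per locus, columns centred, and the covariance matrix
#' eigen-decomposed (via SVD). This is the standard pre-step of
#' discriminant analysis of principal components (DAPC).
#'
#' @param g a [genotype_matrix()].
#' @return list of class `genotype_pca`: `scores` (individuals x
#'   components), `eigenvalues` (non-increasing), `rotation`,
#'   `total_variance`.
#' @export
pca_genotypes <- function(g) {
  x <- genotype_numeric(g)
  x <- impute_mean(x)
  x <- scale(x, center = TRUE, scale = FALSE)
  n <- nrow(x)
  s <- svd(x)
  keep <- s$d > max(s$d) * 1e-9
  eig <- s$d[keep]^2 / (n - 1)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], sum(keep))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, eigenvalues = eig,
                 rotation = s$v[, keep, drop = FALSE],
                 total_variance = sum(x^2) / (n - 1)),
            class = "genotype_pca")
}

# numeric coding: SNPs one dosage column per locus; microsatellites one
# count column per observed allele (adegenet-style "tab" coding)
genotype_numeric <- function(g) {
  snp <- g$loci$marker_class == "snp"
  blocks <- list()
  if (any(snp)) {
    d <- g$a1[, snp, drop = FALSE] + g$a2[, snp, drop = FALSE]
    storage.mode(d) <- "double"
    colnames(d) <- g$loci$id[snp]
    blocks$snp <- d
  }
  if (any(!snp)) {
    cols <- list()
    for (j in which(!snp)) {
      al <- sort(unique(stats::na.omit(c(g$a1[, j], g$a2[, j]))))
      for (a in al) {
        cnt <- (g$a1[, j] == a) + (g$a2[, j] == a)
        cols[[paste0(g$loci$id[j], ".", a)]] <- as.numeric(cnt)
      }
    }
    blocks$msat <- do.call(cbind, cols)
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- g$ind
  out
}

impute_mean <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) x[nas] <- mu[nas[, 2]]
  x
}

#' Scan cluster numbers by k-means with BIC model choice
#'
#' k-means on retained principal components, best of `n_starts` random
#' starts per k; the Bayesian Information Criterion uses the spherical
#' form `BIC(k) = n ln(WSS_k / n) + k ln(n)` and the chosen k minimises
#' it.
#'
#' @param pca a `genotype_pca` (or a plain score matrix).
#' @param k_range candidate cluster numbers (2-6 is a common scan for
#'   regional amphibian data).
#' @param n_pcs principal components retained (default: all).
#' @param n_starts random starts per k.
#' @param seed integer seed.
#' @return list of class `cluster_scan`: `k_chosen`, `bic`
#'   (named per k), `labels` (list per k), `n_pcs`.
#' @export
find_clusters <- function(pca, k_range = 2:6, n_pcs = NULL,
                          n_starts = 10, seed = 1L) {
  scores <- if (inherits(pca, "genotype_pca")) pca$scores else as.matrix(pca)
  if (is.null(n_pcs)) n_pcs <- ncol(scores)
  n_pcs <- min(n_pcs, ncol(scores))
  x <- scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(x)
  set.seed(derive_seed(seed, "kmeans"))
  bic <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  labels <- vector("list", length(k_range))
  names(labels) <- k_range
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- stats::kmeans(x, centers = k, nstart = n_starts,
                        iter.max = 100)
    bic[i] <- n * log(km$tot.withinss / n) + k * log(n)
    labels[[i]] <- km$cluster
  }
  k_chosen <- k_range[which.min(bic)]
  structure(list(k_chosen = k_chosen, bic = bic, labels = labels,
                 best_labels = labels[[as.character(k_chosen)]],
                 n_pcs = n_pcs),
            class = "cluster_scan")
}

#' Discriminant axes and membership probabilities
#'
#' Linear discriminant analysis on retained principal components given
#' cluster labels; at most k-1 axes. Membership probabilities are the
#' LDA posterior class probabilities.
#'
#' @param pca a `genotype_pca` or score matrix.
#' @param labels integer/factor cluster labels per individual.
#' @param n_pcs principal components retained.
#' @return list of class `dapc_fit`: `coords` (individuals x axes),
#'   `posterior` (membership probabilities, rows sum to 1),
#'   `assigned` (MAP label), `loadings`, `n_pcs`.
#' @export
discriminant_axes <- function(pca, labels, n_pcs) {
  scores <- if (inherits(pca, "genotype_pca")) pca$scores else as.matrix(pca)
  n_pcs <- min(n_pcs, ncol(scores))
  x <- scores[, seq_len(n_pcs), drop = FALSE]
  labels <- factor(labels)
  fit <- MASS::lda(x, grouping = labels)
  pr <- stats::predict(fit, x)
  structure(list(coords = pr$x, posterior = pr$posterior,
                 assigned = pr$class, loadings = fit$scaling,
                 labels = labels, n_pcs = n_pcs),
            class = "dapc_fit")
}

#' a-score: choosing how many principal components to retain
#'
#' The a-score is the observed proportion of individuals reassigned to
#' their own cluster by the discriminant analysis minus the mean of the
#' same proportion over label-permuted replicates, computed per
#' candidate number of retained components; it penalises overfitting
#' from retaining too many components. The recommended n_pcs maximises
#' it.
#'
#' @param pca a `genotype_pca` or score matrix.
#' @param labels cluster labels.
#' @param n_pcs_range candidate numbers of retained components.
#' @param n_perm label permutations per candidate.
#' @param seed integer seed.
#' @return list: `a_score` (named per n_pcs), `n_pcs_best`, `observed`,
#'   `permuted_mean`.
#' @export
a_score_optimise <- function(pca, labels, n_pcs_range = NULL,
                             n_perm = 10, seed = 1L) {
  scores <- if (inherits(pca, "genotype_pca")) pca$scores else as.matrix(pca)
  labels <- factor(labels)
  if (is.null(n_pcs_range))
    n_pcs_range <- seq_len(min(ncol(scores), 20))
  n_pcs_range <- n_pcs_range[n_pcs_range <= ncol(scores)]
  set.seed(derive_seed(seed, "a_score"))
  reassign_rate <- function(x, lab) {
    fit <- try(MASS::lda(x, grouping = lab), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    mean(stats::predict(fit, x)$class == lab)
  }
  obs <- perm_mean <- stats::setNames(rep(NA_real_, length(n_pcs_range)),
                                      n_pcs_range)
  for (i in seq_along(n_pcs_range)) {
    x <- scores[, seq_len(n_pcs_range[i]), drop = FALSE]
    obs[i] <- reassign_rate(x, labels)
    perm <- vapply(seq_len(n_perm), function(b)
      reassign_rate(x, sample(labels)), 0)
    perm_mean[i] <- mean(perm, na.rm = TRUE)
  }
  a <- obs - perm_mean
  list(a_score = a,
       n_pcs_best = n_pcs_range[which.max(a)],
       observed = obs, permuted_mean = perm_mean)
}

#' Full DAPC-style clustering of a genotype matrix
#'
#' PCA, k-means/BIC model choice, a-score-guided component retention
#' and discriminant description in one call.
#'
#' @param g a [genotype_matrix()].
#' @param k_range candidate cluster numbers.
#' @param n_pcs_cluster components used during the k-means scan
#'   (default: enough to explain 90% of variance, capped at n - 1).
#' @param n_starts,n_perm,seed see [find_clusters()] and
#'   [a_score_optimise()].
#' @return list of class `cluster_model`: `k_chosen`, `bic`, `a_score`,
#'   `n_pcs`, `labels`, `posterior`, `coords`, `pca`.
#' @export
cluster_genotypes <- function(g, k_range = 2:6, n_pcs_cluster = NULL,
                              n_starts = 10, n_perm = 10, seed = 1L) {
  pca <- pca_genotypes(g)
  if (is.null(n_pcs_cluster)) {
    cum <- cumsum(pca$eigenvalues) / sum(pca$eigenvalues)
    n_pcs_cluster <- max(2, min(which(cum >= 0.9)))
  }
  scan <- find_clusters(pca, k_range = k_range, n_pcs = n_pcs_cluster,
                        n_starts = n_starts, seed = seed)
  asc <- a_score_optimise(pca, scan$best_labels,
                          n_pcs_range = seq_len(min(n_pcs_cluster, 20)),
                          n_perm = n_perm, seed = seed)
  dapc <- discriminant_axes(pca, scan$best_labels, asc$n_pcs_best)
  structure(list(k_chosen = scan$k_chosen, bic = scan$bic,
                 a_score = asc$a_score, n_pcs = asc$n_pcs_best,
                 labels = scan$best_labels, posterior = dapc$posterior,
                 assigned = dapc$assigned, coords = dapc$coords,
                 pca = pca),
            class = "cluster_model")
}

#' Majority cluster label per locality
#'
#' @param labels per-individual labels named by individual id.
#' @param locs a [locality_set()].
#' @return named character vector locality -> majority label (ties
#'   broken by smallest label).
#' @export
majority_cluster <- function(labels, locs) {
  memb <- locs$membership[names(labels)]
  out <- tapply(as.character(labels), memb, function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    names(tb)[1]
  })
  res <- stats::setNames(rep(NA_character_, nrow(locs$localities)),
                         locality_ids(locs))
  res[names(out)] <- as.character(out)
  res
}
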
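#' Variance-inflation-factor screen of environmental predictors
#'
#' Iteratively drops the predictor with the highest VIF until all
#' remaining VIFs fall below `threshold` (VIF_j = 1 / (1 - R^2_j) from
#' regressing predictor j on the others). A threshold of 5 is the usual
#' collinearity cut-off in genotype-environment association work.
#'
#' @param env an [env_table()] (or data.frame with a `locality` column).
#' @param threshold maximum tolerated VIF.
#' @return list: `retained` (predictor names), `vif` (final VIFs),
#'   `dropped` (in drop order).
#' @export
vif_screen <- function(env, threshold = 5) {
  preds <- setdiff(names(env), "locality")
  x <- as.data.frame(env[preds])
  dropped <- character(0)
  vifs <- function(cols) {
    vapply(cols, function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(stats::reformulate(setdiff(cols, j), j),
                          data = x))$r.squared)   # duplicate predictors fit perfectly
      1 / (1 - min(r2, 1 - 1e-12))
    }, 0)
  }
  repeat {
    if (length(preds) < 2) {
      v <- stats::setNames(rep(1, length(preds)), preds)
      break
    }
    v <- vifs(preds)
    if (max(v) < threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    preds <- setdiff(preds, worst)
  }
  list(retained = preds, vif = v, dropped = dropped)
}

#' Redundancy analysis of genotypes on environmental predictors
#'
#' Constrained ordination: the 0/1/2 genotype matrix Y (mean-imputed,
#' column-centred) is regressed on the standardised predictor matrix X
#' expanded per individual; the fitted values X (X'X)^-1 X' Y are
#' decomposed by SVD. Eigenvalues are `d^2 / (n - 1)`; locus loadings
#' are the unit right singular vectors; site scores are the projections
#' of the (centred) genotypes onto the loadings (weighted-average
#' scores) alongside the constrained linear-combination scores; biplot
#' vectors are correlations of each predictor with the constrained site
#' scores.
#'
#' @param g a [genotype_matrix()] (all SNPs).
#' @param env an [env_table()].
#' @param locs a [locality_set()].
#' @param predictors predictor subset (default: all in `env`).
#' @return list of class `rda_fit`: `eig`, `loadings` (loci x axes),
#'   `site_scores` (weighted-average), `lc_scores` (constrained),
#'   `biplot` (predictors x axes), `prop_constrained`, `predictors`,
#'   `loci`, `X`.
#' @export
fit_rda <- function(g, env, locs, predictors = NULL) {
  if (is.null(predictors)) predictors <- setdiff(names(env), "locality")
  envm <- env_per_individual(env[c("locality", predictors)], g, locs)
  X <- scale(envm)
  if (any(!is.finite(X)))
    stop("constant predictor cannot be standardised: ",
         paste(predictors[apply(!is.finite(X), 2, any)], collapse = ", "))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- predictors[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear predictors (rank-deficient design): ",
         paste(bad, collapse = ", "))
  }
  Y <- impute_mean(snp_dosage(g))
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  Yhat <- qr.fitted(qx, Y)
  s <- svd(Yhat)
  k <- min(ncol(X), n - 1, ncol(Y), sum(s$d > max(s$d, 1e-12) * 1e-9))
  d <- s$d[seq_len(k)]
  V <- s$v[, seq_len(k), drop = FALSE]
  U <- s$u[, seq_len(k), drop = FALSE]
  eig <- d^2 / (n - 1)
  lc <- U %*% diag(d, k)                # constrained site scores
  wa <- Y %*% V                         # weighted-average site scores
  bp <- suppressWarnings(stats::cor(X, lc))
  bp[is.na(bp)] <- 0
  ax <- paste0("RDA", seq_len(k))
  dimnames(V) <- list(g$loci$id, ax)
  dimnames(lc) <- dimnames(wa) <- list(g$ind, ax)
  dimnames(bp) <- list(predictors, ax)
  names(eig) <- ax
  structure(list(eig = eig, loadings = V, site_scores = wa,
                 lc_scores = lc, biplot = bp,
                 prop_constrained = sum(d^2) / sum(Y^2),
                 predictors = predictors, loci = g$loci$id, X = X),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("rda_fit:", length(x$loci), "loci,", nrow(x$site_scores),
      "individuals,", length(x$eig), "constrained axes\n")
  cat(sprintf("proportion of variance constrained: %.3f\n",
              x$prop_constrained))
  invisible(x)
}

#' Detect candidate loci from RDA loadings
#'
#' On each retained constrained axis, loci whose loading lies more than
#' `sd_threshold` standard deviations from the mean loading are flagged;
#' the candidate set is the union over axes (each locus counted once).
#' Each candidate is assigned to the predictor with the largest absolute
#' Pearson correlation between its (imputed) dosage and the per-
#' individual predictor values.
#'
#' @param fit an `rda_fit`.
#' @param g the [genotype_matrix()] the fit was made from (for
#'   genotype-predictor correlations).
#' @param sd_threshold outlier threshold in loading standard deviations
#'   (2.5 is the conventional cut-off).
#' @param n_axes axes scanned (default: all constrained axes).
#' @return data.frame of class `candidate_set`: `locus`, `axis`
#'   (first axis flagging it), `z` (loading z-score on that axis),
#'   `predictor` (max-|correlation| assignment), one correlation column
#'   per predictor. Zero rows when nothing exceeds the threshold.
#' @export
detect_candidates <- function(fit, g, sd_threshold = 2.5, n_axes = NULL) {
  if (is.null(n_axes)) n_axes <- length(fit$eig)
  n_axes <- min(n_axes, length(fit$eig))
  V <- fit$loadings[, seq_len(n_axes), drop = FALSE]
  z <- scale(V)                         # per-axis (x - mean) / sd
  hit <- abs(z) > sd_threshold
  loci_idx <- which(rowSums(hit) > 0)
  empty <- data.frame(locus = character(0), axis = character(0),
                      z = numeric(0), predictor = character(0),
                      stringsAsFactors = FALSE)
  if (length(loci_idx) == 0) {
    class(empty) <- c("candidate_set", "data.frame")
    return(empty)
  }
  first_axis <- apply(hit[loci_idx, , drop = FALSE], 1, which.max)
  Y <- impute_mean(snp_dosage(g))
  corr <- suppressWarnings(
    stats::cor(Y[, loci_idx, drop = FALSE], fit$X))
  corr[is.na(corr)] <- 0
  pred <- fit$predictors[apply(abs(corr), 1, which.max)]
  out <- data.frame(locus = fit$loci[loci_idx],
                    axis = colnames(V)[first_axis],
                    z = z[cbind(loci_idx, first_axis)],
                    predictor = pred, stringsAsFactors = FALSE)
  cc <- as.data.frame(corr)
  names(cc) <- paste0("cor_", fit$predictors)
  out <- cbind(out, cc)
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Categorise individuals by adaptive genotype
#'
#' The RDA is refitted on candidate loci only, constrained by one
#' predictor pair (climate: maximum temperature + summer precipitation;
#' topography: terrain ruggedness + wetness). Each individual's site
#' score is projected onto the unit-normalised biplot vector of each
#' predictor; the predictor with the largest absolute projection labels
#' the individual when that projection exceeds `threshold_t` standard
#' deviations of the projections, otherwise the individual is
#' "intermediate". Signs map to labels through `label_map`: by default
#' the temperature-type predictor maps positive/negative to the
#' `pos_label`/`neg_label` pair (warm/cold), while each topographic
#' predictor carries its own positive-side label (rough for ruggedness,
#' moist for wetness) — categories that are not opposite poles.
#'
#' @param g a [genotype_matrix()].
#' @param env an [env_table()].
#' @param locs a [locality_set()].
#' @param candidates a `candidate_set` from [detect_candidates()] (at
#'   least 2 candidate loci required).
#' @param predictor_pair character(2), predictors constraining the
#'   refit.
#' @param labels named list mapping each predictor of the pair to
#'   `c(pos, neg)` labels; `NA` for a side means no label (falls back to
#'   intermediate). Default climate: first predictor warm/cold;
#'   topography-style default can be supplied as e.g.
#'   `list(tri = c("rough", NA), cti = c("moist", NA))`.
#' @param threshold_t projection threshold in standard deviations
#'   (default 0.5; configurable because published analyses differ).
#' @return data.frame of class `adaptive_calls`: `individual`,
#'   `locality`, `category`, `projection`, plus attributes `fit`
#'   (the refit) and `pair`.
#' @export
categorise_individuals <- function(g, env, locs, candidates,
                                   predictor_pair,
                                   labels = NULL,
                                   threshold_t = 0.5) {
  stopifnot(length(predictor_pair) == 2)
  cand_loci <- unique(candidates$locus)
  if (length(cand_loci) < 2)
    stop("categorisation refused: fewer than 2 candidate loci")
  if (!all(predictor_pair %in% setdiff(names(env), "locality")))
    stop("predictor_pair not present in env table")
  if (is.null(labels)) {
    labels <- stats::setNames(
      list(c("warm", "cold"), c(NA, NA)), predictor_pair)
  }
  gsub_ <- g[, cand_loci]
  fit <- fit_rda(gsub_, env, locs, predictors = predictor_pair)
  # unit biplot vectors in the (<=2)-axis constrained plane
  bp <- fit$biplot
  bpu <- bp / sqrt(pmax(rowSums(bp^2), 1e-300))
  proj <- fit$site_scores %*% t(bpu)    # individuals x predictors
  sds <- apply(proj, 2, stats::sd)
  sds[sds == 0] <- 1
  cat_of <- function(i) {
    j <- which.max(abs(proj[i, ]))
    if (abs(proj[i, j]) > threshold_t * sds[j]) {
      lab <- labels[[predictor_pair[j]]]
      side <- if (proj[i, j] >= 0) 1 else 2
      if (!is.na(lab[side])) return(lab[side])
    }
    "intermediate"
  }
  category <- vapply(seq_len(nrow(proj)), cat_of, "")
  out <- data.frame(individual = g$ind,
                    locality = unname(locs$membership[g$ind]),
                    category = category,
                    projection = proj[cbind(seq_len(nrow(proj)),
                                            apply(abs(proj), 1, which.max))],
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "pair") <- predictor_pair
  class(out) <- c("adaptive_calls", "data.frame")
  out
}

#' Per-locality adaptive category proportions
#'
#' @param calls an `adaptive_calls` data.frame.
#' @param locs a [locality_set()].
#' @return data.frame: `locality`, one column per category, fractions
#'   summing to 1 per sampled locality.
#' @export
locality_proportions <- function(calls, locs) {
  cats <- sort(unique(calls$category))
  ids <- locality_ids(locs)
  out <- data.frame(locality = ids, stringsAsFactors = FALSE)
  for (ct in cats) out[[ct]] <- 0
  for (id in ids) {
    sub <- calls$category[calls$locality == id]
    if (length(sub) == 0) {
      out[out$locality == id, cats] <- NA_real_
      next
    }
    for (ct in cats)
      out[out$locality == id, ct] <- mean(sub == ct)
  }
  out
}

#' Convenience: full genotype-environment association analysis
#'
#' VIF screen, RDA fit, candidate detection, and individual
#' categorisation for the two conventional predictor pairs (climate and
#' topography) when those predictors are present.
#'
#' @inheritParams fit_rda
#' @param sd_threshold candidate threshold in loading SDs.
#' @param threshold_t categorisation projection threshold.
#' @param vif_threshold collinearity cut-off.
#' @param climate_pair,topo_pair predictor pairs for categorisation
#'   (skipped when not fully present among retained predictors).
#' @return list of class `gea_result`: `vif`, `fit`, `candidates`,
#'   `calls_climate`, `calls_topo`, `proportions_climate`,
#'   `proportions_topo` (the latter four `NULL` when not computable).
#' @export
run_gea <- function(g, env, locs, sd_threshold = 2.5, threshold_t = 0.5,
                    vif_threshold = 5,
                    climate_pair = c("bio5", "bio18"),
                    topo_pair = c("tri", "cti")) {
  scr <- vif_screen(env, vif_threshold)
  fit <- fit_rda(g, env, locs, predictors = scr$retained)
  cand <- detect_candidates(fit, g, sd_threshold = sd_threshold)
  res <- list(vif = scr, fit = fit, candidates = cand,
              calls_climate = NULL, calls_topo = NULL,
              proportions_climate = NULL, proportions_topo = NULL)
  if (nrow(cand) >= 2) {
    if (all(climate_pair %in% scr$retained)) {
      res$calls_climate <- categorise_individuals(
        g, env, locs, cand, climate_pair,
        labels = stats::setNames(list(c("warm", "cold"), c(NA, NA)),
                                 climate_pair),
        threshold_t = threshold_t)
      res$proportions_climate <- locality_proportions(res$calls_climate,
                                                      locs)
    }
    if (all(topo_pair %in% scr$retained)) {
      res$calls_topo <- categorise_individuals(
        g, env, locs, cand, topo_pair,
        labels = stats::setNames(list(c("rough", NA), c("moist", NA)),
                                 topo_pair),
        threshold_t = threshold_t)
      res$proportions_topo <- locality_proportions(res$calls_topo, locs)
    }
  }
  class(res) <- "gea_result"
  res
}
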
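#' Matrix-level locus filters
#'
#' Removes loci with low call rate and (for SNPs) low minor allele
#' frequency, in that order. Call rate is the fraction of individuals
#' with a non-missing genotype; MAF is computed over non-missing calls
#' only. A locus is dropped when call rate `< min_presence` or MAF
#' `< min_maf` (strict inequality: a locus exactly at a threshold is
#' kept). Order of surviving loci is preserved. Defaults mirror common
#' RAD-seq practice: 80% presence, 5% MAF.
#'
#' @param g a [genotype_matrix()].
#' @param min_presence minimum per-locus call rate in `[0, 1]`.
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`; applied
#'   to SNP loci only (microsatellite loci are never MAF-filtered, but a
#'   monomorphic locus of either class is dropped when `min_maf > 0`).
#' @return the filtered `genotype_matrix`; warns (does not error) when
#'   no locus survives.
#' @export
filter_matrix <- function(g, min_presence = 0.8, min_maf = 0.05) {
  stopifnot(min_presence >= 0, min_presence <= 1,
            min_maf >= 0, min_maf <= 0.5)
  keep <- locus_call_rate(g) >= min_presence
  if (min_maf > 0) {
    snp <- g$loci$marker_class == "snp"
    if (any(snp)) {
      d <- g$a1[, snp, drop = FALSE] + g$a2[, snp, drop = FALSE]
      p <- colMeans(d, na.rm = TRUE) / 2
      maf <- pmin(p, 1 - p)
      maf[is.nan(maf)] <- 0
      keep[snp] <- keep[snp] & maf >= min_maf
    }
    if (any(!snp)) {
      mono <- vapply(which(!snp), function(j) {
        av <- c(g$a1[, j], g$a2[, j])
        length(unique(av[!is.na(av)])) < 2
      }, TRUE)
      keep[!snp] <- keep[!snp] & !mono
    }
  }
  if (!any(keep)) warning("all loci removed by filters; matrix is empty")
  g[, which(keep)]
}

#' Per-individual call-rate filter
#'
#' Drops individuals genotyped at too few loci — e.g. microsatellite
#' panels where samples failing amplification at more than 30% of loci
#' are conventionally discarded (default `min_presence = 0.7`).
#'
#' @param g a [genotype_matrix()].
#' @param min_presence minimum fraction of loci with a call.
#' @return the filtered `genotype_matrix`.
#' @export
filter_individuals <- function(g, min_presence = 0.7) {
  stopifnot(min_presence >= 0, min_presence <= 1)
  keep <- individual_call_rate(g) >= min_presence
  if (!any(keep)) warning("all individuals removed by call-rate filter")
  g[which(keep), ]
}
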
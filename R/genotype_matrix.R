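`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Diploid genotype matrix
#'
#' Container for diploid genotype calls at SNP or microsatellite loci.
#' Calls are stored as two integer allele matrices (individuals x loci);
#' a missing genotype is `NA` in both. Allele pairs are unordered and
#' normalised so that `a1 <= a2`. SNP alleles are coded 0 (REF) / 1 (ALT);
#' microsatellite alleles are integer fragment/repeat sizes (no binning).
#'
#' @param a1,a2 integer matrices of identical dimension holding the two
#'   alleles of each call; rownames are individual ids, colnames locus ids.
#' @param marker_class character vector, one of `"snp"` or
#'   `"microsatellite"` per locus (recycled if length 1).
#' @return An object of class `genotype_matrix` with elements `ind`
#'   (individual ids), `loci` (data.frame with `id`, `marker_class`),
#'   `a1`, `a2`.
#' @examples
#' a1 <- matrix(c(0L, 0L, 1L, 0L), 2, 2,
#'              dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' a2 <- matrix(c(0L, 1L, 1L, 1L), 2, 2,
#'              dimnames = list(c("i1", "i2"), c("L1", "L2")))
#' g <- genotype_matrix(a1, a2, "snp")
#' n_ind(g); n_loci(g)
#' @export
genotype_matrix <- function(a1, a2, marker_class = "snp") {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  dn <- list(if (nrow(a1) > 0)
    rownames(a1) %||0% paste0("ind", seq_len(nrow(a1))),
    if (ncol(a1) > 0)
      colnames(a1) %||0% paste0("locus", seq_len(ncol(a1))))
  dimnames(a1) <- dimnames(a2) <- dn
  marker_class <- rep_len(as.character(marker_class), ncol(a1))
  if (!all(marker_class %in% c("snp", "microsatellite")))
    stop("marker_class must be 'snp' or 'microsatellite'")
  # one allele missing means the whole call is missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  # unordered pair: store sorted
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  g <- structure(
    list(ind = rownames(a1),
         loci = data.frame(id = colnames(a1), marker_class = marker_class,
                           stringsAsFactors = FALSE),
         a1 = a1, a2 = a2),
    class = "genotype_matrix")
  validate_genotype_matrix(g)
  g
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
validate_genotype_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyDuplicated(g$ind)) stop("individual ids must be unique")
  if (anyDuplicated(g$loci$id)) stop("locus ids must be unique")
  snp <- g$loci$marker_class == "snp"
  if (any(snp)) {
    av <- c(g$a1[, snp, drop = FALSE], g$a2[, snp, drop = FALSE])
    av <- av[!is.na(av)]
    if (length(av) && !all(av %in% c(0L, 1L)))
      stop("SNP loci must be bi-allelic with alleles coded 0/1")
  }
  invisible(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$loci$marker_class)
  cat("genotype_matrix:", length(x$ind), "individuals x",
      nrow(x$loci), "loci (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ind)
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(i)) i <- match(i, x$ind)
  if (is.character(j)) j <- match(j, x$loci$id)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  x$loci$marker_class[j])
}

#' Number of individuals / loci
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(g) length(g$ind)

#' @rdname n_ind
#' @export
n_loci <- function(g) nrow(g$loci)

#' Observed alleles per locus
#' @param g a `genotype_matrix`.
#' @return named list of sorted integer allele codes per locus.
#' @export
locus_alleles <- function(g) {
  L <- n_loci(g)
  out <- vector("list", L)
  for (j in seq_len(L)) {
    av <- c(g$a1[, j], g$a2[, j])
    out[[j]] <- sort(unique(av[!is.na(av)]))
  }
  names(out) <- g$loci$id
  out
}

#' Alternate-allele dosage matrix for SNP loci
#'
#' @param g a `genotype_matrix` whose loci are all SNPs.
#' @return numeric matrix individuals x loci with entries 0/1/2 or `NA`.
#' @export
snp_dosage <- function(g) {
  if (!all(g$loci$marker_class == "snp"))
    stop("snp_dosage() requires an all-SNP matrix")
  d <- g$a1 + g$a2
  storage.mode(d) <- "double"
  d
}

#' Per-locus call rate
#' @param g a `genotype_matrix`.
#' @return numeric vector, fraction of non-missing calls per locus.
#' @export
locus_call_rate <- function(g) colMeans(!is.na(g$a1))

#' Per-individual call rate
#' @param g a `genotype_matrix`.
#' @export
individual_call_rate <- function(g) rowMeans(!is.na(g$a1))

#' Minor allele frequency per SNP locus (over non-missing calls)
#' @param g an all-SNP `genotype_matrix`.
#' @return numeric vector in `[0, 0.5]`; `NaN` where no calls.
#' @export
snp_maf <- function(g) {
  d <- snp_dosage(g)
  p <- colMeans(d, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}
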
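#' Read a genotype matrix from standard file formats
#'
#' Supported dialects:
#' \describe{
#'   \item{`vcf`}{VCF 4.x, GT field only (via \pkg{vcfR}); `./.` is
#'     missing. Sites must be bi-allelic SNPs.}
#'   \item{`structure`}{Two-rows-per-individual text: a header line of
#'     whitespace-separated locus ids, then per individual two lines of
#'     `id allele1 allele2 ...` (one allele column per locus). Missing
#'     code `-9` (configurable).}
#'   \item{`csv012`}{CSV, first column `individual`, one column per SNP
#'     locus holding alternate-allele dosage 0/1/2 or `NA`.}
#'   \item{`msat_csv`}{CSV, first column `individual`, two columns per
#'     locus named `<locus>_1` and `<locus>_2` holding integer allele
#'     sizes or `NA`.}
#' }
#'
#' @param path file path.
#' @param format one of `"vcf"`, `"structure"`, `"csv012"`, `"msat_csv"`.
#' @param missing_code missing-allele code for the STRUCTURE dialect.
#' @param marker_class marker class recorded for `structure` input
#'   (`"microsatellite"` by default; STRUCTURE files may carry either).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path,
                           format = c("vcf", "structure", "csv012",
                                      "msat_csv"),
                           missing_code = -9L,
                           marker_class = "microsatellite") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = read_vcf_gt(path),
         structure = read_structure(path, missing_code, marker_class),
         csv012 = read_csv012(path),
         msat_csv = read_msat_csv(path))
}

read_vcf_gt <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop("no GT records in VCF: ", path)
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids))
    ids <- paste0("locus", seq_len(nrow(gt)))
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic site in VCF; SNP loci must be bi-allelic")
  parse_allele <- function(k) {
    a <- sub(paste0("^([^/|]*)[/|]([^/|]*)$"), paste0("\\", k), gt)
    a[a %in% c(".", "")] <- NA
    suppressWarnings(matrix(as.integer(a), nrow = nrow(gt)))
  }
  a1 <- t(parse_allele(1)); a2 <- t(parse_allele(2))
  rownames(a1) <- rownames(a2) <- colnames(gt)
  colnames(a1) <- colnames(a2) <- ids
  g <- genotype_matrix(a1, a2, "snp")
  g
}

read_structure <- function(path, missing_code, marker_class) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("malformed STRUCTURE file: ", path)
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  if (length(body) %% 2 != 0)
    stop("STRUCTURE file must have two rows per individual (line ",
         length(lines), ")")
  parse_row <- function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != length(loci) + 1)
      stop("malformed STRUCTURE record at line ", i + 1, ": expected ",
           length(loci) + 1, " fields, got ", length(f))
    f
  }
  n <- length(body) / 2
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  ids <- character(n)
  for (i in seq_len(n)) {
    r1 <- parse_row(2 * i - 1); r2 <- parse_row(2 * i)
    if (r1[1] != r2[1])
      stop("row pair mismatch at line ", 2 * i, ": ", r1[1], " vs ", r2[1])
    ids[i] <- r1[1]
    a1[i, ] <- as.integer(r1[-1]); a2[i, ] <- as.integer(r2[-1])
  }
  a1[a1 == missing_code] <- NA_integer_
  a2[a2 == missing_code] <- NA_integer_
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loci
  genotype_matrix(a1, a2, marker_class)
}

read_csv012 <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "individual")
    stop("csv012 requires first column 'individual'")
  ids <- as.character(df[[1]])
  d <- as.matrix(df[-1])
  if (!all(d[!is.na(d)] %in% 0:2))
    stop("csv012 entries must be 0/1/2 or NA")
  a1 <- ifelse(d == 2, 1L, 0L)
  a2 <- ifelse(d >= 1, 1L, 0L)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- colnames(d)
  genotype_matrix(a1, a2, "snp")
}

read_msat_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "individual")
    stop("msat_csv requires first column 'individual'")
  cols <- names(df)[-1]
  base <- sub("_(1|2)$", "", cols)
  loci <- unique(base)
  need <- c(paste0(loci, "_1"), paste0(loci, "_2"))
  if (!setequal(cols, need))
    stop("msat_csv requires paired columns '<locus>_1'/'<locus>_2'")
  a1 <- as.matrix(df[paste0(loci, "_1")])
  a2 <- as.matrix(df[paste0(loci, "_2")])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  rownames(a1) <- rownames(a2) <- as.character(df[[1]])
  colnames(a1) <- colnames(a2) <- loci
  genotype_matrix(a1, a2, "microsatellite")
}

#' Write a genotype matrix to a standard format
#'
#' Inverse of [read_genotypes()]; round-trips are exact for every
#' supported dialect. The VCF writer emits plain-text VCF 4.2 with GT
#' only (placeholder REF/ALT bases, since only allele indices are
#' modelled).
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format one of `"vcf"`, `"structure"`, `"csv012"`, `"msat_csv"`.
#' @param missing_code STRUCTURE missing code.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path,
                            format = c("vcf", "structure", "csv012",
                                       "msat_csv"),
                            missing_code = -9L) {
  format <- match.arg(format)
  switch(format,
         vcf = write_vcf_gt(g, path),
         structure = write_structure(g, path, missing_code),
         csv012 = write_csv012(g, path),
         msat_csv = write_msat_csv(g, path))
  invisible(path)
}

write_vcf_gt <- function(g, path) {
  if (!all(g$loci$marker_class == "snp"))
    stop("VCF output supported for SNP matrices only")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$ind), collapse = "\t"))
  gt <- matrix(paste(ifelse(is.na(g$a1), ".", g$a1),
                     ifelse(is.na(g$a2), ".", g$a2), sep = "/"),
               nrow = n_ind(g))
  rows <- vapply(seq_len(n_loci(g)), function(j) {
    paste(c("1", j, g$loci$id[j], "A", "C", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
}

write_structure <- function(g, path, missing_code = -9L) {
  enc <- function(m) {
    m[is.na(m)] <- as.integer(missing_code)
    m
  }
  a1 <- enc(g$a1); a2 <- enc(g$a2)
  out <- character(1 + 2 * n_ind(g))
  out[1] <- paste(g$loci$id, collapse = " ")
  for (i in seq_len(n_ind(g))) {
    out[2 * i]     <- paste(c(g$ind[i], a1[i, ]), collapse = " ")
    out[2 * i + 1] <- paste(c(g$ind[i], a2[i, ]), collapse = " ")
  }
  writeLines(out, path)
}

write_csv012 <- function(g, path) {
  d <- snp_dosage(g)
  df <- data.frame(individual = g$ind, d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
}

write_msat_csv <- function(g, path) {
  a1 <- g$a1; a2 <- g$a2
  colnames(a1) <- paste0(g$loci$id, "_1")
  colnames(a2) <- paste0(g$loci$id, "_2")
  ord <- as.vector(rbind(colnames(a1), colnames(a2)))
  df <- data.frame(individual = g$ind, a1, a2, check.names = FALSE)
  utils::write.csv(df[c("individual", ord)], path, row.names = FALSE)
}

#' Write/read report tables (CSV or JSON)
#'
#' Serialises any of the package's report data.frames with a stable
#' round-trip (`read_report_table(write_report_table(x))` equals `x` up
#' to numeric storage).
#'
#' @param x a data.frame report.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_report_table <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Read a locality table
#'
#' CSV with columns `id`, `name` (optional), `lat`, `lon`, optional
#' `provenance`; membership CSV with columns `individual`, `locality`.
#'
#' @param loc_path locality CSV path.
#' @param membership_path membership CSV path.
#' @return a [locality_set()].
#' @export
read_localities <- function(loc_path, membership_path) {
  loc <- utils::read.csv(loc_path, stringsAsFactors = FALSE)
  mem <- utils::read.csv(membership_path, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "locality") %in% names(mem)))
  locality_set(loc, stats::setNames(as.character(mem$locality),
                                    mem$individual))
}

#' Read an environmental predictor table from CSV
#' @param path CSV with a `locality` column plus numeric predictors.
#' @param predictors optional predictor subset.
#' @return an [env_table()].
#' @export
read_env_table <- function(path, predictors = NULL) {
  env_table(utils::read.csv(path, stringsAsFactors = FALSE), predictors)
}
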
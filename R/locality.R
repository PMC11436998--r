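#' Sampling localities and individual membership
#'
#' @param localities data.frame with columns `id`, `name` (optional,
#'   defaults to `id`), `lat`, `lon` (WGS84 decimal degrees) and optionally
#'   `provenance` (`"autochthonous"`, `"suspected_introduction"` or
#'   `"unknown"`; defaults to `"unknown"`).
#' @param membership named character vector mapping individual id ->
#'   locality id.
#' @return object of class `locality_set`.
#' @export
locality_set <- function(localities, membership) {
  localities <- as.data.frame(localities, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "lat", "lon") %in% names(localities)))
  localities$id <- as.character(localities$id)
  if (is.null(localities$name)) localities$name <- localities$id
  if (is.null(localities$provenance))
    localities$provenance <- rep("unknown", nrow(localities))
  ok <- localities$provenance %in%
    c("autochthonous", "suspected_introduction", "unknown")
  if (!all(ok)) stop("invalid provenance flag")
  if (anyDuplicated(localities$id)) stop("locality ids must be unique")
  if (any(abs(localities$lat) > 90) || any(abs(localities$lon) > 180))
    stop("coordinates outside valid WGS84 range")
  membership <- vapply(membership, as.character, "")
  if (length(membership) &&
      (is.null(names(membership)) || anyDuplicated(names(membership))))
    stop("membership must be named by unique individual ids")
  if (!all(membership %in% localities$id))
    stop("membership refers to unknown locality ids")
  structure(list(localities = localities, membership = membership),
            class = "locality_set")
}

#' @export
print.locality_set <- function(x, ...) {
  cat("locality_set:", nrow(x$localities), "localities,",
      length(x$membership), "individuals\n")
  invisible(x)
}

#' Locality ids in table order
#' @param locs a `locality_set`.
#' @export
locality_ids <- function(locs) locs$localities$id

#' Indices of a genotype matrix's individuals grouped by locality
#'
#' @param g a `genotype_matrix`.
#' @param locs a `locality_set`; every individual of `g` must be mapped.
#' @return named list of integer row indices, one element per locality
#'   (localities without sampled individuals get an empty vector).
#' @export
locality_indices <- function(g, locs) {
  miss <- setdiff(g$ind, names(locs$membership))
  if (length(miss))
    stop("individuals without locality membership: ",
         paste(utils::head(miss, 5), collapse = ", "))
  memb <- locs$membership[g$ind]
  out <- lapply(locality_ids(locs), function(id) which(memb == id))
  names(out) <- locality_ids(locs)
  out
}

#' Environmental predictor table
#'
#' One row per locality, continuous predictors in source units.
#'
#' @param df data.frame with a `locality` column plus numeric predictor
#'   columns (e.g. `bio5`, `bio18`, `tri`, `cti`).
#' @param predictors which columns to validate/keep; default all non-id.
#' @return data.frame of class `env_table` (locality ids as rownames too).
#' @export
env_table <- function(df, predictors = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot("locality" %in% names(df))
  df$locality <- as.character(df$locality)
  if (anyDuplicated(df$locality)) stop("one row per locality required")
  if (is.null(predictors)) predictors <- setdiff(names(df), "locality")
  num <- vapply(df[predictors], is.numeric, TRUE)
  if (!all(num)) stop("predictors must be numeric")
  if (anyNA(df[predictors]))
    stop("missing values among selected predictors")
  out <- df[c("locality", predictors)]
  rownames(out) <- out$locality
  class(out) <- c("env_table", "data.frame")
  out
}

#' Expand locality-level predictors to individuals
#'
#' Environmental values are constant within a locality; each individual
#' receives its locality's row.
#'
#' @param env an `env_table`.
#' @param g a `genotype_matrix`.
#' @param locs a `locality_set`.
#' @return numeric matrix individuals x predictors.
#' @export
env_per_individual <- function(env, g, locs) {
  memb <- locs$membership[g$ind]
  if (!all(memb %in% env$locality))
    stop("env table lacks rows for localities: ",
         paste(setdiff(memb, env$locality), collapse = ", "))
  m <- as.matrix(env[match(memb, env$locality),
                     setdiff(names(env), "locality"), drop = FALSE])
  rownames(m) <- g$ind
  m
}
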
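#' Configuration for the translocation decision framework
#'
#' All thresholds of the rule set in one block; the decision report
#' echoes the values used.
#'
#' @param diversity_quantile localities below this quantile of A_R and
#'   H_O count as low-diversity (concern flagging).
#' @param isolation_quantile localities above this quantile of mean
#'   linearised F_ST or mean geographic distance count as isolated.
#' @param majority_frac fraction above which an adaptive category is
#'   "held" by a locality (opposite-pole compatibility rule).
#' @param theta_max maximum tolerated pairwise theta between donor and
#'   recipient (soft differentiation bound).
#' @param diversity_tolerance slack allowed when requiring donor
#'   diversity to be at least the recipient's.
#' @param connectivity_quantile pairs with linearised F_ST and distance
#'   at or below this quantile of all pairs count as connected.
#' @param opposite_poles list of length-2 character vectors naming
#'   mutually incompatible adaptive categories (warm vs cold by
#'   default; rough/moist are non-opposing).
#' @return list of class `decision_config`.
#' @export
decision_config <- function(diversity_quantile = 0.25,
                            isolation_quantile = 0.75,
                            majority_frac = 0.5,
                            theta_max = 0.3,
                            diversity_tolerance = 0.05,
                            connectivity_quantile = 0.5,
                            opposite_poles = list(c("warm", "cold"))) {
  structure(list(diversity_quantile = diversity_quantile,
                 isolation_quantile = isolation_quantile,
                 majority_frac = majority_frac,
                 theta_max = theta_max,
                 diversity_tolerance = diversity_tolerance,
                 connectivity_quantile = connectivity_quantile,
                 opposite_poles = opposite_poles),
            class = "decision_config")
}

#' Assemble the inputs of the decision framework
#'
#' All components are optional except the locality set; rules whose
#' inputs are missing return `"not_evaluable"` rather than silently
#' passing.
#'
#' @param locs a [locality_set()].
#' @param diversity a `diversity_report` (or `NULL`).
#' @param fst an `fst_matrix` (or `NULL`).
#' @param clusters named vector locality -> cluster label (or `NULL`);
#'   e.g. [majority_cluster()] output or externally supplied labels.
#' @param adaptive named list of per-locality category-proportion
#'   data.frames from [locality_proportions()] (e.g.
#'   `list(climate = ..., topo = ...)`), or `NULL`.
#' @param geo geographic distance matrix (default: computed from
#'   `locs`).
#' @param habitat named logical vector locality -> recipient habitat
#'   suitability (externally supplied), or `NULL`.
#' @return list of class `decision_inputs`.
#' @export
decision_inputs <- function(locs, diversity = NULL, fst = NULL,
                            clusters = NULL, adaptive = NULL,
                            geo = NULL, habitat = NULL) {
  ids <- locality_ids(locs)
  chk <- function(x, what) {
    if (is.null(x)) return(NULL)
    x
  }
  if (!is.null(fst) && !all(rownames(fst$theta) %in% ids))
    stop("fst matrix indexed by unknown localities")
  if (is.null(geo)) geo <- geo_distances(locs)
  structure(list(locs = locs, ids = ids, diversity = diversity,
                 fst = fst,
                 linearised = if (is.null(fst)) NULL else
                   rousset_linearise(fst, floor_negative = TRUE),
                 clusters = clusters, adaptive = adaptive, geo = geo,
                 habitat = habitat),
            class = "decision_inputs")
}

#' Flag localities of conservation concern
#'
#' A locality is flagged when its diversity (both rarefied allelic
#' richness and observed heterozygosity) falls below the configured
#' quantile of the locality distribution AND it is isolated — mean
#' pairwise linearised F_ST above the isolation quantile OR mean
#' geographic distance to the other localities above it.
#'
#' @param inputs a [decision_inputs()].
#' @param config a [decision_config()].
#' @return data.frame: `locality`, `flagged`, `reasons` (semicolon-
#'   separated), plus the intermediate metrics.
#' @export
flag_concern <- function(inputs, config = decision_config()) {
  ids <- inputs$ids
  if (length(ids) == 0)
    return(data.frame(locality = character(0), flagged = logical(0),
                      reasons = character(0), stringsAsFactors = FALSE))
  div <- inputs$diversity
  if (is.null(div) || is.null(inputs$linearised))
    stop("flag_concern needs diversity and fst components")
  m <- match(ids, div$locality)
  ar <- div$ar[m]; ho <- div$ho[m]
  lin <- inputs$linearised
  geo <- inputs$geo
  present <- ids[ids %in% rownames(lin)]
  mean_off <- function(M, id)
    mean(M[id, setdiff(present, id)], na.rm = TRUE)
  mean_lin <- vapply(ids, function(id)
    if (id %in% present && length(present) > 1) mean_off(lin, id)
    else NA_real_, 0)
  mean_geo <- vapply(ids, function(id)
    mean(geo[id, setdiff(ids, id)], na.rm = TRUE), 0)
  q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE)
  # boundary quantiles disable the respective criterion entirely
  if (config$diversity_quantile > 0) {
    low_ar <- !is.na(ar) & ar <= q(ar, config$diversity_quantile)
    low_ho <- !is.na(ho) & ho <= q(ho, config$diversity_quantile)
  } else {
    low_ar <- low_ho <- rep(FALSE, length(ids))
  }
  if (config$isolation_quantile < 1) {
    iso_gen <- !is.na(mean_lin) &
      mean_lin >= q(mean_lin, config$isolation_quantile)
    iso_geo <- mean_geo >= q(mean_geo, config$isolation_quantile)
  } else {
    iso_gen <- iso_geo <- rep(FALSE, length(ids))
  }
  flag <- low_ar & low_ho & (iso_gen | iso_geo)
  reasons <- vapply(seq_along(ids), function(i) {
    if (!flag[i]) return("")
    r <- c("low allelic richness", "low heterozygosity",
           if (iso_gen[i]) "genetically isolated",
           if (iso_geo[i]) "geographically remote")
    paste(r, collapse = "; ")
  }, "")
  data.frame(locality = ids, flagged = flag, reasons = reasons,
             ar = ar, ho = ho, mean_linearised_fst = mean_lin,
             mean_geo_distance = mean_geo, stringsAsFactors = FALSE)
}

held_categories <- function(prop_row, majority_frac) {
  cats <- setdiff(names(prop_row), "locality")
  vals <- unlist(prop_row[cats])
  cats[!is.na(vals) & vals > majority_frac]
}

#' Evaluate the translocation rule set for one donor-recipient pair
#'
#' Hard rules (any fail disqualifies the pair): `same_cluster`
#' (majority cluster labels equal), `adaptive_compatibility` (no
#' category held by more than `majority_frac` of the donor that is the
#' opposite pole of one held by the recipient — warm vs cold;
#' rough/moist do not oppose), `provenance` (donor not flagged as a
#' suspected introduction). Soft rules: `donor_diversity` (donor A_R
#' and H_O at least the recipient's minus a tolerance),
#' `donor_inbreeding` (donor F_IS confidence interval does not sit
#' wholly above zero), `differentiation_bound` (pairwise theta at most
#' `theta_max`), `connectivity` (linearised F_ST and distance at or
#' below the configured quantile of all pairs), `habitat_suitability`
#' (recipient flagged suitable). Rules lacking inputs return
#' `"not_evaluable"`.
#'
#' @param donor,recipient locality ids (must differ).
#' @param inputs a [decision_inputs()].
#' @param config a [decision_config()].
#' @return named character vector of verdicts in
#'   `{"pass", "fail", "not_evaluable"}`.
#' @export
evaluate_pair <- function(donor, recipient, inputs,
                          config = decision_config()) {
  if (identical(donor, recipient))
    stop("degenerate pair: donor and recipient are the same locality")
  stopifnot(donor %in% inputs$ids, recipient %in% inputs$ids)
  verdict <- function(cond) {
    if (is.na(cond)) "not_evaluable" else if (cond) "pass" else "fail"
  }
  out <- c(same_cluster = NA, adaptive_compatibility = NA,
           provenance = NA, donor_diversity = NA, donor_inbreeding = NA,
           differentiation_bound = NA, connectivity = NA,
           habitat_suitability = NA)
  res <- character(0)

  # same_cluster
  cl <- inputs$clusters
  res["same_cluster"] <- verdict(
    if (is.null(cl) || !all(c(donor, recipient) %in% names(cl)) ||
        anyNA(cl[c(donor, recipient)])) NA
    else cl[[donor]] == cl[[recipient]])

  # adaptive_compatibility
  res["adaptive_compatibility"] <- verdict(adaptive_compatible(
    donor, recipient, inputs$adaptive, config))

  # provenance
  prov <- inputs$locs$localities$provenance[
    match(donor, inputs$locs$localities$id)]
  res["provenance"] <- verdict(
    if (is.na(prov)) NA else prov != "suspected_introduction")

  # donor_diversity / donor_inbreeding
  div <- inputs$diversity
  if (is.null(div)) {
    res["donor_diversity"] <- res["donor_inbreeding"] <- "not_evaluable"
  } else {
    d <- div[match(donor, div$locality), ]
    r <- div[match(recipient, div$locality), ]
    res["donor_diversity"] <- verdict(
      if (anyNA(c(d$ar, d$ho, r$ar, r$ho))) NA
      else d$ar >= r$ar - config$diversity_tolerance &&
        d$ho >= r$ho - config$diversity_tolerance)
    res["donor_inbreeding"] <- verdict(
      if (is.na(d$fis_lower)) NA else !(d$fis_lower > 0))
  }

  # differentiation_bound / connectivity
  fst <- inputs$fst
  if (is.null(fst) || !all(c(donor, recipient) %in% fst$localities)) {
    res["differentiation_bound"] <- res["connectivity"] <- "not_evaluable"
  } else {
    th <- fst$theta[donor, recipient]
    res["differentiation_bound"] <- verdict(th <= config$theta_max)
    lin <- inputs$linearised
    offdiag <- lin[lower.tri(lin)]
    geo <- inputs$geo
    geo_off <- geo[fst$localities, fst$localities][lower.tri(lin)]
    qlin <- stats::quantile(offdiag, config$connectivity_quantile,
                            names = FALSE)
    qgeo <- stats::quantile(geo_off, config$connectivity_quantile,
                            names = FALSE)
    res["connectivity"] <- verdict(
      lin[donor, recipient] <= qlin &&
        geo[donor, recipient] <= qgeo)
  }

  # habitat_suitability (recipient side)
  hab <- inputs$habitat
  res["habitat_suitability"] <- verdict(
    if (is.null(hab) || !(recipient %in% names(hab))) NA
    else isTRUE(hab[[recipient]]))

  res[names(out)]
}

adaptive_compatible <- function(donor, recipient, adaptive, config) {
  if (is.null(adaptive) || length(adaptive) == 0) return(NA)
  ok <- TRUE
  seen <- FALSE
  for (tab in adaptive) {
    if (!all(c(donor, recipient) %in% tab$locality)) next
    dh <- held_categories(tab[tab$locality == donor, , drop = FALSE],
                          config$majority_frac)
    rh <- held_categories(tab[tab$locality == recipient, , drop = FALSE],
                          config$majority_frac)
    if (anyNA(dh) || anyNA(rh)) next
    seen <- TRUE
    for (pp in config$opposite_poles) {
      if ((pp[1] %in% dh && pp[2] %in% rh) ||
          (pp[2] %in% dh && pp[1] %in% rh)) ok <- FALSE
    }
  }
  if (!seen) return(NA)
  ok
}

HARD_RULES <- c("same_cluster", "adaptive_compatibility", "provenance")
SOFT_RULES <- c("donor_diversity", "donor_inbreeding",
                "differentiation_bound", "connectivity",
                "habitat_suitability")

#' Rank all donor-recipient pairs
#'
#' Every ordered pair of distinct localities is evaluated with
#' [evaluate_pair()] and ranked by: number of hard-rule passes
#' (descending), number of soft-rule passes (descending), pairwise
#' theta (ascending, missing last), geographic distance (ascending),
#' then donor and recipient id — a deterministic total order. A pair
#' with any hard-rule fail can never outrank an all-pass pair, and a
#' pair is `all_pass` only when every rule evaluates to pass.
#'
#' @param inputs a [decision_inputs()].
#' @param config a [decision_config()].
#' @return list of class `decision_report`: `pairs` (ranked data.frame
#'   with per-rule verdicts, counts and a free-text trace), `concern`
#'   (from [flag_concern()] when computable), `config`.
#' @export
rank_pairs <- function(inputs, config = decision_config()) {
  ids <- inputs$ids
  pairs <- expand.grid(donor = ids, recipient = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$donor != pairs$recipient, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- pairs$donor[i]; r <- pairs$recipient[i]
    v <- evaluate_pair(d, r, inputs, config)
    th <- if (!is.null(inputs$fst) &&
              all(c(d, r) %in% inputs$fst$localities))
      inputs$fst$theta[d, r] else NA_real_
    geo <- inputs$geo[d, r]
    trace <- paste0(names(v), "=", v, collapse = "; ")
    c(list(donor = d, recipient = r), as.list(v),
      list(hard_passes = sum(v[HARD_RULES] == "pass"),
           soft_passes = sum(v[SOFT_RULES] == "pass"),
           hard_fails = sum(v[HARD_RULES] == "fail"),
           all_pass = all(v == "pass"),
           theta = th, distance = geo, trace = trace))
  })
  df <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  ord <- order(-df$hard_passes, -df$soft_passes,
               xtfrm(ifelse(is.na(df$theta), Inf, df$theta)),
               df$distance, df$donor, df$recipient)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  concern <- tryCatch(flag_concern(inputs, config), error = function(e) NULL)
  structure(list(pairs = df, concern = concern, config = config),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, n = 10, ...) {
  cat("decision_report:", nrow(x$pairs), "ranked donor->recipient pairs\n")
  cols <- c("rank", "donor", "recipient", "hard_passes", "soft_passes",
            "all_pass", "theta", "distance")
  print(utils::head(x$pairs[cols], n))
  if (!is.null(x$concern) && any(x$concern$flagged)) {
    cat("localities of concern:",
        paste(x$concern$locality[x$concern$flagged], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Serialise a decision report to JSON (stable byte-for-byte)
#'
#' @param report a `decision_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string invisibly (and writes `path` if given).
#' @export
write_decision_report <- function(report, path = NULL) {
  obj <- list(config = unclass(report$config),
              pairs = report$pairs,
              concern = report$concern)
  js <- jsonlite::toJSON(obj, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}
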
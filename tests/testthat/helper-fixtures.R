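# hand-built locality panel: four localities, two clusters, one
# suspected introduction, contrasting adaptive categories
framework_fixture <- function() {
  ids <- c("Salz", "Thue", "Tuch", "Ober")
  locs <- locality_set(
    data.frame(id = ids,
               lat = c(52.06, 52.02, 51.95, 52.27),
               lon = c(9.60, 9.65, 9.59, 9.21),
               provenance = c("autochthonous", "autochthonous",
                              "autochthonous", "suspected_introduction")),
    setNames(rep(ids, each = 2), paste0(rep(ids, each = 2), 1:2)))
  div <- data.frame(
    locality = ids, n = c(17, 26, 18, 17), flagged = FALSE,
    pa = c(0.06, 0.02, 0.02, 0.14), pa_raw = c(0, 0, 0, 3),
    ar = c(1.47, 1.27, 1.23, 1.34),
    ho = c(0.44, 0.41, 0.39, 0.40), he = c(0.23, 0.25, 0.23, 0.23),
    fis = c(0.01, -0.06, -0.06, -0.02),
    fis_lower = c(-0.1, -0.2, -0.2, -0.1),
    fis_upper = c(0.1, 0.05, 0.05, 0.05),
    fis_significant = FALSE, stringsAsFactors = FALSE)
  theta <- matrix(0.35, 4, 4, dimnames = list(ids, ids))
  theta["Salz", "Thue"] <- theta["Thue", "Salz"] <- 0.05
  theta["Tuch", "Ober"] <- theta["Ober", "Tuch"] <- 0.30
  diag(theta) <- 0
  fst <- structure(list(theta = theta, lower = theta - 0.02,
                        upper = theta + 0.02, localities = ids),
                   class = "fst_matrix")
  clusters <- c(Salz = "green", Thue = "green", Tuch = "green",
                Ober = "blue")
  climate <- data.frame(locality = ids,
                        warm = c(0.1, 0.0, 0.6, 0.0),
                        cold = c(0.0, 0.0, 0.0, 1.0),
                        intermediate = c(0.9, 1.0, 0.4, 0.0),
                        stringsAsFactors = FALSE)
  topo <- data.frame(locality = ids,
                     rough = c(0.0, 0.1, 0.2, 0.2),
                     moist = c(0.8, 0.8, 0.3, 0.2),
                     intermediate = c(0.2, 0.1, 0.5, 0.6),
                     stringsAsFactors = FALSE)
  habitat <- c(Salz = TRUE, Thue = TRUE, Tuch = TRUE, Ober = TRUE)
  decision_inputs(locs, diversity = div, fst = fst, clusters = clusters,
                  adaptive = list(climate = climate, topo = topo),
                  habitat = habitat)
}
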
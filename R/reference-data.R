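# Synthetic stand-in for the study's archived occurrence tables.
#
# The original supplementary coordinate tables are not redistributable
# here, but their published summary structure is: 319 focal-species
# (woodpecker) records that collapse to 113 distinct 1-km sites under
# spatial thinning, and 117 resource-species (oak) records.  The
# generator below reproduces that structure exactly by construction: the
# focal records form 113 clusters, each with diameter well under 1 km,
# with all between-cluster point distances well above 1 km.  Any maximal
# 1-km thinning of such a configuration -- greedy, randomized, or the
# exact maximum independent set -- retains exactly one point per cluster.

#' Synthetic occurrence archive mirroring the study's data structure
#'
#' Generates two synthetic occurrence tables shaped like the archived
#' survey data the pipeline was designed for: a focal-species table of
#' `n_focal` records clustered into `n_sites` sub-kilometer sites
#' (so 1-km thinning retains exactly `n_sites` records), and a
#' resource-species table of `n_resource` herbarium-style records.
#' Coordinates fall in a montane band of the default modeling extent
#' (77W--72.2W, 1N--10N).  All focal records carry effort metadata that
#' passes the record-acceptance filter, emulating a pre-filtered archive.
#'
#' @param n_focal Total focal-species records (default 319).
#' @param n_sites Number of distinct 1-km sites among them (default 113).
#' @param n_resource Resource-species records (default 117).
#' @param seed Integer seed; the shipped `inst/extdata` CSVs use the
#'   default `seed = 20150617`.
#' @return List with elements `focal` and `resource`, both
#'   [occurrence_set()]s.
#' @examples
#' arch <- synthetic_reference_occurrences()
#' nrow(arch$focal)     # 319
#' nrow(arch$resource)  # 117
#' @export
synthetic_reference_occurrences <- function(n_focal = 319, n_sites = 113,
                                            n_resource = 117,
                                            seed = 20150617) {
  stopifnot(n_focal >= n_sites, n_sites >= 1, n_resource >= 1)
  with_local_seed(seed, {
    # candidate site lattice at 0.06 deg (~6.6 km): jitter of up to
    # +/-0.008 deg keeps every inter-site distance > 3 km
    lons <- seq(-77, -72.2, by = 0.06)
    lats <- seq(1, 10, by = 0.06)
    cand <- expand.grid(longitude = lons, latitude = lats)
    pick <- cand[sample.int(nrow(cand), n_sites), ]
    site_lon <- pick$longitude + stats::runif(n_sites, -0.008, 0.008)
    site_lat <- pick$latitude + stats::runif(n_sites, -0.008, 0.008)

    # one record per site, plus satellites within 200 m of their site
    site_of <- c(seq_len(n_sites),
                 sample.int(n_sites, n_focal - n_sites, replace = TRUE))
    r_km <- c(rep(0, n_sites), stats::runif(n_focal - n_sites, 0.02, 0.2))
    bearing <- stats::runif(n_focal, 0, 2 * pi)
    dlat <- r_km * cos(bearing) / 111.195
    dlon <- r_km * sin(bearing) /
      (111.195 * cos(site_lat[site_of] * pi / 180))
    lon <- site_lon[site_of] + dlon
    lat <- site_lat[site_of] + dlat

    protocol <- sample(c("stationary", "traveling", "area", "specimen"),
                       n_focal, replace = TRUE,
                       prob = c(0.45, 0.3, 0.1, 0.15))
    distance_km <- ifelse(protocol == "traveling",
                          round(stats::runif(n_focal, 0.2, 4.9), 2),
                          NA_real_)
    area_km2 <- ifelse(protocol == "area",
                       round(stats::runif(n_focal, 0.05, 0.95), 2),
                       NA_real_)
    ord <- sample.int(n_focal)   # shuffle so clusters are not contiguous
    focal <- occurrence_set(data.frame(
      longitude = lon[ord], latitude = lat[ord],
      protocol = protocol[ord], distance_km = distance_km[ord],
      area_km2 = area_km2[ord],
      source_id = sprintf("syn-focal-%04d", seq_len(n_focal))),
      species = "synthetic-woodpecker")

    resource <- occurrence_set(data.frame(
      longitude = stats::runif(n_resource, -76.8, -72.5),
      latitude = stats::runif(n_resource, 1.2, 9.8),
      protocol = "specimen", distance_km = NA_real_, area_km2 = NA_real_,
      source_id = sprintf("syn-oak-%04d", seq_len(n_resource))),
      species = "synthetic-oak")

    list(focal = focal, resource = resource)
  })
}
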
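# Clustering site points into candidate sites: neighbour-count support
# filter, single-linkage joining with the dthresh cut, size ranking and
# grid-cell volume.

#' Support-filter site points
#'
#' Retains points that have at least `nthresh` other site points within
#' `neighbor_radius` (1.76 A, the square root of the squared-distance
#' threshold). Applied once, without iteration.
#'
#' @param points n x 3 matrix of site-point coordinates
#' @param cfg [detection_config()]
#' @return filtered coordinate matrix
#' @export
filter_supported_points <- function(points, cfg = detection_config()) {
  if (nrow(points) == 0) return(points)
  counts <- cpp_neighbor_count(points, cfg$neighbor_radius)
  points[counts >= cfg$nthresh, , drop = FALSE]
}

#' Cluster site points into sites
#'
#' Single-linkage clustering cut at `dthresh`: two groups are joined when
#' their closest points are closer than `dthresh`. Clusters smaller than
#' `mingroup` are discarded.
#'
#' @param points n x 3 matrix of (supported) site points
#' @param cfg [detection_config()]
#' @return list of `site` objects sorted by descending point count; each has
#'   `points`, `n`, `volume` (A^3), `centroid`, and `site_id`
#' @export
cluster_sites <- function(points, cfg = detection_config()) {
  if (nrow(points) == 0) return(list())
  labels <- cpp_cluster_threshold(points, cfg$dthresh)
  sites <- lapply(sort(unique(labels)), function(l) {
    pts <- points[labels == l, , drop = FALSE]
    if (nrow(pts) < cfg$mingroup) return(NULL)
    new_site(pts, cfg)
  })
  sites <- Filter(Negate(is.null), sites)
  ord <- order(-vapply(sites, function(s) s$n, numeric(1)))
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$site_id <- i
  sites
}

new_site <- function(pts, cfg) {
  structure(list(
    site_id = NA_integer_, points = pts, n = nrow(pts),
    volume = site_volume_points(pts, cfg), centroid = colMeans(pts),
    rank = NA_integer_, descriptors = NULL
  ), class = "site")
}

#' Rank sites and keep the largest
#'
#' Top `max_sites` sites by site-point count; ties broken by larger volume,
#' then by lexicographically smaller centroid so the order is reproducible.
#'
#' @param sites list of `site`
#' @param cfg [detection_config()]
#' @return ranked list of at most `max_sites` sites
#' @export
rank_sites <- function(sites, cfg = detection_config()) {
  if (!length(sites)) return(sites)
  cent <- t(vapply(sites, function(s) s$centroid, numeric(3)))
  ord <- order(-vapply(sites, function(s) s$n, numeric(1)),
               -vapply(sites, function(s) s$volume, numeric(1)),
               cent[, 1], cent[, 2], cent[, 3])
  sites <- sites[ord]
  sites <- utils::head(sites, cfg$max_sites)
  for (i in seq_along(sites)) {
    sites[[i]]$rank <- i
    sites[[i]]$site_id <- i
  }
  sites
}

site_volume_points <- function(pts, cfg) {
  nrow(unique(round(pts / cfg$grid_spacing))) * cfg$grid_spacing^3
}

#' Site volume from occupied grid cells
#'
#' Volume is the number of distinct occupied grid cells times the cell
#' volume (`spacing^3`).
#'
#' @param site a `site`
#' @param cfg [detection_config()]
#' @return volume in A^3
#' @export
site_volume <- function(site, cfg = detection_config()) {
  site_volume_points(site$points, cfg)
}

#' Detect and rank candidate sites on a structure
#'
#' Runs the full geometric pipeline: grid fields, site-point marking,
#' support filter, clustering, ranking, and descriptor computation.
#'
#' @param s `prepared_structure`
#' @param cfg [detection_config()]
#' @param weights [score_weights()]
#' @param bounds optional grid bounds (see [build_grid()])
#' @return list with `sites` (ranked, with descriptors) and `grid`
#' @export
detect_sites <- function(s, cfg = detection_config(), weights = score_weights(),
                         bounds = NULL) {
  g <- compute_site_grid(s, cfg, bounds = bounds)
  pts <- g$coords[g$is_site_point, , drop = FALSE]
  pts <- filter_supported_points(pts, cfg)
  sites <- rank_sites(cluster_sites(pts, cfg), cfg)
  sites <- lapply(sites, function(site) {
    site$descriptors <- site_descriptors(site, g, cfg, weights)
    site
  })
  list(sites = sites, grid = g)
}

#' Serialize sites as JSON
#' @param sites list of `site`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sites_json <- function(sites, path) {
  jsonlite::write_json(lapply(sites, function(s) {
    c(list(site_id = s$site_id, n = s$n, volume = s$volume,
           centroid = s$centroid, rank = s$rank),
      if (!is.null(s$descriptors)) unclass(s$descriptors))
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.site <- function(x, ...) {
  cat("site", x$site_id, ": n =", x$n, ", V =", round(x$volume, 1), "A^3")
  if (!is.null(x$descriptors))
    cat(", Dscore+ =", x$descriptors$dscore_plus_reported)
  cat("\n")
  invisible(x)
}
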
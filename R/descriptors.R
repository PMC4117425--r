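# Site-level descriptors and the druggability scores. Dscore is a weighted
# sum of pocket size (sqrt of the site-point count), enclosure, and a
# negative hydrophilic contribution; Dscore+ adds 0.3 times the hydrophobic
# score. Reported scores are rounded half-away-from-zero to one decimal.

#' Mean enclosure over the points of a site
#'
#' @param site a `site`
#' @param grid the populated `site_grid` it was detected on
#' @return arithmetic mean enclosure fraction in [0, 1]
#' @export
enclosure_score <- function(site, grid) {
  mean(field_at_points(grid, site$points, "enclosure"))
}

# look up a per-point grid field at site-point coordinates
field_at_points <- function(grid, pts, field) {
  ijk <- round(sweep(pts, 2, grid$origin) / grid$spacing)
  lin <- 1 + ijk[, 1] + grid$dims[1] * (ijk[, 2] + grid$dims[2] * ijk[, 3])
  grid[[field]][lin]
}

#' Site descriptors including Dscore and Dscore+
#'
#' The size term uses a volume-equivalent site-point count at the reference
#' spacing `score_count_spacing` (`n_eff = V / spacing_ref^3`), which keeps
#' the score on its conventional scale independently of the fine detection
#' grid. `e` is the mean site-point enclosure, `h`/`p` the mean normalized
#' hydrophobic/hydrophilic potentials.
#'
#' @param site a `site`
#' @param grid populated `site_grid`
#' @param cfg [detection_config()]
#' @param weights [score_weights()]
#' @return `site_descriptors`: e, n, n_eff, V, h, p, dscore, dscore_plus,
#'   and their one-decimal reported values
#' @export
site_descriptors <- function(site, grid, cfg = detection_config(),
                             weights = score_weights()) {
  e <- enclosure_score(site, grid)
  h <- mean(field_at_points(grid, site$points, "phobic"))
  p <- mean(field_at_points(grid, site$points, "philic"))
  V <- site$volume
  n_eff <- V / cfg$score_count_spacing^3
  d <- dscore(list(e = e, n = n_eff, p = p), weights)
  dp <- dscore_plus(d, h)
  structure(list(
    e = e, n = site$n, n_eff = n_eff, V = V, h = h, p = p,
    dscore = d, dscore_plus = dp,
    dscore_reported = round_half_away(d, 1),
    dscore_plus_reported = round_half_away(dp, 1)
  ), class = "site_descriptors")
}

#' Dscore: weighted-sum druggability score
#'
#' `dscore = w_size * sqrt(n) + w_enclosure * e - w_philic * min(p, philic_cap)`
#'
#' @param d list or `site_descriptors` with `e`, `n`, `p`
#' @param w [score_weights()]
#' @return unrounded score
#' @export
dscore <- function(d, w = score_weights()) {
  if (is.null(d$n) || is.na(d$n) || d$n <= 0) stop("undefined site: n must be positive")
  w$w_size * sqrt(d$n) + w$w_enclosure * d$e - w$w_philic * min(d$p, w$philic_cap)
}

#' Dscore+: Dscore plus 0.3 times the hydrophobic score
#'
#' @param dscore unrounded Dscore
#' @param h hydrophobic score (non-negative)
#' @return unrounded Dscore+; report with [round_half_away()] at one decimal
#' @export
dscore_plus <- function(dscore, h) {
  stopifnot(is.finite(dscore), is.finite(h))
  dscore + 0.3 * h
}

#' Write a per-structure descriptor table as TSV
#'
#' @param sites list of `site` with descriptors
#' @param path output file
#' @return `path`, invisibly
#' @export
write_descriptor_table <- function(sites, path) {
  rows <- lapply(sites, function(s) {
    d <- s$descriptors
    data.frame(site_id = s$site_id, n = d$n, e = signif(d$e, 4),
               V = signif(d$V, 6), h = signif(d$h, 4), p = signif(d$p, 4),
               Dscore = d$dscore_reported, Dscore_plus = d$dscore_plus_reported)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
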
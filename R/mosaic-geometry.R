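# Density recovery profiles of cell mosaics and the circle-intersection
# model of dendritic overlap versus soma-to-soma distance.

#' Cell mosaic constructor
#'
#' @param points n x 2 matrix of (x, y) positions in um.
#' @param field_extent_um length-2 field side lengths (um); points must lie
#'   within `[0, field_extent_um]`.
#' @param cell_type_label free-text label.
#' @return An object of class `mosaic`; `density_per_mm2` is derived as
#'   count / area.
#' @export
mosaic <- function(points, field_extent_um, cell_type_label = "") {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must be an n x 2 matrix (um)")
  if (any(points[, 1] < 0 | points[, 1] > field_extent_um[1] |
          points[, 2] < 0 | points[, 2] > field_extent_um[2]))
    stop("all points must lie within the field extent")
  structure(list(points = unname(points),
                 field_extent_um = field_extent_um,
                 cell_type_label = cell_type_label,
                 density_per_mm2 = nrow(points) / prod(field_extent_um) * 1e6),
            class = "mosaic")
}

#' @export
print.mosaic <- function(x, ...) {
  cat(sprintf("<mosaic> %d cells in %g x %g um (%.0f cells/mm^2)\n",
              nrow(x$points), x$field_extent_um[1], x$field_extent_um[2],
              x$density_per_mm2))
  invisible(x)
}

#' Density recovery profile of a mosaic
#'
#' For every reference cell lying at least `r_max_um` inside the field
#' boundary (interior-buffer edge handling), neighbours are counted in
#' concentric annuli of width `bin_width_um` out to `r_max_um`; the annulus
#' density is the total count divided by the number of reference cells and
#' the annulus area. A flat profile at the mean density indicates complete
#' spatial randomness; a central dip indicates an exclusion zone.
#'
#' @param mos a [mosaic()].
#' @param bin_width_um annulus width (default 10 um).
#' @param r_max_um profile extent (default 150 um).
#' @return An object of class `drp_result`: `annulus_edges_um`,
#'   `densities_per_mm2`, `mean_density_per_mm2`, `effective_radius_um`
#'   (inner edge of the first annulus whose density reaches the mean
#'   density) and `n_reference`.
#' @export
#' @examples
#' mos <- simulate_mosaic(500, exclusion_radius_um = 30, seed = 1)
#' density_recovery_profile(mos)
density_recovery_profile <- function(mos, bin_width_um = 10,
                                     r_max_um = 150) {
  stopifnot(inherits(mos, "mosaic"))
  pts <- mos$points
  if (nrow(pts) < 2L) stop("need at least 2 points for a profile")
  fx <- mos$field_extent_um[1]
  fy <- mos$field_extent_um[2]
  interior <- pts[, 1] >= r_max_um & pts[, 1] <= fx - r_max_um &
    pts[, 2] >= r_max_um & pts[, 2] <= fy - r_max_um
  if (!any(interior))
    stop("no interior reference points; reduce r_max_um or enlarge field")
  ref <- which(interior)
  edges <- seq(0, r_max_um, by = bin_width_um)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (i in ref) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    d <- d[-i]
    d <- d[d < r_max_um]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges), nbins = n_bins)
  }
  areas_um2 <- pi * (edges[-1]^2 - edges[-(n_bins + 1L)]^2)
  dens <- counts / length(ref) / areas_um2 * 1e6
  mean_dens <- mos$density_per_mm2
  reached <- which(dens >= mean_dens)
  structure(
    list(annulus_edges_um = edges,
         densities_per_mm2 = dens,
         mean_density_per_mm2 = mean_dens,
         effective_radius_um = if (length(reached))
           edges[reached[1]] else NA_real_,
         n_reference = length(ref)),
    class = "drp_result")
}

#' @export
print.drp_result <- function(x, ...) {
  cat(sprintf(paste0("<drp_result> %d reference cells, mean density ",
                     "%.0f /mm^2, effective radius %s um\n"),
              x$n_reference, x$mean_density_per_mm2,
              format(x$effective_radius_um)))
  invisible(x)
}

#' Dendritic overlap of two circular arbors
#'
#' Area of intersection of two circles of radius `radius_um` whose centres
#' are `distance_um` apart:
#' `2 R^2 acos(d / 2R) - (d/2) sqrt(4 R^2 - d^2)` for `d < 2R`, else 0.
#' Starburst amacrine cell arbors are well approximated by 100 um radius
#' circles, so overlap vanishes for somata more than 200 um apart.
#'
#' @param distance_um centre-to-centre distance(s), >= 0 (vectorised).
#' @param radius_um arbor radius R (default 100 um).
#' @return Overlap area(s) in um^2.
#' @export
#' @examples
#' dendritic_overlap_area(0)    # pi * 100^2
#' dendritic_overlap_area(100)  # ~12283.7
#' dendritic_overlap_area(200)  # 0
dendritic_overlap_area <- function(distance_um, radius_um = 100) {
  if (any(distance_um < 0)) stop("'distance_um' must be >= 0")
  check_number(radius_um, "radius_um")
  if (radius_um <= 0) stop("'radius_um' must be > 0")
  d <- pmin(distance_um, 2 * radius_um)
  area <- 2 * radius_um^2 * acos(d / (2 * radius_um)) -
    (d / 2) * sqrt(4 * radius_um^2 - d^2)
  ifelse(distance_um >= 2 * radius_um, 0, area)
}

#' Summary of dendritic radii
#'
#' @param radii_um measured dendritic radii (um), length >= 1.
#' @param bin_width_um histogram bin width (default 10 um).
#' @return List with `mean_um`, `sd_um` (`NA` for a single value) and a
#'   `histogram` data frame.
#' @export
radius_summary <- function(radii_um, bin_width_um = 10) {
  if (!length(radii_um)) stop("'radii_um' must be non-empty")
  lo <- floor(min(radii_um) / bin_width_um) * bin_width_um
  hi <- ceiling(max(radii_um) / bin_width_um) * bin_width_um
  if (hi == lo) hi <- lo + bin_width_um
  edges <- seq(lo, hi, by = bin_width_um)
  counts <- tabulate(findInterval(radii_um, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  list(mean_um = mean(radii_um),
       sd_um = if (length(radii_um) > 1) stats::sd(radii_um) else NA_real_,
       histogram = data.frame(bin_start_um = edges[-length(edges)],
                              bin_end_um = edges[-1L],
                              count = counts))
}

#' Read a mosaic from a CSV of coordinates
#'
#' @param path CSV with header columns `x_um`, `y_um`.
#' @param field_extent_um field size; defaults to the bounding box ceiling.
#' @param cell_type_label label for the mosaic.
#' @return A [mosaic()].
#' @export
read_mosaic_csv <- function(path, field_extent_um = NULL,
                            cell_type_label = "") {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("mosaic CSV must have columns 'x_um' and 'y_um'")
  if (is.null(field_extent_um))
    field_extent_um <- c(max(df$x_um), max(df$y_um))
  mosaic(cbind(df$x_um, df$y_um), field_extent_um, cell_type_label)
}
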
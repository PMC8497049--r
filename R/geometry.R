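#' Vessel centerline
#'
#' An ordered 3-D polyline in world millimeters with cumulative arc-length.
#' All tubular volumes of interest are defined by distance to this polyline
#' and by arc-length intervals along it.
#'
#' @param points numeric matrix, one row per point, columns x/y/z in mm;
#'   at least 2 rows, consecutive rows distinct.
#' @return An object of class `centerline` with elements `points` and
#'   `arclen` (cumulative arc-length per point, starting at 0).
#' @export
centerline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 2L)
    stop("centerline needs an n x 3 matrix with n >= 2")
  if (!all(is.finite(points))) stop("centerline points must be finite")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  structure(list(points = points, arclen = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline> ", nrow(x$points), " points, length ",
      format(max(x$arclen), digits = 6), " mm\n", sep = "")
  invisible(x)
}

centerline_length <- function(cl) max(cl$arclen)

# Resample a centerline at (at most) `step` mm arc-length spacing.
# Returns list(points = m x 3, arclen = m). Endpoints always included.
resample_centerline <- function(cl, step = 0.25) {
  total <- centerline_length(cl)
  n <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = n)
  pts <- cbind(
    stats::approx(cl$arclen, cl$points[, 1], xout = s)$y,
    stats::approx(cl$arclen, cl$points[, 2], xout = s)$y,
    stats::approx(cl$arclen, cl$points[, 3], xout = s)$y
  )
  list(points = pts, arclen = s)
}

# World coordinates of voxel centers for 1-based index vectors along each
# axis. Returns list(x, y, z) of per-axis center coordinate vectors.
axis_coords <- function(grid, i = NULL, j = NULL, k = NULL) {
  g <- grid_info(grid)
  if (is.null(i)) i <- seq_len(g$dim[1])
  if (is.null(j)) j <- seq_len(g$dim[2])
  if (is.null(k)) k <- seq_len(g$dim[3])
  list(x = g$origin[1] + (i - 1) * g$spacing[1],
       y = g$origin[2] + (j - 1) * g$spacing[2],
       z = g$origin[3] + (k - 1) * g$spacing[3],
       i = i, j = j, k = k)
}

# Nearest-centerline query on a subgrid: for every voxel center in the
# index box (i, j, k ranges), the distance to the densely resampled
# polyline and the arc-length of the nearest sample. Running-minimum over
# samples; ties keep the most proximal (smallest arc-length) sample.
# Returns list(dist, s) as arrays of dim (length(i), length(j), length(k)).
nearest_centerline <- function(grid, cl, i, j, k, step = 0.25) {
  rs <- resample_centerline(cl, step)
  ax <- axis_coords(grid, i, j, k)
  ni <- length(ax$x); nj <- length(ax$y); nk <- length(ax$z)
  vx <- rep(ax$x, times = nj * nk)
  vy <- rep(rep(ax$y, each = ni), times = nk)
  vz <- rep(ax$z, each = ni * nj)
  best <- rep(Inf, ni * nj * nk)
  bs <- rep(NA_real_, ni * nj * nk)
  for (m in seq_len(nrow(rs$points))) {
    d2 <- (vx - rs$points[m, 1])^2 + (vy - rs$points[m, 2])^2 +
      (vz - rs$points[m, 3])^2
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      bs[upd] <- rs$arclen[m]
    }
  }
  list(dist = array(sqrt(best), dim = c(ni, nj, nk)),
       s = array(bs, dim = c(ni, nj, nk)))
}

#' Volume-of-interest radius for an aortic section
#'
#' The tubular VOI diameter is the maximal luminal diameter of the section
#' plus a 4 mm margin, chosen to match the approximate spatial resolution
#' of PET; the radius is half of that.
#'
#' @param lumen_diameter maximal luminal diameter of the section in mm
#'   (> 0).
#' @return VOI radius in mm: `(lumen_diameter + 4) / 2`.
#' @export
section_radius <- function(lumen_diameter) {
  if (any(!is.finite(lumen_diameter)) || any(lumen_diameter <= 0))
    stop("lumen diameter must be positive")
  (lumen_diameter + 4) / 2
}

#' Define an aortic section along the centerline
#'
#' A section is a half-open arc-length interval `[a, b)` with one VOI
#' radius derived from the section's maximal lumen diameter. The half-open
#' convention makes adjacent sections disjoint (the next section starts at
#' the slice immediately distal to the previous one).
#'
#' @param name section name, e.g. `"ascending"` or `"arch"`.
#' @param a,b arc-length interval bounds in mm, `a < b`.
#' @param lumen_diameter maximal lumen diameter of the section, mm.
#' @return An object of class `tube_section`.
#' @export
tube_section <- function(name, a, b, lumen_diameter) {
  if (!is.finite(a) || !is.finite(b) || a >= b)
    stop("section interval must satisfy a < b")
  structure(list(name = as.character(name), a = a, b = b,
                 lumen_diameter = lumen_diameter,
                 voi_radius = section_radius(lumen_diameter)),
            class = "tube_section")
}

#' Build a tubular section mask
#'
#' A voxel belongs to the section VOI iff the nearest point of the densely
#' resampled centerline (sample step <= 0.25 mm) lies in the section's
#' arc-length interval `[a, b)` AND the distance to that nearest point is
#' at most the section's VOI radius. Voxel centers decide inclusion; no
#' partial-volume weighting.
#'
#' @param grid a [voxel_image] / [binary_mask] or grid description giving
#'   the PET grid.
#' @param cl a [centerline].
#' @param section a [tube_section] whose interval lies within the
#'   centerline arc-length.
#' @param step centerline resampling step in mm.
#' @return A [binary_mask] on `grid`; error if the mask would be empty.
#' @export
build_tube_mask <- function(grid, cl, section, step = 0.25) {
  g <- grid_info(grid)
  if (section$a < 0 || section$b > centerline_length(cl) + step)
    stop("section interval outside centerline arc-length")
  rs <- resample_centerline(cl, step)
  inside <- rs$arclen >= section$a & rs$arclen < section$b
  if (!any(inside)) stop("section interval contains no centerline samples")
  r <- section$voi_radius
  box <- index_box(g, rs$points[inside, , drop = FALSE], r)
  nn <- nearest_centerline(g, cl, box$i, box$j, box$k, step = step)
  sel <- nn$dist <= r & nn$s >= section$a & nn$s < section$b
  if (!any(sel)) stop("section VOI '", section$name, "' is empty on this grid")
  vals <- array(FALSE, dim = g$dim)
  vals[box$i, box$j, box$k] <- sel
  binary_mask(vals, g$spacing, g$origin)
}

# index ranges of voxels whose centers lie within `margin` mm of the
# bounding box of `pts` (world mm), clipped to the grid
index_box <- function(g, pts, margin) {
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  rng <- function(ax) {
    a <- ceiling((lo[ax] - g$origin[ax]) / g$spacing[ax]) + 1
    b <- floor((hi[ax] - g$origin[ax]) / g$spacing[ax]) + 1
    a <- max(1L, as.integer(a)); b <- min(g$dim[ax], as.integer(b))
    if (a > b) stop("geometry lies outside the voxel grid")
    a:b
  }
  list(i = rng(1), j = rng(2), k = rng(3))
}

#' Build a spherical volume-of-interest mask
#'
#' The sphere radius is derived from the requested volume,
#' `r = (3 V / 4 pi)^(1/3)` (about 7.816 mm for the standard 2 cm^3
#' blood-pool sphere). Voxels are included iff their center lies within
#' the radius.
#'
#' @param grid grid description (see [build_tube_mask]).
#' @param center sphere center in world mm; must lie inside the grid.
#' @param volume sphere volume in cm^3 (default 2).
#' @return A [binary_mask].
#' @export
sphere_mask <- function(grid, center, volume = 2) {
  g <- grid_info(grid)
  center <- as.numeric(center)
  ext_lo <- g$origin - g$spacing / 2
  ext_hi <- g$origin + (g$dim - 1 + 0.5) * g$spacing
  if (any(center < ext_lo) || any(center > ext_hi))
    stop("sphere center lies outside the grid")
  r <- (3 * volume * 1000 / (4 * pi))^(1 / 3)  # cm^3 -> mm^3
  box <- index_box(g, matrix(center, nrow = 1), r)
  ax <- axis_coords(g, box$i, box$j, box$k)
  d2 <- outer(outer((ax$x - center[1])^2, (ax$y - center[2])^2, `+`),
              (ax$z - center[3])^2, `+`)
  vals <- array(FALSE, dim = g$dim)
  vals[box$i, box$j, box$k] <- d2 <= r^2
  binary_mask(vals, g$spacing, g$origin)
}

#' Per-slice 2-D regions of interest along the vessel
#'
#' For every axial slice in `slice_range` the 2-D ROI is the intersection
#' of that slice with the union of the section tube masks. Empty slices at
#' the edges of the range are dropped with a warning; an empty slice in
#' the interior, or an entirely empty series, is an error.
#'
#' @param grid grid description.
#' @param cl a [centerline].
#' @param sections list of [tube_section] objects.
#' @param slice_range integer length-2, first and last axial slice index
#'   (1-based) to cover.
#' @param step centerline resampling step in mm.
#' @return An object of class `slice_roi_series`: list with `slices`
#'   (integer vector of slice indices), `masks` (list of 2-D logical
#'   matrices), and `slice_spacing` (mm).
#' @export
slice_rois <- function(grid, cl, sections, slice_range, step = 0.25) {
  g <- grid_info(grid)
  slice_range <- as.integer(slice_range)
  if (length(slice_range) != 2L || slice_range[1] > slice_range[2] ||
      slice_range[1] < 1L || slice_range[2] > g$dim[3])
    stop("slice_range must be within the grid z-extent")
  tube <- array(FALSE, dim = g$dim)
  for (sec in sections)
    tube <- tube | build_tube_mask(g, cl, sec, step = step)$values
  slice_series_from_mask(tube, slice_range, g$spacing[3])
}

# slice a 3-D tube mask into the per-slice ROI series, trimming empty
# edge slices (shared by slice_rois and the pipeline mask builder)
slice_series_from_mask <- function(tube, slice_range, slice_spacing) {
  ks <- slice_range[1]:slice_range[2]
  nonempty <- vapply(ks, function(k) any(tube[, , k]), logical(1))
  if (!any(nonempty)) stop("no slice in range intersects the vessel VOI")
  keep <- which(nonempty)
  first <- min(keep); last <- max(keep)
  if (first > 1L || last < length(ks))
    warning("dropped ", (first - 1L) + (length(ks) - last),
            " empty slice(s) at the range edges")
  if (!all(nonempty[first:last]))
    stop("empty slice inside the ROI series")
  ks <- ks[first:last]
  structure(list(slices = ks,
                 masks = lapply(ks, function(k) tube[, , k]),
                 slice_spacing = slice_spacing),
            class = "slice_roi_series")
}

#' @export
print.slice_roi_series <- function(x, ...) {
  cat("<slice_roi_series> ", length(x$slices), " slices (",
      x$slices[1], "..", x$slices[length(x$slices)], "), ",
      format(x$slice_spacing), " mm apart\n", sep = "")
  invisible(x)
}
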
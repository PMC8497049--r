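#' VOI geometry definition
#'
#' Bundles everything needed to quantify one scan: the aortic centerline,
#' the landmark arc-lengths that cut it into sections (sinotubular
#' junction, brachiocephalic origin, left subclavian origin, and the
#' distal end of the arch VOI), per-section maximal lumen diameters, the
#' two atrial sphere centers, the bone reference VOI (a cube just outside
#' the sternum whose SUVmax sets the bone-exclusion threshold), and the
#' axial slice range for the per-slice ROI series.
#'
#' @param cl a [centerline].
#' @param landmarks_mm named list/vector with `stj`, `brachiocephalic`,
#'   `left_subclavian` arc-lengths (mm), strictly increasing and within
#'   the centerline length.
#' @param lumen_diameter_mm named list/vector with `ascending` and `arch`
#'   maximal lumen diameters (mm).
#' @param spheres_mm named list with `ra` and `la` sphere centers (mm).
#' @param bone_ref list with `center_mm` (length 3) and `edge_mm`
#'   (scalar cube edge), or `NULL` when bone thresholding is not used.
#' @param slice_range integer length-2, 1-based axial slice range.
#' @param arch_end_mm arc-length at which the arch VOI ends (immediately
#'   distal to the left subclavian origin); defaults to
#'   `left_subclavian + 6` mm.
#' @return An object of class `voi_geometry`.
#' @export
voi_geometry <- function(cl, landmarks_mm, lumen_diameter_mm, spheres_mm,
                         bone_ref = NULL, slice_range = NULL,
                         arch_end_mm = NULL) {
  stopifnot(inherits(cl, "centerline"))
  lm <- lapply(landmarks_mm[c("stj", "brachiocephalic", "left_subclavian")],
               as.numeric)
  if (any(vapply(lm, function(v) is.null(v) || !is.finite(v), logical(1))))
    stop("landmarks_mm must contain finite stj, brachiocephalic, left_subclavian")
  lmv <- unlist(lm)
  if (is.null(arch_end_mm)) arch_end_mm <- lmv[["left_subclavian"]] + 6
  if (any(diff(c(lmv, arch_end_mm)) <= 0))
    stop("landmark arc-lengths must be strictly increasing")
  if (arch_end_mm > centerline_length(cl))
    stop("arch end lies beyond the centerline")
  ld <- lapply(lumen_diameter_mm[c("ascending", "arch")], as.numeric)
  if (any(vapply(ld, function(v) is.null(v) || v <= 0, logical(1))))
    stop("lumen_diameter_mm must contain positive ascending and arch diameters")
  sp <- lapply(spheres_mm[c("ra", "la")], as.numeric)
  if (any(vapply(sp, function(v) length(v) != 3L || any(!is.finite(v)),
                 logical(1))))
    stop("spheres_mm must contain 3-D ra and la centers")
  if (!is.null(bone_ref)) {
    if (length(bone_ref$center_mm) != 3L || !is.numeric(bone_ref$edge_mm) ||
        bone_ref$edge_mm <= 0)
      stop("bone_ref needs center_mm (length 3) and positive edge_mm")
    bone_ref <- list(center_mm = as.numeric(bone_ref$center_mm),
                     edge_mm = as.numeric(bone_ref$edge_mm))
  }
  if (!is.null(slice_range)) {
    slice_range <- as.integer(slice_range)
    if (length(slice_range) != 2L || slice_range[1] > slice_range[2])
      stop("slice_range must be c(first, last) with first <= last")
  }
  structure(list(centerline = cl, landmarks_mm = lm,
                 lumen_diameter_mm = ld, spheres_mm = sp,
                 bone_ref = bone_ref, slice_range = slice_range,
                 arch_end_mm = as.numeric(arch_end_mm)),
            class = "voi_geometry")
}

#' @export
print.voi_geometry <- function(x, ...) {
  lm <- unlist(x$landmarks_mm)
  cat("<voi_geometry>\n")
  cat("  centerline: ", nrow(x$centerline$points), " points, ",
      format(centerline_length(x$centerline), digits = 5), " mm\n", sep = "")
  cat("  landmarks (mm): stj ", format(lm[["stj"]]),
      ", brachiocephalic ", format(lm[["brachiocephalic"]]),
      ", left subclavian ", format(lm[["left_subclavian"]]),
      ", arch end ", format(x$arch_end_mm), "\n", sep = "")
  cat("  lumen diameters (mm): ascending ",
      format(x$lumen_diameter_mm$ascending), ", arch ",
      format(x$lumen_diameter_mm$arch), "\n", sep = "")
  if (!is.null(x$slice_range))
    cat("  slice range: ", x$slice_range[1], "..", x$slice_range[2], "\n",
        sep = "")
  cat("  bone reference VOI: ",
      if (is.null(x$bone_ref)) "none" else
        paste0("cube edge ", x$bone_ref$edge_mm, " mm"), "\n", sep = "")
  invisible(x)
}

#' Aortic sections implied by a VOI geometry
#'
#' The ascending VOI runs from the sinotubular junction to just proximal
#' to the brachiocephalic origin; the arch VOI from there to just distal
#' to the left subclavian origin. Intervals are half-open so the two
#' sections are disjoint. The descending aorta is never included.
#'
#' @param voi a [voi_geometry].
#' @return Named list of two [tube_section]s (`ascending`, `arch`).
#' @export
voi_sections <- function(voi) {
  lm <- unlist(voi$landmarks_mm)
  list(
    ascending = tube_section("ascending", lm[["stj"]],
                             lm[["brachiocephalic"]],
                             voi$lumen_diameter_mm$ascending),
    arch = tube_section("arch", lm[["brachiocephalic"]], voi$arch_end_mm,
                        voi$lumen_diameter_mm$arch)
  )
}

# cube mask for the bone reference VOI
bone_ref_mask <- function(grid, bone_ref) {
  g <- grid_info(grid)
  half <- bone_ref$edge_mm / 2
  ax <- axis_coords(g)
  sel <- function(co, c0) co >= c0 - half & co <= c0 + half
  vals <- outer(outer(sel(ax$x, bone_ref$center_mm[1]),
                      sel(ax$y, bone_ref$center_mm[2]), `&`),
                sel(ax$z, bone_ref$center_mm[3]), `&`)
  if (!any(vals)) stop("bone reference VOI lies outside the grid")
  binary_mask(vals, g$spacing, g$origin)
}

#' Write a VOI geometry to JSON
#'
#' The JSON dialect stores the centerline point list, landmark
#' arc-lengths, per-section lumen diameters, atrial sphere centers, the
#' bone reference VOI and the slice range. [read_voi] restores the
#' geometry to well below 1e-9 mm.
#'
#' @param voi a [voi_geometry].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voi <- function(voi, path) {
  stopifnot(inherits(voi, "voi_geometry"))
  obj <- list(
    centerline = unname(apply(voi$centerline$points, 1, as.numeric,
                              simplify = FALSE)),
    landmarks_mm = voi$landmarks_mm,
    arch_end_mm = voi$arch_end_mm,
    lumen_diameter_mm = voi$lumen_diameter_mm,
    spheres_mm = voi$spheres_mm,
    bone_ref = if (is.null(voi$bone_ref)) NULL else voi$bone_ref,
    slice_range = voi$slice_range
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a VOI geometry from JSON
#'
#' @param path path to a JSON file written by [write_voi] (or assembled
#'   by hand in the same dialect). Unknown top-level keys are ignored
#'   with a warning; missing required fields raise an error naming the
#'   field.
#' @return A [voi_geometry].
#' @export
read_voi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("centerline", "landmarks_mm", "arch_end_mm",
             "lumen_diameter_mm", "spheres_mm", "bone_ref", "slice_range")
  extra <- setdiff(names(obj), known)
  if (length(extra))
    warning("ignoring unknown VOI fields: ", paste(extra, collapse = ", "))
  for (f in c("centerline", "landmarks_mm", "lumen_diameter_mm",
              "spheres_mm")) {
    if (is.null(obj[[f]]))
      stop("VOI file is missing required field '", f, "'")
  }
  for (f in c("stj", "brachiocephalic", "left_subclavian")) {
    if (is.null(obj$landmarks_mm[[f]]))
      stop("VOI file is missing landmark '", f, "'")
  }
  pts <- obj$centerline
  if (is.list(pts)) pts <- do.call(rbind, pts)
  voi_geometry(centerline(pts),
               landmarks_mm = as.list(obj$landmarks_mm),
               lumen_diameter_mm = as.list(obj$lumen_diameter_mm),
               spheres_mm = lapply(obj$spheres_mm, as.numeric),
               bone_ref = obj$bone_ref,
               slice_range = obj$slice_range,
               arch_end_mm = obj$arch_end_mm)
}

#' Convert phantom ground truth to a VOI geometry
#'
#' The phantom knows its own anatomy exactly; this extracts the VOI
#' definition a human observer would otherwise draw, so phantom scans can
#' be quantified through the same interface as patient scans.
#'
#' @param truth a `geometry_truth` object from [generate_phantom].
#' @return A [voi_geometry].
#' @export
truth_to_voi <- function(truth) {
  stopifnot(inherits(truth, "geometry_truth"))
  voi_geometry(truth$centerline,
               landmarks_mm = truth$landmarks_mm,
               lumen_diameter_mm = truth$lumen_diameter_mm,
               spheres_mm = truth$spheres_mm,
               bone_ref = truth$bone_ref,
               slice_range = truth$slice_range,
               arch_end_mm = truth$arch_end_mm)
}
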
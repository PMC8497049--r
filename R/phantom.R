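#' Configuration of the synthetic thoracic-aorta PET phantom
#'
#' The phantom is a "candy-cane" aorta: a vertical ascending segment that
#' continues into a semicircular arch, plus a short descending stub next
#' to the spine so spine-overspill scenarios can be exercised (the
#' descending aorta itself is never quantified). Tissue, blood pool
#' (lumen and two atrial spheres), aortic wall, focal wall lesions and
#' bone cuboids are painted at configurable SUV levels, convolved with an
#' isotropic Gaussian point-spread function, and degraded with i.i.d.
#' Gaussian noise in SUV space.
#'
#' Defaults emulate a clinical 18F-NaF PET reconstruction: 2 mm isotropic
#' voxels on a 128^3 grid, a 5 mm FWHM post-filter, blood pool SUV 1,
#' and a baseline wall-to-blood ratio of 1.3 with two modest focal
#' lesions.
#'
#' @param shape integer length-3 grid size in voxels.
#' @param spacing voxel size in mm.
#' @param ascending_length length of the vertical ascending segment, mm.
#' @param arch_radius radius of the semicircular arch, mm.
#' @param lumen_diameter named list, maximal lumen diameter (mm) of the
#'   `ascending` and `arch` sections.
#' @param wall_thickness aortic wall thickness, mm (lumen diameters must
#'   exceed twice this).
#' @param blood_suv blood-pool SUV.
#' @param wall_tbr baseline wall SUV as a multiple of `blood_suv`.
#' @param tissue_suv background soft-tissue SUV.
#' @param lesions list of focal wall lesions, each
#'   `list(position_mm, amplitude, sigma_mm)`: a Gaussian bump in
#'   arc-length added to the wall (SUV amplitude at the lesion center).
#' @param bones list of bone cuboids, each
#'   `list(corner_mm, size_mm, suv)` (sternum and thoracic spine by
#'   default).
#' @param bone_ref bone-exclusion reference VOI, `list(center_mm,
#'   edge_mm)`: a cube in soft tissue immediately outside the sternum.
#' @param psf_fwhm full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (0 disables blurring).
#' @param noise_sd standard deviation of additive Gaussian noise, SUV.
#' @param seed integer RNG seed for the noise field.
#' @param fill_voi_uniform if `TRUE`, every voxel of the tube region
#'   (lumen + wall) is set to `wall_tbr * blood_suv` before blurring, so
#'   quantification must recover the ratio exactly in the noise- and
#'   blur-free limit.
#' @param stj_offset_mm arc-length of the sinotubular junction above the
#'   centerline start (a short aortic-root stub precedes it).
#' @param lsa_frac fraction of the arch arc at which the left subclavian
#'   artery originates.
#' @param arch_margin_mm how far past the left subclavian origin the arch
#'   VOI extends ("immediately distal").
#' @param descending_length length of the descending stub, mm.
#' @param rpa_level_mm world z at which the right pulmonary artery first
#'   appears: the first slice of the per-slice ROI series.
#' @param atria named list with `ra`, `la` atrial blood-pool centers (mm)
#'   and `radius_mm` of the blood region painted around each.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(128L, 128L, 128L),
                           spacing = c(2, 2, 2),
                           ascending_length = 95,
                           arch_radius = 30,
                           lumen_diameter = list(ascending = 30, arch = 26),
                           wall_thickness = 3,
                           blood_suv = 1,
                           wall_tbr = 1.3,
                           tissue_suv = 0.4,
                           lesions = list(
                             list(position_mm = 60, amplitude = 1.0,
                                  sigma_mm = 8),
                             list(position_mm = 130, amplitude = 0.6,
                                  sigma_mm = 10)),
                           bones = list(
                             list(corner_mm = c(28, 108, 60),
                                  size_mm = c(12, 40, 80), suv = 8),
                             list(corner_mm = c(180, 112, 30),
                                  size_mm = c(26, 32, 130), suv = 8)),
                           bone_ref = list(center_mm = c(45, 128, 100),
                                           edge_mm = 8),
                           psf_fwhm = 5,
                           noise_sd = 0.1,
                           seed = 1L,
                           fill_voi_uniform = FALSE,
                           stj_offset_mm = 10,
                           lsa_frac = 0.65,
                           arch_margin_mm = 6,
                           descending_length = 40,
                           rpa_level_mm = 70,
                           atria = list(ra = c(60, 100, 60),
                                        la = c(60, 156, 60),
                                        radius_mm = 15)) {
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              ascending_length = ascending_length,
              arch_radius = arch_radius,
              lumen_diameter = lumen_diameter,
              wall_thickness = wall_thickness,
              blood_suv = blood_suv, wall_tbr = wall_tbr,
              tissue_suv = tissue_suv,
              lesions = lesions, bones = bones, bone_ref = bone_ref,
              psf_fwhm = psf_fwhm, noise_sd = noise_sd,
              seed = as.integer(seed),
              fill_voi_uniform = isTRUE(fill_voi_uniform),
              stj_offset_mm = stj_offset_mm, lsa_frac = lsa_frac,
              arch_margin_mm = arch_margin_mm,
              descending_length = descending_length,
              rpa_level_mm = rpa_level_mm, atria = atria)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$shape) != 3L || any(cfg$shape < 8L))
    stop("phantom grid must be 3-D with at least 8 voxels per axis")
  if (length(cfg$spacing) != 3L || any(cfg$spacing <= 0))
    stop("voxel spacing must be positive")
  for (d in unlist(cfg$lumen_diameter))
    if (d <= 2 * cfg$wall_thickness)
      stop("lumen diameters must exceed twice the wall thickness")
  if (cfg$wall_thickness <= 0) stop("wall thickness must be positive")
  if (cfg$psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$blood_suv <= 0) stop("blood_suv must be positive")
  total <- cfg$stj_offset_mm + cfg$ascending_length +
    pi * cfg$arch_radius + cfg$descending_length
  for (le in cfg$lesions) {
    if (is.null(le$position_mm) || le$position_mm < 0 ||
        le$position_mm > total)
      stop("lesion position outside the centerline arc-length")
    if (is.null(le$amplitude) || is.null(le$sigma_mm) || le$sigma_mm <= 0)
      stop("lesions need amplitude and positive sigma_mm")
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> grid ", paste(x$shape, collapse = "x"),
      " @ ", paste(format(x$spacing), collapse = "x"), " mm\n", sep = "")
  cat("  blood SUV ", format(x$blood_suv), ", wall TBR ",
      format(x$wall_tbr), ", tissue SUV ", format(x$tissue_suv),
      ", ", length(x$lesions), " lesion(s), ", length(x$bones),
      " bone(s)\n", sep = "")
  cat("  PSF FWHM ", format(x$psf_fwhm), " mm, noise sd ",
      format(x$noise_sd), " SUV, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# candy-cane centerline and landmark arc-lengths for a config
phantom_centerline <- function(cfg) {
  # anatomy sits at fixed world coordinates; the grid must contain it
  x_a <- 85; y_c <- 128; z_root <- 40
  R <- cfg$arch_radius
  z_top <- z_root + cfg$stj_offset_mm + cfg$ascending_length
  th <- seq(pi, 0, length.out = 65)
  asc_z <- seq(z_root, z_top, by = 2)
  if (asc_z[length(asc_z)] < z_top) asc_z <- c(asc_z, z_top)
  pts <- rbind(
    cbind(x_a, y_c, asc_z[-length(asc_z)]),
    cbind(x_a + R + R * cos(th), y_c, z_top + R * sin(th)),
    cbind(x_a + 2 * R, y_c,
          seq(z_top, z_top - cfg$descending_length, by = -2)[-1])
  )
  cl <- centerline(pts)
  arch_start <- cfg$stj_offset_mm + cfg$ascending_length
  arch_len <- pi * R
  landmarks <- list(stj = cfg$stj_offset_mm,
                    brachiocephalic = arch_start,
                    left_subclavian = arch_start + cfg$lsa_frac * arch_len)
  list(cl = cl, landmarks = landmarks,
       arch_end = landmarks$left_subclavian + cfg$arch_margin_mm,
       arch_start = arch_start, arch_top_z = z_top + R)
}

# cache for phantom_geometry: anatomy is often shared across many scans
# (rescans, harness subjects), and the label masks are the expensive part
.geom_cache <- new.env(parent = emptyenv())

geometry_key <- function(cfg) {
  paste(deparse(cfg[c("shape", "spacing", "ascending_length", "arch_radius",
                      "lumen_diameter", "wall_thickness", "bones",
                      "bone_ref", "stj_offset_mm", "lsa_frac",
                      "arch_margin_mm", "descending_length", "rpa_level_mm",
                      "atria")]), collapse = "")
}

phantom_geometry <- function(cfg, step = 0.25) {
  key <- geometry_key(cfg)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- phantom_geometry_impl(cfg, step)
  if (length(ls(.geom_cache)) > 8) rm(list = ls(.geom_cache),
                                      envir = .geom_cache)
  .geom_cache[[key]] <- out
  out
}

# geometry-only part of the phantom: label masks, nearest-centerline
# field over the tube bounding box, ground truth. Depends only on the
# geometric fields of cfg, not on SUV levels, lesions or noise.
phantom_geometry_impl <- function(cfg, step = 0.25) {
  g <- list(dim = cfg$shape, spacing = cfg$spacing, origin = c(0, 0, 0))
  pc <- phantom_centerline(cfg)
  lum_r <- c(ascending = cfg$lumen_diameter$ascending / 2,
             arch = cfg$lumen_diameter$arch / 2)
  outer_r <- max(lum_r) + cfg$wall_thickness
  rs_pts <- resample_centerline(pc$cl, 2)$points
  ext <- (g$dim - 1) * g$spacing
  if (any(apply(rs_pts, 2, max) + outer_r > ext) ||
      any(apply(rs_pts, 2, min) - outer_r < 0))
    stop("grid too small to contain the phantom geometry")
  box <- index_box(g, rs_pts, outer_r + 2 * max(g$spacing))
  nn <- nearest_centerline(g, pc$cl, box$i, box$j, box$k, step = step)
  # section-dependent lumen radius: ascending-sized up to the arch start
  rloc <- ifelse(nn$s < pc$arch_start, lum_r[["ascending"]], lum_r[["arch"]])
  lumen_sub <- nn$dist <= rloc
  wall_sub <- nn$dist > rloc & nn$dist <= rloc + cfg$wall_thickness
  lumen <- array(FALSE, g$dim); lumen[box$i, box$j, box$k] <- lumen_sub
  wall <- array(FALSE, g$dim); wall[box$i, box$j, box$k] <- wall_sub
  bone <- array(FALSE, g$dim)
  ax <- axis_coords(g)
  for (b in cfg$bones) {
    lo <- b$corner_mm; hi <- b$corner_mm + b$size_mm
    sel <- outer(outer(ax$x >= lo[1] & ax$x <= hi[1],
                       ax$y >= lo[2] & ax$y <= hi[2], `&`),
                 ax$z >= lo[3] & ax$z <= hi[3], `&`)
    bone <- bone | sel
  }
  bone <- bone & !lumen & !wall
  z_idx <- function(z, round_up) {
    k <- (z - g$origin[3]) / g$spacing[3] + 1
    as.integer(if (round_up) ceiling(k) else floor(k))
  }
  slice_range <- c(max(1L, z_idx(cfg$rpa_level_mm, TRUE)),
                   min(g$dim[3], z_idx(pc$arch_top_z, FALSE)))
  truth <- structure(list(
    centerline = pc$cl,
    landmarks_mm = pc$landmarks,
    arch_end_mm = pc$arch_end,
    lumen_diameter_mm = cfg$lumen_diameter,
    spheres_mm = list(ra = cfg$atria$ra, la = cfg$atria$la),
    bone_ref = cfg$bone_ref,
    slice_range = slice_range,
    masks = list(
      lumen = binary_mask(lumen, g$spacing, g$origin),
      wall = binary_mask(wall, g$spacing, g$origin),
      bone = binary_mask(bone, g$spacing, g$origin)),
    grid = g), class = "geometry_truth")
  list(truth = truth, box = box, nn = nn,
       lumen_sub = lumen_sub, wall_sub = wall_sub, bone = bone, grid = g)
}

#' @export
print.geometry_truth <- function(x, ...) {
  cat("<geometry_truth> grid ", paste(x$grid$dim, collapse = "x"),
      ", centerline ", format(centerline_length(x$centerline), digits = 5),
      " mm\n  slice range ", x$slice_range[1], "..", x$slice_range[2],
      "; wall ", format(mask_volume(x$masks$wall), digits = 4),
      " cm^3, lumen ", format(mask_volume(x$masks$lumen), digits = 4),
      " cm^3\n", sep = "")
  invisible(x)
}

# noiseless SUV field for a config given its geometry
phantom_signal <- function(cfg, geom) {
  g <- geom$grid
  vol <- array(cfg$tissue_suv, g$dim)
  ax <- axis_coords(g)
  for (nm in c("ra", "la")) {
    ctr <- cfg$atria[[nm]]
    d2 <- outer(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, `+`),
                (ax$z - ctr[3])^2, `+`)
    vol[d2 <= cfg$atria$radius_mm^2] <- cfg$blood_suv
  }
  vol[geom$bone] <- 0
  for (b in cfg$bones) {
    lo <- b$corner_mm; hi <- b$corner_mm + b$size_mm
    sel <- outer(outer(ax$x >= lo[1] & ax$x <= hi[1],
                       ax$y >= lo[2] & ax$y <= hi[2], `&`),
                 ax$z >= lo[3] & ax$z <= hi[3], `&`)
    vol[sel & geom$bone] <- b$suv
  }
  sub <- vol[geom$box$i, geom$box$j, geom$box$k]
  sub[geom$lumen_sub] <- cfg$blood_suv
  wall_val <- rep(cfg$wall_tbr * cfg$blood_suv, sum(geom$wall_sub))
  if (length(cfg$lesions)) {
    s_wall <- geom$nn$s[geom$wall_sub]
    for (le in cfg$lesions)
      wall_val <- wall_val + le$amplitude *
        exp(-(s_wall - le$position_mm)^2 / (2 * le$sigma_mm^2))
  }
  sub[geom$wall_sub] <- wall_val
  if (cfg$fill_voi_uniform)
    sub[geom$lumen_sub | geom$wall_sub] <- cfg$wall_tbr * cfg$blood_suv
  vol[geom$box$i, geom$box$j, geom$box$k] <- sub
  if (cfg$psf_fwhm > 0)
    vol <- gaussian_blur3d(vol, cfg$psf_fwhm / (2 * sqrt(2 * log(2))) /
                                  g$spacing)
  vol
}

# separable 3-D Gaussian convolution, sigma per axis in voxels,
# zero-padded, kernel normalized to unit sum
gaussian_blur3d <- function(vol, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    h <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-h:h, sd = s)
    kern <- kern / sum(kern)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(vol, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    m <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
    f <- stats::filter(m, kern, method = "convolution", sides = 2)
    m <- as.matrix(f)[(h + 1):(h + d[1]), , drop = FALSE]
    a <- array(m, dim = d)
    vol <- aperm(a, order(perm))
  }
  vol
}

#' Generate a synthetic thoracic-aorta PET volume
#'
#' Builds the phantom anatomy described by a [phantom_config], paints the
#' configured SUV levels, applies the Gaussian point-spread function and
#' adds seeded Gaussian noise. The companion `geometry_truth` carries the
#' exact centerline, landmarks, sphere centers, bone reference VOI, slice
#' range and the pre-blur lumen/wall/bone label masks.
#'
#' Deterministic: two calls with the same configuration (including seed)
#' return bit-identical volumes.
#'
#' @param cfg a [phantom_config].
#' @return List with `pet` (a [voxel_image] in SUV) and `truth`
#'   (a `geometry_truth`).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  validate_phantom_config(cfg)
  geom <- phantom_geometry(cfg)
  vol <- phantom_signal(cfg, geom)
  if (cfg$noise_sd > 0)
    vol <- vol + with_seed(cfg$seed,
      array(stats::rnorm(length(vol), sd = cfg$noise_sd), dim = dim(vol)))
  list(pet = voxel_image(vol, cfg$spacing, c(0, 0, 0)), truth = geom$truth)
}

#' Simulate a rescan of the same subject
#'
#' Same anatomy and noiseless signal as [generate_phantom] for `cfg`, but
#' a fresh noise realization — the digital analogue of a repeat PET-CT
#' scan a short interval after the first.
#'
#' @param cfg a [phantom_config].
#' @param seed2 RNG seed for the new noise field.
#' @return A [voxel_image].
#' @export
rescan <- function(cfg, seed2) {
  stopifnot(inherits(cfg, "phantom_config"))
  cfg$seed <- as.integer(seed2)
  generate_phantom(cfg)$pet
}
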
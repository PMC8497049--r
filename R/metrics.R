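#' Blood-pool background activity
#'
#' Background activity is the mean SUV per cm^3 over the union of the two
#' 2-cm^3 atrial spheres (right and left atrium): cumulative SUV times
#' voxel volume divided by total sphere volume, which for a uniform grid
#' is simply the mean SUV over the union. This single value is the
#' normalization denominator for AMA and every TBR metric.
#'
#' @param pet a [voxel_image] in SUV.
#' @param sphere_ra,sphere_la non-empty, disjoint [binary_mask]s on the
#'   PET grid.
#' @return Object of class `background_activity` with elements `value`
#'   (mean SUV), `per_sphere` (named means), `total_volume_cm3`, and
#'   `correction` (time-delay correction record, `NULL` when off).
#' @export
background_activity <- function(pet, sphere_ra, sphere_la) {
  stopifnot(inherits(pet, "voxel_image"))
  if (!same_grid(pet, sphere_ra) || !same_grid(pet, sphere_la))
    stop("sphere masks must share the PET grid")
  if (!any(sphere_ra$values) || !any(sphere_la$values))
    stop("background spheres must be non-empty")
  if (any(sphere_ra$values & sphere_la$values))
    stop("background spheres must not overlap")
  un <- sphere_ra$values | sphere_la$values
  structure(list(
    value = mean(pet$values[un]),
    per_sphere = c(ra = mean(pet$values[sphere_ra$values]),
                   la = mean(pet$values[sphere_la$values])),
    total_volume_cm3 = sum(un) * voxel_volume(pet),
    correction = NULL), class = "background_activity")
}

#' @export
print.background_activity <- function(x, ...) {
  cat("<background_activity> ", format(x$value, digits = 5), " SUV (ra ",
      format(x$per_sphere[["ra"]], digits = 4), ", la ",
      format(x$per_sphere[["la"]], digits = 4), "; ",
      format(x$total_volume_cm3, digits = 4), " cm^3",
      if (!is.null(x$correction)) "; time-delay corrected", ")\n", sep = "")
  invisible(x)
}

#' Bone-exclusion SUV threshold
#'
#' Contamination of the aortic VOI by spill-over from the sternum or
#' clavicles is excluded by an upper voxel-intensity limit, set at the
#' SUVmax of a reference VOI placed just outside the sternum.
#'
#' @param pet a [voxel_image] in SUV.
#' @param bone_ref a non-empty [binary_mask], or `NULL` to disable
#'   thresholding (returns `Inf`, so nothing is excluded downstream).
#' @return Threshold SUV (scalar; `Inf` when disabled).
#' @export
bone_threshold <- function(pet, bone_ref = NULL) {
  if (is.null(bone_ref)) return(Inf)
  if (!same_grid(pet, bone_ref)) stop("reference mask must share the PET grid")
  if (!any(bone_ref$values)) stop("bone reference VOI is empty")
  max(pet$values[bone_ref$values])
}

#' Aortic microcalcification activity (AMA)
#'
#' Per section, the aortic intensity per cm^3 is the cumulative voxel
#' intensity in the section VOI divided by the VOI volume in cm^3, over
#' voxels at or below the bone-exclusion threshold; AMA is that intensity
#' divided by the blood-pool background intensity per cm^3 — a unitless
#' number. The overall AMA combines sections by pooling cumulative
#' intensity and volume (a volume-weighted mean of the section AMAs).
#' Voxels above the threshold are removed from both the cumulative
#' intensity and the volume denominator.
#'
#' @param pet a [voxel_image] in SUV.
#' @param sections named list of non-empty [binary_mask]s (typically
#'   `ascending` and `arch`).
#' @param bg a [background_activity] with positive value.
#' @param threshold upper voxel SUV limit (default `Inf`: no exclusion).
#' @return Object of class `ama_result`: per-section table (`cumulative
#'   intensity` SUV cm^3, `volume_cm3`, `intensity_per_cm3`, `ama`,
#'   `excluded` voxel count), `overall` AMA, `threshold`, `excluded`
#'   total.
#' @export
ama <- function(pet, sections, bg, threshold = Inf) {
  stopifnot(inherits(pet, "voxel_image"),
            inherits(bg, "background_activity"))
  if (bg$value <= 0) stop("background activity must be positive")
  vv <- voxel_volume(pet)
  rows <- lapply(names(sections), function(nm) {
    m <- sections[[nm]]
    if (!same_grid(pet, m)) stop("section mask '", nm,
                                 "' must share the PET grid")
    v <- pet$values[m$values]
    if (!length(v)) stop("section VOI '", nm, "' is empty")
    keep <- v <= threshold
    if (!any(keep))
      stop("all voxels of section '", nm, "' exceed the threshold")
    data.frame(section = nm,
               cumulative_suv_cm3 = sum(v[keep]) * vv,
               volume_cm3 = sum(keep) * vv,
               intensity_per_cm3 = mean(v[keep]),
               ama = mean(v[keep]) / bg$value,
               excluded = sum(!keep))
  })
  tab <- do.call(rbind, rows)
  overall <- sum(tab$cumulative_suv_cm3) / sum(tab$volume_cm3) / bg$value
  structure(list(sections = tab, overall = overall,
                 threshold = threshold, excluded = sum(tab$excluded),
                 background = bg$value),
            class = "ama_result")
}

#' @export
print.ama_result <- function(x, ...) {
  cat("Aortic microcalcification activity\n")
  for (r in seq_len(nrow(x$sections)))
    cat(sprintf("  %-10s AMA %.4f  (%.1f cm^3, %.4f SUV/cm^3)\n",
                x$sections$section[r], x$sections$ama[r],
                x$sections$volume_cm3[r], x$sections$intensity_per_cm3[r]))
  cat(sprintf("  overall    AMA %.4f\n", x$overall))
  cat(sprintf("  background %.4f SUV; threshold %s; %d voxel(s) excluded\n",
              x$background,
              if (is.finite(x$threshold)) format(x$threshold, digits = 4)
              else "off", x$excluded))
  invisible(x)
}

#' SUVmean and SUVmax of one 2-D region of interest
#'
#' @param pet a [voxel_image].
#' @param roi 2-D logical matrix matching the axial slice dimensions.
#' @param slice 1-based axial slice index.
#' @return Named numeric: `suv_mean`, `suv_max`.
#' @export
roi_stats <- function(pet, roi, slice) {
  v <- pet$values[, , slice][roi]
  if (!length(v)) stop("empty ROI on slice ", slice)
  c(suv_mean = mean(v), suv_max = max(v))
}

#' Whole-vessel SUV and TBR
#'
#' For each axial ROI of the series, SUVmean and SUVmax are computed and
#' divided by the blood-pool background to give per-slice TBRmean and
#' TBRmax; whole-vessel values are the unweighted averages over all
#' slices.
#'
#' @param pet a [voxel_image] in SUV.
#' @param rois a `slice_roi_series` from [slice_rois].
#' @param bg a [background_activity] with positive value.
#' @return Object of class `whole_vessel_result`: `per_slice` data frame
#'   (`slice`, `suv_mean`, `suv_max`, `tbr_mean`, `tbr_max`) and scalars
#'   `suv_mean`, `suv_max`, `tbr_mean`, `tbr_max`, `n_slices`.
#' @export
whole_vessel <- function(pet, rois, bg) {
  stopifnot(inherits(pet, "voxel_image"),
            inherits(rois, "slice_roi_series"),
            inherits(bg, "background_activity"))
  if (bg$value <= 0) stop("background activity must be positive")
  st <- t(vapply(seq_along(rois$slices),
                 function(q) roi_stats(pet, rois$masks[[q]], rois$slices[q]),
                 numeric(2)))
  per <- data.frame(slice = rois$slices,
                    suv_mean = st[, 1], suv_max = st[, 2],
                    tbr_mean = st[, 1] / bg$value,
                    tbr_max = st[, 2] / bg$value)
  structure(list(per_slice = per,
                 suv_mean = mean(per$suv_mean), suv_max = mean(per$suv_max),
                 tbr_mean = mean(per$tbr_mean), tbr_max = mean(per$tbr_max),
                 n_slices = nrow(per), background = bg$value),
            class = "whole_vessel_result")
}

#' @export
print.whole_vessel_result <- function(x, ...) {
  cat("Whole-vessel uptake over ", x$n_slices, " slices\n", sep = "")
  cat(sprintf("  SUVmean %.4f  SUVmax %.4f\n", x$suv_mean, x$suv_max))
  cat(sprintf("  TBRmean %.4f  TBRmax %.4f  (background %.4f SUV)\n",
              x$tbr_mean, x$tbr_max, x$background))
  invisible(x)
}

# highest mean over windows of `width` consecutive values; earliest
# (most proximal) window wins ties
best_window <- function(v, width = 3L) {
  n <- length(v)
  if (n < width) stop("need at least ", width, " slices")
  means <- vapply(seq_len(n - width + 1L),
                  function(i) mean(v[i:(i + width - 1L)]), numeric(1))
  i <- which.max(means)  # which.max returns the first maximum
  list(start = i, value = means[i])
}

#' Most-diseased-segment uptake
#'
#' Considers only the three consecutive axial ROIs with the highest mean
#' (SUV_MDSmean, TBR_MDSmean) and, independently, the three with the
#' highest max (SUV_MDSmax, TBR_MDSmax), so the score represents the
#' single most intense lesion. Windows for the mean- and max-based series
#' are selected independently; ties are broken in favor of the most
#' proximal window.
#'
#' @param wv a [whole_vessel] result with at least 3 slices.
#' @param width window width in slices (default 3).
#' @return Object of class `mds_result`: `suv_mds_mean`, `suv_mds_max`,
#'   `tbr_mds_mean`, `tbr_mds_max`, and the starting slice of each
#'   window (`window_mean_start`, `window_max_start`, 1-based positions
#'   in the ROI series).
#' @export
most_diseased_segment <- function(wv, width = 3L) {
  stopifnot(inherits(wv, "whole_vessel_result"))
  p <- wv$per_slice
  wm <- best_window(p$tbr_mean, width)
  wx <- best_window(p$tbr_max, width)
  sm <- best_window(p$suv_mean, width)
  sx <- best_window(p$suv_max, width)
  structure(list(tbr_mds_mean = wm$value, tbr_mds_max = wx$value,
                 suv_mds_mean = sm$value, suv_mds_max = sx$value,
                 window_mean_start = wm$start, window_max_start = wx$start,
                 width = as.integer(width)),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("Most diseased segment (", x$width, " consecutive slices)\n",
      sep = "")
  cat(sprintf("  TBR_MDSmean %.4f (window at slice position %d)\n",
              x$tbr_mds_mean, x$window_mean_start))
  cat(sprintf("  TBR_MDSmax  %.4f (window at slice position %d)\n",
              x$tbr_mds_max, x$window_max_start))
  cat(sprintf("  SUV_MDSmean %.4f  SUV_MDSmax %.4f\n",
              x$suv_mds_mean, x$suv_mds_max))
  invisible(x)
}

#' Time-delay (blood-pool clearance) background correction
#'
#' Optionally adjusts the background activity for the interval between
#' tracer injection and scan acquisition, using an exponential blood-pool
#' clearance model: `value * exp(rate * (t_scan - t_ref))`. Off by
#' default throughout the package — for aortic AMA the correction devised
#' for coronary studies is not recommended — and only applied through
#' this explicit call.
#'
#' @param bg a [background_activity].
#' @param t_scan actual injection-to-scan time, minutes.
#' @param t_ref reference injection-to-scan time, minutes.
#' @param clearance_rate blood-pool clearance rate, 1/minute.
#' @return A corrected `background_activity` with the correction recorded.
#' @export
time_delay_correct <- function(bg, t_scan, t_ref, clearance_rate) {
  stopifnot(inherits(bg, "background_activity"))
  if (!is.finite(clearance_rate) || t_scan < 0 || t_ref < 0)
    stop("need finite clearance rate and non-negative times")
  f <- exp(clearance_rate * (t_scan - t_ref))
  bg$value <- bg$value * f
  bg$per_sphere <- bg$per_sphere * f
  bg$correction <- list(t_scan = t_scan, t_ref = t_ref,
                        clearance_rate = clearance_rate, factor = f)
  bg
}

#' Build every mask a quantification needs from a VOI geometry
#'
#' Constructs the atrial sphere masks, ascending and arch tube VOIs, the
#' bone reference cube and the per-slice ROI series on a given grid.
#' Masks depend only on the geometry and the grid, so when many scans
#' share one VOI (a scan-rescan study) they can be built once and passed
#' to [quantify_aorta].
#'
#' @param grid a [voxel_image] or grid description.
#' @param voi a [voi_geometry].
#' @param sphere_volume atrial sphere volume in cm^3.
#' @param step centerline resampling step in mm.
#' @return List with `sections` (named list of tube [binary_mask]s),
#'   `sphere_ra`, `sphere_la`, `bone_ref` (mask or `NULL`), `rois`
#'   (a `slice_roi_series`).
#' @export
build_voi_masks <- function(grid, voi, sphere_volume = 2, step = 0.25) {
  stopifnot(inherits(voi, "voi_geometry"))
  g <- grid_info(grid)
  secs <- voi_sections(voi)
  masks <- lapply(secs, function(s) build_tube_mask(g, voi$centerline, s,
                                                    step = step))
  tube <- masks[[1]]$values
  for (m in masks[-1]) tube <- tube | m$values
  slice_range <- voi$slice_range
  if (is.null(slice_range)) slice_range <- c(1L, g$dim[3])
  if (slice_range[1] < 1L || slice_range[2] > g$dim[3])
    stop("slice_range must be within the grid z-extent")
  list(sections = masks,
       sphere_ra = sphere_mask(g, voi$spheres_mm$ra, sphere_volume),
       sphere_la = sphere_mask(g, voi$spheres_mm$la, sphere_volume),
       bone_ref = if (is.null(voi$bone_ref)) NULL
                  else bone_ref_mask(g, voi$bone_ref),
       rois = slice_series_from_mask(tube, slice_range, g$spacing[3]))
}

#' Quantify a PET scan with all three uptake methods
#'
#' End-to-end pipeline: builds the atrial sphere masks, the ascending and
#' arch tube VOIs and the per-slice ROI series from a VOI geometry,
#' measures blood-pool background (optionally time-delay corrected),
#' derives the bone-exclusion threshold, and computes AMA, whole-vessel
#' SUV/TBR and the most-diseased-segment metrics.
#'
#' @param pet a [voxel_image] in SUV.
#' @param voi a [voi_geometry].
#' @param threshold_ref `"bone"` to take the exclusion threshold from the
#'   VOI's bone reference cube, `"off"` to disable exclusion.
#' @param bg_correct `NULL` (default, no correction) or
#'   `list(clearance_rate, t_scan, t_ref)` for [time_delay_correct].
#' @param sphere_volume atrial sphere volume in cm^3 (default 2).
#' @param step centerline resampling step in mm for mask construction.
#' @param masks optional precomputed [build_voi_masks] result for this
#'   VOI and grid (used when quantifying many scans with one geometry).
#' @return Object of class `aorta_quant` bundling `background`,
#'   `threshold`, `ama` ([ama]), `whole_vessel` ([whole_vessel]), `mds`
#'   ([most_diseased_segment]) and the masks used.
#' @export
quantify_aorta <- function(pet, voi, threshold_ref = c("bone", "off"),
                           bg_correct = NULL, sphere_volume = 2,
                           step = 0.25, masks = NULL) {
  stopifnot(inherits(pet, "voxel_image"), inherits(voi, "voi_geometry"))
  threshold_ref <- match.arg(threshold_ref)
  if (is.null(masks))
    masks <- build_voi_masks(pet, voi, sphere_volume = sphere_volume,
                             step = step)
  bg <- background_activity(pet, masks$sphere_ra, masks$sphere_la)
  if (!is.null(bg_correct))
    bg <- time_delay_correct(bg, bg_correct$t_scan, bg_correct$t_ref,
                             bg_correct$clearance_rate)
  thr <- Inf
  if (threshold_ref == "bone") {
    if (is.null(masks$bone_ref))
      stop("threshold_ref = 'bone' but the VOI has no bone reference")
    thr <- bone_threshold(pet, masks$bone_ref)
  }
  ama_res <- ama(pet, masks$sections, bg, thr)
  wv <- whole_vessel(pet, masks$rois, bg)
  mds <- most_diseased_segment(wv)
  structure(list(background = bg, threshold = thr, ama = ama_res,
                 whole_vessel = wv, mds = mds,
                 masks = masks, rois = masks$rois),
            class = "aorta_quant")
}

#' @export
print.aorta_quant <- function(x, ...) {
  cat("18F-NaF aortic uptake quantification\n")
  cat(sprintf("  AMA          %.4f\n", x$ama$overall))
  cat(sprintf("  TBRmean      %.4f\n", x$whole_vessel$tbr_mean))
  cat(sprintf("  TBRmax       %.4f\n", x$whole_vessel$tbr_max))
  cat(sprintf("  TBR_MDSmean  %.4f\n", x$mds$tbr_mds_mean))
  cat(sprintf("  TBR_MDSmax   %.4f\n", x$mds$tbr_mds_max))
  cat(sprintf("  background %.4f SUV over %.2f cm^3; %d slice(s); %s\n",
              x$background$value, x$background$total_volume_cm3,
              x$whole_vessel$n_slices,
              if (is.finite(x$threshold))
                sprintf("bone threshold %.3f (%d voxels excluded)",
                        x$threshold, x$ama$excluded)
              else "bone threshold off"))
  invisible(x)
}

#' @export
summary.aorta_quant <- function(object, ...) {
  print(object)
  cat("\nPer-section AMA:\n")
  print(object$ama$sections, row.names = FALSE)
  invisible(object)
}

#' Headline metrics of a quantification as a one-row data frame
#'
#' @param x an `aorta_quant` object.
#' @return One-row data frame with AMA, whole-vessel and MDS metrics,
#'   volumes, threshold and excluded-voxel count — the flat form used for
#'   CSV export and agreement studies.
#' @export
quant_row <- function(x) {
  stopifnot(inherits(x, "aorta_quant"))
  data.frame(
    ama = x$ama$overall,
    tbr_mean = x$whole_vessel$tbr_mean,
    tbr_max = x$whole_vessel$tbr_max,
    tbr_mds_mean = x$mds$tbr_mds_mean,
    tbr_mds_max = x$mds$tbr_mds_max,
    suv_mean = x$whole_vessel$suv_mean,
    suv_max = x$whole_vessel$suv_max,
    background_suv = x$background$value,
    aorta_volume_cm3 = sum(x$ama$sections$volume_cm3),
    threshold = x$threshold,
    excluded_voxels = x$ama$excluded,
    n_slices = x$whole_vessel$n_slices)
}

#' Serialize a quantification result to JSON
#'
#' Writes the full result, including the per-slice SUV/TBR series, in a
#' stable JSON layout.
#'
#' @param x an `aorta_quant` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_json <- function(x, path) {
  stopifnot(inherits(x, "aorta_quant"))
  obj <- list(
    background = list(value = x$background$value,
                      per_sphere = as.list(x$background$per_sphere),
                      total_volume_cm3 = x$background$total_volume_cm3,
                      correction = x$background$correction),
    threshold = if (is.finite(x$threshold)) x$threshold else "off",
    ama = list(overall = x$ama$overall, excluded = x$ama$excluded,
               sections = x$ama$sections),
    whole_vessel = list(
      suv_mean = x$whole_vessel$suv_mean, suv_max = x$whole_vessel$suv_max,
      tbr_mean = x$whole_vessel$tbr_mean, tbr_max = x$whole_vessel$tbr_max,
      n_slices = x$whole_vessel$n_slices,
      per_slice = x$whole_vessel$per_slice),
    most_diseased_segment = unclass(x$mds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
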
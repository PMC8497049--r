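#' Construct a voxel image
#'
#' A `voxel_image` is a 3-D numeric array of voxel intensities (SUV unless
#' stated otherwise) together with its physical grid: per-axis voxel size in
#' mm and the world position of the first voxel's center. Voxel indices are
#' 0-based in world-coordinate formulas: the center of voxel `(i, j, k)`
#' (0-based) sits at `origin + c(i, j, k) * spacing`. No resampling is ever
#' performed; all masks are built directly on this grid.
#'
#' @param values 3-D numeric array of finite voxel values.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, world position (mm) of the center of the
#'   first voxel.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array, got ", length(dim(values)), " dims")
  if (!all(is.finite(values)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n",
      sep = "")
  v <- range(x$values)
  cat("  value range [", format(v[1]), ", ", format(v[2]), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$values)

#' Binary mask on a voxel grid
#'
#' A `binary_mask` shares the grid of a paired [voxel_image] and stores a
#' logical array marking voxels inside a volume of interest.
#'
#' @param values 3-D logical array.
#' @param spacing,origin grid metadata, as in [voxel_image].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical (or 0/1)")
    storage.mode(values) <- "logical"
  }
  g <- voxel_image(array(0, dim = dim(values)), spacing, origin)
  structure(list(values = values, spacing = g$spacing, origin = g$origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels, ", sum(x$values), " set (",
      format(mask_volume(x), digits = 4), " cm^3)\n", sep = "")
  invisible(x)
}

# shared grid description: list(dim, spacing, origin)
grid_info <- function(x) {
  if (inherits(x, c("voxel_image", "binary_mask")))
    return(list(dim = dim(x$values), spacing = x$spacing, origin = x$origin))
  if (is.list(x) && all(c("dim", "spacing", "origin") %in% names(x)))
    return(list(dim = as.integer(x$dim), spacing = as.numeric(x$spacing),
                origin = as.numeric(x$origin)))
  stop("cannot interpret object as a voxel grid")
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_info(a); gb <- grid_info(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol
}

#' Volume of a single voxel in cubic centimeters
#'
#' @param img a [voxel_image], [binary_mask], or grid description.
#' @return Voxel volume in cm^3 (product of the spacings in mm divided by
#'   1000).
#' @export
voxel_volume <- function(img) {
  prod(grid_info(img)$spacing) / 1000
}

#' Volume of a binary mask in cubic centimeters
#'
#' @param mask a [binary_mask].
#' @return Number of set voxels times the voxel volume, in cm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$values) * voxel_volume(mask)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [voxel_image], taking the voxel spacing from
#' the pixdim field and the origin from the sform/qform translation. Only
#' 3-D volumes are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) != 3L)
    stop("expected a 3-D volume, got ", length(d), " dimensions in ", path)
  sp <- RNifti::pixdim(nii)
  if (length(sp) < 3L || any(sp[1:3] <= 0))
    stop("non-positive voxel spacing in ", path)
  xf <- RNifti::xform(nii)
  org <- as.numeric(xf[1:3, 4])
  voxel_image(array(as.numeric(nii), dim = d), spacing = sp[1:3], origin = org)
}

#' Write a voxel image as NIfTI
#'
#' Values are stored as float64, so [read_image] reproduces them bit-exactly;
#' spacing and origin survive the round trip to well below 1e-6 mm.
#'
#' @param img a [voxel_image] (a [binary_mask] is accepted and written as
#'   0/1 doubles).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  g <- grid_info(img)
  vals <- img$values
  if (is.logical(vals)) storage.mode(vals) <- "double"
  nii <- RNifti::asNifti(vals)
  RNifti::pixdim(nii) <- g$spacing
  m <- diag(c(g$spacing, 1))
  m[1:3, 4] <- g$origin
  RNifti::sform(nii) <- structure(m, code = 2L)
  RNifti::qform(nii) <- structure(m, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Parameters for SUV conversion
#'
#' @param injected_dose injected activity in MBq.
#' @param body_weight patient body weight in kg.
#' @param injection_to_scan minutes from injection to scan acquisition.
#' @param half_life isotope half-life in minutes; default 109.77 (18F).
#' @return An object of class `suv_params`.
#' @export
suv_params <- function(injected_dose, body_weight, injection_to_scan,
                       half_life = 109.77) {
  p <- list(injected_dose = as.numeric(injected_dose),
            body_weight = as.numeric(body_weight),
            injection_to_scan = as.numeric(injection_to_scan),
            half_life = as.numeric(half_life))
  if (any(vapply(p, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("all SUV parameters must be strictly positive and finite")
  structure(p, class = "suv_params")
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV: `SUV = C / (D_decayed / W)` with the activity
#' concentration `C` in kBq/mL, the injected dose decayed to scan time
#' (`D_decayed = dose * 2^(-t/half_life)`) expressed in kBq, and the body
#' weight in g (1 g of tissue is taken as 1 mL). The result is unitless and
#' linear in the input activity.
#'
#' @param activity a [voxel_image] whose values are activity concentration
#'   in kBq/mL (all >= 0).
#' @param params an [suv_params] object.
#' @return A [voxel_image] in SUV units on the same grid.
#' @export
suv_convert <- function(activity, params) {
  stopifnot(inherits(activity, "voxel_image"), inherits(params, "suv_params"))
  if (any(activity$values < 0))
    stop("activity values must be non-negative")
  dose_kbq <- params$injected_dose * 1000 *
    2^(-params$injection_to_scan / params$half_life)
  weight_g <- params$body_weight * 1000
  voxel_image(activity$values / (dose_kbq / weight_g),
              spacing = activity$spacing, origin = activity$origin)
}
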
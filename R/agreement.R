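#' Bland-Altman agreement analysis
#'
#' For paired measurements of the same quantity, computes the paired
#' differences `d = a - b`, their mean (the bias, "mean error"), the 95%
#' limits of agreement `mean(d) +/- 1.96 sd(d)` (sample standard
#' deviation, n-1), the coefficient of repeatability `CR = 1.96 sd(d)`
#' (the smallest change detectable beyond measurement error) and CR as a
#' percentage of the grand mean of all 2n measurements. Pairs with a
#' missing value in either series are dropped (listwise deletion).
#'
#' @param a,b numeric vectors of paired measurements (same length,
#'   same units), at least 2 complete pairs.
#' @return Object of class `bland_altman`: `mean_error`, `loa`
#'   (length 2), `cr`, `cr_pct`, `sd_diff`, `n`, plus the retained pairs.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  ok <- stats::complete.cases(a, b)
  a <- as.numeric(a[ok]); b <- as.numeric(b[ok])
  n <- length(a)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  cr <- 1.96 * s
  grand <- mean(c(a, b))
  structure(list(mean_error = m, loa = c(m - cr, m + cr),
                 cr = cr, cr_pct = if (grand != 0) 100 * cr / grand else NA,
                 sd_diff = s, n = n, a = a, b = b),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean error %.4f, 95%% LOA (%.4f, %.4f)\n",
    x$n, x$mean_error, x$loa[1], x$loa[2]))
  cat(sprintf("  coefficient of repeatability %.4f (%s of mean)\n",
              x$cr, if (is.na(x$cr_pct)) "NA"
                    else sprintf("%.1f%%", x$cr_pct)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Paired means against paired differences, with the bias (solid line)
#' and 95% limits of agreement (dashed lines).
#'
#' @param x a [bland_altman] object.
#' @param ... further arguments to [graphics::plot].
#' @export
plot.bland_altman <- function(x, ...) {
  m <- (x$a + x$b) / 2
  d <- x$a - x$b
  graphics::plot(m, d, xlab = "Mean of pair", ylab = "Difference", ...)
  graphics::abline(h = x$mean_error, col = "blue")
  graphics::abline(h = x$loa, col = "red", lty = 2)
  invisible(x)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' for paired measurements (two raters/scans per subject), computed from
#' the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`.
#' Absolute agreement penalizes systematic offsets between the two
#' measurement occasions, the appropriate choice for test-retest of a
#' measurement method.
#'
#' @param a,b numeric vectors of paired measurements, at least 3
#'   complete pairs.
#' @return The ICC (scalar, at most 1).
#' @export
icc <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  ok <- stats::complete.cases(a, b)
  a <- as.numeric(a[ok]); b <- as.numeric(b[ok])
  n <- length(a)
  if (n < 3) stop("need at least 3 complete pairs")
  k <- 2
  x <- cbind(a, b)
  grand <- mean(x)
  subj <- rowMeans(x)
  rater <- colMeans(x)
  if (sum((x - grand)^2) == 0)
    stop("ICC undefined: zero total variance")
  msr <- k * sum((subj - grand)^2) / (n - 1)
  msc <- n * sum((rater - grand)^2) / (k - 1)
  resid <- x - outer(subj, rep(1, k)) - outer(rep(1, n), rater) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Pearson correlation with two-sided test
#'
#' Sample Pearson correlation and its two-sided p-value from the
#' t-distribution with n-2 degrees of freedom — the association test used
#' between PET uptake metrics and clinical risk scores.
#'
#' @param x,y numeric vectors, equal length, n >= 3 complete pairs,
#'   non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Full agreement report for one paired series
#'
#' Bundles the Bland-Altman quantities and the ICC for a paired
#' measurement series — one row of a repeatability/reproducibility table.
#'
#' @param a,b numeric vectors of paired measurements (>= 3 pairs).
#' @param label optional series label.
#' @return Object of class `agreement_report`: `mean_error`, `loa`,
#'   `cr`, `cr_pct`, `icc`, `n`, `label`.
#' @export
agreement_report <- function(a, b, label = NULL) {
  ba <- bland_altman(a, b)
  icc_val <- tryCatch(icc(a, b), error = function(e) NA_real_)
  structure(list(label = label, mean_error = ba$mean_error, loa = ba$loa,
                 cr = ba$cr, cr_pct = ba$cr_pct, icc = icc_val, n = ba$n),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  if (!is.null(x$label)) cat(x$label, "\n")
  cat(sprintf(
    "  n %d  mean error %.4f  95%% LOA (%.4f, %.4f)  CR %.4f (%s)  ICC %s\n",
    x$n, x$mean_error, x$loa[1], x$loa[2], x$cr,
    if (is.na(x$cr_pct)) "NA" else sprintf("%.0f%%", x$cr_pct),
    if (is.na(x$icc)) "NA" else sprintf("%.3f", x$icc)))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(label = if (is.null(x$label)) NA_character_ else x$label,
             n = x$n, mean_error = x$mean_error,
             loa_low = x$loa[1], loa_high = x$loa[2],
             cr = x$cr, cr_pct = x$cr_pct, icc = x$icc)
}

# metrics carried through the repeatability harnesses
harness_metrics <- c("ama", "tbr_mean", "tbr_max", "tbr_mds_mean",
                     "tbr_mds_max")

# randomized per-subject disease burden for the harness: wall TBR uniform
# in `wall_tbr_range`, Poisson(lesion_rate) lesions with uniform
# position, amplitude and width
randomize_subject <- function(cfg, wall_tbr_range, lesion_rate) {
  cfg$wall_tbr <- stats::runif(1, wall_tbr_range[1], wall_tbr_range[2])
  n_les <- stats::rpois(1, lesion_rate)
  span <- c(cfg$stj_offset_mm,
            cfg$stj_offset_mm + cfg$ascending_length +
              cfg$lsa_frac * pi * cfg$arch_radius)
  cfg$lesions <- replicate(n_les, list(
    position_mm = stats::runif(1, span[1], span[2]),
    amplitude = stats::runif(1, 0.3, 1.5),
    sigma_mm = stats::runif(1, 5, 15)), simplify = FALSE)
  cfg
}

#' Scan-rescan reproducibility harness on phantom subjects
#'
#' Draws `n_subjects` phantom anatomies from a common configuration
#' template with randomized disease burden (wall TBR and focal lesion
#' count/intensity), simulates two noise realizations of each — the
#' digital counterpart of a scan-rescan study — quantifies both scans
#' with the identical ground-truth VOI, and reports agreement statistics
#' per uptake metric. Fully reproducible from `seed`.
#'
#' @param cfg a [phantom_config] template (its geometry is shared by all
#'   subjects; its `noise_sd` applies unless overridden).
#' @param n_subjects number of simulated subjects (>= 3).
#' @param seed integer master seed.
#' @param wall_tbr_range range of the per-subject baseline wall TBR.
#' @param lesion_rate expected lesion count per subject (Poisson).
#' @param noise_sd optional override of the template's noise level.
#' @param threshold_ref passed to [quantify_aorta].
#' @return List with `pairs` (data frame: subject, metric, value_a,
#'   value_b) and `reports` (named list of [agreement_report]s, one per
#'   metric).
#' @export
scan_rescan_harness <- function(cfg, n_subjects = 20, seed = 1,
                                wall_tbr_range = c(1.0, 1.6),
                                lesion_rate = 2,
                                noise_sd = NULL,
                                threshold_ref = "bone") {
  stopifnot(inherits(cfg, "phantom_config"))
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (!is.null(noise_sd)) cfg$noise_sd <- noise_sd
  draws <- with_seed(as.integer(seed), {
    list(subj_seeds = sample.int(2^30, 2 * n_subjects),
         cfgs = replicate(n_subjects,
                          randomize_subject(cfg, wall_tbr_range,
                                            lesion_rate),
                          simplify = FALSE))
  })
  geom <- phantom_geometry(cfg)
  voi <- truth_to_voi(geom$truth)
  voi_masks <- build_voi_masks(geom$grid, voi)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cs <- draws$cfgs[[s]]
    signal <- phantom_signal(cs, geom)
    quant_one <- function(noise_seed) {
      vol <- signal
      if (cs$noise_sd > 0)
        vol <- vol + with_seed(noise_seed,
          array(stats::rnorm(length(vol), sd = cs$noise_sd),
                dim = dim(vol)))
      pet <- voxel_image(vol, cs$spacing, c(0, 0, 0))
      quant_row(quantify_aorta(pet, voi, threshold_ref = threshold_ref,
                               masks = voi_masks))
    }
    qa <- quant_one(draws$subj_seeds[2 * s - 1])
    qb <- quant_one(draws$subj_seeds[2 * s])
    rows[[s]] <- data.frame(subject = s, metric = harness_metrics,
                            value_a = unlist(qa[harness_metrics],
                                             use.names = FALSE),
                            value_b = unlist(qb[harness_metrics],
                                             use.names = FALSE))
  }
  pairs <- do.call(rbind, rows)
  reports <- lapply(harness_metrics, function(m) {
    sub <- pairs[pairs$metric == m, ]
    agreement_report(sub$value_a, sub$value_b, label = m)
  })
  names(reports) <- harness_metrics
  list(pairs = pairs, reports = reports)
}

#' Simulate observer redrawing of a VOI geometry
#'
#' Human observers vary in where they place the centerline, landmarks and
#' atrial spheres, not in the image itself. This perturbs a VOI geometry
#' accordingly: a random rigid shift plus smooth per-point jitter of the
#' centerline, Gaussian jitter of the landmark arc-lengths and of the
#' sphere centers.
#'
#' @param voi a [voi_geometry].
#' @param sd_mm jitter magnitude (mm): standard deviation of the shifts.
#' @param seed integer seed.
#' @return A perturbed [voi_geometry].
#' @export
jitter_voi <- function(voi, sd_mm, seed) {
  stopifnot(inherits(voi, "voi_geometry"))
  if (sd_mm < 0) stop("sd_mm must be >= 0")
  if (sd_mm == 0) return(voi)
  with_seed(as.integer(seed), {
    pts <- voi$centerline$points
    shift <- stats::rnorm(3, sd = sd_mm)
    # smooth per-point wobble: low-frequency sine with random phase
    s <- voi$centerline$arclen
    wobble <- vapply(1:3, function(ax)
      stats::rnorm(1, sd = sd_mm / 2) *
        sin(2 * pi * s / max(s) + stats::runif(1, 0, 2 * pi)),
      numeric(length(s)))
    pts <- sweep(pts, 2, -shift) + wobble
    lm <- lapply(voi$landmarks_mm, function(v) v + stats::rnorm(1, sd = sd_mm))
    total <- centerline_length(centerline(pts))
    lm$stj <- max(0.5, lm$stj)
    lm$brachiocephalic <- max(lm$stj + 1, lm$brachiocephalic)
    lm$left_subclavian <- max(lm$brachiocephalic + 1, lm$left_subclavian)
    arch_end <- min(total - 0.5,
                    voi$arch_end_mm - voi$landmarks_mm$left_subclavian +
                      lm$left_subclavian)
    sph <- lapply(voi$spheres_mm, function(c0) c0 + stats::rnorm(3, sd = sd_mm))
    voi_geometry(centerline(pts), lm, voi$lumen_diameter_mm, sph,
                 bone_ref = voi$bone_ref, slice_range = voi$slice_range,
                 arch_end_mm = arch_end)
  })
}

#' Simulated observer and scan-rescan validation study
#'
#' Recreates the design of a repeatability table on phantom subjects:
#' for each simulated subject, intra-observer agreement (same scan,
#' small VOI redraw jitter), inter-observer agreement (same scan, larger
#' jitter) and scan-rescan reproducibility (second noise realization,
#' same VOI) are evaluated for every uptake metric.
#'
#' @param cfg a [phantom_config] template.
#' @param n_subjects number of simulated subjects (>= 3).
#' @param seed integer master seed.
#' @param jitter_intra,jitter_inter VOI jitter (mm) for the intra- and
#'   inter-observer comparisons.
#' @param wall_tbr_range,lesion_rate per-subject disease burden, as in
#'   [scan_rescan_harness].
#' @param threshold_ref passed to [quantify_aorta].
#' @return List with `table` (data frame: comparison, metric, n,
#'   mean_error, loa_low, loa_high, cr, cr_pct, icc) and `pairs` (all
#'   paired values).
#' @export
validate_study <- function(cfg, n_subjects = 20, seed = 1,
                           jitter_intra = 0.5, jitter_inter = 1.5,
                           wall_tbr_range = c(1.0, 1.6), lesion_rate = 2,
                           threshold_ref = "bone") {
  stopifnot(inherits(cfg, "phantom_config"))
  if (n_subjects < 3) stop("need at least 3 subjects")
  draws <- with_seed(as.integer(seed), {
    list(seeds = matrix(sample.int(2^30, 4 * n_subjects), ncol = 4),
         cfgs = replicate(n_subjects,
                          randomize_subject(cfg, wall_tbr_range,
                                            lesion_rate),
                          simplify = FALSE))
  })
  geom <- phantom_geometry(cfg)
  voi <- truth_to_voi(geom$truth)
  voi_masks <- build_voi_masks(geom$grid, voi)
  quant_metrics <- function(pet, v, m = NULL)
    unlist(quant_row(quantify_aorta(pet, v, threshold_ref = threshold_ref,
                                    masks = m))[harness_metrics])
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cs <- draws$cfgs[[s]]
    signal <- phantom_signal(cs, geom)
    make_pet <- function(noise_seed) {
      vol <- signal
      if (cs$noise_sd > 0)
        vol <- vol + with_seed(noise_seed,
          array(stats::rnorm(length(vol), sd = cs$noise_sd),
                dim = dim(vol)))
      voxel_image(vol, cs$spacing, c(0, 0, 0))
    }
    pet1 <- make_pet(draws$seeds[s, 1])
    pet2 <- make_pet(draws$seeds[s, 2])
    base <- quant_metrics(pet1, voi, voi_masks)
    intra <- quant_metrics(pet1, jitter_voi(voi, jitter_intra,
                                            draws$seeds[s, 3]))
    inter <- quant_metrics(pet1, jitter_voi(voi, jitter_inter,
                                            draws$seeds[s, 4]))
    rescan_m <- quant_metrics(pet2, voi, voi_masks)
    for (m in harness_metrics) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, metric = m,
        comparison = c("intra_observer", "inter_observer", "scan_rescan"),
        value_a = base[[m]],
        value_b = c(intra[[m]], inter[[m]], rescan_m[[m]]))
    }
  }
  pairs <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(
    pairs, list(pairs$comparison, pairs$metric)), function(sub) {
      rep <- agreement_report(sub$value_a, sub$value_b)
      cbind(data.frame(comparison = sub$comparison[1],
                       metric = sub$metric[1]),
            as.data.frame(rep)[, -1])
    }))
  rownames(tab) <- NULL
  list(table = tab, pairs = pairs)
}
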
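# Compact phantom configurations used throughout the suite: same anatomy
# family as the defaults, on a 64^3 grid with 3 mm voxels so the full
# candy-cane (ascending + arch + descending stub), atria and sternum fit.

small_cfg <- function(...) {
  phantom_config(shape = c(64L, 64L, 64L), spacing = c(3, 3, 3),
                 ascending_length = 60, rpa_level_mm = 60, ...)
}

# degenerate limit: no lesions, no bones, no blur, no noise (callers may
# override any of those)
clean_cfg <- function(...) {
  args <- list(psf_fwhm = 0, noise_sd = 0, lesions = list(),
               bones = list())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(small_cfg, args)
}
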
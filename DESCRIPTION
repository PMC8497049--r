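Package: aortama
Title: Aortic Microcalcification Activity Scoring for 18F-NaF PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification of 18F-sodium fluoride uptake in the thoracic
    aorta from PET volumes in standardized uptake value (SUV) units.
    Implements the aortic microcalcification activity (AMA) score together
    with the conventional whole-vessel and most-diseased-segment
    tissue-to-background ratio (TBR) methods, tubular volume-of-interest
    geometry built from a vessel centerline, atrial blood-pool background
    sampling with 2-cm3 spheres, bone spill-over thresholding, a synthetic
    thoracic-aorta PET phantom generator with known ground truth, and the
    repeatability and agreement statistics (Bland-Altman limits of
    agreement, coefficient of repeatability, intraclass correlation) used
    to validate PET uptake metrics in scan-rescan and observer studies.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
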
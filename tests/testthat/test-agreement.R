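test_that("Bland-Altman matches hand computation and degenerate cases", {
  x <- c(1, 2, 3, 4)
  perfect <- bland_altman(x, x)
  expect_equal(perfect$mean_error, 0)
  expect_equal(perfect$loa, c(0, 0))
  expect_equal(perfect$cr, 0)

  a <- c(1, 2, 3); b <- c(1.1, 1.9, 3.2)
  ba <- bland_altman(a, b)
  d <- c(-0.1, 0.1, -0.2)
  expect_equal(ba$mean_error, mean(d), tolerance = 1e-12)
  expect_equal(ba$cr, 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa, mean(d) + c(-1, 1) * 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$cr_pct, 100 * ba$cr / mean(c(a, b)), tolerance = 1e-12)

  expect_error(bland_altman(1, c(1, 2)), "equal length")
  expect_error(bland_altman(c(1, NA), c(2, 3)), "at least 2")
})

test_that("Bland-Altman difference statistics ignore a common shift", {
  set.seed(21)
  a <- rnorm(12, 10); b <- a + rnorm(12, 0, 0.3)
  base <- bland_altman(a, b)
  shifted <- bland_altman(a + 5, b + 5)
  expect_equal(shifted$mean_error, base$mean_error, tolerance = 1e-12)
  expect_equal(shifted$loa, base$loa, tolerance = 1e-12)
  expect_equal(shifted$cr, base$cr, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(shifted$cr_pct, base$cr_pct)))

  # antisymmetry under swapping the two series
  sw <- bland_altman(b, a)
  expect_equal(sw$mean_error, -base$mean_error, tolerance = 1e-12)
  expect_equal(sw$loa, -rev(base$loa), tolerance = 1e-12)
  expect_equal(sw$cr, base$cr, tolerance = 1e-12)
})

test_that("ICC(2,1) agrees with the ANOVA mean-square route", {
  a <- c(1, 2, 3, 4); b <- c(1.1, 1.9, 3.2, 3.9)
  expect_equal(icc(a, b), bf_icc_aov(a, b), tolerance = 1e-10)

  # perfect agreement with spread
  expect_equal(icc(c(1, 2, 3, 5), c(1, 2, 3, 5)), 1, tolerance = 1e-12)

  # a large constant offset is penalized by absolute agreement
  small <- c(1, 1.1, 1.2, 1.05)
  expect_lt(icc(small, small + 5), 0.1)

  expect_error(icc(c(1, 1, 1), c(1, 1, 1)), "zero total variance")
  expect_error(icc(c(1, 2), c(1, 2)), "at least 3")
})

test_that("ICC is invariant under a common positive affine transform", {
  set.seed(8)
  a <- rnorm(10, 1.2, 0.2); b <- a + rnorm(10, 0.02, 0.05)
  expect_equal(icc(3 * a + 2, 3 * b + 2), icc(a, b), tolerance = 1e-10)
})

test_that("Pearson correlation matches the closed-form oracle", {
  x <- 1:5
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  y <- c(2, 1, 4, 3, 5)
  pc <- pearson_cor(x, y)
  bf <- bf_pearson(x, y)
  expect_equal(pc$r, bf$r, tolerance = 1e-12)
  expect_equal(pc$p, bf$p, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  # positive affine transforms of either variable leave r unchanged
  expect_equal(pearson_cor(2 * x + 3, y)$r, pc$r, tolerance = 1e-12)
})

test_that("all statistics match brute force on random 10-subject tables", {
  set.seed(99)
  for (rep in 1:10) {
    a <- rnorm(10, 1.2, 0.25)
    b <- a + rnorm(10, 0.01, 0.08)
    ba <- bland_altman(a, b); bf <- bf_bland_altman(a, b)
    expect_equal(ba$mean_error, bf$mean_error, tolerance = 1e-10)
    expect_equal(ba$loa, bf$loa, tolerance = 1e-10)
    expect_equal(ba$cr_pct, bf$cr_pct, tolerance = 1e-10)
    expect_equal(icc(a, b), bf_icc_aov(a, b), tolerance = 1e-10)
    pc <- pearson_cor(a, b); bp <- bf_pearson(a, b)
    expect_equal(pc$r, bp$r, tolerance = 1e-10)
    expect_equal(pc$p, bp$p, tolerance = 1e-10)
  }
})

test_that("agreement tables and risk-score correlations round-trip", {
  set.seed(4)
  pairs <- do.call(rbind, lapply(c("ama", "tbr_max"), function(m) {
    a <- rnorm(8, 1.2, 0.2)
    data.frame(subject = 1:8, metric = m, value_a = a,
               value_b = a + rnorm(8, 0, 0.05))
  }))
  rep <- agreement_from_table(pairs)
  expect_setequal(rep$metric, c("ama", "tbr_max"))
  sub <- pairs[pairs$metric == "ama", ]
  expect_equal(rep$icc[rep$metric == "ama"],
               icc(sub$value_a, sub$value_b), tolerance = 1e-12)

  metrics <- data.frame(subject_id = 1:10, ama = rnorm(10, 1.1, 0.15))
  scores <- data.frame(subject_id = 1:10,
                       framingham_stroke = rnorm(10, 12, 4))
  out <- correlate_risk_scores(metrics, scores)
  expect_equal(out$r, pearson_cor(metrics$ama,
                                  scores$framingham_stroke)$r)
  expect_error(correlate_risk_scores(metrics[1:2, ], scores[1:2, ]),
               "fewer than 3")
})

test_that("observer jitter is seeded, bounded and optional", {
  ph <- generate_phantom(clean_cfg())
  voi <- truth_to_voi(ph$truth)
  expect_identical(jitter_voi(voi, 0, 1), voi)
  j1 <- jitter_voi(voi, 1, 7)
  j2 <- jitter_voi(voi, 1, 7)
  expect_equal(j1$centerline$points, j2$centerline$points)
  expect_false(identical(j1$centerline$points, voi$centerline$points))
  # jitter magnitude stays in the vicinity of sd_mm
  expect_lt(max(abs(j1$centerline$points - voi$centerline$points)), 10)
  # jittered geometry still quantifies
  q <- quantify_aorta(ph$pet, j1, threshold_ref = "off")
  expect_true(is.finite(q$ama$overall))
})

test_that("a noise-free scan-rescan study has perfect agreement", {
  hr <- scan_rescan_harness(clean_cfg(), n_subjects = 4, seed = 3,
                            noise_sd = 0, threshold_ref = "off")
  for (m in names(hr$reports)) {
    expect_equal(hr$reports[[m]]$cr, 0)
    expect_equal(hr$reports[[m]]$mean_error, 0)
    expect_equal(hr$reports[[m]]$icc, 1, tolerance = 1e-9)
  }
  # subjects genuinely differ
  amas <- hr$pairs$value_a[hr$pairs$metric == "ama"]
  expect_gt(sd(amas), 0)
})
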
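test_that("volume fraction is the Delesse area fraction", {
  expect_equal(as.numeric(volume_fraction(10, 2e4, 1e7)), 0.02)
  expect_identical(as.numeric(volume_fraction(0, 2e4, 1e7)), 0)
  expect_error(volume_fraction(10, 2e4, 0), class = "nephest_domain_error")
  expect_warning(vf <- volume_fraction(1e5, 2e4, 1e7), "clipped")
  expect_identical(as.numeric(vf), 1)
  expect_true(attr(vf, "clipped"))
})

test_that("total glomerular number reconciles units and is linear", {
  g <- glomerular_geometry(100, 2.5)
  # 0.03 of 100 cm^3 = 3e12 um^3 of glomerular volume; mean glomerular
  # volume 4/3*pi*1e6 um^3
  expect_equal(total_glomerular_number(0.03, 100, g, "cm3"),
               0.03 * 1e14 / (4 / 3 * pi * 1e6))
  expect_equal(total_glomerular_number(0.03, 100, g, "cm3"), 716197,
               tolerance = 1e-5)
  expect_identical(total_glomerular_number(0, 100, g, "cm3"), 0)
  expect_equal(total_glomerular_number(0.03, 200, g, "cm3"),
               2 * total_glomerular_number(0.03, 100, g, "cm3"))
  # the same volume under both unit tags agrees
  expect_equal(total_glomerular_number(0.03, 100, g, "cm3"),
               total_glomerular_number(0.03, 1e5, g, "mm3"))
  expect_error(total_glomerular_number(0.03, 100, g, "litre"))
})

test_that("cohort mean radius subsamples deterministically", {
  radii <- seq(40, 59, length.out = 20)
  noshrink <- shrinkage_model(0, 0)
  # ceiling(0.05 * 20) = 1 patient
  r1 <- cohort_mean_radius(radii, 0.05, seed = 7, shrinkage = noshrink)
  expect_true(r1 %in% radii)
  expect_identical(r1, cohort_mean_radius(radii, 0.05, seed = 7,
                                          shrinkage = noshrink))
  expect_equal(cohort_mean_radius(radii, 1, shrinkage = noshrink),
               mean(radii))
  # on-slide radii are corrected by the glomerular factor
  f <- shrinkage_model()$linear_factor_glomerulus
  expect_equal(cohort_mean_radius(radii * f, 1), mean(radii))
  expect_error(cohort_mean_radius(numeric()), class = "nephest_domain_error")
})

test_that("estimate_nephrons composes the chain consistently", {
  sp <- make_specimen(counts = 10, lengths = list(10))
  g <- glomerular_geometry(100, 2.5)
  est <- estimate_nephrons(sp, 100, g, table = c(`16` = 1.0), unit = "cm3")
  # recompute step by step
  a_cortex <- cortex_section_area(sp, shrinkage_model(), c(`16` = 1.0))
  a_h <- mean_profile_area(g)
  vf <- as.numeric(volume_fraction(10, a_h, a_cortex))
  expect_equal(est$mean_profile_area, a_h)
  expect_equal(est$cortex_area, a_cortex)
  expect_identical(est$n_profiles_used, 10L)
  expect_equal(est$volume_fraction, vf)
  expect_equal(est$total_number,
               total_glomerular_number(vf, 100, g, "cm3"))
  expect_identical(est$adequacy, "adequate")
})

test_that("the estimate is invariant under a global change of volume unit", {
  sp <- make_specimen(counts = c(6, 8), lengths = list(8, c(4, 3)))
  g <- glomerular_geometry(90, 2.5)
  est_cm <- estimate_nephrons(sp, 150, g, unit = "cm3")
  est_mm <- estimate_nephrons(sp, 150e3, g, unit = "mm3")
  expect_equal(est_cm$total_number, est_mm$total_number)
})

test_that("sclerotic glomeruli reduce only the non-sclerotic count", {
  sp <- make_specimen(counts = c(6, 6), lengths = list(8, 8),
                      sclerotic = c(2, 1))
  g <- glomerular_geometry(100, 2.5)
  est <- estimate_nephrons(sp, 100, g)
  expect_equal(est$total_number_nonsclerotic / est$total_number, 9 / 12)
  expect_lte(est$total_number_nonsclerotic, est$total_number)
})

test_that("all-single-glomerulus specimens report zero with the flag", {
  sp <- make_specimen(counts = c(1, 1), lengths = list(5, 5))
  g <- glomerular_geometry(100, 2.5)
  est <- estimate_nephrons(sp, 100, g)
  expect_identical(est$adequacy, "insufficient")
  expect_identical(est$n_profiles_used, 0L)
  expect_identical(est$total_number, 0)
})

test_that("insufficient specimens still carry the numeric estimate", {
  sp <- make_specimen(counts = c(3, 4), lengths = list(5, 5))
  est <- estimate_nephrons(sp, 100, glomerular_geometry(100, 2.5))
  expect_identical(est$adequacy, "insufficient")
  expect_gt(est$total_number, 0)
})

test_that("the audit payload names every intermediate", {
  sp <- make_specimen(counts = 10, lengths = list(10))
  est <- estimate_nephrons(sp, 100, glomerular_geometry(100, 2.5))
  rep <- estimate_report(est)
  expect_true(all(c("linear_factor_tissue", "linear_factor_glomerulus",
                    "mean_profile_area_um2", "cortex_area_um2",
                    "n_profiles_used", "volume_fraction", "total_number",
                    "total_number_nonsclerotic", "adequacy",
                    "sections_ignored") %in% names(rep)))
})
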
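# Constitutive models, plaque scoring and material-table behavior.

test_that("uniaxial stress is zero at the reference state for every material", {
  for (nm in names(fix_table$soft))
    expect_identical(uniaxial_stress(fix_table$soft[[nm]], 1), 0,
                     label = nm)
})

test_that("uniaxial stress matches numerical differentiation of the strain energy", {
  # independent oracle: sigma = lambda * dW/dlambda (incompressible uniaxial),
  # dW/dlambda by central differences on the energy density
  h <- 1e-6
  lam <- seq(0.9, 1.3, by = 0.02)
  for (nm in names(fix_table$soft)) {
    co <- fix_table$soft[[nm]]
    co_nocap <- rp_coeffs(co$C, label = nm)   # cap off: differentiation oracle
    sig_num <- lam * (strain_energy(co_nocap, lam + h) -
                      strain_energy(co_nocap, lam - h)) / (2 * h)
    sig <- uniaxial_stress(co_nocap, lam)
    denom <- pmax(abs(sig_num), 1e-6)   # floor: sigma(1) = 0 exactly
    expect_lt(max(abs(sig - sig_num) / denom), 1e-4, label = nm)
  }
})

test_that("silicone Neo-Hookean stress at 10% stretch matches the derivative oracle", {
  # frozen from the central-difference oracle above: 2*C10*(lam^2 - 1/lam)
  expect_equal(uniaxial_stress(fix_table$soft$silicone, 1.1), 0.0926800,
               tolerance = 1e-5)
  expect_equal(neo_hookean_stress(0.154, 1.1),
               uniaxial_stress(fix_table$soft$silicone, 1.1))
  expect_lt(neo_hookean_stress(0.154, 0.9), 0)   # compression is negative
})

test_that("plaque yield caps apply (very stiff saturates at 627 MPa)", {
  expect_equal(uniaxial_stress(fix_table$soft$very_stiff, 1.3), 627)
  # below the cap the curve is untouched
  lo <- uniaxial_stress(fix_table$soft$very_stiff, 1.001)
  expect_lt(lo, 627)
  expect_gt(lo, 0)
})

test_that("plaque-class stresses are strictly ordered at 20% stretch (not at small strain)", {
  s12 <- vapply(fix_table$plaque_classes, function(nm)
    uniaxial_stress(fix_table$soft[[nm]], 1.2), numeric(1L))
  expect_true(all(diff(s12) > 0))
  # the infinitesimal limit is NOT ordered: C10(soft) < C10(very_soft)
  s_small <- vapply(fix_table$plaque_classes, function(nm)
    uniaxial_stress(fix_table$soft[[nm]], 1.0001), numeric(1L))
  expect_false(all(diff(s_small) > 0))
})

test_that("fit_neo_hookean recovers C10 and rejects degenerate input", {
  lam <- seq(1.01, 1.3, length.out = 20)
  sig <- neo_hookean_stress(0.154, lam)
  expect_equal(fit_neo_hookean(lam, sig), 0.154, tolerance = 1e-6)
  # symmetric noise: bias shrinks like sd/sqrt(n)
  set.seed(42)
  n <- 100
  lam2 <- seq(1.05, 1.3, length.out = n)
  noise <- stats::rnorm(n, sd = 0.005)
  fit <- fit_neo_hookean(lam2, neo_hookean_stress(0.154, lam2) + noise)
  expect_lt(abs(fit - 0.154), 5 * 0.005 / sqrt(n))
  expect_error(fit_neo_hookean(1.1, 0.05), "3 samples")
  expect_error(fit_neo_hookean(c(1, 1, 1), c(0, 0, 0)), "degenerate")
})

test_that("plaque score endpoints and symmetry", {
  expect_equal(score_composition(0, 0, 1), 2)     # calcium only
  expect_equal(score_composition(1, 0, 0), -2)    # lipid only
  expect_equal(score_composition(0, 1, 0), 0)     # fibrous only
  expect_equal(score_composition(0.5, 0, 0.5), 0) # equal Ca and lipid
})

test_that("score formula verified by brute force over a composition grid", {
  # independent oracle: raw contrast + quarter rounding recomputed inline
  g <- seq(0, 1, by = 0.1)
  for (fl in g) for (fc in g) {
    ff <- 1 - fl - fc
    if (ff < -1e-12) next
    ff <- max(ff, 0)
    raw <- 2 * (fc - fl) / (fl + ff + fc)
    q <- raw * 4
    expected <- (if (abs(abs(q) %% 1 - 0.5) < 1e-9)
      sign(q) * floor(abs(q)) else round(q)) / 4
    got <- score_composition(fl, ff, fc)
    expect_equal(got, expected, tolerance = 1e-12)
    expect_true(abs(got * 4 - round(got * 4)) < 1e-12)  # quarter steps
    expect_true(got >= -2 && got <= 2)
  }
  expect_error(score_composition(0, 0, 0), "all-zero")
})

test_that("curve_for_score: integer scores exact, fractional scores interpolate", {
  lam <- c(1.05, 1.2, 1.3)
  expect_equal(stress_for_score(0, lam, fix_table),
               uniaxial_stress(fix_table$soft$neutral, lam))
  expect_equal(stress_for_score(2, lam, fix_table),
               uniaxial_stress(fix_table$soft$very_stiff, lam))
  mid <- (uniaxial_stress(fix_table$soft$neutral, 1.2) +
          uniaxial_stress(fix_table$soft$stiff, 1.2)) / 2
  expect_equal(stress_for_score(0.5, 1.2, fix_table), mid)
  expect_error(stress_for_score(2.25, 1.1, fix_table), "outside")
  cv <- curve_for_score(0.25, fix_table)
  expect_named(cv, c("stretch", "strain", "stress_MPa"))
})

test_that("curve family is continuous in score", {
  lam <- seq(1, 1.3, length.out = 61)
  scores <- seq(-2, 2, by = 0.25)
  curves <- vapply(scores, stress_for_score, numeric(length(lam)),
                   stretch = lam, table = fix_table)
  # max pointwise jump between adjacent quarter steps is a quarter of the
  # class-to-class gap, by linear interpolation
  for (k in seq_len(length(scores) - 1L)) {
    lo4 <- floor(scores[k]); hi4 <- ceiling(scores[k + 1L])
    class_gap <- max(abs(
      uniaxial_stress(fix_table$soft[[fix_table$plaque_classes[hi4 + 3L]]], lam) -
      uniaxial_stress(fix_table$soft[[fix_table$plaque_classes[lo4 + 3L]]], lam)))
    jump <- max(abs(curves[, k + 1L] - curves[, k]))
    expect_lte(jump, class_gap / 4 + 1e-9)
  }
})

test_that("alloy plasticity: yield points, perfect plasticity, unloading", {
  mp <- fix_table$alloys$MP35N
  expect_equal(alloy_stress(mp, 414 / 233000), 414)
  # hardening continues toward tensile strength
  expect_gt(alloy_stress(mp, 0.1), 414)
  expect_lte(alloy_stress(mp, 0.45), 930)
  ptir <- fix_table$alloys$PtIr
  expect_equal(alloy_stress(ptir, 0.2), 285)   # flat plateau past yield
  expect_equal(alloy_stress(ptir, 0.5), 285)
  # odd extension for compression/unloading
  expect_equal(alloy_stress(mp, -414 / 233000), -414)
  # unloading slope is E: stress drop over strain drop
  e1 <- 0.05; e2 <- 0.0499
  expect_equal((alloy_stress(mp, e1) - 233000 * (e1 - e2)) -
                 alloy_stress(mp, e2) < 233000 * (e1 - e2), TRUE)
})

test_that("balloon compliance classes map to 300/900/1500 MPa", {
  expect_equal(balloon_modulus("compliant", fix_table), 300)
  expect_equal(balloon_modulus("semi_compliant", fix_table), 900)
  expect_equal(balloon_modulus("non_compliant", fix_table), 1500)
})

test_that("material table resource is versioned and complete", {
  expect_length(fix_table$soft, 7L)
  expect_identical(fix_table$plaque_classes,
                   c("very_soft", "soft", "neutral", "stiff", "very_stiff"))
  expect_s3_class(fix_table$alloys$PtCr, "alloy_model")
  p <- withr::local_tempfile(fileext = ".csv")
  write_material_curve(curve_for_score(1, fix_table), p)
  expect_true(file.exists(p))
})
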
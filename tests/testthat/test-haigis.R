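test_that("ELP is the affine Haigis model with hard geometric guards", {
  cst <- iol_constants(a0 = 1, a1 = 0.4, a2 = 0.1)
  expect_equal(haigis_elp(3.63, 28.08, cst), 5.260, tolerance = 1e-12)
  # all-zero constants give ELP 0: lens on the cornea is invalid geometry
  expect_error(haigis_elp(3.63, 28.08, iol_constants(0, 0, 0)),
               "invalid geometry")
  # constants placing the lens behind the retina are equally invalid
  expect_error(haigis_elp(3.63, 28.08, iol_constants(30, 0.4, 0.1)),
               "invalid geometry")
  # mean post-LASIK biometry with a plausible triple: ELP behind the ACD,
  # well inside the anterior segment
  d <- haigis_elp(3.63, 28.08, test_constants())
  expect_gt(d, 3.63)
  expect_lt(d, 8)
})

test_that("keratometric handling modes behave as documented", {
  expect_equal(corneal_power(40), 40)
  expect_equal(corneal_power(40, "reindex"), 40 * 331.5 / 337.5)
  expect_equal(corneal_power(33.75, "reindex"), 33.15)   # r = 10 mm exactly
  expect_error(corneal_power(-1), "positive")
  expect_error(corneal_power(0, "reindex"), "positive")
})

test_that("IOL power and predicted refraction are exact mutual inverses", {
  cst <- test_constants()
  set.seed(101)
  st <- sample_states(2000)
  elp <- haigis_elp(st$acd, st$axial_length, cst)
  p <- iol_power_for_target(st$k, st$target, st$axial_length, elp, cst)
  rx <- predict_refraction(st$k, p, st$axial_length, elp, cst)
  expect_lt(max(abs(rx - st$target)), 1e-9)
  # and the reverse order recovers the power
  p2 <- iol_power_for_target(st$k, rx, st$axial_length, elp, cst)
  expect_lt(max(abs(p2 - p)), 1e-9)
})

test_that("back-calculated K recovers the simulating corneal power", {
  cst <- test_constants()
  set.seed(102)
  st <- sample_states(2000)
  elp <- haigis_elp(st$acd, st$axial_length, cst)
  p <- round_iol_power(iol_power_for_target(st$k, st$target,
                                            st$axial_length, elp, cst))
  k_true <- st$k + runif(nrow(st), -3, 3)
  se <- predict_refraction(k_true, p, st$axial_length, elp, cst)
  krd <- back_calculated_k(se, p, st$axial_length, elp, cst)
  expect_lt(max(abs(krd - k_true)), 1e-9)
})

test_that("an emmetropic aphakic toy eye predicts plano", {
  # with no IOL (P = 0) and vertex distance 0, an eye whose corneal power
  # equals n/L is focused on the retina: refraction must be exactly 0
  cst <- iol_constants(a0 = 1, a1 = 0.4, a2 = 0.1, vertex_distance = 0)
  L <- 22
  k <- cst$n_aqueous / (L / 1000)
  expect_equal(predict_refraction(k, 0, L, haigis_elp(3.2, L, cst), cst), 0,
               tolerance = 1e-12)
})

test_that("closed forms agree with independent vergence-trace oracles", {
  cst <- test_constants()
  set.seed(103)
  st <- sample_states(100)
  elp <- haigis_elp(st$acd, st$axial_length, cst)
  p <- round_iol_power(iol_power_for_target(st$k, st$target,
                                            st$axial_length, elp, cst))
  for (i in seq_len(nrow(st))) {
    rx <- predict_refraction(st$k[i], p[i], st$axial_length[i], elp[i], cst)
    expect_equal(rx, oracle_predict_refraction(st$k[i], p[i],
                                               st$axial_length[i], elp[i], cst),
                 tolerance = 1e-6)
    krd <- back_calculated_k(rx, p[i], st$axial_length[i], elp[i], cst)
    expect_equal(krd, oracle_back_calculated_k(rx, p[i], st$axial_length[i],
                                               elp[i], cst),
                 tolerance = 1e-6)
  }
  # grid-search oracle for the power inversion on a handful of cases
  for (i in 1:5) {
    expect_equal(iol_power_for_target(st$k[i], st$target[i],
                                      st$axial_length[i], elp[i], cst),
                 oracle_iol_power_grid(st$k[i], st$target[i],
                                       st$axial_length[i], elp[i], cst),
                 tolerance = 1e-4)
  }
})

test_that("IOL power is monotone in axial length and target refraction", {
  cst <- test_constants()
  al <- seq(23, 31, by = 0.5)
  p_al <- iol_power_for_target(39, -0.5, al, haigis_elp(3.6, al, cst), cst)
  expect_true(all(diff(p_al) < 0))  # longer eye, lower power
  targets <- seq(-3, 0.5, by = 0.25)
  elp <- haigis_elp(3.6, 28, cst)
  p_t <- iol_power_for_target(39, targets, 28, elp, cst)
  expect_true(all(diff(p_t) < 0))   # more myopic target, higher power
})

test_that("clinical rounding steps by 0.5 D with ties toward more power", {
  expect_equal(round_iol_power(16.24), 16.0)
  expect_equal(round_iol_power(16.25), 16.5)
  expect_equal(round_iol_power(16.26), 16.5)
  expect_equal(round_iol_power(-0.25), 0)
  expect_equal(round_iol_power(c(10.1, 10.74, 10.75), step = 0.5),
               c(10.0, 10.5, 11.0))
})

test_that("optical singularities and suspicious records are reported", {
  cst <- test_constants()
  elp <- haigis_elp(3.6, 28, cst)
  # an IOL power equal to the vergence at the IOL plane is a singular state
  p_singular <- cst$n_aqueous / ((28 - elp) / 1000)
  expect_error(predict_refraction(39, p_singular, 28, elp, cst),
               "optical singularity.*IOL")
  # back-calculated K far from the measured K flags the record
  expect_warning(
    k <- back_calculated_k(5, 16, 28, elp, cst, k_measured = 39),
    "suspicious")
  expect_true(attr(k, "suspicious"))
})

test_that("cohort-level prediction wrapper reproduces the generator's optics", {
  cst <- test_constants()
  g <- generate_cohort(cohort_spec(n = 40, seed = 12), cst)
  # predictions from the latent truth have zero error by construction
  pred_meas <- cohort_predictions(g$cohort, cst, "tcrp4")
  expect_equal(pred_meas$method_label[1], "TCRP 4 mm K")
  expect_equal(pred_meas$pe_d,
               prediction_error(pred_meas$actual_se_d, pred_meas$predicted_se_d))
  # entering K_true instead of measured K must predict the achieved SE exactly
  elp <- haigis_elp(g$cohort$acd_mm, g$cohort$axial_length_mm, cst)
  rx <- predict_refraction(g$truth$k_true, g$cohort$implanted_power_d,
                           g$cohort$axial_length_mm, elp, cst)
  expect_equal(rx, g$cohort$postop_sphere_d, tolerance = 1e-12)
})
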
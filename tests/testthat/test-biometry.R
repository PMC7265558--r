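test_that("record constructors validate ranges with actionable errors", {
  expect_s3_class(eye_biometry("e1", 28.08, 3.63, k_tcrp_4mm = 39.24),
                  "eye_biometry")
  expect_error(eye_biometry("e1", 3.0, 3.63, k_tcrp_4mm = 39.24),
               "axial_length.*outside valid range")
  # a length three orders of magnitude too small should point at units
  expect_error(eye_biometry("e1", 0.028, 3.63, k_tcrp_4mm = 39.24),
               "metres")
  expect_error(eye_biometry("e1", 28, 0.5, k_tcrp_4mm = 39.24), "acd")
  expect_error(eye_biometry("e1", 28, 3.6, k_tcrp_4mm = 20), "k_tcrp_4mm")
  expect_error(eye_biometry("e1", 28, 3.6), "at least one")

  expect_s3_class(surgery_outcome(16, -0.5, -0.25, -0.5), "surgery_outcome")
  expect_error(surgery_outcome(55, -0.5, 0, 0), "implanted_power")
  expect_error(surgery_outcome(16, -12, 0, 0), "target_refraction")
  expect_error(surgery_outcome(16, -0.5, -20, 0), "spherical equivalent")

  expect_error(iol_constants(1, 0.4, 0.1, n_aqueous = 0.9), "n_aqueous")
  expect_error(iol_constants(1, 0.4, 0.1, vertex_distance = 25),
               "vertex_distance")
})

test_that("spherical equivalent is invariant under cross-cylinder transposition", {
  expect_equal(spherical_equivalent(-1.5, -0.5), -1.75)
  expect_equal(spherical_equivalent(refraction(-1.5, -0.5)), -1.75)
  set.seed(11)
  for (i in 1:50) {
    s <- runif(1, -10, 5); c <- runif(1, -4, 4)
    tr <- transpose_refraction(s, c)
    expect_equal(spherical_equivalent(tr$sphere, tr$cylinder),
                 spherical_equivalent(s, c), tolerance = 1e-12)
  }
})

test_that("cohort CSV round-trips field for field", {
  g <- generate_cohort(cohort_spec(n = 25, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- load_cohort(path)
  expect_equal(nrow(back), 25)
  expect_equal(nrow(attr(back, "rejected")), 0)
  for (col in names(g$cohort)) {
    if (is.numeric(g$cohort[[col]])) {
      expect_equal(back[[col]], g$cohort[[col]], tolerance = 1e-6)
    } else {
      expect_identical(back[[col]], g$cohort[[col]])
    }
  }
})

test_that("invalid rows are rejected by row number, valid rows kept", {
  g <- generate_cohort(cohort_spec(n = 5, seed = 4))
  df <- as.data.frame(g$cohort)
  df$axial_length_mm[2] <- 3.0       # impossible eye
  df$k_tcrp_4mm_d[4] <- NA           # no K at all on this row
  df$k_trp_4mm_d[4] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(cohort <- load_cohort(path), "2 of 5 rows rejected")
  expect_equal(nrow(cohort), 3)
  expect_equal(attr(cohort, "rejected")$row, c(2L, 4L))
  expect_match(attr(cohort, "rejected")$message[1], "axial_length")
})

test_that("a cohort recorded in metres is rejected wholesale with a unit hint", {
  g <- generate_cohort(cohort_spec(n = 4, seed = 5))
  df <- as.data.frame(g$cohort)
  df$axial_length_mm <- df$axial_length_mm / 1000
  df$acd_mm <- df$acd_mm / 1000
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(cohort <- load_cohort(path), "4 of 4 rows rejected")
  expect_equal(nrow(cohort), 0)
  expect_match(attr(cohort, "rejected")$message[1], "metres")
})

test_that("missing mandatory columns are a schema error", {
  g <- generate_cohort(cohort_spec(n = 3, seed = 6))
  df <- as.data.frame(g$cohort)
  df$acd_mm <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(load_cohort(path), "missing mandatory column.*acd_mm")
})

test_that("constants configuration round-trips through JSON", {
  cst <- iol_constants(-1.302, 0.210, 0.251, label = "ZCB00 (ULIB)")
  path <- withr::local_tempfile(fileext = ".json")
  write_iol_constants(cst, path, k_mode = "direct")
  cfg <- read_iol_constants(path)
  expect_equal(cfg$constants$a0, -1.302)
  expect_equal(cfg$constants$vertex_distance, 12)
  expect_equal(cfg$k_mode, "direct")
  expect_error(read_iol_constants(withr::local_tempfile()), "not found")
})
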
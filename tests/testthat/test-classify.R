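ctx10 <- fixed_wbc_context(10)

test_that("the gating tree reproduces the defining examples", {
  # round, DAPI-negative, CK+ object of 9.8 um -> LEV
  lev <- classify_object(
    make_morph(equivalent_diameter_um = 9.8, circularity = 0.9), ctx10
  )
  expect_equal(as.character(lev), "LEV")
  # same object below the 6 um gate -> EXCLUDED
  expect_equal(as.character(classify_object(
    make_morph(equivalent_diameter_um = 5.0, circularity = 0.9), ctx10
  )), "EXCLUDED")
  # intact nucleated 25 um cell, WBC median 10 um -> CTC
  expect_equal(as.character(classify_object(
    make_morph(
      equivalent_diameter_um = 25, snr_DAPI = 8, dapi_area_um2 = 120,
      dapi_fragment_count = 1L
    ), ctx10
  )), "CTC")
  # fragmented nucleus -> APOPTOTIC regardless of size
  expect_equal(as.character(classify_object(
    make_morph(
      equivalent_diameter_um = 13, snr_DAPI = 8, dapi_area_um2 = 30,
      dapi_fragment_count = 3L
    ), ctx10
  )), "APOPTOTIC")
  # CK-negative CD45+ nucleated -> WBC; CK-negative bare -> EXCLUDED
  expect_equal(as.character(classify_object(
    make_morph(snr_CK = 0, snr_CD45 = 10, snr_DAPI = 8, dapi_area_um2 = 60),
    ctx10
  )), "WBC")
  expect_equal(as.character(classify_object(
    make_morph(snr_CK = 0), ctx10
  )), "EXCLUDED")
  # CK+ but CD45+ -> WBC (gate order)
  expect_equal(as.character(classify_object(
    make_morph(snr_CD45 = 5), ctx10
  )), "WBC")
})

test_that("disruption trumps intactness and the CTC gate tracks WBC size", {
  m <- make_morph(
    equivalent_diameter_um = 25, snr_DAPI = 8, dapi_area_um2 = 120,
    dapi_fragment_count = 3L
  )
  expect_equal(as.character(classify_object(m, ctx10)), "APOPTOTIC")
  # intact but not larger than 1.25 x median WBC -> EXCLUDED
  m2 <- make_morph(
    equivalent_diameter_um = 12, snr_DAPI = 8, dapi_area_um2 = 60,
    dapi_fragment_count = 1L
  )
  expect_equal(as.character(classify_object(m2, ctx10)), "EXCLUDED")
  expect_equal(
    as.character(classify_object(m2, fixed_wbc_context(8))), "CTC"
  )
  # fallback context uses the absolute 12 um threshold
  m3 <- make_morph(
    equivalent_diameter_um = 12.5, snr_DAPI = 8, dapi_area_um2 = 60,
    dapi_fragment_count = 1L
  )
  expect_equal(
    as.character(classify_object(m3, fixed_wbc_context(10, n = 5))), "CTC"
  )
})

test_that("every object gets exactly one class, deterministically", {
  set.seed(20)
  for (i in 1:200) {
    m <- make_morph(
      snr_CK = runif(1, -1, 15), snr_CD45 = runif(1, -1, 8),
      snr_DAPI = runif(1, -1, 10),
      dapi_area_um2 = runif(1, 0, 150),
      dapi_fragment_count = sample(0:4, 1),
      nucleus_solidity = runif(1, 0.3, 1),
      ck_texture_cv = runif(1, 0, 1.2),
      equivalent_diameter_um = runif(1, 4, 40),
      circularity = runif(1, 0.4, 1.05)
    )
    k1 <- as.character(classify_object(m, ctx10))
    k2 <- as.character(classify_object(m, ctx10))
    expect_identical(k1, k2)
    expect_true(k1 %in% c("CTC", "LEV", "APOPTOTIC", "WBC", "EXCLUDED"))
  }
})

test_that("gates are monotone in DAPI signal and diameter", {
  # increasing DAPI on a fixed round object can leave LEV but never return
  base <- function(dapi_snr, dapi_area) {
    make_morph(
      equivalent_diameter_um = 9, circularity = 0.92,
      snr_DAPI = dapi_snr, dapi_area_um2 = dapi_area,
      dapi_fragment_count = 1L
    )
  }
  klasses <- vapply(
    seq(0, 10, by = 0.5),
    function(s) as.character(classify_object(base(s, s * 12), ctx10)), ""
  )
  was_lev <- klasses == "LEV"
  expect_true(all(diff(was_lev) <= 0)) # once not-LEV, never LEV again
  expect_true(all(klasses[!was_lev] %in% c("CTC", "APOPTOTIC", "EXCLUDED")))

  # increasing diameter across 6 um flips EXCLUDED -> LEV exactly once
  klasses <- vapply(
    seq(4, 12, by = 0.25),
    function(d) {
      as.character(classify_object(
        make_morph(equivalent_diameter_um = d, circularity = 0.95), ctx10
      ))
    }, ""
  )
  is_lev <- klasses == "LEV"
  expect_true(all(diff(is_lev) >= 0)) # once LEV, stays LEV
  expect_identical(unique(klasses[!is_lev]), "EXCLUDED")
})

test_that("WBC context summarizes nuclei and flags sparse slides", {
  cfg <- slide_config(
    dim_px = c(800, 800), n_wbc = 120, n_ctc = 0, n_lev = 3,
    n_apoptotic = 0, n_debris = 0
  )
  rs <- render_slide(cfg, seed = 12)
  cand <- segment_candidates(rs$slide)
  ctx <- wbc_context(cand)
  expect_false(ctx$fallback)
  expect_gte(ctx$n_wbc, 100)
  expect_equal(ctx$median_wbc_diameter_um, 10, tolerance = 0.06)

  # LEVs never enter the WBC statistics: every contributing nucleus is CK-
  fake <- cand
  fake$wbc_records <- rbind(
    cand$wbc_records,
    data.frame(
      label = 9999, x_um = 1, y_um = 1, equivalent_diameter_um = 50,
      snr_DAPI = 10, snr_CK = 10, snr_CD45 = 10
    )
  )
  expect_equal(
    wbc_context(fake)$median_wbc_diameter_um,
    ctx$median_wbc_diameter_um
  )

  empty <- render_slide(slide_config(
    dim_px = c(256, 256), n_wbc = 0, n_ctc = 0, n_lev = 1,
    n_apoptotic = 0, n_debris = 0
  ), seed = 13)
  ctx0 <- wbc_context(segment_candidates(empty$slide))
  expect_true(ctx0$fallback)
  expect_equal(ctx0$n_wbc, 0)
})

test_that("reports carry classified objects in stable order and round-trip", {
  cfg <- slide_config(
    dim_px = c(600, 600), n_wbc = 70, n_ctc = 1, n_lev = 1,
    n_apoptotic = 0, n_debris = 0
  )
  rs <- render_slide(cfg, seed = 14)
  an <- analyze_slide(rs$slide)
  expect_equal(nrow(an$report), 2)
  expect_setequal(an$report$class, c("CTC", "LEV"))
  expect_true(!is.unsorted(an$report$y_um))

  f <- tempfile(fileext = ".csv")
  write_report(an$report, f)
  back <- read_report(f)
  expect_equal(back, an$report, tolerance = 1e-12)
  unlink(f)

  empty <- analyze_slide(render_slide(slide_config(
    dim_px = c(256, 256), n_wbc = 0, n_ctc = 0, n_lev = 0,
    n_apoptotic = 0, n_debris = 0
  ), seed = 15)$slide)
  expect_equal(nrow(empty$report), 0)
  f2 <- tempfile(fileext = ".csv")
  write_report(empty$report, f2)
  expect_equal(nrow(read_report(f2)), 0)
  unlink(f2)
})
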
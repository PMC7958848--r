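test_that("an empty slide is background-only with an empty manifest", {
  cfg <- slide_config(
    dim_px = c(128, 128), n_wbc = 0, n_ctc = 0, n_lev = 0,
    n_apoptotic = 0, n_debris = 0
  )
  rs <- render_slide(cfg, seed = 1)
  expect_equal(nrow(rs$manifest), 0)
  for (ch in names(rs$slide$channels)) {
    expect_equal(median(rs$slide$channels[[ch]]), cfg$background[[ch]],
      tolerance = 0.02)
    expect_lt(sd(rs$slide$channels[[ch]]), 1.1 * cfg$noise_sd[[ch]])
  }
})

test_that("rendering is bit-reproducible for fixed config and seed", {
  cfg <- small_slide_config(dim_px = c(300, 300), n_wbc = 20, n_ctc = 1,
    n_lev = 2, n_apoptotic = 1, n_debris = 1)
  a <- render_slide(cfg, seed = 42)
  b <- render_slide(cfg, seed = 42)
  expect_identical(a$slide$channels, b$slide$channels)
  expect_identical(a$manifest, b$manifest)
  d <- render_slide(cfg, seed = 43)
  expect_false(identical(a$slide$channels$CK, d$slide$channels$CK))
})

test_that("a planted LEV renders as a CK disk of the planted size with no DAPI", {
  cfg <- slide_config(
    dim_px = c(200, 200), n_wbc = 0, n_ctc = 0, n_lev = 1,
    n_apoptotic = 0, n_debris = 0
  )
  rs <- render_slide(cfg, seed = 5)
  man <- rs$manifest
  expect_equal(man$klass, "LEV")
  # CK component diameter in px matches diameter_um / scale (e.g. a 9.8 um
  # LEV at 0.65 um/px is a ~15.1 px disk)
  ck <- rs$slide$channels$CK
  mask <- ck > cfg$background[["CK"]] + 5 * cfg$noise_sd[["CK"]]
  d_px <- 2 * sqrt(sum(mask) / pi)
  expect_equal(d_px, man$diameter_um / cfg$pixel_scale_um,
    tolerance = 1.5 / d_px)
  # DAPI flat at the LEV location
  dapi <- rs$slide$channels$DAPI
  expect_lt(
    abs(mean(dapi[mask]) - cfg$background[["DAPI"]]),
    3 * cfg$noise_sd[["DAPI"]] / sqrt(sum(mask))
  )
})

test_that("manifests respect the class invariants", {
  cfg <- small_slide_config(dim_px = c(1000, 1000), n_wbc = 60, n_ctc = 10,
    n_lev = 20, n_apoptotic = 10, n_debris = 5)
  man <- render_slide(cfg, seed = 9)$manifest
  lev <- man[man$klass == "LEV", ]
  expect_true(all(lev$nucleus_fragments == 0))
  expect_true(all(lev$diameter_um >= 6.3 & lev$diameter_um <= 20.4))
  expect_true(all(lev$mult_DAPI <= cfg$weak_dna_ceiling))
  ctc <- man[man$klass == "CTC", ]
  expect_true(all(ctc$diameter_um >= 15 & ctc$diameter_um <= 45))
  apo <- man[man$klass == "APOPTOTIC", ]
  expect_true(all(apo$nucleus_fragments >= 2))
  expect_true(all(apo$diameter_um >= 6.7 & apo$diameter_um <= 25.1))
  expect_true(all(man[, c("mult_DAPI", "mult_CK", "mult_CD45")] >= 0))
})

test_that("planted size distributions match the configured moments", {
  cfg <- slide_config(
    dim_px = c(3500, 3500), n_wbc = 0, n_ctc = 400, n_lev = 400,
    n_apoptotic = 400, n_debris = 0
  )
  man <- render_slide(cfg, seed = 33)$manifest
  m <- tapply(man$diameter_um, man$klass, mean)
  s <- tapply(man$diameter_um, man$klass, sd)
  expect_equal(unname(m["LEV"]), 9.8, tolerance = 0.45 / 9.8)
  expect_equal(unname(m["CTC"]), 25.3, tolerance = 0.9 / 25.3)
  expect_equal(unname(m["APOPTOTIC"]), 13.5, tolerance = 0.55 / 13.5)
  expect_equal(unname(s["LEV"]), 3.0, tolerance = 0.3 / 3.0)
  expect_equal(unname(s["CTC"]), 5.9, tolerance = 0.6 / 5.9)
})

test_that("impossible placements raise a placement error naming the class", {
  cfg <- slide_config(
    dim_px = c(128, 128), n_wbc = 0, n_ctc = 30, n_lev = 0,
    n_apoptotic = 0, n_debris = 0, max_tries = 20
  )
  expect_error(render_slide(cfg, seed = 1), "placement error.*CTC")
})

test_that("LEV DNA multipliers above the weak ceiling are rejected", {
  expect_error(slide_config(lev_dna_mult = 2), "anucleate")
})

test_that("cohort tables have the configured shape and deterministic mode is exact", {
  co <- generate_cohort_counts(cohort_config(), seed = 1)
  expect_equal(nrow(co), 88) # 44 patients x 2 slides
  expect_equal(length(unique(co$patient_id)), 44)
  det <- generate_cohort_counts(
    cohort_config(lev_ratio = 1, deterministic = TRUE),
    seed = 2
  )
  expect_identical(det$n_lev, det$n_ctc)
  expect_identical(
    generate_cohort_counts(cohort_config(), seed = 7),
    generate_cohort_counts(cohort_config(), seed = 7)
  )
})

test_that("the Poisson limit concentrates the LEV/CTC ratio at lev_ratio", {
  cfg <- cohort_config(
    n_patients = 1500, mean_rate = 50, sdlog = 0.4,
    dispersion = Inf, lev_ratio_sdlog = 0
  )
  co <- generate_cohort_counts(cfg, seed = 3)
  expect_equal(sum(co$n_lev) / sum(co$n_ctc), 1.9, tolerance = 0.02)
})

test_that("cohort config validation rejects bad parameters", {
  expect_error(cohort_config(lev_ratio = 0), "lev_ratio")
  expect_error(cohort_config(dispersion = -1), "dispersion")
  expect_error(cohort_config(n_patients = 1), "n_patients")
})

test_that("the IMC generator delivers the requested class composition", {
  cfg <- imc_profile_config(n_ctc = 6, n_lev = 9, n_apoptotic = 5)
  out <- render_imc_rois(cfg, seed = 4)
  expect_length(out$rois, 20)
  expect_equal(
    as.integer(table(out$truth$klass)[c("CTC", "LEV", "APOPTOTIC")]),
    c(6, 9, 5)
  )
  kl <- vapply(out$rois, function(r) r$klass, "")
  expect_identical(kl, out$truth$klass)
  # every stack: one centered object, >= 5 WBC disks, 34 channels
  for (r in out$rois[1:3]) {
    expect_true(any(r$object_mask))
    expect_gte(r$n_wbc, 5)
    expect_length(r$channels, 34)
  }
})

test_that("planted bins map to in-range signal multipliers", {
  cfg <- imc_profile_config(n_ctc = 8, n_lev = 0, n_apoptotic = 0)
  out <- render_imc_rois(cfg, seed = 6)
  for (i in seq_along(out$rois)) {
    r <- out$rois[[i]]
    for (m in c("EpCAM", "HSPD1", "AR")) {
      bin <- out$truth$bins[i, m]
      rng <- cfg$snr_ranges[[bin + 1]]
      snr <- mean(r$channels[[m]][r$object_mask]) /
        mean(r$channels[[m]][r$wbc_mask])
      # realized ratio within the planted range up to Poisson noise
      expect_gt(snr, rng[1] * 0.85)
      expect_lt(snr, rng[2] * 1.15)
    }
    # bin 0 markers sit within noise of the WBC background
    zero <- names(which(out$truth$bins[i, ] == 0))[1]
    if (!is.na(zero)) {
      expect_lt(
        mean(r$channels[[zero]][r$object_mask]) /
          mean(r$channels[[zero]][r$wbc_mask]),
        2
      )
    }
  }
})

test_that("objects larger than the ROI raise a configuration error", {
  cfg <- imc_profile_config(n_ctc = 1, n_lev = 0, n_apoptotic = 0)
  expect_error(
    ctclev:::render_one_roi(195, cfg$profiles$CTC[, 1] * 0, "positive", cfg),
    "configuration error"
  )
})

test_that("IMC rendering is seed-deterministic", {
  cfg <- imc_profile_config(n_ctc = 2, n_lev = 2, n_apoptotic = 1)
  a <- render_imc_rois(cfg, seed = 11)
  b <- render_imc_rois(cfg, seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(a$rois[[3]]$channels, b$rois[[3]]$channels)
})
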
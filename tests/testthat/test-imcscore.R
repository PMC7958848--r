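test_that("score bins are left-closed at 2, 5 and 10", {
  # SNR exactly 1 -> 0; exactly 2 -> 1; 4.99 -> 1; 5 -> 2; exactly 10 -> 3
  for (case in list(c(10, 0L), c(19.9, 0L), c(20, 1L), c(49.9, 1L),
    c(50, 2L), c(99, 2L), c(100, 3L), c(500, 3L))) {
    roi <- make_fake_roi(object_value = case[1], wbc_value = 10)
    expect_identical(score_marker(roi, "m1"), as.integer(case[2]))
  }
  roi <- make_fake_roi(10, 10)
  expect_identical(score_marker(roi, "m1"), 0L) # null case: SNR 1
  expect_error(score_marker(roi, "nope"), "not present")
  roi$wbc_mask[] <- FALSE
  expect_warning(s <- score_marker(roi, "m1"), "unscorable")
  expect_true(is.na(s))
})

test_that("DNA load thresholds at 1.5 and 5", {
  expect_equal(dna_load(make_fake_roi(1, 10, dna_value = 10)), "negative")
  expect_equal(dna_load(make_fake_roi(1, 10, dna_value = 25)), "weak")
  expect_equal(dna_load(make_fake_roi(1, 10, dna_value = 80)), "positive")
  expect_error(dna_load(make_fake_roi(1, 10)), "DNA channel")
})

test_that("planted DNA classes are recovered per object class", {
  sm <- imc_score_cohort(small_imc_config(), seed = 21)
  tr <- attr(sm, "truth")
  ord <- match(sm$ann$roi_id, tr$roi_id)
  expect_identical(sm$ann$dna_load, tr$dna[ord])
  expect_true(all(sm$ann$dna_load[sm$ann$klass == "CTC"] == "positive"))
  expect_true(all(sm$ann$dna_load[sm$ann$klass == "LEV"] %in%
    c("negative", "weak")))
})

test_that("the score matrix is canonical, integer and complete", {
  cfg <- small_imc_config(n_ctc = 4, n_lev = 5, n_apoptotic = 3)
  out <- render_imc_rois(cfg, seed = 22)
  sm <- build_score_matrix(out$rois)
  expect_equal(dim(sm$scores), c(12, 33))
  expect_true(all(sm$scores %in% 0:3))
  # shuffled input yields the identical matrix
  sm2 <- build_score_matrix(out$rois[c(7, 2, 11, 1, 12, 3, 9, 4, 10, 5, 8, 6)])
  expect_identical(sm, sm2)
  # ordering: by class, then patient, then roi
  expect_true(!is.unsorted(sm$ann$klass))
  # unscorable ROIs are dropped, all-unscorable errors
  broken <- out$rois
  broken[[1]]$wbc_mask[] <- FALSE
  expect_message(
    suppressWarnings(sm3 <- build_score_matrix(broken)), "unscorable"
  )
  expect_equal(nrow(sm3$scores), 11)
  none <- lapply(out$rois, function(r) {
    r$wbc_mask[] <- FALSE
    r
  })
  expect_error(build_score_matrix(none), "all ROIs")
})

test_that("per-object score sums and their class means behave", {
  x <- matrix(0L, 3, 33, dimnames = list(NULL, default_imc_markers()))
  x[2, 1:3] <- 3L
  sm <- ctclev:::new_score_matrix(
    x,
    data.frame(
      roi_id = c("r1", "r2", "r3"), klass = c("LEV", "CTC", "LEV"),
      patient_id = "p", dna_load = "weak"
    )
  )
  cs <- class_score_sums(sm)
  expect_equal(unname(cs["CTC"]), 9)
  expect_equal(unname(cs["LEV"]), 0)
})

test_that("marker and panel positivity handle edge cases exactly", {
  x <- matrix(0L, 4, 33, dimnames = list(NULL, default_imc_markers()))
  x[, "EpCAM"] <- 0:3
  x[, "HSPD1"] <- 3L
  x[2, "PSA"] <- 1L
  sm <- ctclev:::new_score_matrix(
    x,
    data.frame(
      roi_id = sprintf("r%d", 1:4), klass = "CTC", patient_id = "p",
      dna_load = "positive"
    )
  )
  mp <- marker_positivity(sm, "EpCAM")
  ov <- mp[mp$group == "overall", ]
  expect_equal(ov$p_ge1, 3 / 4)
  expect_equal(ov$p0, 1 / 4)
  expect_equal(ov$pct_ge2, 50)
  expect_equal(
    marker_positivity(sm, "HSPD1")[1, "p_ge1"], 1
  )
  pp <- panel_positivity(sm, c("AR", "PSA"))
  expect_equal(pp$positivity[pp$positivity$group == "overall", "frac"], 1 / 4)
  expect_equal(
    panel_positivity(sm, "Cav1")$positivity[1, "frac"], 0
  )
  expect_error(panel_positivity(sm, character(0)), "empty marker set")
  expect_error(marker_positivity(sm, "XYZ"), "not in matrix")
})

test_that("scoring is monotone in planted intensity and scale invariant", {
  # monotone: higher object signal at fixed background never lowers a score
  vals <- c(5, 15, 30, 60, 120, 300)
  scores <- vapply(vals, function(v) {
    score_marker(make_fake_roi(v, 10), "m1")
  }, integer(1))
  expect_true(all(diff(scores) >= 0))
  # ratio invariance: multiplying object and WBC counts together changes
  # nothing
  expect_identical(
    score_marker(make_fake_roi(60, 10), "m1"),
    score_marker(make_fake_roi(600, 100), "m1")
  )
})

test_that("planted bins are recovered through rendering and scoring", {
  sm <- imc_score_cohort(small_imc_config(n_ctc = 20, n_lev = 25,
    n_apoptotic = 15), seed = 23)
  tr <- attr(sm, "truth")
  ord <- match(sm$ann$roi_id, tr$roi_id)
  agree <- mean(sm$scores == tr$bins[ord, ])
  expect_gte(agree, 0.95)
})

test_that("clustering splits planted extremes and embeds deterministically", {
  x <- rbind(
    matrix(0L, 6, 33), matrix(3L, 6, 33)
  )
  colnames(x) <- default_imc_markers()
  rownames(x) <- sprintf("r%02d", 1:12)
  sm <- ctclev:::new_score_matrix(
    x,
    data.frame(
      roi_id = sprintf("r%02d", 1:12),
      klass = rep(c("LEV", "CTC"), each = 6),
      patient_id = "p", dna_load = "weak"
    )
  )
  cl <- cluster_objects(sm, seed = 3)
  cut2 <- stats::cutree(cl$object_hclust, 2)
  expect_equal(length(unique(cut2[sm$ann$klass == "CTC"])), 1)
  expect_equal(length(unique(cut2[sm$ann$klass == "LEV"])), 1)
  expect_false(cut2[1] == cut2[12])
  # identical rows merge at distance zero
  expect_equal(min(cl$object_hclust$height), 0)
  # determinism and shape
  cl2 <- cluster_objects(sm, seed = 3)
  expect_identical(cl$embedding, cl2$embedding)
  expect_equal(dim(cl$embedding), c(12, 2))
  expect_true(all(is.finite(cl$embedding)))
  one <- ctclev:::new_score_matrix(
    x[1, , drop = FALSE], data.frame(
      roi_id = "r01", klass = "LEV",
      patient_id = "p", dna_load = "weak"
    )
  )
  expect_error(cluster_objects(one), "at least 2")
})

test_that("IMC ROI stacks round-trip through TIFF with sidecar", {
  out <- render_imc_rois(small_imc_config(n_ctc = 1, n_lev = 0,
    n_apoptotic = 0), seed = 24)
  roi <- out$rois[[1]]
  f <- tempfile(fileext = ".tif")
  write_imc_roi(roi, f)
  back <- read_imc_roi(f)
  expect_identical(back$channels, roi$channels)
  expect_identical(back$object_mask, roi$object_mask)
  expect_identical(back$wbc_mask, roi$wbc_mask)
  expect_equal(back$klass, roi$klass)
  expect_identical(
    vapply(names(roi$channels), function(m) score_marker(back, m),
      integer(1)),
    vapply(names(roi$channels), function(m) score_marker(roi, m), integer(1))
  )
  unlink(c(f, paste0(f, ".json")))
})
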
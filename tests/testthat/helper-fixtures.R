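# Shared fixtures: small desk-scale configurations and manifest matching.

small_slide_config <- function(dim_px = c(700, 700), n_wbc = 80, n_ctc = 5,
                               n_lev = 8, n_apoptotic = 5, n_debris = 3,
                               ...) {
  slide_config(
    dim_px = dim_px, n_wbc = n_wbc, n_ctc = n_ctc, n_lev = n_lev,
    n_apoptotic = n_apoptotic, n_debris = n_debris, ...
  )
}

small_imc_config <- function(n_ctc = 12, n_lev = 15, n_apoptotic = 8, ...) {
  imc_profile_config(
    n_ctc = n_ctc, n_lev = n_lev, n_apoptotic = n_apoptotic, ...
  )
}

# Nearest planted object for each detected record; NA when farther than
# tol_um from any planted center.
match_to_manifest <- function(manifest, records, tol_um = 3) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- sqrt((manifest$x_um - records$x_um[i])^2 +
      (manifest$y_um - records$y_um[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= tol_um) j else NA_integer_
  }, integer(1))
}

# The class the gating tree should assign to a planted object.
expected_class <- function(klass) {
  ifelse(klass == "DEBRIS", "EXCLUDED", klass)
}

# A one-row morphometrics record with overridable fields, for direct
# classifier tests.
make_morph <- function(...) {
  m <- list(
    x_um = 10, y_um = 10, area_um2 = 80, equivalent_diameter_um = 10,
    circularity = 0.95, snr_DAPI = 0, snr_CK = 10, snr_CD45 = 0,
    dapi_area_um2 = 0, dapi_fragment_count = 0L, nucleus_solidity = 1,
    ck_texture_cv = 0.1
  )
  ov <- list(...)
  m[names(ov)] <- ov
  as.data.frame(m)
}

fixed_wbc_context <- function(median_um = 10, n = 100) {
  structure(
    list(
      median_wbc_diameter_um = median_um, wbc_diameter_mad = 1,
      n_wbc = n, fallback = n < 50
    ),
    class = "wbc_context"
  )
}

# Minimal ROI stack with constant channels for boundary tests.
make_fake_roi <- function(object_value, wbc_value, side = 40,
                          markers = c("m1"), dna_value = NULL) {
  obj <- matrix(FALSE, side, side)
  obj[15:25, 15:25] <- TRUE
  wbc <- matrix(FALSE, side, side)
  wbc[2:8, 2:8] <- TRUE
  ch <- lapply(markers, function(m) {
    x <- matrix(0, side, side)
    x[obj] <- object_value
    x[wbc] <- wbc_value
    x
  })
  names(ch) <- markers
  if (!is.null(dna_value)) {
    x <- matrix(0, side, side)
    x[obj] <- dna_value
    x[wbc] <- wbc_value
    ch$DNA <- x
  }
  list(
    roi_id = "fake", klass = "CTC", patient_id = "p1",
    object_mask = obj, wbc_mask = wbc, channels = ch
  )
}

# A cohort with the reference margins: 21/44 CTC-positive, 35/44
# LEV-positive and 17 of the 23 CTC-negative patients LEV-positive (hence
# 18 both, 3 CTC-only, 17 LEV-only, 6 neither).
margins_cohort <- function() {
  pattern <- rbind(
    matrix(rep(c(1, 2), 18), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 2), 17), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), 6), ncol = 2, byrow = TRUE)
  )
  data.frame(
    patient_id = rep(sprintf("P%02d", 1:44), each = 2),
    slide_id = sprintf("P%02d_S%d", rep(1:44, each = 2), rep(1:2, 44)),
    n_ctc = rep(pattern[, 1], each = 2) * rep(c(1, 0), 44),
    n_lev = rep(pattern[, 2], each = 2) * rep(c(0, 1), 44)
  )
}
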
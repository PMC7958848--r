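#' Classification parameters
#'
#' Gate thresholds for the rule-based decision tree. Defaults: CK positivity
#' at SNR >= 3, CD45 exclusion at SNR >= 2, nucleation at >= 10 um^2 of
#' DAPI-positive area with DAPI SNR >= 3, the LEV roundness gate at
#' circularity >= 0.80 (an automatable surrogate for manual brightfield
#' membrane confirmation), the 6 um lower LEV size gate, apoptotic criteria
#' (>= 2 nuclear fragments, nucleus solidity < 0.85, or CK texture CV > 0.8),
#' and the CTC size gate at 1.25 x the median WBC diameter with an absolute
#' 12 um fallback when fewer than `min_wbc` WBCs are available.
#'
#' @param ck_snr_min minimum CK SNR for a CK+ object.
#' @param cd45_snr_max CD45 SNR at or above which an object is a WBC.
#' @param dapi_area_min_um2,dapi_snr_min nucleation criteria.
#' @param lev_circularity_min,lev_diameter_min_um LEV gates.
#' @param apoptotic_fragments_min,apoptotic_solidity_max,apoptotic_ck_cv_max
#'   apoptotic-like criteria (any one suffices).
#' @param ctc_size_factor CTC size gate as a multiple of the median WBC
#'   diameter.
#' @param min_wbc minimum WBC count for relative size gating.
#' @param ctc_diameter_fallback_um absolute CTC size gate when WBC context is
#'   insufficient.
#' @return list of class `"classify_config"`.
#' @export
classify_config <- function(ck_snr_min = 3,
                            cd45_snr_max = 2,
                            dapi_area_min_um2 = 10,
                            dapi_snr_min = 3,
                            lev_circularity_min = 0.80,
                            lev_diameter_min_um = 6.0,
                            apoptotic_fragments_min = 2L,
                            apoptotic_solidity_max = 0.85,
                            apoptotic_ck_cv_max = 0.8,
                            ctc_size_factor = 1.25,
                            min_wbc = 50L,
                            ctc_diameter_fallback_um = 12) {
  structure(
    list(
      ck_snr_min = ck_snr_min, cd45_snr_max = cd45_snr_max,
      dapi_area_min_um2 = dapi_area_min_um2, dapi_snr_min = dapi_snr_min,
      lev_circularity_min = lev_circularity_min,
      lev_diameter_min_um = lev_diameter_min_um,
      apoptotic_fragments_min = as.integer(apoptotic_fragments_min),
      apoptotic_solidity_max = apoptotic_solidity_max,
      apoptotic_ck_cv_max = apoptotic_ck_cv_max,
      ctc_size_factor = ctc_size_factor,
      min_wbc = as.integer(min_wbc),
      ctc_diameter_fallback_um = ctc_diameter_fallback_um
    ),
    class = "classify_config"
  )
}

#' Summarize the surrounding WBC population of a slide
#'
#' WBCs (DAPI+/CD45+/CK- nuclei) provide the size reference for the "larger
#' than surrounding WBCs" CTC gate. When fewer than `min_wbc` qualifying
#' nuclei are found the context is flagged and classification falls back to
#' an absolute size threshold. CK+ objects (LEVs included) never enter the
#' WBC statistics.
#'
#' @param candidates a `candidate_set` from [segment_candidates()].
#' @param config a [classify_config()].
#' @return list of class `"wbc_context"`: `median_wbc_diameter_um`,
#'   `wbc_diameter_mad`, `n_wbc`, `fallback`.
#' @export
wbc_context <- function(candidates, config = classify_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  w <- candidates$wbc_records
  w <- w[
    w$snr_DAPI >= config$dapi_snr_min &
      w$snr_CD45 >= config$cd45_snr_max &
      w$snr_CK < config$ck_snr_min, ,
    drop = FALSE
  ]
  n <- nrow(w)
  fallback <- n < config$min_wbc
  structure(
    list(
      median_wbc_diameter_um = if (n) stats::median(w$equivalent_diameter_um) else NA_real_,
      wbc_diameter_mad = if (n) stats::mad(w$equivalent_diameter_um) else NA_real_,
      n_wbc = n,
      fallback = fallback
    ),
    class = "wbc_context"
  )
}

ctc_size_threshold <- function(ctx, config) {
  if (isTRUE(ctx$fallback) || is.na(ctx$median_wbc_diameter_um)) {
    config$ctc_diameter_fallback_um
  } else {
    config$ctc_size_factor * ctx$median_wbc_diameter_um
  }
}

#' Classify one measured object
#'
#' Deterministic decision tree over the morphometrics, evaluated in order:
#' \enumerate{
#'   \item CK gate: objects below `ck_snr_min` are WBC when CD45+ and
#'     nucleated, otherwise EXCLUDED.
#'   \item CD45 gate: CK+ objects at or above `cd45_snr_max` are WBC.
#'   \item Nucleation: DAPI+ means DAPI-positive area overlapping the mask
#'     of at least `dapi_area_min_um2` with DAPI SNR >= `dapi_snr_min`.
#'   \item DAPI- objects: LEV when round (circularity >= 0.80) and at least
#'     6 um in equivalent diameter, otherwise EXCLUDED (sub-6-um CK+ specks
#'     are deliberately omitted).
#'   \item DAPI+ objects: APOPTOTIC when the nucleus is fragmented
#'     (>= 2 fragments), poorly solid (< 0.85) or the CK texture CV exceeds
#'     0.8 (disruption trumps intactness); otherwise CTC when larger than
#'     `ctc_size_factor` x the median WBC diameter; otherwise EXCLUDED.
#' }
#'
#' @param m one-row data.frame (or coercible list) of morphometrics as
#'   produced by [measure_object()].
#' @param ctx a [wbc_context()] (or `NULL` to force the absolute fallback).
#' @param config a [classify_config()].
#' @return character class label, with the gate trail in
#'   `attr(x, "gates_passed")`.
#' @export
classify_object <- function(m, ctx = NULL, config = classify_config()) {
  m <- as.list(m)
  gates <- character()
  dapi_pos <- m$dapi_area_um2 >= config$dapi_area_min_um2 &&
    m$snr_DAPI >= config$dapi_snr_min

  if (m$snr_CK < config$ck_snr_min) {
    if (m$snr_CD45 >= config$cd45_snr_max && dapi_pos) {
      return(structure("WBC", gates_passed = c("CK-", "CD45+", "DAPI+")))
    }
    return(structure("EXCLUDED", gates_passed = "CK-"))
  }
  gates <- c(gates, "CK+")
  if (m$snr_CD45 >= config$cd45_snr_max) {
    return(structure("WBC", gates_passed = c(gates, "CD45+")))
  }
  gates <- c(gates, "CD45-")

  if (!dapi_pos) {
    gates <- c(gates, "DAPI-")
    if (m$circularity >= config$lev_circularity_min &&
      m$equivalent_diameter_um >= config$lev_diameter_min_um) {
      return(structure("LEV", gates_passed = c(gates, "round", "size>=6um")))
    }
    return(structure("EXCLUDED", gates_passed = gates))
  }
  gates <- c(gates, "DAPI+")

  disrupted <- m$dapi_fragment_count >= config$apoptotic_fragments_min ||
    m$nucleus_solidity < config$apoptotic_solidity_max ||
    m$ck_texture_cv > config$apoptotic_ck_cv_max
  if (disrupted) {
    return(structure("APOPTOTIC", gates_passed = c(gates, "disrupted")))
  }
  gates <- c(gates, "intact")
  if (m$equivalent_diameter_um > ctc_size_threshold(ctx, config)) {
    return(structure("CTC", gates_passed = c(gates, "larger-than-WBC")))
  }
  structure("EXCLUDED", gates_passed = gates)
}

#' Classify all candidates of a slide
#'
#' Applies [classify_object()] to every record of a `candidate_set` using the
#' slide's own WBC context.
#'
#' @param candidates a `candidate_set` from [segment_candidates()].
#' @param ctx optional [wbc_context()]; computed from `candidates` when
#'   omitted.
#' @param config a [classify_config()].
#' @return data.frame of object records: the morphometrics columns plus
#'   `slide_id`, `object_id`, `klass` and `gates_passed`
#'   (semicolon-separated).
#' @export
classify_candidates <- function(candidates, ctx = NULL,
                                config = classify_config()) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (is.null(ctx)) ctx <- wbc_context(candidates, config)
  rec <- candidates$records
  n <- nrow(rec)
  klass <- character(n)
  gates <- character(n)
  for (i in seq_len(n)) {
    k <- classify_object(rec[i, ], ctx, config)
    klass[i] <- as.character(k)
    gates[i] <- paste(attr(k, "gates_passed"), collapse = ";")
  }
  out <- cbind(
    data.frame(
      slide_id = rep(candidates$slide_id, n),
      object_id = sprintf("%s-%04d", candidates$slide_id, rec$label),
      klass = klass,
      stringsAsFactors = FALSE
    ),
    rec
  )
  out$gates_passed <- gates
  out
}

#' Build the slide report
#'
#' One row per reportable object (non-WBC, non-EXCLUDED), in stable reading
#' order (by `y_um`, then `x_um`): identifiers, class, coordinates in um from
#' the top-left origin, equivalent diameter, circularity, per-channel SNRs
#' and the gate trail.
#'
#' @param records classified records from [classify_candidates()].
#' @return data.frame of report rows.
#' @export
build_report <- function(records) {
  keep <- !(records$klass %in% c("WBC", "EXCLUDED"))
  r <- records[keep, , drop = FALSE]
  r <- r[order(r$y_um, r$x_um), , drop = FALSE]
  out <- data.frame(
    slide_id = r$slide_id,
    object_id = r$object_id,
    class = r$klass,
    x_um = r$x_um,
    y_um = r$y_um,
    diameter_um = r$equivalent_diameter_um,
    circularity = r$circularity,
    snr_DAPI = r$snr_DAPI,
    snr_CK = r$snr_CK,
    snr_CD45 = r$snr_CD45,
    gates_passed = r$gates_passed,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write / read a slide report CSV
#'
#' Round-trip safe: `read_report(write_report(x, f))` reproduces the report
#' rows (numeric columns to full precision).
#'
#' @param report data.frame from [build_report()].
#' @param path file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns the
#'   report data.frame.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = c(
      slide_id = "character", object_id = "character", class = "character",
      gates_passed = "character"
    ))
}

#' End-to-end slide analysis
#'
#' Convenience wrapper: segmentation, WBC context, classification and report
#' assembly in one call.
#'
#' @param slide a `slide_image`.
#' @param detect a [detect_config()].
#' @param classify a [classify_config()].
#' @return list with `candidates`, `context`, `records` and `report`.
#' @export
analyze_slide <- function(slide, detect = detect_config(),
                          classify = classify_config()) {
  cand <- segment_candidates(slide, detect)
  ctx <- wbc_context(cand, classify)
  rec <- classify_candidates(cand, ctx, classify)
  list(
    candidates = cand, context = ctx, records = rec,
    report = build_report(rec)
  )
}
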
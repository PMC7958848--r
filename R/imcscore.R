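#' Score one marker of an IMC ROI on the 0-3 scale
#'
#' The ion-count signal-to-noise ratio is the mean count over the centered
#' object mask divided by the mean count over the surrounding WBC pixels of
#' the same ROI (floored to keep the ratio defined). Scores are binned
#' left-closed: SNR in `[0, 2)` scores 0, `[2, 5)` scores 1, `[5, 10)` scores
#' 2 and `[10, Inf)` scores 3, so an SNR of exactly 2 scores 1 and exactly 10
#' scores 3.
#'
#' @param roi an ROI stack (list with `object_mask`, `wbc_mask` and
#'   `channels`; see [render_imc_rois()]).
#' @param marker channel name.
#' @param bin_edges lower edges of score bins 1..3.
#' @param wbc_floor minimum WBC mean used in the denominator.
#' @return integer score in 0..3, or `NA` (with a warning) for an unscorable
#'   ROI without WBC pixels.
#' @export
score_marker <- function(roi, marker, bin_edges = c(2, 5, 10),
                         wbc_floor = 1e-8) {
  if (!marker %in% names(roi$channels)) {
    stop("marker channel not present: ", marker)
  }
  if (is.null(roi$wbc_mask) || !any(roi$wbc_mask)) {
    warning("unscorable ROI (no WBC pixels): ", roi$roi_id %||% "<unnamed>")
    return(NA_integer_)
  }
  ch <- roi$channels[[marker]]
  snr <- mean(ch[roi$object_mask]) / max(mean(ch[roi$wbc_mask]), wbc_floor)
  as.integer(findInterval(snr, bin_edges))
}

#' DNA load of an IMC ROI
#'
#' Classifies the DNA-intercalator signal of the centered object relative to
#' surrounding WBCs: SNR below 1.5 is `negative`, `[1.5, 5)` is `weak`
#' (the trace nucleic-acid signal seen in a subset of LEVs), and 5 or more is
#' `positive`.
#'
#' @param roi an ROI stack with a `"DNA"` channel.
#' @param thresholds length-2 numeric, the weak and positive SNR cut points.
#' @return `"negative"`, `"weak"` or `"positive"`.
#' @export
dna_load <- function(roi, thresholds = c(1.5, 5)) {
  if (!"DNA" %in% names(roi$channels)) stop("DNA channel not present")
  ch <- roi$channels[["DNA"]]
  if (is.null(roi$wbc_mask) || !any(roi$wbc_mask)) {
    return(NA_character_)
  }
  snr <- mean(ch[roi$object_mask]) / max(mean(ch[roi$wbc_mask]), 1e-8)
  c("negative", "weak", "positive")[findInterval(snr, thresholds) + 1L]
}

new_score_matrix <- function(scores, ann) {
  ord <- order(ann$klass, ann$patient_id, ann$roi_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  structure(
    list(scores = scores[ord, , drop = FALSE], ann = ann),
    class = "score_matrix"
  )
}

#' Assemble the object x marker score matrix
#'
#' Scores every protein channel of every ROI with [score_marker()] and the
#' DNA channel with [dna_load()]. Rows are canonically ordered by (class,
#' patient, ROI id), so any input order yields the same matrix. The DNA
#' channel is held apart from the protein scores in the annotations.
#'
#' @param rois list of ROI stacks (each with `roi_id`, `klass`,
#'   `patient_id`), e.g. `render_imc_rois(...)$rois`.
#' @return object of class `"score_matrix"`: `scores` (integer matrix,
#'   objects x markers) and `ann` (per-object class, patient and DNA load).
#'   Unscorable ROIs are dropped with a message; an error is raised if none
#'   remain.
#' @export
build_score_matrix <- function(rois) {
  stopifnot(length(rois) >= 1)
  markers <- setdiff(names(rois[[1]]$channels), "DNA")
  scorable <- vapply(rois, function(r) any(r$wbc_mask), TRUE)
  if (!any(scorable)) stop("all ROIs are unscorable (no WBC masks)")
  if (any(!scorable)) {
    message(sum(!scorable), " unscorable ROI(s) excluded from the matrix")
  }
  rois <- rois[scorable]
  n <- length(rois)
  scores <- matrix(NA_integer_, n, length(markers),
    dimnames = list(
      vapply(rois, function(r) r$roi_id, ""), markers
    ))
  dna <- character(n)
  for (i in seq_len(n)) {
    for (m in markers) scores[i, m] <- score_marker(rois[[i]], m)
    dna[i] <- if ("DNA" %in% names(rois[[i]]$channels)) {
      dna_load(rois[[i]])
    } else {
      NA_character_
    }
  }
  ann <- data.frame(
    roi_id = vapply(rois, function(r) r$roi_id, ""),
    klass = vapply(rois, function(r) r$klass, ""),
    patient_id = vapply(rois, function(r) r$patient_id, ""),
    dna_load = dna,
    stringsAsFactors = FALSE
  )
  new_score_matrix(scores, ann)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(
    "score_matrix: ", nrow(x$scores), " objects x ", ncol(x$scores),
    " protein markers (DNA held separately)\n",
    sep = ""
  )
  print(table(x$ann$klass))
  invisible(x)
}

#' Mean per-object sum of protein scores, by class
#'
#' Sums the protein scores (DNA excluded by construction) per object and
#' averages within each class — the overall protein load of the object
#' classes.
#'
#' @param sm a `score_matrix`.
#' @return named numeric vector of class means; attribute `"per_object"`
#'   carries the per-object sums.
#' @export
class_score_sums <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"), nrow(sm$scores) > 0)
  sums <- rowSums(sm$scores)
  out <- tapply(sums, sm$ann$klass, mean)
  structure(as.numeric(out), names = names(out), per_object = sums)
}

positivity_row <- function(col) {
  n <- length(col)
  data.frame(
    n = n,
    p0 = mean(col == 0),
    p1 = mean(col == 1),
    p_ge1 = mean(col >= 1),
    p_ge2 = mean(col >= 2),
    pct0 = round_percent(mean(col == 0)),
    pct1 = round_percent(mean(col == 1)),
    pct_ge1 = round_percent(mean(col >= 1)),
    pct_ge2 = round_percent(mean(col >= 2))
  )
}

#' Score-bin distribution and positivity of one marker
#'
#' Per class and overall: the fraction of objects with score 0, exactly 1,
#' at least 1 (positivity) and at least 2, as exact fractions and
#' nearest-integer percents.
#'
#' @param sm a `score_matrix`.
#' @param marker marker name.
#' @param by_class include per-class rows (default `TRUE`).
#' @return data.frame with one row per group (`overall` first).
#' @export
marker_positivity <- function(sm, marker, by_class = TRUE) {
  stopifnot(inherits(sm, "score_matrix"))
  if (!marker %in% colnames(sm$scores)) stop("marker not in matrix: ", marker)
  col <- sm$scores[, marker]
  out <- cbind(group = "overall", positivity_row(col))
  if (by_class) {
    per <- lapply(split(seq_along(col), sm$ann$klass), function(i) {
      positivity_row(col[i])
    })
    out <- rbind(
      out,
      cbind(group = names(per), do.call(rbind, per))
    )
  }
  rownames(out) <- NULL
  out
}

#' Positivity for at least one marker of a set
#'
#' Per class and overall, the fraction of objects whose maximum score over
#' `marker_set` is at least 1. When `ref_marker` is given, the complementary
#' cross-tab is included: among objects negative for the reference marker,
#' the fraction lacking all markers of the set.
#'
#' @param sm a `score_matrix`.
#' @param marker_set character vector of marker names (non-empty).
#' @param ref_marker optional reference marker (e.g. EpCAM) for the
#'   "reference-negative yet panel-status" cross-tab.
#' @return list: `positivity` (data.frame per group: fraction and percent)
#'   and, when `ref_marker` is given, `ref_negative_crosstab`.
#' @export
panel_positivity <- function(sm, marker_set, ref_marker = NULL) {
  stopifnot(inherits(sm, "score_matrix"))
  if (length(marker_set) == 0) stop("validation error: empty marker set")
  miss <- setdiff(marker_set, colnames(sm$scores))
  if (length(miss)) stop("markers not in matrix: ", paste(miss, collapse = ", "))
  mx <- apply(sm$scores[, marker_set, drop = FALSE], 1, max)
  grp <- c(list(overall = seq_along(mx)), split(seq_along(mx), sm$ann$klass))
  pos <- do.call(rbind, lapply(names(grp), function(g) {
    i <- grp[[g]]
    data.frame(
      group = g, n = length(i), frac = mean(mx[i] >= 1),
      pct = round_percent(mean(mx[i] >= 1))
    )
  }))
  out <- list(positivity = pos)
  if (!is.null(ref_marker)) {
    if (!ref_marker %in% colnames(sm$scores)) {
      stop("marker not in matrix: ", ref_marker)
    }
    refneg <- sm$scores[, ref_marker] == 0
    ct <- do.call(rbind, lapply(names(grp), function(g) {
      i <- intersect(grp[[g]], which(refneg))
      data.frame(
        group = g, n_ref_negative = length(i),
        frac_panel_negative = if (length(i)) mean(mx[i] == 0) else NA_real_,
        pct_panel_negative = if (length(i)) {
          round_percent(mean(mx[i] == 0))
        } else {
          NA_real_
        }
      )
    }))
    out$ref_negative_crosstab <- ct
  }
  out
}
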
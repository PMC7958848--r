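#' Robust background estimate for one channel
#'
#' Background level is the median pixel intensity; spread is the median
#' absolute deviation scaled to an SD equivalent (x 1.4826) and floored at
#' machine epsilon so downstream signal-to-noise ratios are always defined.
#' Rare, bright objects on a slide occupy a small fraction of pixels, so the
#' median/MAD pair is insensitive to them.
#'
#' @param x numeric matrix (one channel raster).
#' @return named numeric vector `c(level, mad_sd)`.
#' @export
estimate_background <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0)
  med <- stats::median(x)
  s <- max(stats::mad(x, center = med), .Machine$double.eps)
  c(level = med, mad_sd = s)
}

#' Detection parameters
#'
#' @param ck_snr_k CK threshold in robust SDs above background (default 5).
#' @param min_detect_um smallest equivalent diameter kept as a candidate
#'   (default 4 um, deliberately below the 6 um LEV classification gate so
#'   the gate is applied exactly once, in classification).
#' @param min_nucleus_um smallest DAPI component kept as a nucleus record.
#' @return list of class `"detect_config"`.
#' @export
detect_config <- function(ck_snr_k = 5, min_detect_um = 4,
                          min_nucleus_um = 4) {
  structure(
    list(
      ck_snr_k = ck_snr_k, min_detect_um = min_detect_um,
      min_nucleus_um = min_nucleus_um
    ),
    class = "detect_config"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass and relabeled 1..k.
label8 <- function(mask) {
  lab <- imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nmax <- max(lab)
  if (nmax < 2) return(lab)
  h <- nrow(lab)
  w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1] # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w] # down-left diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs)) {
    parent <- seq_len(nmax)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1])
      rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    root <- vapply(seq_len(nmax), find, 0L)
    map <- integer(nmax)
    map[sort(unique(root))] <- seq_along(unique(root))
    lab[lab > 0] <- map[root[lab[lab > 0]]]
  }
  lab
}

# Contour-following perimeter: polygon length of the boundary-pixel chain
# smoothed with a circular 3-point moving average, plus pi for the half-pixel
# offset between pixel centers and the true mask boundary (Minkowski
# correction). Unbiased within ~2% for rasterized disks down to r = 3 px and
# within ~4% for squares, which keeps 4*pi*A/P^2 of a disk in (0.95, 1.05]
# and of a square near pi/4.
contour_perimeter <- function(mask) {
  a <- sum(mask)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0L) {
    return(2 * sqrt(pi * max(a, 1)))
  }
  oc <- oc[[which.max(vapply(oc, nrow, 0L))]]
  n <- nrow(oc)
  if (n < 4) {
    return(max(2 * sqrt(pi * max(a, 1)), n))
  }
  idx <- function(i) ((i - 1) %% n) + 1
  sm <- (oc + oc[idx(seq_len(n) + 1), ] + oc[idx(seq_len(n) - 1), ]) / 3
  sum(sqrt(rowSums((sm - sm[idx(seq_len(n) + 1), ])^2))) + pi
}

# Solidity of a pixel set: number of pixels over the estimated lattice count
# inside its convex hull (Pick-style: hull area + boundary/2 + 1).
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 4) return(1)
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3) return(1)
  x <- hp[, 1]
  y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(rowSums((hp - hp[c(2:k, 1), , drop = FALSE])^2)))
  min(1, n / (area + per / 2 + 1))
}

# Measure one connected component given global context. `rows`/`cols` are
# 1-based pixel indices of the mask.
measure_component <- function(rows, cols, slide, bg, dapi_mask, dapi_lab) {
  scale <- slide$pixel_scale_um
  dims <- dim(slide$channels$CK)
  n <- length(rows)
  area_um2 <- n * scale^2
  eqd <- 2 * sqrt(n / pi) * scale

  # crop with 2 px padding for the contour
  r0 <- max(1L, min(rows) - 2L)
  r1 <- min(dims[1], max(rows) + 2L)
  c0 <- max(1L, min(cols) - 2L)
  c1 <- min(dims[2], max(cols) + 2L)
  crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  crop[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  per <- contour_perimeter(crop)
  circ <- 4 * pi * n / per^2

  lin <- (cols - 1L) * dims[1] + rows
  snr <- vapply(names(slide$channels), function(ch) {
    b <- bg[[ch]]
    max((mean(slide$channels[[ch]][lin]) - b[["level"]]) / b[["mad_sd"]], -1)
  }, 0)
  ckv <- slide$channels$CK[lin]
  ck_cv <- if (mean(ckv) > 0) stats::sd(ckv) / mean(ckv) else 0

  din <- dapi_mask[lin]
  dapi_area <- sum(din) * scale^2
  if (any(din)) {
    frag <- length(unique(dapi_lab[lin[din]]))
    sol <- pixel_solidity(rows[din], cols[din])
  } else {
    frag <- 0L
    sol <- 1
  }

  data.frame(
    x_um = (mean(cols) - 1) * scale,
    y_um = (mean(rows) - 1) * scale,
    area_um2 = area_um2,
    equivalent_diameter_um = eqd,
    circularity = circ,
    snr_DAPI = unname(snr["DAPI"]),
    snr_CK = unname(snr["CK"]),
    snr_CD45 = unname(snr["CD45"]),
    dapi_area_um2 = dapi_area,
    dapi_fragment_count = as.integer(frag),
    nucleus_solidity = sol,
    ck_texture_cv = ck_cv
  )
}

dapi_segmentation <- function(slide, bg, config) {
  thr <- bg$DAPI[["level"]] + config$ck_snr_k * bg$DAPI[["mad_sd"]]
  mask <- slide$channels$DAPI > thr
  lab <- imageData(EBImage::fillHull(EBImage::Image(label8(mask))))
  list(mask = lab > 0, lab = lab, threshold = thr)
}

#' Segment candidate objects from a slide
#'
#' Thresholds the pan-CK channel at `background + k * MAD-SD` (default
#' k = 5), labels 8-connected components, fills holes, and discards
#' components with equivalent diameter below `min_detect_um`. Full
#' morphometrics (see [measure_object()]) are computed for every surviving
#' component. DAPI-positive components (nuclei; the WBC context population)
#' are segmented the same way and summarized with the cheaper statistics
#' needed for WBC size context.
#'
#' @param slide a `slide_image` (see [render_slide()] or
#'   [read_slide_tiff()]).
#' @param config a [detect_config()].
#' @return a list of class `"candidate_set"`: `records` (one morphometrics
#'   row per CK+ candidate), `wbc_records` (per-nucleus diameter and channel
#'   SNRs), `backgrounds`, `ck_threshold`, `labels` (CK label matrix) and
#'   `slide_id`.
#' @export
segment_candidates <- function(slide, config = detect_config()) {
  stopifnot(inherits(slide, "slide_image"))
  if (is.null(slide$channels$CK)) stop("input error: CK channel is required")
  scale <- slide$pixel_scale_um
  bg <- lapply(slide$channels, estimate_background)

  thr <- bg$CK[["level"]] + config$ck_snr_k * bg$CK[["mad_sd"]]
  mask <- slide$channels$CK > thr
  lab <- imageData(EBImage::fillHull(EBImage::Image(label8(mask))))
  dseg <- dapi_segmentation(slide, bg, config)

  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  records <- NULL
  if (length(labs)) {
    area <- tabulate(labs)
    keep <- which(2 * sqrt(area / pi) * scale >= config$min_detect_um)
    if (length(keep)) {
      by_lab <- split(seq_along(labs), labs)
      rows_l <- lapply(keep, function(l) {
        i <- by_lab[[as.character(l)]]
        cbind(idx[i, 1], idx[i, 2])
      })
      recs <- lapply(seq_along(keep), function(k) {
        m <- measure_component(
          rows_l[[k]][, 1], rows_l[[k]][, 2], slide, bg,
          dseg$mask, dseg$lab
        )
        cbind(label = keep[k], m)
      })
      records <- do.call(rbind, recs)
    }
  }
  if (is.null(records)) records <- empty_morphometrics()

  wbc_records <- nucleus_records(slide, dseg, bg, config)

  structure(
    list(
      slide_id = slide$slide_id,
      records = records,
      wbc_records = wbc_records,
      backgrounds = bg,
      ck_threshold = thr,
      labels = lab
    ),
    class = "candidate_set"
  )
}

empty_morphometrics <- function() {
  data.frame(
    label = integer(), x_um = numeric(), y_um = numeric(),
    area_um2 = numeric(), equivalent_diameter_um = numeric(),
    circularity = numeric(), snr_DAPI = numeric(), snr_CK = numeric(),
    snr_CD45 = numeric(), dapi_area_um2 = numeric(),
    dapi_fragment_count = integer(), nucleus_solidity = numeric(),
    ck_texture_cv = numeric()
  )
}

# Vectorized summary of DAPI components: diameter, centroid and channel
# means (fast path; thousands of nuclei per slide).
nucleus_records <- function(slide, dseg, bg, config) {
  scale <- slide$pixel_scale_um
  lin <- which(dseg$lab > 0)
  out <- data.frame(
    label = integer(), x_um = numeric(), y_um = numeric(),
    equivalent_diameter_um = numeric(), snr_DAPI = numeric(),
    snr_CK = numeric(), snr_CD45 = numeric()
  )
  if (!length(lin)) return(out)
  labs <- dseg$lab[lin]
  area <- tabulate(labs)
  eqd <- 2 * sqrt(area / pi) * scale
  keep <- which(eqd >= config$min_nucleus_um)
  if (!length(keep)) return(out)
  h <- dim(dseg$lab)[1]
  rows <- ((lin - 1L) %% h) + 1L
  cols <- ((lin - 1L) %/% h) + 1L
  csum <- rowsum(cbind(
    rows, cols,
    DAPI = slide$channels$DAPI[lin],
    CK = slide$channels$CK[lin],
    CD45 = slide$channels$CD45[lin]
  ), labs)
  ulab <- sort(unique(labs))
  a <- area[ulab]
  snr <- function(ch) {
    b <- bg[[ch]]
    pmax((csum[, ch] / a - b[["level"]]) / b[["mad_sd"]], -1)
  }
  res <- data.frame(
    label = ulab,
    x_um = (csum[, "cols"] / a - 1) * scale,
    y_um = (csum[, "rows"] / a - 1) * scale,
    equivalent_diameter_um = eqd[ulab],
    snr_DAPI = snr("DAPI"),
    snr_CK = snr("CK"),
    snr_CD45 = snr("CD45")
  )
  res[res$label %in% keep, , drop = FALSE]
}

#' Morphometrics of a single object mask
#'
#' Computes the full per-object feature set: equivalent diameter
#' (`2 * sqrt(area/pi) * scale`), circularity (`4*pi*A/P^2` with a
#' contour-following perimeter), per-channel signal-to-noise
#' (`(object mean - background) / background MAD-SD`, floored at -1),
#' DAPI-positive area and fragment count within the mask, nucleus solidity,
#' and the coefficient of variation of CK intensity inside the mask.
#'
#' @param mask logical (or 0/1) matrix with the same dimensions as the slide
#'   channels; must be non-empty.
#' @param slide a `slide_image`.
#' @param config a [detect_config()] (controls the DAPI threshold used for
#'   fragment counting).
#' @return a one-row data.frame of morphometrics.
#' @export
measure_object <- function(mask, slide, config = detect_config()) {
  stopifnot(inherits(slide, "slide_image"))
  mask <- mask > 0
  if (!any(mask)) stop("input error: empty mask")
  if (!all(dim(mask) == dim(slide$channels$CK))) {
    stop("input error: mask dimensions do not match the slide")
  }
  bg <- lapply(slide$channels, estimate_background)
  dseg <- dapi_segmentation(slide, bg, detect_config())
  idx <- which(mask, arr.ind = TRUE)
  measure_component(idx[, 1], idx[, 2], slide, bg, dseg$mask, dseg$lab)
}

# re-export EBImage's imageData accessor locally (avoids attaching EBImage)
imageData <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}
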
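#' Configuration for the synthetic immunofluorescence slide generator
#'
#' Builds the configuration consumed by [render_slide()]. The generator
#' emulates a monolayer of plated nucleated blood cells with rare planted
#' tumor-derived objects: white blood cells (WBC, DAPI+/CD45+/CK-),
#' circulating tumor cells (CTC, DAPI+/CK+/CD45-, larger than WBCs), large
#' extracellular vesicles (LEV, CK+ only, round, anucleate), apoptotic-like
#' cells (fragmented DAPI, speckled CK) and sub-6-micron CK+ debris specks.
#'
#' Class size distributions are truncated normals whose *truncated* mean and
#' SD equal the requested values (the parent parameters are solved by moment
#' matching at configuration time), so the planted population reproduces the
#' observed per-class size statistics: LEVs 9.8 +/- 3.0 um on 6.3-20.4 um,
#' CTCs 25.3 +/- 5.9 um on 15-45 um, apoptotic-like cells 13.5 +/- 3.7 um on
#' 6.7-25.1 um, WBCs 10 +/- 1 um.
#'
#' Fluorescence is rendered as anti-aliased ellipses on a constant background
#' with additive Gaussian read noise. The default CK and DAPI amplitudes are
#' one background unit above background with read noise at a tenth of the
#' background, which places the detection threshold (background + 5 robust
#' SDs) at half the object amplitude; with a symmetric noise model this makes
#' pixel inclusion at the object rim unbiased, so measured equivalent
#' diameters are centered on the planted ones.
#'
#' @param dim_px integer length-2, raster size (rows, cols) in pixels.
#' @param pixel_scale_um microns per pixel (default 0.65, a typical 10x
#'   slide-scanner resolution; use 0.1625 for a 40x re-image surrogate).
#' @param n_wbc,n_ctc,n_lev,n_apoptotic,n_debris planted object counts.
#' @param background named background level per channel (arbitrary units).
#' @param noise_sd named Gaussian read-noise SD per channel.
#' @param lev_dna_mult DAPI multiplier for LEVs; must stay at or below
#'   `weak_dna_ceiling` (LEVs are anucleate; values slightly above 1 emulate
#'   trace nucleic-acid content).
#' @param weak_dna_ceiling maximum allowed LEV DAPI multiplier.
#' @param allow_overlap if `TRUE`, objects may overlap (excluded from all
#'   validation suites; the pipeline analyzes isolated objects).
#' @param max_tries placement retries per object before failing.
#' @return a list of class `"slide_config"`.
#' @seealso [render_slide()]
#' @export
slide_config <- function(dim_px = c(3000L, 3000L),
                         pixel_scale_um = 0.65,
                         n_wbc = 5000L,
                         n_ctc = 4L,
                         n_lev = 8L,
                         n_apoptotic = 3L,
                         n_debris = 4L,
                         background = c(DAPI = 50, CK = 50, CD45 = 50),
                         noise_sd = c(DAPI = 5, CK = 5, CD45 = 5),
                         lev_dna_mult = 1.0,
                         weak_dna_ceiling = 1.3,
                         allow_overlap = FALSE,
                         max_tries = 500L) {
  stopifnot(
    length(dim_px) == 2, all(dim_px >= 64),
    pixel_scale_um > 0,
    all(c("DAPI", "CK", "CD45") %in% names(background)),
    all(c("DAPI", "CK", "CD45") %in% names(noise_sd)),
    all(background >= 0), all(noise_sd > 0)
  )
  if (lev_dna_mult > weak_dna_ceiling) {
    stop("lev_dna_mult exceeds weak_dna_ceiling: LEVs are anucleate")
  }
  classes <- list(
    WBC = list(
      n = as.integer(n_wbc),
      size = truncnorm_match(10, 1, 7, 13),
      axis_ratio = c(1, 1.10),
      mult = c(DAPI = 3, CK = 1, CD45 = 6),
      ck_cv = 0
    ),
    CTC = list(
      n = as.integer(n_ctc),
      size = truncnorm_match(25.3, 5.9, 15, 45),
      axis_ratio = c(1, 1.25),
      mult = c(DAPI = 3, CK = 2, CD45 = 1),
      ck_cv = 0.10,
      nucleus_frac = 0.6
    ),
    LEV = list(
      n = as.integer(n_lev),
      size = truncnorm_match(9.8, 3.0, 6.3, 20.4),
      axis_ratio = c(1, 1.08),
      mult = c(DAPI = lev_dna_mult, CK = 2, CD45 = 1),
      ck_cv = 0.05
    ),
    APOPTOTIC = list(
      n = as.integer(n_apoptotic),
      size = truncnorm_match(13.5, 3.7, 6.7, 25.1),
      axis_ratio = c(1.30, 1.40),
      # bright, compact DAPI fragments: the nuclear remnant fills only a
      # small fraction of the cell, so the whole-mask DAPI SNR must still
      # clear the nucleation gate after dilution
      mult = c(DAPI = 6, CK = 2, CD45 = 1),
      ck_cv = 0.90,
      fragments = c(2L, 4L)
    ),
    DEBRIS = list(
      n = as.integer(n_debris),
      size = c(lo = 4.6, hi = 5.5), # uniform, below the 6 um LEV gate
      axis_ratio = c(1, 1.15),
      mult = c(DAPI = 1, CK = 2, CD45 = 1),
      ck_cv = 0.05
    )
  )
  structure(
    list(
      dim_px = as.integer(dim_px),
      pixel_scale_um = pixel_scale_um,
      background = background,
      noise_sd = noise_sd,
      classes = classes,
      weak_dna_ceiling = weak_dna_ceiling,
      allow_overlap = isTRUE(allow_overlap),
      max_tries = as.integer(max_tries),
      gap_px = 2
    ),
    class = "slide_config"
  )
}

# Draw true equivalent diameters for one class.
sample_diameters <- function(cls, n) {
  if (!is.null(names(cls$size)) && all(c("mu", "sigma") %in% names(cls$size))) {
    rtruncnorm(n, cls$size[["mu"]], cls$size[["sigma"]],
      cls$size[["lo"]], cls$size[["hi"]])
  } else {
    stats::runif(n, cls$size[["lo"]], cls$size[["hi"]])
  }
}

# Anti-aliased coverage of a rotated ellipse over its bounding box.
# Returns NULL if the box is empty; coordinates are 1-based matrix indices.
ellipse_coverage <- function(dim_px, row0, col0, a, b, theta) {
  r0 <- max(1L, floor(row0 - a - 1))
  r1 <- min(dim_px[1], ceiling(row0 + a + 1))
  c0 <- max(1L, floor(col0 - a - 1))
  c1 <- min(dim_px[2], ceiling(col0 + a + 1))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  dy <- rows - row0
  dx <- cols - col0
  ct <- cos(theta)
  st <- sin(theta)
  u <- outer(dy, dx, function(y, x) x * ct + y * st)
  v <- outer(dy, dx, function(y, x) -x * st + y * ct)
  d <- sqrt((u / a)^2 + (v / b)^2)
  s <- (1 - d) * b # approximate signed distance (px) to the boundary
  cov <- pmin(pmax(s + 0.5, 0), 1)
  list(rows = rows, cols = cols, cov = cov, s = s)
}

# Multiplicative lognormal texture with unit mean and the requested CV,
# applied only to the object interior (>= 1.5 px inside the rim) so the rim
# stays at nominal amplitude and the detection threshold still cuts the edge
# at half amplitude.
apply_texture <- function(cov, s, cv) {
  if (cv <= 0) return(cov)
  interior <- which(s >= 1.5)
  if (length(interior)) {
    sl <- sqrt(log(1 + cv^2))
    cov[interior] <- cov[interior] *
      stats::rlnorm(length(interior), -sl^2 / 2, sl)
  }
  cov
}

place_objects <- function(obj, dim_px, gap_px, max_tries, allow_overlap) {
  n <- nrow(obj)
  ord <- order(obj$a_px, decreasing = TRUE) # large objects first
  row0 <- numeric(n)
  col0 <- numeric(n)
  pr <- numeric(0)
  pc <- numeric(0)
  pa <- numeric(0)
  for (i in ord) {
    a <- obj$a_px[i]
    lo_r <- a + 2
    hi_r <- dim_px[1] - a - 1
    lo_c <- a + 2
    hi_c <- dim_px[2] - a - 1
    if (lo_r >= hi_r || lo_c >= hi_c) {
      stop("placement error: object of class ", obj$klass[i],
        " (", round(2 * a), " px) does not fit the raster")
    }
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- stats::runif(1, lo_r, hi_r)
      cc <- stats::runif(1, lo_c, hi_c)
      if (allow_overlap || length(pr) == 0L ||
        all((pr - r)^2 + (pc - cc)^2 >= (pa + a + gap_px)^2)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("placement error: could not place object of class ",
        obj$klass[i], " after ", max_tries, " tries")
    }
    row0[i] <- r
    col0[i] <- cc
    pr <- c(pr, r)
    pc <- c(pc, cc)
    pa <- c(pa, a)
  }
  obj$row0 <- row0
  obj$col0 <- col0
  obj
}

# Fragment centers for an apoptotic-like nucleus: evenly spread inside the
# cell (along the major axis for k = 2) so fragments stay separated and
# resolvable at the default pixel scale.
fragment_layout <- function(k, a, b, theta, fr_px) {
  if (k == 2L) {
    off <- a - fr_px - 0.5
    ang <- theta + stats::runif(1, -0.15, 0.15)
    d <- rbind(c(-off, 0), c(off, 0))
  } else {
    ring <- min(0.55 * a, a - fr_px - 0.5)
    ang0 <- stats::runif(1, 0, 2 * pi)
    phi <- ang0 + 2 * pi * seq_len(k) / k +
      stats::runif(k, -0.2, 0.2)
    d <- cbind(ring * cos(phi), ring * sin(phi))
    ang <- theta
  }
  ct <- cos(ang)
  st <- sin(ang)
  cbind(
    drow = d[, 1] * st + d[, 2] * ct,
    dcol = d[, 1] * ct - d[, 2] * st
  )
}

#' Render a synthetic multichannel immunofluorescence slide
#'
#' Plants the configured objects at non-overlapping random positions and
#' renders DAPI, pan-CK and CD45 channels (anti-aliased ellipses on a noisy
#' background). Identical `(config, seed)` pairs yield bit-identical slides
#' and manifests.
#'
#' @param config a [slide_config()].
#' @param seed integer seed controlling all randomness of the call.
#' @param slide_id identifier stored with the slide and manifest.
#' @return a list with elements `slide` (a `slide_image`: named list of
#'   channel matrices plus `pixel_scale_um` and `slide_id`) and `manifest`
#'   (the ground-truth table: one row per planted object with class, center
#'   in um from the top-left origin, true equivalent diameter, true
#'   circularity, nucleus fragment count, planted CK texture CV and channel
#'   multipliers).
#' @export
render_slide <- function(config, seed = 1L, slide_id = "synthetic-slide") {
  stopifnot(inherits(config, "slide_config"))
  with_seed(seed, {
    scale <- config$pixel_scale_um
    # --- sample planted objects -------------------------------------------
    rows <- list()
    for (kl in names(config$classes)) {
      cls <- config$classes[[kl]]
      n <- cls$n
      if (n == 0L) next
      diam <- sample_diameters(cls, n)
      q <- stats::runif(n, cls$axis_ratio[1], cls$axis_ratio[2])
      theta <- stats::runif(n, 0, 2 * pi)
      r_eq <- (diam / scale) / 2
      a <- r_eq * sqrt(q)
      b <- r_eq / sqrt(q)
      frag <- rep(0L, n)
      if (kl == "APOPTOTIC") {
        # fragment count grows with cell size so fragments stay resolvable
        frag <- ifelse(diam < 12, 2L,
          ifelse(diam < 18,
            sample(2:3, n, replace = TRUE),
            sample(3:cls$fragments[2], n, replace = TRUE)
          ))
      }
      rows[[kl]] <- data.frame(
        klass = kl, diameter_um = diam, axis_ratio = q, theta = theta,
        a_px = a, b_px = b, nucleus_fragments = as.integer(frag),
        ck_texture_cv = cls$ck_cv,
        mult_DAPI = cls$mult[["DAPI"]], mult_CK = cls$mult[["CK"]],
        mult_CD45 = cls$mult[["CD45"]],
        stringsAsFactors = FALSE
      )
    }
    obj <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(
        klass = character(), diameter_um = numeric(),
        axis_ratio = numeric(), theta = numeric(), a_px = numeric(),
        b_px = numeric(), nucleus_fragments = integer(),
        ck_texture_cv = numeric(), mult_DAPI = numeric(),
        mult_CK = numeric(), mult_CD45 = numeric()
      )
    }
    rownames(obj) <- NULL

    # --- channels: background + read noise --------------------------------
    h <- config$dim_px[1]
    w <- config$dim_px[2]
    channels <- list()
    for (ch in c("DAPI", "CK", "CD45")) {
      channels[[ch]] <- matrix(
        config$background[[ch]] +
          stats::rnorm(h * w, 0, config$noise_sd[[ch]]),
        nrow = h, ncol = w
      )
    }

    if (nrow(obj)) {
      obj <- place_objects(
        obj, config$dim_px, config$gap_px,
        config$max_tries, config$allow_overlap
      )
      for (i in seq_len(nrow(obj))) {
        kl <- obj$klass[i]
        cls <- config$classes[[kl]]
        ec <- ellipse_coverage(
          config$dim_px, obj$row0[i], obj$col0[i],
          obj$a_px[i], obj$b_px[i], obj$theta[i]
        )
        if (is.null(ec)) next
        sub <- function(m) m[ec$rows, ec$cols]
        # CK over the whole object
        amp_ck <- (obj$mult_CK[i] - 1) * config$background[["CK"]]
        if (amp_ck > 0) {
          channels$CK[ec$rows, ec$cols] <- sub(channels$CK) +
            amp_ck * apply_texture(ec$cov, ec$s, obj$ck_texture_cv[i])
        }
        # CD45 over the whole object (WBC membrane marker)
        amp_cd <- (obj$mult_CD45[i] - 1) * config$background[["CD45"]]
        if (amp_cd > 0) {
          channels$CD45[ec$rows, ec$cols] <- sub(channels$CD45) + amp_cd * ec$cov
        }
        # DAPI: whole disk for WBC, scaled nucleus for CTC, fragments for
        # apoptotic-like cells, nothing (or sub-threshold trace) for LEVs
        amp_da <- (obj$mult_DAPI[i] - 1) * config$background[["DAPI"]]
        if (amp_da > 0) {
          if (kl == "WBC" || kl == "LEV") {
            channels$DAPI[ec$rows, ec$cols] <- sub(channels$DAPI) +
              amp_da * ec$cov
          } else if (kl == "CTC") {
            nf <- cls$nucleus_frac
            en <- ellipse_coverage(
              config$dim_px, obj$row0[i], obj$col0[i],
              obj$a_px[i] * nf, obj$b_px[i] * nf, obj$theta[i]
            )
            channels$DAPI[en$rows, en$cols] <-
              channels$DAPI[en$rows, en$cols] + amp_da * en$cov
          } else if (kl == "APOPTOTIC") {
            k <- obj$nucleus_fragments[i]
            fr_um <- min(max(0.12 * obj$diameter_um[i], 1.4), 3.0)
            fr_px <- min(fr_um / scale, 0.45 * obj$a_px[i])
            lay <- fragment_layout(
              k, obj$a_px[i], obj$b_px[i], obj$theta[i], fr_px
            )
            for (j in seq_len(k)) {
              ef <- ellipse_coverage(
                config$dim_px,
                obj$row0[i] + lay[j, "drow"], obj$col0[i] + lay[j, "dcol"],
                fr_px, fr_px, 0
              )
              channels$DAPI[ef$rows, ef$cols] <-
                channels$DAPI[ef$rows, ef$cols] + amp_da * ef$cov
            }
          }
        }
      }
    }

    manifest <- data.frame(
      object_id = sprintf("obj%04d", seq_len(nrow(obj))),
      klass = obj$klass,
      x_um = (obj$col0 - 1) * scale,
      y_um = (obj$row0 - 1) * scale,
      diameter_um = obj$diameter_um,
      circularity_true = ellipse_circularity(obj$a_px, obj$b_px),
      nucleus_fragments = obj$nucleus_fragments,
      ck_texture_cv = obj$ck_texture_cv,
      mult_DAPI = obj$mult_DAPI,
      mult_CK = obj$mult_CK,
      mult_CD45 = obj$mult_CD45,
      stringsAsFactors = FALSE
    )
    if (!nrow(obj)) manifest <- manifest[0, ]
    attr(manifest, "slide_id") <- slide_id
    attr(manifest, "pixel_scale_um") <- scale
    attr(manifest, "seed") <- as.integer(seed)

    slide <- structure(
      list(
        channels = channels, pixel_scale_um = scale,
        slide_id = slide_id
      ),
      class = "slide_image"
    )
    list(slide = slide, manifest = manifest)
  })
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(
    "slide_image '", x$slide_id, "': ", d[1], " x ", d[2], " px @ ",
    x$pixel_scale_um, " um/px; channels: ",
    paste(names(x$channels), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
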
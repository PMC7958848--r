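#' Default IMC marker panel
#'
#' Thirty-three protein markers spanning epithelial identity, EMT, prostate
#' lineage, heat-shock/EV biology, proliferation and immune markers, in the
#' column order used by the default profiles. The DNA intercalator channel is
#' named `"DNA"` and is always kept separate from the protein panel.
#'
#' @return character vector of 33 marker names.
#' @export
default_imc_markers <- function() {
  c(
    "EpCAM", "CK8_18", "Ecadherin", "Vimentin", "Twist1",
    "AR", "ARv7", "PSA", "PSMA", "HSPD1", "HSPA5", "ATP5B",
    "Cav1", "CD59", "CD9", "ClCasp3", "pP38", "PD1", "PDL1",
    "CD24", "CD31", "CD44", "Ki67", "EGFR", "HER2", "MYC",
    "PTEN", "CHGA", "SYP", "NSE", "CD56", "B7H3", "TROP2"
  )
}

# Named per-class score-bin profiles (P(score = 0..3)). These are the
# calibration surface of the generator: expected per-class sums of scores and
# the headline marker positivities are fixed here, and the remaining
# "generic" markers are filled with Binomial(3, t/3) bins solved so the
# expected per-class sum of all 33 protein scores hits the class target.
imc_named_profiles <- function() {
  list(
    EpCAM = list( # identical across classes: overall 49%/32%/19% split
      CTC = c(0.49, 0.32, 0.12, 0.07),
      LEV = c(0.49, 0.32, 0.12, 0.07),
      APOPTOTIC = c(0.49, 0.32, 0.12, 0.07)
    ),
    HSPD1 = list( # near-universal, predominantly strong in tumor objects
      CTC = c(0.02, 0.10, 0.44, 0.44),
      LEV = c(0.03, 0.13, 0.44, 0.40),
      APOPTOTIC = c(0.14, 0.40, 0.28, 0.18)
    ),
    CK8_18 = list( # all objects were CK+ at selection; IMC signal weaker
      CTC = c(0.05, 0.25, 0.40, 0.30),
      LEV = c(0.05, 0.35, 0.40, 0.20),
      APOPTOTIC = c(0.26, 0.52, 0.17, 0.05)
    ),
    ClCasp3 = list(
      CTC = c(0.92, 0.06, 0.015, 0.005),
      LEV = c(0.81, 0.13, 0.04, 0.02),
      APOPTOTIC = c(0.85, 0.10, 0.04, 0.01)
    ),
    Cav1 = list(
      CTC = c(0.94, 0.05, 0.01, 0.00),
      LEV = c(0.90, 0.08, 0.015, 0.005),
      APOPTOTIC = c(0.95, 0.04, 0.01, 0.00)
    ),
    CD59 = list(
      CTC = c(1.00, 0.00, 0.00, 0.00),
      LEV = c(0.91, 0.09, 0.00, 0.00),
      APOPTOTIC = c(0.97, 0.03, 0.00, 0.00)
    ),
    CD9 = list(
      CTC = c(0.97, 0.03, 0.00, 0.00),
      LEV = c(0.985, 0.015, 0.00, 0.00),
      APOPTOTIC = c(0.98, 0.02, 0.00, 0.00)
    ),
    Vimentin = list(
      CTC = c(0.85, 0.08, 0.05, 0.02),
      LEV = c(0.88, 0.07, 0.04, 0.01),
      APOPTOTIC = c(0.90, 0.06, 0.03, 0.01)
    ),
    Twist1 = list(
      CTC = c(0.88, 0.07, 0.04, 0.01),
      LEV = c(0.91, 0.06, 0.02, 0.01),
      APOPTOTIC = c(0.93, 0.05, 0.015, 0.005)
    )
  )
}

# AR/PSA/PSMA are planted jointly: panel positivity (at least one of the
# three with score >= 1) is a headline statistic, so the all-negative
# fraction is a planted parameter and conditional bins apply to panel-
# positive objects (all-zero draws are rejected).
imc_panel_profile <- function() {
  list(
    markers = c("AR", "PSA", "PSMA"),
    all_negative = c(CTC = 0.14, LEV = 0.37, APOPTOTIC = 0.55),
    conditional = list(
      CTC = list(
        AR = c(0.35, 0.30, 0.20, 0.15),
        PSA = c(0.40, 0.25, 0.20, 0.15),
        PSMA = c(0.45, 0.25, 0.15, 0.15)
      ),
      LEV = list(
        AR = c(0.45, 0.30, 0.15, 0.10),
        PSA = c(0.50, 0.28, 0.14, 0.08),
        PSMA = c(0.55, 0.25, 0.12, 0.08)
      ),
      APOPTOTIC = list(
        AR = c(0.60, 0.30, 0.08, 0.02),
        PSA = c(0.60, 0.30, 0.08, 0.02),
        PSMA = c(0.62, 0.28, 0.08, 0.02)
      )
    )
  )
}

#' Configuration for the synthetic IMC ROI generator
#'
#' Each region of interest (ROI) is a multichannel ion-count stack of
#' `roi_um` x `roi_um` pixels at 1 um/px (one pixel per ablation pulse) with
#' one centered object of known class and several surrounding WBC disks.
#' Marker signal is planted per object and marker as a score bin in
#' \{0,1,2,3\}; at render time each bin maps to a signal-to-noise multiplier
#' drawn from `snr_ranges`, and every channel is Poisson ion counts around
#' the local rate. The per-class bin profiles are calibrated so the expected
#' sum of the 33 protein scores is `sum_targets` per class (11.9 CTC,
#' 8.1 LEV, 4.8 apoptotic-like by default) while fixing the headline marker
#' statistics (EpCAM split 49/32/19, HSPD1 positivity, AR/PSA/PSMA panel
#' positivity 86/63/45).
#'
#' Bin frequencies are realized by proportional (largest-remainder) quota
#' assignment within each class rather than i.i.d. draws, so the planted
#' cohort margins match the configured profiles up to rounding; which object
#' receives which bin is randomized by the seed.
#'
#' @param n_ctc,n_lev,n_apoptotic objects per class (defaults 51/79/40, a
#'   170-ROI cohort).
#' @param n_patients number of patient labels to distribute (default 3).
#' @param markers protein marker names (33 by default).
#' @param roi_um ROI side length in um (and pixels; 1 um/px).
#' @param n_wbc_per_roi surrounding WBC disks per ROI (>= 5).
#' @param base_rate WBC ion-count rate (counts per pixel).
#' @param ambient_rate off-cell ion-count rate.
#' @param snr_ranges list of length 4: SNR multiplier range rendered for each
#'   planted bin. Ranges sit inside the scoring bins `[0,2) [2,5) [5,10)
#'   [10,Inf)` with a margin so Poisson noise rarely crosses a boundary.
#' @param sum_targets named expected per-class sum of protein scores.
#' @param dna_profiles named list per class: probability of DNA load class
#'   (negative/weak/positive).
#' @return a list of class `"imc_profile_config"` with the per-class,
#'   per-marker bin distributions in `$profiles` (marker x 4 matrix per
#'   class).
#' @export
imc_profile_config <- function(n_ctc = 51L, n_lev = 79L, n_apoptotic = 40L,
                               n_patients = 3L,
                               markers = default_imc_markers(),
                               roi_um = 200L,
                               n_wbc_per_roi = 8L,
                               base_rate = 10,
                               ambient_rate = 1,
                               snr_ranges = list(
                                 c(0.7, 1.4), c(2.6, 4.4),
                                 c(5.8, 9.2), c(11, 18)
                               ),
                               sum_targets = c(
                                 CTC = 11.9, LEV = 8.1,
                                 APOPTOTIC = 4.8
                               ),
                               dna_profiles = list(
                                 CTC = c(negative = 0, weak = 0, positive = 1),
                                 LEV = c(negative = 0.5, weak = 0.5, positive = 0),
                                 APOPTOTIC = c(negative = 0, weak = 0.1, positive = 0.9)
                               )) {
  stopifnot(
    length(markers) >= 1, !"DNA" %in% markers,
    n_wbc_per_roi >= 5, roi_um >= 50, base_rate > 0, ambient_rate >= 0,
    length(snr_ranges) == 4,
    all(c("CTC", "LEV", "APOPTOTIC") %in% names(sum_targets))
  )
  named <- imc_named_profiles()
  panel <- imc_panel_profile()
  named <- named[intersect(names(named), markers)]
  panel_ok <- all(panel$markers %in% markers)
  classes <- c("CTC", "LEV", "APOPTOTIC")

  profiles <- list()
  for (cl in classes) {
    prof <- matrix(NA_real_, nrow = length(markers), ncol = 4,
      dimnames = list(markers, paste0("bin", 0:3)))
    for (m in names(named)) prof[m, ] <- named[[m]][[cl]]
    exp_named <- sum(prof[!is.na(prof[, 1]), , drop = FALSE] %*% 0:3)
    exp_panel <- 0
    if (panel_ok) {
      cond <- panel$conditional[[cl]]
      p_all0 <- prod(vapply(cond, function(p) p[1], 0))
      e_raw <- sum(vapply(cond, function(p) sum(p * 0:3), 0))
      exp_panel <- (1 - panel$all_negative[[cl]]) * e_raw / (1 - p_all0)
      for (m in panel$markers) prof[m, ] <- NA_real_ # handled jointly
    }
    generic <- setdiff(markers, c(names(named), if (panel_ok) panel$markers))
    t_generic <- (sum_targets[[cl]] - exp_named - exp_panel) / length(generic)
    if (t_generic < 0 || t_generic > 3) {
      stop("cannot reach sum target ", sum_targets[[cl]], " for class ", cl)
    }
    gbins <- stats::dbinom(0:3, 3, t_generic / 3)
    for (m in generic) prof[m, ] <- gbins
    profiles[[cl]] <- prof
  }

  structure(
    list(
      n_objects = c(CTC = as.integer(n_ctc), LEV = as.integer(n_lev),
        APOPTOTIC = as.integer(n_apoptotic)),
      n_patients = as.integer(n_patients),
      markers = markers,
      roi_um = as.integer(roi_um),
      n_wbc_per_roi = as.integer(n_wbc_per_roi),
      base_rate = base_rate,
      ambient_rate = ambient_rate,
      snr_ranges = snr_ranges,
      sum_targets = sum_targets,
      dna_profiles = dna_profiles,
      dna_snr_ranges = list(
        negative = c(0.7, 1.3), weak = c(1.8, 4.0), positive = c(8, 16)
      ),
      profiles = profiles,
      panel = if (panel_ok) imc_panel_profile() else NULL,
      size_dists = list(
        CTC = truncnorm_match(25.3, 5.9, 15, 45),
        LEV = truncnorm_match(9.8, 3.0, 6.3, 20.4),
        APOPTOTIC = truncnorm_match(13.5, 3.7, 6.7, 25.1)
      )
    ),
    class = "imc_profile_config"
  )
}

# Largest-remainder apportionment of n objects over bins with probs p.
quota_counts <- function(n, p) {
  raw <- n * p / sum(p)
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  as.integer(cnt)
}

# Quota-assign bins 0..3 to n objects, in seeded random order. Largest-
# remainder apportionment matches the bin fractions but can clip rare high
# bins and so bias the mean score; single objects are therefore promoted or
# demoted between adjacent bins (toward the most under-allocated bin) until
# the realized total score equals round(n * expected score).
assign_bins <- function(n, p) {
  cnt <- quota_counts(n, p)
  raw <- n * p / sum(p)
  target <- round(n * sum(p * 0:3) / sum(p))
  repeat {
    d <- target - sum(cnt * 0:3)
    if (d == 0) break
    if (d > 0) {
      cand <- which(cnt[1:3] > 0)
      b <- cand[which.max((raw - cnt)[cand + 1])]
      cnt[b] <- cnt[b] - 1
      cnt[b + 1] <- cnt[b + 1] + 1
    } else {
      cand <- which(cnt[2:4] > 0) + 1
      b <- cand[which.max((raw - cnt)[cand - 1])]
      cnt[b] <- cnt[b] - 1
      cnt[b - 1] <- cnt[b - 1] + 1
    }
  }
  sample_vec(rep(0:3, cnt))
}

# Plant the full object x marker bin matrix plus DNA class for one cohort.
plant_imc_bins <- function(config) {
  n_tot <- sum(config$n_objects)
  bins <- matrix(0L, n_tot, length(config$markers),
    dimnames = list(NULL, config$markers))
  klass <- rep(names(config$n_objects), config$n_objects)
  dna <- character(n_tot)
  for (cl in names(config$n_objects)) {
    idx <- which(klass == cl)
    n <- length(idx)
    if (n == 0L) next
    prof <- config$profiles[[cl]]
    joint <- if (!is.null(config$panel)) config$panel$markers else character()
    for (m in config$markers) {
      if (m %in% joint) next
      bins[idx, m] <- assign_bins(n, prof[m, ])
    }
    if (length(joint)) {
      n_neg <- round(n * config$panel$all_negative[[cl]])
      neg <- sample_vec(idx, n_neg)
      pos <- setdiff(idx, neg)
      cond <- config$panel$conditional[[cl]]
      for (i in pos) {
        repeat {
          s <- vapply(joint, function(m) {
            sample(0:3, 1, prob = cond[[m]])
          }, integer(1))
          if (any(s > 0)) break
        }
        bins[i, joint] <- s
      }
    }
    dp <- config$dna_profiles[[cl]]
    dna[idx] <- sample_vec(rep(names(dp), quota_counts(n, dp)))
  }
  list(bins = bins, klass = klass, dna = dna)
}

# Render one ROI stack: centered object + surrounding WBC disks, Poisson
# ion counts per channel.
render_one_roi <- function(diam_um, bins_row, dna_class, config) {
  side <- config$roi_um
  if (diam_um >= side - 10) {
    stop("configuration error: ROI (", side, " um) smaller than object (",
      round(diam_um, 1), " um)")
  }
  c0 <- (side + 1) / 2
  q <- stats::runif(1, 1, 1.15)
  r_eq <- diam_um / 2 # 1 um per px
  ec <- ellipse_coverage(c(side, side), c0, c0,
    r_eq * sqrt(q), r_eq / sqrt(q), stats::runif(1, 0, 2 * pi))
  obj_mask <- matrix(FALSE, side, side)
  obj_mask[ec$rows, ec$cols] <- ec$cov >= 0.5

  # WBC disks in the surround, non-overlapping with object and each other
  wbc_mask <- matrix(FALSE, side, side)
  placed <- matrix(numeric(0), ncol = 3)
  n_wbc <- config$n_wbc_per_roi
  guard <- r_eq + 8
  for (j in seq_len(n_wbc)) {
    rw <- rtruncnorm(1, 10, 1, 7, 13) / 2
    for (t in 1:200) {
      pr <- stats::runif(1, rw + 2, side - rw - 1)
      pc <- stats::runif(1, rw + 2, side - rw - 1)
      d0 <- sqrt((pr - c0)^2 + (pc - c0)^2)
      if (d0 < guard + rw) next
      if (nrow(placed) &&
        any((placed[, 1] - pr)^2 + (placed[, 2] - pc)^2 <
          (placed[, 3] + rw + 2)^2)) next
      ew <- ellipse_coverage(c(side, side), pr, pc, rw, rw, 0)
      wbc_mask[ew$rows, ew$cols] <- wbc_mask[ew$rows, ew$cols] |
        (ew$cov >= 0.5)
      placed <- rbind(placed, c(pr, pc, rw))
      break
    }
  }
  if (nrow(placed) < 5) {
    stop("configuration error: could not place >= 5 WBCs in the ROI")
  }

  obj_idx <- which(obj_mask)
  wbc_idx <- which(wbc_mask)
  npx <- side * side
  channels <- vector("list", length(config$markers) + 1L)
  names(channels) <- c(config$markers, "DNA")
  for (m in config$markers) {
    mult <- {
      rg <- config$snr_ranges[[bins_row[[m]] + 1L]]
      stats::runif(1, rg[1], rg[2])
    }
    rate <- rep(config$ambient_rate, npx)
    rate[wbc_idx] <- config$base_rate
    rate[obj_idx] <- mult * config$base_rate
    channels[[m]] <- matrix(stats::rpois(npx, rate), side, side)
  }
  rg <- config$dna_snr_ranges[[dna_class]]
  dna_mult <- stats::runif(1, rg[1], rg[2])
  rate <- rep(config$ambient_rate, npx)
  rate[wbc_idx] <- config$base_rate
  rate[obj_idx] <- dna_mult * config$base_rate
  channels[["DNA"]] <- matrix(stats::rpois(npx, rate), side, side)

  list(
    object_mask = obj_mask, wbc_mask = wbc_mask, n_wbc = nrow(placed),
    channels = channels, pixel_scale_um = 1
  )
}

#' Render synthetic IMC ROI stacks with planted score bins
#'
#' Generates one 200 x 200 um ion-count ROI per object: a centered object of
#' known class plus surrounding WBC disks. Each protein channel is Poisson
#' counts whose object-over-WBC signal-to-noise ratio falls in the SNR range
#' of the planted score bin; the DNA intercalator channel is planted per the
#' class DNA-load profile (positive in CTCs, weak or negative in LEVs).
#'
#' For the full default cohort prefer [imc_score_cohort()], which renders and
#' scores one ROI at a time without holding all stacks in memory.
#'
#' @param config an [imc_profile_config()].
#' @param seed integer seed.
#' @return list with `rois` (list of ROI stacks: `object_mask`, `wbc_mask`,
#'   `channels`, `roi_id`, `klass`, `patient_id`) and `truth` (planted bin
#'   matrix, class, patient and DNA-load vectors).
#' @export
render_imc_rois <- function(config = imc_profile_config(), seed = 1L) {
  stopifnot(inherits(config, "imc_profile_config"))
  with_seed(seed, {
    plan <- imc_cohort_plan(config)
    rois <- vector("list", length(plan$klass))
    for (i in seq_along(rois)) {
      st <- render_one_roi(
        plan$diam[i], plan$bins[i, , drop = TRUE], plan$dna[i], config
      )
      st$roi_id <- plan$roi_id[i]
      st$klass <- plan$klass[i]
      st$patient_id <- plan$patient[i]
      rois[[i]] <- st
    }
    list(rois = rois, truth = plan)
  })
}

# Shared cohort plan: classes, patients, sizes and planted bins.
imc_cohort_plan <- function(config) {
  planted <- plant_imc_bins(config)
  n <- length(planted$klass)
  diam <- numeric(n)
  for (cl in names(config$n_objects)) {
    idx <- which(planted$klass == cl)
    sd <- config$size_dists[[cl]]
    diam[idx] <- rtruncnorm(length(idx), sd[["mu"]], sd[["sigma"]],
      sd[["lo"]], sd[["hi"]])
  }
  list(
    roi_id = sprintf("roi%03d", seq_len(n)),
    klass = planted$klass,
    patient = sprintf("IMCpat%d", sample(seq_len(config$n_patients), n,
      replace = TRUE)),
    dna = planted$dna,
    diam = diam,
    bins = planted$bins
  )
}

#' Render and score a full synthetic IMC cohort
#'
#' Streams ROI rendering and scoring: each ROI is rendered, scored with
#' [score_marker()] and [dna_load()], and discarded, so the default
#' 170-object, 34-channel cohort never resides in memory at once.
#'
#' @inheritParams render_imc_rois
#' @return a `score_matrix` (see [build_score_matrix()]) with the planted
#'   truth attached as `attr(x, "truth")`.
#' @export
imc_score_cohort <- function(config = imc_profile_config(), seed = 1L) {
  stopifnot(inherits(config, "imc_profile_config"))
  with_seed(seed, {
    plan <- imc_cohort_plan(config)
    n <- length(plan$klass)
    scores <- matrix(NA_integer_, n, length(config$markers),
      dimnames = list(plan$roi_id, config$markers))
    dna <- character(n)
    for (i in seq_len(n)) {
      st <- render_one_roi(
        plan$diam[i], plan$bins[i, , drop = TRUE], plan$dna[i], config
      )
      for (m in config$markers) scores[i, m] <- score_marker(st, m)
      dna[i] <- dna_load(st)
    }
    ann <- data.frame(
      roi_id = plan$roi_id, klass = plan$klass, patient_id = plan$patient,
      dna_load = dna, stringsAsFactors = FALSE
    )
    sm <- new_score_matrix(scores, ann)
    attr(sm, "truth") <- plan
    sm
  })
}
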
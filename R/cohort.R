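#' Per-patient mean counts per class
#'
#' Arithmetic mean across slides, per patient and object class.
#'
#' @param cohort data.frame with columns `patient_id`, `slide_id` and count
#'   columns `n_ctc`, `n_lev` (and optionally `n_apoptotic`).
#' @return data.frame with one row per patient: `patient_id`, `n_slides`,
#'   `mean_ctc`, `mean_lev` (and `mean_apoptotic` when present).
#' @export
enumerate_cohort <- function(cohort) {
  check_cohort(cohort)
  cls <- count_columns(cohort)
  out <- data.frame(
    patient_id = sort(unique(cohort$patient_id)),
    stringsAsFactors = FALSE
  )
  out$n_slides <- as.integer(table(cohort$patient_id)[out$patient_id])
  for (cc in cls) {
    m <- tapply(cohort[[cc]], cohort$patient_id, mean)
    out[[sub("^n_", "mean_", cc)]] <- as.numeric(m[out$patient_id])
  }
  out
}

check_cohort <- function(cohort) {
  stopifnot(
    is.data.frame(cohort),
    all(c("patient_id", "slide_id", "n_ctc", "n_lev") %in% names(cohort))
  )
  cls <- count_columns(cohort)
  for (cc in cls) {
    if (any(cohort[[cc]] < 0) || any(cohort[[cc]] != round(cohort[[cc]]))) {
      stop("counts must be non-negative integers: ", cc)
    }
  }
  invisible(TRUE)
}

count_columns <- function(cohort) {
  intersect(c("n_ctc", "n_lev", "n_apoptotic"), names(cohort))
}

#' Average inter-slide coefficient of variation per class
#'
#' For each patient with at least two slides and a mean slide count strictly
#' greater than `min_mean` events, the CV is the sample SD (n - 1
#' denominator) of the slide counts divided by their mean. Returns the
#' average CV over included patients, per class.
#'
#' @param cohort cohort count table (see [enumerate_cohort()]).
#' @param min_mean inclusion threshold on the per-patient mean count
#'   (default 5; patients at or below it are excluded).
#' @return data.frame with `class`, `mean_cv`, `n_patients`. When no patient
#'   passes the filter for a class, `mean_cv` is `NA` and a warning is
#'   raised.
#' @export
slide_cv <- function(cohort, min_mean = 5) {
  check_cohort(cohort)
  cls <- count_columns(cohort)
  res <- lapply(cls, function(cc) {
    spl <- split(cohort[[cc]], cohort$patient_id)
    spl <- spl[vapply(spl, length, 0L) >= 2]
    mu <- vapply(spl, mean, 0)
    inc <- mu > min_mean
    if (!any(inc)) {
      warning("no patient passes the >", min_mean, " filter for ", cc)
      return(data.frame(
        class = sub("^n_", "", cc), mean_cv = NA_real_, n_patients = 0L
      ))
    }
    cv <- vapply(spl[inc], function(x) stats::sd(x) / mean(x), 0)
    data.frame(
      class = sub("^n_", "", cc), mean_cv = mean(cv),
      n_patients = sum(inc)
    )
  })
  do.call(rbind, res)
}

#' Regression of per-patient mean LEV on mean CTC counts
#'
#' Ordinary least squares of mean LEV count on mean CTC count across
#' patients, with the Pearson correlation and its two-sided p value. Also
#' reports the ratio of total LEV to total CTC counts, a distinct reading of
#' "x times as many LEVs" kept alongside the regression slope.
#'
#' @param means per-patient means from [enumerate_cohort()], or a cohort
#'   count table (automatically aggregated).
#' @return list: `slope`, `intercept`, `r`, `p`, `n`, `count_ratio`.
#' @export
lev_ctc_regression <- function(means) {
  if (!("mean_ctc" %in% names(means))) means <- enumerate_cohort(means)
  if (nrow(means) < 3) stop("need at least 3 patients")
  if (stats::var(means$mean_ctc) == 0) {
    stop("undefined fit: zero variance in CTC counts")
  }
  fit <- stats::lm(mean_lev ~ mean_ctc, data = means)
  ct <- stats::cor.test(means$mean_ctc, means$mean_lev)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate),
    p = ct$p.value,
    n = nrow(means),
    count_ratio = sum(means$mean_lev * means$n_slides) /
      sum(means$mean_ctc * means$n_slides)
  )
}

#' Detection rates and the LEV sensitivity gain
#'
#' A patient is positive for a class when the total count across all their
#' slides is at least one. The LEV rescue rate is the fraction of
#' CTC-negative patients with at least one LEV — the sensitivity added by
#' scoring LEVs in parallel with CTCs.
#'
#' @param cohort cohort count table.
#' @return list with exact fractions (`ctc_pos`, `lev_pos`, `double_neg`,
#'   `lev_rescue`, each as `c(k, n)`), the corresponding rates, and percents
#'   rounded to the nearest integer (halves away from zero).
#' @export
sensitivity_gain <- function(cohort) {
  check_cohort(cohort)
  tot_ctc <- tapply(cohort$n_ctc, cohort$patient_id, sum)
  tot_lev <- tapply(cohort$n_lev, cohort$patient_id, sum)
  n <- length(tot_ctc)
  ctc_pos <- sum(tot_ctc >= 1)
  lev_pos <- sum(tot_lev >= 1)
  dneg <- sum(tot_ctc == 0 & tot_lev == 0)
  ctc_neg_ids <- tot_ctc == 0
  rescue_k <- sum(ctc_neg_ids & tot_lev >= 1)
  rescue_n <- sum(ctc_neg_ids)
  rate <- function(k, nn) if (nn > 0) k / nn else 0
  list(
    n_patients = n,
    ctc_pos = c(ctc_pos, n),
    lev_pos = c(lev_pos, n),
    double_neg = c(dneg, n),
    lev_rescue = c(rescue_k, rescue_n),
    ctc_pos_rate = rate(ctc_pos, n),
    lev_pos_rate = rate(lev_pos, n),
    double_neg_rate = rate(dneg, n),
    lev_rescue_rate = rate(rescue_k, rescue_n),
    ctc_pos_pct = round_percent(rate(ctc_pos, n)),
    lev_pos_pct = round_percent(rate(lev_pos, n)),
    double_neg_pct = round_percent(rate(dneg, n)),
    lev_rescue_pct = round_percent(rate(rescue_k, rescue_n))
  )
}

#' Group summaries and covariate correlation
#'
#' Per-covariate-group means and SDs of per-patient counts (per class and
#' combined), plus the Pearson correlation between counts and the
#' ordinal-coded covariate (`low`/`intermediate`/`high` coded 0/1/2;
#' `no`/`yes` coded 0/1; other factors in level order). Rows with missing
#' covariate are dropped and their number reported.
#'
#' @param cohort cohort count table with a per-patient covariate column.
#' @param covariate name of the covariate column.
#' @return list: `groups` (group x class mean/SD table), `correlation`
#'   (data.frame of Pearson r and p per class; `NULL` when fewer than two
#'   non-missing groups), `n_dropped`.
#' @export
group_summary <- function(cohort, covariate) {
  check_cohort(cohort)
  if (!covariate %in% names(cohort)) {
    stop("covariate column not found: ", covariate)
  }
  means <- enumerate_cohort(cohort)
  cov_pat <- tapply(
    as.character(cohort[[covariate]]), cohort$patient_id,
    function(x) x[1]
  )
  means$covariate <- as.character(cov_pat[means$patient_id])
  n_dropped <- sum(is.na(means$covariate))
  means <- means[!is.na(means$covariate), , drop = FALSE]

  ordered_levels <- c("low", "intermediate", "high", "no", "yes")
  lv <- unique(means$covariate)
  lv <- c(intersect(ordered_levels, lv), setdiff(sort(lv), ordered_levels))
  means$covariate <- factor(means$covariate, levels = lv)

  cls <- sub("^n_", "mean_", count_columns(cohort))
  means$mean_combined <- rowSums(means[, cls, drop = FALSE])
  cls <- c(cls, "mean_combined")

  groups <- do.call(rbind, lapply(split(means, means$covariate), function(g) {
    row <- data.frame(group = as.character(g$covariate[1]), n = nrow(g))
    for (cc in cls) {
      row[[paste0(cc, "_mean")]] <- mean(g[[cc]])
      row[[paste0(cc, "_sd")]] <- stats::sd(g[[cc]])
    }
    row
  }))
  rownames(groups) <- NULL

  correlation <- NULL
  if (nlevels(droplevels(means$covariate)) >= 2 && nrow(means) >= 3) {
    code <- as.numeric(means$covariate) - 1
    correlation <- do.call(rbind, lapply(cls, function(cc) {
      if (stats::var(means[[cc]]) == 0 || stats::var(code) == 0) {
        return(data.frame(class = sub("^mean_", "", cc), r = 0, p = NA_real_))
      }
      ct <- stats::cor.test(means[[cc]], code)
      data.frame(
        class = sub("^mean_", "", cc), r = unname(ct$estimate),
        p = ct$p.value
      )
    }))
  }
  list(groups = groups, correlation = correlation, n_dropped = n_dropped)
}
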
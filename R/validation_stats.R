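## Validation-stage statistics: clone fractions, chromatogram peak ratios,
## one-tailed unpaired t-tests, 2^-ddCt fold changes and EAE clinical-course
## summaries.

#' Editing frequency from cDNA clone counts
#'
#' Fraction of sequenced cDNA clones displaying the edited base. Vectorized
#' over replicates.
#'
#' @param edited clones carrying the edited base (>= 0).
#' @param total clones tested (>= 1).
#' @return numeric frequencies in \[0, 1\].
#' @examples
#' clone_editing_frequency(c(4, 1), c(20, 20))
#' @export
clone_editing_frequency <- function(edited, total) {
  check_that(all(total >= 1), "total clone count must be >= 1")
  check_that(all(edited >= 0 & edited <= total),
             "edited clones must lie in [0, total]")
  edited / total
}

#' Per-position detection summary across replicates
#'
#' A predicted editing position is *verified* when at least one replicate
#' yields at least one edited clone. Returns per-position detection
#' fractions (x of y replicates) and the number of verified positions.
#'
#' @param clones data.frame with columns `position`, `replicate`, `edited`,
#'   `total` (one row per position x replicate).
#' @return list: `per_position` (data.frame position, n_detected,
#'   n_replicates, verified), `n_verified`, `n_predicted`.
#' @export
detection_summary <- function(clones) {
  check_that(all(c("position", "replicate", "edited", "total") %in%
                   names(clones)),
             "clones table needs position, replicate, edited, total columns")
  check_that(all(clones$edited >= 0 & clones$edited <= clones$total),
             "edited clones must lie in [0, total]")
  sp <- split(clones, clones$position)
  per <- data.frame(
    position = names(sp),
    n_detected = vapply(sp, function(d) sum(d$edited >= 1), 0L),
    n_replicates = vapply(sp, nrow, 0L),
    stringsAsFactors = FALSE)
  per$verified <- per$n_detected >= 1L
  rownames(per) <- NULL
  list(per_position = per,
       n_verified = sum(per$verified),
       n_predicted = nrow(per))
}

#' Editing frequency from chromatogram peak heights
#'
#' For an A-to-I site read as A/G, the edited fraction is the G peak height
#' relative to the summed A + G heights. Vectorized.
#'
#' @param a_peak,g_peak non-negative peak heights; `a_peak + g_peak > 0`.
#' @return numeric frequencies in \[0, 1\].
#' @examples
#' peak_editing_frequency(70, 30)
#' @export
peak_editing_frequency <- function(a_peak, g_peak) {
  check_that(all(a_peak >= 0 & g_peak >= 0), "peak heights must be >= 0")
  check_that(all(a_peak + g_peak > 0),
             "at least one of the two peaks must be non-zero")
  g_peak / (a_peak + g_peak)
}

#' One-tailed unpaired t-test
#'
#' Student's unpaired t-test (pooled variance by default, the historical
#' "unpaired t-test" convention; set `var_equal = FALSE` for Welch) with a
#' one-tailed p-value. `alternative = "greater"` tests mean(case) >
#' mean(baseline).
#'
#' Degenerate inputs: zero pooled variance with equal means gives p = 0.5;
#' zero variance with unequal means gives p of 0 or 1 by direction, with
#' `degenerate = TRUE`.
#'
#' @param case,baseline numeric vectors, each of length >= 2.
#' @param alternative `"greater"` (default) or `"less"`, direction of the
#'   case mean relative to the baseline mean.
#' @param var_equal pooled-variance Student's test when `TRUE`.
#' @return list: t, df, p, degenerate.
#' @examples
#' one_tailed_unpaired_t(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3))
#' @export
one_tailed_unpaired_t <- function(case, baseline,
                                  alternative = c("greater", "less"),
                                  var_equal = TRUE) {
  alternative <- match.arg(alternative)
  check_that(length(case) >= 2 && length(baseline) >= 2,
             "each group needs at least 2 observations")
  if (stats::sd(case) == 0 && stats::sd(baseline) == 0) {
    d <- mean(case) - mean(baseline)
    df <- length(case) + length(baseline) - 2
    if (d == 0) return(list(t = 0, df = df, p = 0.5, degenerate = FALSE))
    p <- if ((d > 0) == (alternative == "greater")) 0 else 1
    return(list(t = sign(d) * Inf, df = df, p = p, degenerate = TRUE))
  }
  tt <- stats::t.test(case, baseline, alternative = alternative,
                      var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' Per sample, dCt = Ct_target - Ct_reference (reference gene, e.g. Gapdh);
#' ddCt = mean dCt(case) - mean dCt(baseline); fold change = 2^-ddCt.
#' Samples lacking a reference Ct are dropped with a warning.
#'
#' @param case,baseline data.frames with columns `ct_target` and
#'   `ct_reference` (one row per sample).
#' @return list: fold_change, ddct, dct_case, dct_baseline, n_case,
#'   n_baseline.
#' @examples
#' ddct_fold_change(data.frame(ct_target = 22, ct_reference = 20),
#'                  data.frame(ct_target = 24, ct_reference = 20))
#' @export
ddct_fold_change <- function(case, baseline) {
  prep <- function(df, label) {
    check_that(all(c("ct_target", "ct_reference") %in% names(df)),
               "qPCR tables need ct_target and ct_reference columns")
    drop <- is.na(df$ct_reference) | is.na(df$ct_target)
    if (any(drop)) {
      warning(sum(drop), " ", label,
              " sample(s) dropped: missing Ct value", call. = FALSE)
      df <- df[!drop, , drop = FALSE]
    }
    check_that(nrow(df) >= 1, paste0("no usable ", label, " samples"))
    check_that(all(df$ct_target > 0 & df$ct_reference > 0),
               "Ct values must be positive")
    df$ct_target - df$ct_reference
  }
  dct_case <- prep(case, "case")
  dct_base <- prep(baseline, "baseline")
  ddct <- mean(dct_case) - mean(dct_base)
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct_case = mean(dct_case), dct_baseline = mean(dct_base),
       n_case = length(dct_case), n_baseline = length(dct_base))
}

## trapezoidal integral of y over x
trapezoid_auc <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Clinical-course statistics for scored animal groups
#'
#' From per-animal daily clinical scores (0-5 ordinal scale), computes per
#' animal the maximal score (MS), the trapezoidal area under the
#' score-versus-day curve (AUC) over the observed window, and the day of
#' disease onset (DO: first day with score >= `onset_score`; animals never
#' reaching onset are excluded from the DO mean, with the exclusion count
#' reported). Group summaries are mean +/- SE; with exactly two groups each
#' statistic is compared by an unpaired two-tailed t-test (Student's pooled
#' variance by default).
#'
#' @param scores data.frame with columns `animal`, `group`, `day`, `score`;
#'   days per animal strictly increasing, each animal scored on >= 2 days.
#' @param onset_score onset threshold (default 1, "limp tail").
#' @param half_points allow half-point scores when `TRUE`; otherwise scores
#'   must lie in {0, 1, 2, 3, 4, 5}.
#' @param var_equal passed to the group t-tests.
#' @return list of class `clinical_stats`: `per_animal` (animal, group, ms,
#'   auc, onset_day), `groups` (group, n, mms, mms_se, mauc, mauc_se, ddo,
#'   ddo_se, n_onset, n_no_onset), and `tests` (statistic, t, df, p) when
#'   exactly two groups are present.
#' @examples
#' sc <- data.frame(animal = rep(c("m1", "m2"), each = 3),
#'                  group = "wt", day = rep(10:12, 2),
#'                  score = c(0, 1, 2, 0, 0, 1))
#' clinical_course_stats(sc)
#' @export
clinical_course_stats <- function(scores, onset_score = 1,
                                  half_points = FALSE, var_equal = TRUE) {
  check_that(all(c("animal", "group", "day", "score") %in% names(scores)),
             "scores table needs animal, group, day, score columns")
  allowed <- if (half_points) seq(0, 5, by = 0.5) else 0:5
  check_that(all(scores$score %in% allowed),
             "scores must lie on the 0-5 clinical scale")
  sp <- split(scores, scores$animal)
  per <- do.call(rbind, lapply(sp, function(d) {
    d <- d[order(d$day), , drop = FALSE]
    check_that(nrow(d) >= 2, paste0("animal ", d$animal[1],
                                    " has fewer than 2 scored days"))
    check_that(all(diff(d$day) > 0),
               paste0("duplicated days for animal ", d$animal[1]))
    onset <- d$day[d$score >= onset_score][1]
    data.frame(animal = d$animal[1], group = d$group[1],
               ms = max(d$score),
               auc = trapezoid_auc(d$day, d$score),
               onset_day = if (is.na(onset)) NA_real_ else onset,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL

  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  gs <- split(per, per$group)
  groups <- do.call(rbind, lapply(gs, function(d) {
    on <- d$onset_day[!is.na(d$onset_day)]
    data.frame(group = d$group[1], n = nrow(d),
               mms = mean(d$ms), mms_se = se(d$ms),
               mauc = mean(d$auc), mauc_se = se(d$auc),
               ddo = if (length(on)) mean(on) else NA_real_,
               ddo_se = se(on),
               n_onset = length(on), n_no_onset = sum(is.na(d$onset_day)),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL

  tests <- NULL
  if (length(gs) == 2) {
    cmp <- function(stat, values) {
      a <- values[[1]]; b <- values[[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(data.frame(statistic = stat, t = NA_real_, df = NA_real_,
                          p = NA_real_))
      }
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        p <- if (mean(a) == mean(b)) 1 else 0
        return(data.frame(statistic = stat, t = if (p == 1) 0 else Inf,
                          df = length(a) + length(b) - 2, p = p))
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      data.frame(statistic = stat, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
    tests <- rbind(
      cmp("mMS", lapply(gs, function(d) d$ms)),
      cmp("mAUC", lapply(gs, function(d) d$auc)),
      cmp("dDO", lapply(gs, function(d) d$onset_day[!is.na(d$onset_day)])))
    rownames(tests) <- NULL
  }
  structure(list(per_animal = per, groups = groups, tests = tests,
                 onset_score = onset_score),
            class = "clinical_stats")
}

#' @export
print.clinical_stats <- function(x, ...) {
  cat("Clinical-course statistics (onset at score >=", x$onset_score, ")\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s (n=%d): mMS %.2f +/- %.2f, mAUC %.2f +/- %.2f, dDO %s\n",
                g$group, g$n, g$mms, g$mms_se, g$mauc, g$mauc_se,
                if (is.na(g$ddo)) "not reached"
                else sprintf("%.2f +/- %.2f (%d/%d with onset)", g$ddo,
                             g$ddo_se, g$n_onset, g$n)))
  }
  if (!is.null(x$tests)) {
    for (i in seq_len(nrow(x$tests))) {
      tst <- x$tests[i, ]
      cat(sprintf("  %s: t = %.3f, df = %.1f, p = %.4f (two-tailed)\n",
                  tst$statistic, tst$t, tst$df, tst$p))
    }
  }
  invisible(x)
}
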
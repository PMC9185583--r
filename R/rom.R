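# Range-of-motion analysis of joint-angle traces: percentiles, the
# percentile range P95 - P5, and the paired between-condition comparison.

#' Percentiles of a joint-angle trace
#'
#' The five summary percentiles (P5, P25, P50, P75, P95), linear
#' interpolation convention.
#'
#' @param x Numeric trace (degrees); at least 20 samples.
#' @return Named vector `P5`, `P25`, `P50`, `P75`, `P95`.
#' @export
rom_percentiles <- function(x) {
  if (length(x) < 20) abort_input("trace too short for stable percentiles")
  setNames(quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                    type = 7),
           c("P5", "P25", "P50", "P75", "P95"))
}

#' Percentile range of motion
#'
#' @param p5,p95 Extreme percentiles (degrees).
#' @return `p95 - p5` (degrees).
#' @export
prom <- function(p5, p95) p95 - p5

#' Compare one RoM statistic between conditions
#'
#' Paired two-sided t-test on per-subject values (subjects matched by
#' position), plus the percent change of the condition means (negative =
#' reduction with the exoskeleton). When every paired difference is equal
#' the test is degenerate and flagged instead of returning a p-value.
#'
#' @param values_exo,values_noexo Per-subject statistic under each condition.
#' @param paired Paired (default) or two-sample comparison.
#' @param conf_level Confidence level for the percent-change half-width.
#' @return One-row data frame: `percent`, `ci_halfwidth`, `p`, `t`, `df`,
#'   `degenerate`.
#' @export
compare_conditions <- function(values_exo, values_noexo, paired = TRUE,
                               conf_level = 0.95) {
  if (paired && length(values_exo) != length(values_noexo)) {
    abort_input("paired comparison needs equal-length condition vectors")
  }
  m_ex <- mean(values_exo)
  m_no <- mean(values_noexo)
  pc <- as.numeric(percent_change(m_ex, m_no))
  d <- if (paired) values_exo - values_noexo
  degenerate <- if (paired) isTRUE(all.equal(var(d), 0)) || length(d) < 2 else
    (var(values_exo) == 0 && var(values_noexo) == 0)
  if (degenerate) {
    return(data.frame(percent = pc, ci_halfwidth = NA_real_, p = NA_real_,
                      t = NA_real_, df = NA_real_, degenerate = TRUE))
  }
  tt <- if (paired) t.test(values_exo, values_noexo, paired = TRUE) else
    t.test(values_exo, values_noexo)
  half <- if (paired && is.finite(m_no) && m_no != 0) {
    qt(1 - (1 - conf_level) / 2, df = tt$parameter) *
      sd(d) / sqrt(length(d)) / abs(m_no) * 100
  } else {
    NA_real_
  }
  data.frame(percent = pc, ci_halfwidth = half, p = tt$p.value,
             t = unname(tt$statistic), df = unname(tt$parameter),
             degenerate = FALSE)
}

#' Range-of-motion summary of a study
#'
#' Per coordinate: the five percentiles and PRoM of each exercise trace,
#' averaged over exercises (all box weights pooled) within subject and
#' condition, then compared between conditions with a paired t-test for the
#' two reported statistics (PRoM and P5).
#'
#' @param recordings List of `motion_recording` objects (with subject and
#'   condition metadata).
#' @param statistics Which statistics to compare between conditions.
#' @param paired Passed to [compare_conditions()].
#' @return List with `percentiles` (per subject x condition x coordinate)
#'   and `comparison` (per coordinate x statistic: percent change, CI
#'   half-width, p).
#' @export
rom_summary <- function(recordings, statistics = c("PRoM", "P5"),
                        paired = TRUE) {
  per <- list()
  for (rec in recordings) {
    if (!inherits(rec, "motion_recording")) {
      abort_input("`recordings` must be motion_recording objects")
    }
    for (coord in rec$coordinates) {
      p <- rom_percentiles(rec$angles[, coord])
      per[[length(per) + 1L]] <- data.frame(
        subject = rec$meta$subject, condition = rec$meta$condition,
        weight_kg = rec$meta$weight_kg %||% NA, coordinate = coord,
        t(p), PRoM = prom(p[["P5"]], p[["P95"]]))
    }
  }
  per <- do.call(rbind, per)

  # average over exercises (weights) within subject x condition
  agg <- stats::aggregate(
    per[, c("P5", "P25", "P50", "P75", "P95", "PRoM")],
    by = per[, c("subject", "condition", "coordinate")], FUN = mean)

  comp <- list()
  for (coord in unique(agg$coordinate)) {
    for (st in statistics) {
      a <- agg[agg$coordinate == coord, ]
      ex <- a[a$condition == "exo", ]
      no <- a[a$condition == "noexo", ]
      common <- intersect(ex$subject, no$subject)
      if (length(common) < 2) next
      res <- compare_conditions(
        ex[[st]][match(common, ex$subject)],
        no[[st]][match(common, no$subject)], paired = paired)
      comp[[paste(coord, st)]] <- cbind(coordinate = coord, statistic = st,
                                        res, n_subjects = length(common))
    }
  }
  list(percentiles = agg,
       comparison = if (length(comp)) {
         do.call(rbind, c(comp, make.row.names = FALSE))
       })
}
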
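#' Statistical parameters for power / sample-size calculations
#'
#' @param alpha two-sided significance level (0 < alpha < 1).
#' @param power target power, 1 - beta (0 < power < 1).
#' @param sd common standard deviation of the normalized G/R ratio.
#' @param fold detectable fold difference between group means (> 1).
#' @param baseline_mean mean normalized ratio of the reference group; with
#'   control normalization this is 1 by construction.
#' @return a validated list of class `stat_params`.
#' @export
stat_params <- function(alpha = 0.05, power = 0.8, sd = 0.5, fold = 1.5,
                        baseline_mean = 1.0) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, sd > 0,
            baseline_mean > 0)
  if (fold <= 1) stop("fold must exceed 1")
  structure(list(alpha = alpha, power = power, sd = sd, fold = fold,
                 baseline_mean = baseline_mean), class = "stat_params")
}

#' Normalize ratios to the negative-control mean
#'
#' Raw G/R ratios are divided by the mean G/R of the negative controls
#' (cells processed without lambda-exonuclease, which retain the maximal
#' sensor signal), putting all specimens on a common scale on which the
#' control mean is exactly 1.
#'
#' @param ratios numeric vector of raw ratios.
#' @param control_ratios nonempty numeric vector of control ratios with
#'   positive mean.
#' @return `ratios / mean(control_ratios)`.
#' @export
normalize_to_control <- function(ratios, control_ratios) {
  control_ratios <- control_ratios[is.finite(control_ratios)]
  if (length(control_ratios) == 0L)
    stop("no finite control ratios to normalize by")
  m <- mean(control_ratios)
  if (m <= 0) stop("control mean must be positive, got ", signif(m, 4))
  ratios / m
}

#' Coefficient of variation
#'
#' CV = SD/mean, with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return unitless CV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  sd(values) / m
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Thin wrapper that returns the U statistic and p value. Small samples
#' (n_x + n_y <= 12) without ties use the exact null distribution;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y nonempty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `U` (the Mann-Whitney statistic for `x`) and
#'   `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Minimum sample size per group for a two-sample comparison
#'
#' Normal-approximation formula for two groups with common standard
#' deviation `sd` and mean difference `delta = baseline_mean * (fold - 1)`:
#' `n = ceil( 2 * (z_{1-alpha/2} + z_{power})^2 * sd^2 / delta^2 )`.
#'
#' @param p a [stat_params()] object.
#' @return integer n per group.
#' @examples
#' sample_size_two_groups(stat_params(fold = 1.5, sd = 0.5)) # 16
#' @export
sample_size_two_groups <- function(p = stat_params()) {
  stopifnot(inherits(p, "stat_params"))
  delta <- p$baseline_mean * (p$fold - 1)
  z <- qnorm(1 - p$alpha / 2) + qnorm(p$power)
  as.integer(ceiling(2 * z^2 * p$sd^2 / delta^2))
}

#' Calibrate the dynamic range from a labeled-fraction mixing series
#'
#' In the calibration experiment the labeled sensor oligo is mixed with
#' unlabeled oligo at known fractions (no exonuclease), so the fraction-0
#' condition defines the floor and the fraction-1 condition the ceiling of
#' the attainable G/R. Any measured G/R can then be expressed as a percent
#' of the maximum:
#' `percent_of_max(x) = 100 * (mean_GR(x) - floor) / (ceiling - floor)`.
#' The per-condition CV estimates technical noise, and a least-squares
#' line of mean G/R against fraction summarizes linearity.
#'
#' @param condition_ratios named list mapping fraction (as numeric-valued
#'   names, e.g. `"0"`, `"0.33"`) to a numeric vector of G/R values
#'   (typically per-cell means). Must include fractions 0 and 1.
#' @return object of class `calibration_result`: list with `conditions`
#'   (data frame: `fraction`, `n`, `mean_GR`, `cv`, `percent_of_max`),
#'   `floor_GR`, `ceiling_GR`, `fit` (`slope`, `intercept`, `r_squared`).
#' @export
calibrate_dynamic_range <- function(condition_ratios) {
  stopifnot(is.list(condition_ratios), length(condition_ratios) >= 2L,
            !is.null(names(condition_ratios)))
  fr <- as.numeric(names(condition_ratios))
  if (any(is.na(fr))) stop("condition names must be numeric fractions")
  if (!any(abs(fr) < 1e-9) || !any(abs(fr - 1) < 1e-9))
    stop("calibration requires both a 0 and a 1 fraction condition")
  means <- vapply(condition_ratios, function(v) mean(v, na.rm = TRUE),
                  numeric(1))
  cvs <- vapply(condition_ratios, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2 && mean(v) != 0) coefficient_of_variation(v)
    else NA_real_
  }, numeric(1))
  floor_GR <- means[which.min(abs(fr))]
  ceiling_GR <- means[which.min(abs(fr - 1))]
  if (ceiling_GR <= floor_GR)
    stop("degenerate calibration: ceiling G/R <= floor G/R")
  pom <- 100 * (means - floor_GR) / (ceiling_GR - floor_GR)
  fit <- lm(means ~ fr)
  sst <- sum((means - mean(means))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(
    conditions = data.frame(fraction = fr,
                            n = lengths(condition_ratios),
                            mean_GR = unname(means), cv = unname(cvs),
                            percent_of_max = unname(pom)),
    floor_GR = unname(floor_GR), ceiling_GR = unname(ceiling_GR),
    fit = list(slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = r2)),
    class = "calibration_result")
}

#' Express a G/R value as percent of the calibrated maximum
#'
#' @param cal a [calibrate_dynamic_range()] result.
#' @param gr G/R value(s) on the same scale as the calibration.
#' @return percent of the dynamic range (0 at the floor, 100 at the
#'   ceiling).
#' @export
percent_of_max <- function(cal, gr) {
  stopifnot(inherits(cal, "calibration_result"))
  100 * (gr - cal$floor_GR) / (cal$ceiling_GR - cal$floor_GR)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Dynamic-range calibration\n")
  print(x$conditions, row.names = FALSE)
  cat(sprintf("fit: slope %.4f, intercept %.4f, R^2 %.4f\n",
              x$fit$slope, x$fit$intercept, x$fit$r_squared))
  invisible(x)
}

#' Classify two-locus cells by sensor positivity
#'
#' Each of a cell's two loci is "green-positive" when its normalized G/R
#' exceeds `positivity_threshold`; cells fall into di+/+ (both positive),
#' mono+/- (one) or di-/- (neither).
#'
#' @param cells data frame with columns `ratio1` and `ratio2` (normalized
#'   G/R of the two loci), e.g. from [aggregate_cells()] in allelic mode.
#' @param positivity_threshold normalized G/R above which a locus counts
#'   as positive. See [positivity_threshold_from_controls()] for the
#'   default rule.
#' @return list with `class` (per-cell factor) and `fractions` (named
#'   numeric, sums to 1).
#' @export
classify_cells <- function(cells, positivity_threshold) {
  stopifnot(is.data.frame(cells),
            all(c("ratio1", "ratio2") %in% names(cells)))
  if (nrow(cells) == 0L) stop("no cells to classify")
  npos <- (cells$ratio1 > positivity_threshold) +
          (cells$ratio2 > positivity_threshold)
  cls <- factor(c("di-/-", "mono+/-", "di+/+")[npos + 1L],
                levels = c("di+/+", "mono+/-", "di-/-"))
  fr <- as.numeric(table(cls)) / nrow(cells)
  names(fr) <- levels(cls)
  list(class = cls, fractions = fr)
}

#' Positivity threshold from negative-control ratios
#'
#' Default rule: mean + 3 SD of the normalized negative-control (signal
#' floor) ratios.
#'
#' @param control_norm_ratios normalized ratios of the floor control.
#' @return numeric threshold.
#' @export
positivity_threshold_from_controls <- function(control_norm_ratios) {
  v <- control_norm_ratios[is.finite(control_norm_ratios)]
  if (length(v) < 2L) stop("need >= 2 control ratios")
  mean(v) + 3 * sd(v)
}

#' Per-cell allelic fold ratios (RNA- vs RNA+)
#'
#' For each two-locus cell with exactly one RNA-positive locus, the
#' allelic ratio is `G/R(RNA-) / G/R(RNA+)`. The summary reports the
#' median and mean ratio and a rank-sum test of the RNA- against the RNA+
#' ratio sets. Cells without a usable RNA+ ratio (zero or invalid) are
#' skipped and counted.
#'
#' @param cells data frame with columns `ratio1`, `ratio2`,
#'   `rna_positive1`, `rna_positive2` ([aggregate_cells()] allelic mode).
#' @param alternative alternative hypothesis for the rank-sum test
#'   (default two-sided).
#' @return list with `per_cell` (data frame: `nucleus_id`, `ratio_rna_neg`,
#'   `ratio_rna_pos`, `allelic_ratio`), `median_ratio`, `mean_ratio`,
#'   `test` (from [wilcoxon_rank_sum()]) and `n_skipped`.
#' @export
allelic_fold_ratio <- function(cells, alternative = "two.sided") {
  stopifnot(is.data.frame(cells),
            all(c("ratio1", "ratio2", "rna_positive1", "rna_positive2")
                %in% names(cells)))
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    tagged <- c(r$rna_positive1, r$rna_positive2)
    if (is.na(tagged[1]) || is.na(tagged[2]) || sum(tagged) != 1L) {
      skipped <- skipped + 1L; next
    }
    pos <- if (tagged[1]) r$ratio1 else r$ratio2
    neg <- if (tagged[1]) r$ratio2 else r$ratio1
    if (!is.finite(pos) || pos <= 0 || !is.finite(neg)) {
      skipped <- skipped + 1L; next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      nucleus_id = r$nucleus_id, ratio_rna_neg = neg,
      ratio_rna_pos = pos, allelic_ratio = neg / pos)
  }
  if (length(rows) == 0L)
    stop("no cells with a single tagged RNA+ locus and valid ratios")
  per_cell <- do.call(rbind, rows)
  test <- wilcoxon_rank_sum(per_cell$ratio_rna_neg,
                            per_cell$ratio_rna_pos,
                            alternative = alternative)
  list(per_cell = per_cell,
       median_ratio = median(per_cell$allelic_ratio),
       mean_ratio = mean(per_cell$allelic_ratio),
       test = test, n_skipped = skipped)
}
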
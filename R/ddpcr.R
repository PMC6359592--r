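# Droplet digital PCR: Poisson-corrected concentrations and normalised
# expression ratios.

#' Poisson-corrected concentration from droplet counts
#'
#' In digital PCR the mean number of template copies per droplet is
#' `lambda = -ln(1 - p)` with `p` the fraction of positive droplets;
#' concentration is `lambda` divided by the droplet volume. The 95 percent
#' interval uses the delta-method standard error
#' `SE(lambda) = sqrt(p / ((1 - p) * total))` by default; a Clopper-Pearson
#' mode transforms an exact binomial interval on `p` for low-count wells.
#' Wells with fewer than 10 positive or 10 negative droplets are flagged as
#' outside the reliable Poisson regime.
#'
#' @param positives Number of positive droplets (>= 0, < `total`).
#' @param total Total accepted droplets (> 0).
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"normal"` (delta method) or `"clopper-pearson"`.
#' @return `data.frame`: `positives`, `total`, `lambda`,
#'   `conc_copies_per_ul`, `ci_low`, `ci_high` (copies/ul), `flagged`.
#' @examples
#' poisson_concentration(5000, 10000)   # lambda = ln 2, ~815.5 copies/ul
#' @export
poisson_concentration <- function(positives, total, droplet_volume_nl = 0.85,
                                  conf_level = 0.95,
                                  ci_method = c("normal", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  if (any(total <= 0)) stop("`total` droplets must be positive")
  if (any(positives < 0)) stop("`positives` must be non-negative")
  if (any(positives >= total))
    stop("saturated well (positives = total): concentration not estimable")
  if (any(droplet_volume_nl <= 0)) stop("droplet volume must be positive")
  p <- positives / total
  lambda <- -log1p(-p)
  vol_ul <- droplet_volume_nl * 1e-3
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "normal") {
    se <- sqrt(p / ((1 - p) * total))
    lo <- pmax(lambda - z * se, 0)
    hi <- lambda + z * se
  } else {
    ci <- mapply(function(x, n) {
      as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
    }, positives, total)
    lo <- -log1p(-ci[1L, ])
    hi <- -log1p(-ci[2L, ])
  }
  data.frame(
    positives = positives, total = total,
    lambda = lambda,
    conc_copies_per_ul = lambda / vol_ul,
    ci_low = lo / vol_ul, ci_high = hi / vol_ul,
    flagged = positives < 10 | (total - positives) < 10
  )
}

.mean_conc <- function(wells, sample, assay, droplet_volume_nl) {
  rows <- wells$sample == sample & wells$assay == assay
  if (!any(rows))
    stop("no ddPCR wells for sample '", sample, "', assay '", assay, "'")
  w <- wells[rows, , drop = FALSE]
  vol <- if (!is.null(w$droplet_volume_nl) &&
             all(is.finite(w$droplet_volume_nl))) w$droplet_volume_nl
         else droplet_volume_nl
  est <- poisson_concentration(w$positives, w$total, vol)
  conc <- mean(est$conc_copies_per_ul)
  if (conc <= 0)
    stop("zero concentration for sample '", sample, "', assay '", assay, "'")
  se_each <- (est$ci_high - est$ci_low) / (2 * stats::qnorm(0.975))
  list(conc = conc,
       se_log = sqrt(sum(se_each^2)) / length(se_each) / conc,
       n = nrow(w))
}

#' Reference-normalised ddPCR expression ratio
#'
#' Concentrations are averaged across duplicate wells on the concentration
#' scale; the fold change is the target/reference concentration ratio in the
#' test sample divided by the same ratio in the calibrator. The confidence
#' interval propagates the per-well Poisson errors on the log scale.
#'
#' @param wells `data.frame` with columns `sample`, `assay`, `positives`,
#'   `total`, optional `droplet_volume_nl`.
#' @param target_assay,reference_assay Assay labels.
#' @param test_sample,calibrator_sample Sample labels.
#' @param droplet_volume_nl Fallback droplet volume (cancels in the ratio).
#' @param conf_level Confidence level for the interval.
#' @return One-row `data.frame`: `sample`, `calibrator`, `fold_change`,
#'   `ci_low`, `ci_high`.
#' @export
normalized_ratio <- function(wells, target_assay, reference_assay,
                             test_sample, calibrator_sample,
                             droplet_volume_nl = 0.85, conf_level = 0.95) {
  tt <- .mean_conc(wells, test_sample, target_assay, droplet_volume_nl)
  tr <- .mean_conc(wells, test_sample, reference_assay, droplet_volume_nl)
  ct <- .mean_conc(wells, calibrator_sample, target_assay, droplet_volume_nl)
  cr <- .mean_conc(wells, calibrator_sample, reference_assay,
                   droplet_volume_nl)
  fold <- (tt$conc / tr$conc) / (ct$conc / cr$conc)
  se_log <- sqrt(tt$se_log^2 + tr$se_log^2 + ct$se_log^2 + cr$se_log^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(sample = test_sample, calibrator = calibrator_sample,
             fold_change = fold,
             ci_low = fold * exp(-z * se_log),
             ci_high = fold * exp(z * se_log),
             stringsAsFactors = FALSE)
}
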
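# Core Cq arithmetic: relative quantities, restriction-digestion efficiency
# QC, delta-delta-Ct relative expression, and significance flags.

#' Relative template quantity from a Cq value
#'
#' Maps a quantification cycle to a relative amount of starting template,
#' `(1 + E)^(-cq)`, where `E` is the amplification efficiency in `(0, 1]`
#' (1.0 = perfect doubling each cycle). Arbitrary units; only ratios of
#' quantities are meaningful.
#'
#' @param cq Quantification cycle(s), finite.
#' @param efficiency Amplification efficiency `E` in `(0, 1]`.
#' @return Numeric vector of relative quantities, monotone decreasing in `cq`.
#' @examples
#' relative_quantity(0)            # 1
#' relative_quantity(1)            # 0.5
#' relative_quantity(10, 0.9)      # 1.9^-10
#' @export
relative_quantity <- function(cq, efficiency = 1.0) {
  if (any(!is.finite(cq))) stop("`cq` must be finite")
  if (any(!is.finite(efficiency)) || any(efficiency <= 0) ||
      any(efficiency > 1))
    stop("`efficiency` must lie in (0, 1]")
  (1 + efficiency)^(-cq)
}

#' Restriction-digestion efficiency from paired qPCR assays
#'
#' Standard 3C library QC: one SYBR assay spans a restriction site (its
#' template is destroyed by digestion), a control assay does not. The
#' digested/undigested delta-delta-Cq gives the fraction of templates cut:
#' `100 - 100 / 2^ddCq` with
#' `ddCq = (cq_site_dig - cq_ctrl_dig) - (cq_site_undig - cq_ctrl_undig)`.
#'
#' Values are bounded above by 100; negative values are possible under noise
#' and should be flagged by QC, not silently clipped.
#'
#' @param cq_site_digested,cq_ctrl_digested Cq of site-spanning and control
#'   assays on the digested template.
#' @param cq_site_undigested,cq_ctrl_undigested Same on undigested template.
#' @return Digestion efficiency in percent (vectorised).
#' @examples
#' digestion_efficiency(24, 20, 21, 20)   # ddCq = 3 -> 87.5
#' @export
digestion_efficiency <- function(cq_site_digested, cq_ctrl_digested,
                                 cq_site_undigested, cq_ctrl_undigested) {
  cqs <- c(cq_site_digested, cq_ctrl_digested,
           cq_site_undigested, cq_ctrl_undigested)
  if (any(!is.finite(cqs))) stop("all four Cq values must be finite")
  ddcq <- (cq_site_digested - cq_ctrl_digested) -
    (cq_site_undigested - cq_ctrl_undigested)
  100 - 100 / 2^ddcq
}

#' Library digestion QC
#'
#' A 3C library passes when every assayed restriction site exceeds the
#' efficiency threshold (default 85 percent).
#'
#' @param efficiencies Numeric vector of per-site digestion efficiencies
#'   (percent); names, if present, label the sites in the report.
#' @param threshold_percent Pass threshold (default 85).
#' @return A list of class `digestion_qc`: `pass` (logical),
#'   `threshold_percent`, `efficiencies`, `failing_sites` (names or indices
#'   of sites at or below threshold), `anomalies` (sites with negative
#'   efficiency).
#' @export
qc_digestion <- function(efficiencies, threshold_percent = 85) {
  if (length(efficiencies) == 0L)
    stop("`efficiencies` must contain at least one site")
  if (any(!is.finite(efficiencies))) stop("efficiencies must be finite")
  labs <- names(efficiencies)
  if (is.null(labs)) labs <- as.character(seq_along(efficiencies))
  fail <- efficiencies <= threshold_percent
  structure(
    list(pass = !any(fail),
         threshold_percent = threshold_percent,
         efficiencies = stats::setNames(efficiencies, labs),
         failing_sites = labs[fail],
         anomalies = labs[efficiencies < 0]),
    class = "digestion_qc"
  )
}

#' @export
print.digestion_qc <- function(x, ...) {
  cat("digestion QC:", if (x$pass) "PASS" else "FAIL",
      sprintf("(threshold > %g%%, %d site(s))\n",
              x$threshold_percent, length(x$efficiencies)))
  if (length(x$failing_sites))
    cat("  failing sites:", paste(x$failing_sites, collapse = ", "), "\n")
  if (length(x$anomalies))
    cat("  anomalous (negative) sites:",
        paste(x$anomalies, collapse = ", "), "\n")
  invisible(x)
}

#' Significance stars for a p-value
#'
#' Three-tier scheme by default: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`. Supply two cutoffs for a two-tier figure-legend scheme.
#'
#' @param p_value p-value(s) in `[0, 1]`.
#' @param thresholds Decreasing vector of cutoffs; stars are assigned from
#'   `rep("*", k)` for the k-th smallest exceeded cutoff.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p_value, thresholds = c(0.05, 0.01, 0.001)) {
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1))
    stop("`p_value` must lie in [0, 1]")
  thresholds <- sort(thresholds, decreasing = TRUE)
  vapply(p_value, function(p) {
    k <- sum(p < thresholds)
    if (k == 0L) "ns" else strrep("*", k)
  }, character(1))
}

# Welch t-test that tolerates (exactly) constant groups, as arise on
# noiseless synthetic plates: equal means give p = 1, different means p = 0,
# and the interval collapses to the point estimate.
.welch_test <- function(x, y, conf_level = 0.95) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    delta <- mean(x) - mean(y)
    return(list(p.value = if (abs(delta) < 1e-12) 1 else 0,
                conf.int = c(delta, delta)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  list(p.value = tt$p.value, conf.int = as.numeric(tt$conf.int))
}

# mean Cq per (sample, assay) with replicate vectors, validated
.cq_replicates <- function(records, sample, assay) {
  rows <- records$sample == sample & records$assay == assay
  if (!any(rows))
    stop("no Cq records for sample '", sample, "', assay '", assay, "'")
  cq <- records$cq[rows]
  if (length(cq) < 2L)
    stop("fewer than 2 replicates for sample '", sample,
         "', assay '", assay, "'")
  cq[order(records$replicate[rows])]
}

.assay_efficiency <- function(records, assay) {
  if (is.null(records$efficiency)) return(1.0)
  e <- records$efficiency[records$assay == assay]
  e <- e[is.finite(e)]
  if (length(e) == 0L) 1.0 else mean(e)
}

#' Delta-delta-Ct relative expression
#'
#' Computes the fold change of a target transcript in a test sample relative
#' to a calibrator sample, normalised to one or more reference genes.
#' Per sample, `dCq = Cq_target - Cq_reference` replicate-wise; the fold
#' change is `2^-(dCq_test - dCq_cal)` at perfect efficiency, and the
#' efficiency-corrected ratio
#' `(1+E_t)^(dCq_t) / (1+E_r)^(dCq_r)` (with `dCq = calibrator - test` per
#' assay) otherwise. The p-value comes from a two-sided Welch t-test on the
#' per-replicate `dCq` values; the confidence interval is a t-interval on
#' the ddCq scale, back-transformed.
#'
#' With several reference genes, `reference_mode = "separate"` (default)
#' returns one result per reference, as expression figures typically show;
#' `"geometric"` averages the reference Cq values replicate-wise, i.e.
#' normalises to the geometric mean of the reference quantities.
#'
#' @param records Plate `data.frame` with columns `sample`, `assay`,
#'   `replicate`, `cq`, optional `efficiency`.
#' @param target_assay Target gene assay label.
#' @param reference_assay Character vector of reference gene assay labels.
#' @param test_sample,calibrator_sample Sample labels.
#' @param reference_mode `"separate"` or `"geometric"`.
#' @param conf_level Confidence level for the fold-change interval.
#' @param star_thresholds Passed to [significance_stars()].
#' @return `data.frame` with one row per reference gene (or a single
#'   `"geomean"` row): `sample`, `calibrator`, `target_assay`,
#'   `reference_gene`, `fold_change`, `ci_low`, `ci_high`, `p_value`,
#'   `stars`, `n_test`, `n_calibrator`.
#' @export
delta_delta_ct <- function(records, target_assay, reference_assay,
                           test_sample, calibrator_sample,
                           reference_mode = c("separate", "geometric"),
                           conf_level = 0.95,
                           star_thresholds = c(0.05, 0.01, 0.001)) {
  reference_mode <- match.arg(reference_mode)
  stopifnot(is.data.frame(records))
  refs <- if (reference_mode == "geometric") list(reference_assay)
          else as.list(reference_assay)
  out <- lapply(refs, function(ref) {
    tgt_t <- .cq_replicates(records, test_sample, target_assay)
    tgt_c <- .cq_replicates(records, calibrator_sample, target_assay)
    ref_mat_t <- vapply(ref, function(a) .cq_replicates(records, test_sample, a),
                        numeric(length(tgt_t)))
    ref_mat_c <- vapply(ref, function(a)
      .cq_replicates(records, calibrator_sample, a), numeric(length(tgt_c)))
    ref_t <- rowMeans(ref_mat_t)
    ref_c <- rowMeans(ref_mat_c)
    dcq_t <- tgt_t - ref_t
    dcq_c <- tgt_c - ref_c
    tt <- .welch_test(dcq_t, dcq_c, conf_level)
    ddcq <- mean(dcq_t) - mean(dcq_c)
    e_t <- .assay_efficiency(records, target_assay)
    e_r <- mean(vapply(ref, function(a) .assay_efficiency(records, a),
                       numeric(1)))
    # (1+E_t)^(cal - test) for target over the same for reference
    fold <- (1 + e_t)^(mean(tgt_c) - mean(tgt_t)) /
      (1 + e_r)^(mean(ref_c) - mean(ref_t))
    # t-interval on ddCq, back-transformed around the fold estimate
    half <- abs(ddcq - tt$conf.int[1L])
    ci <- sort(c(fold * 2^(-half), fold * 2^(half)))
    data.frame(
      sample = test_sample,
      calibrator = calibrator_sample,
      target_assay = target_assay,
      reference_gene = paste(ref, collapse = "+"),
      fold_change = fold,
      ci_low = ci[1L], ci_high = ci[2L],
      p_value = tt$p.value,
      stars = significance_stars(tt$p.value, star_thresholds),
      n_test = length(dcq_t), n_calibrator = length(dcq_c),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
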
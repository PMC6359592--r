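# ChIP-qPCR quantification: percent input and fold enrichment over IgG.

#' Percent input from IP and input Cq values
#'
#' The input well measures only a fraction of the chromatin, so its Cq is
#' first adjusted by `log2(1/input_fraction)` to the full-input scale;
#' percent input is then `100 * 2^(adjusted_input_cq - cq_ip)`.
#'
#' @param cq_ip Cq of the immunoprecipitated material.
#' @param cq_input Cq of the saved input aliquot.
#' @param input_fraction Fraction of chromatin saved as input, in `(0, 1]`
#'   (default 0.01, the common 1 percent-input convention).
#' @return Percent input (vectorised).
#' @examples
#' percent_input(24, 24, 1)      # 100
#' percent_input(24, 24, 0.01)   # 1
#' percent_input(27, 24, 1)      # 12.5
#' @export
percent_input <- function(cq_ip, cq_input, input_fraction = 0.01) {
  if (any(!is.finite(input_fraction)) || any(input_fraction <= 0) ||
      any(input_fraction > 1))
    stop("`input_fraction` must lie in (0, 1]")
  adj <- cq_input - log2(1 / input_fraction)
  100 * 2^(adj - cq_ip)
}

#' Fold enrichment of an antibody over IgG
#'
#' Combines per-experiment percent-input values: the fold is the ratio of
#' geometric means (equivalently the geometric mean of per-experiment
#' folds when experiments are paired), and the p-value comes from a
#' two-sided Welch t-test on log2 percent input, antibody vs IgG, across
#' experiments. Ratios of percent inputs are approximately log-normal, so
#' both the combination and the test live on the log scale.
#'
#' @param percent_ab Percent-input values for the specific antibody, one per
#'   experiment.
#' @param percent_igg Percent-input values for the IgG control, same
#'   experiments.
#' @param star_thresholds Significance cutoffs for [significance_stars()];
#'   use `c(0.05, 0.001)` for a two-tier figure-legend scheme.
#' @return A list: `fold_over_igg`, `percent_input_ab`, `percent_input_igg`
#'   (geometric means), `p_value`, `stars`, `n_experiments`.
#' @export
fold_over_igg <- function(percent_ab, percent_igg,
                          star_thresholds = c(0.05, 0.01, 0.001)) {
  if (any(!is.finite(percent_igg)) || any(percent_igg <= 0))
    stop("IgG percent input must be positive (degenerate control)")
  if (any(!is.finite(percent_ab)) || any(percent_ab <= 0))
    stop("antibody percent input must be positive")
  gm_ab <- exp(mean(log(percent_ab)))
  gm_igg <- exp(mean(log(percent_igg)))
  p <- if (length(percent_ab) >= 2L && length(percent_igg) >= 2L)
    .welch_test(log2(percent_ab), log2(percent_igg))$p.value
  else NA_real_
  list(fold_over_igg = gm_ab / gm_igg,
       percent_input_ab = gm_ab,
       percent_input_igg = gm_igg,
       p_value = p,
       stars = if (is.na(p)) NA_character_
               else significance_stars(p, star_thresholds),
       n_experiments = length(percent_ab))
}

#' ChIP enrichment table from a well-level plate
#'
#' For every (cell line, region) computes per-experiment percent input for
#' the specific antibody and the IgG control against that experiment's input
#' well, then combines experiments with [fold_over_igg()]. Both
#' normalisations are reported side by side: percent of input and fold over
#' IgG.
#'
#' @param wells `data.frame` with columns `cell_line`, `region`, `antibody`
#'   (the specific antibody label, `"IgG"`, or `"input"`), `experiment`,
#'   `cq`, and `input_fraction` (recorded on input wells; others may be NA).
#' @param antibody Specific antibody label (default `"H3K27ac"`).
#' @param star_thresholds Passed to [fold_over_igg()].
#' @return `data.frame` with one row per (cell_line, region):
#'   `percent_input_ab`, `percent_input_igg`, `fold_over_igg`, `p_value`,
#'   `stars`, `n_experiments`.
#' @export
chip_enrichment <- function(wells, antibody = "H3K27ac",
                            star_thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(is.data.frame(wells),
            all(c("cell_line", "region", "antibody", "experiment", "cq")
                %in% names(wells)))
  groups <- unique(wells[, c("cell_line", "region")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- wells[wells$cell_line == groups$cell_line[i] &
                 wells$region == groups$region[i], , drop = FALSE]
    exps <- sort(unique(g$experiment))
    pct <- vapply(exps, function(e) {
      ge <- g[g$experiment == e, , drop = FALSE]
      inp <- ge[ge$antibody == "input", , drop = FALSE]
      if (nrow(inp) != 1L)
        stop("expected exactly one input well for cell line '",
             groups$cell_line[i], "', region '", groups$region[i],
             "', experiment ", e)
      frac <- inp$input_fraction
      if (is.null(frac) || !is.finite(frac)) frac <- 0.01
      c(ab = percent_input(mean(ge$cq[ge$antibody == antibody]),
                           inp$cq, frac),
        igg = percent_input(mean(ge$cq[ge$antibody == "IgG"]),
                            inp$cq, frac))
    }, numeric(2))
    res <- fold_over_igg(pct["ab", ], pct["igg", ], star_thresholds)
    data.frame(cell_line = groups$cell_line[i], region = groups$region[i],
               percent_input_ab = res$percent_input_ab,
               percent_input_igg = res$percent_input_igg,
               fold_over_igg = res$fold_over_igg,
               p_value = res$p_value, stars = res$stars,
               n_experiments = res$n_experiments,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
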
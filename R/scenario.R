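# Scenario: a complete, seeded parameterisation of the synthetic-data
# generator. The defaults encode the study conditions the pipeline is
# designed around: a ~200-kb HindIII locus assayed at seven TSS-relative
# anchors, a power-law contact decay, loops injected multiplicatively over
# the decay, and the expression / ChIP / ddPCR effect sizes of the
# corresponding cell-line presets.

# Decay exponent: the reported profiles put the loop fragments ~9x and ~6x
# over the background while only ~3x over the -6.8 kb proximal fragment;
# those coexist only for b = log(3)/log(63.2/6.8) ~ 0.5. The amplitude `a`
# is set so the proximal fragment sits at rel ~ 1.
.default_decay <- c(a = 6.8^0.5, b = 0.5)

.default_anchors_kb <- c(-79.7, -63.2, -30.7, -6.8, 48.4, 71.3, 119.3)

#' Construct a synthetic-data scenario
#'
#' A scenario fully determines every synthetic input: locus geometry, the
#' distance-decay background and injected loops, Cq noise, replicate
#' structure, and the true effect sizes for the expression, ChIP and ddPCR
#' generators. The seed fixes all randomness; identical scenarios produce
#' identical outputs.
#'
#' @param name Scenario label.
#' @param seed Integer RNG seed.
#' @param locus_length_bp,tss,gene_strand,motif Locus geometry. The default
#'   201-kb span with the TSS at 80,500 leaves room for anchor fragments
#'   from -79.7 kb to +119.3 kb.
#' @param anchors_kb TSS-relative anchor positions (kb) assayed by 3C.
#' @param decay Named vector `c(a=, b=)`: background `rel = a * |d_kb|^-b`.
#' @param loops `data.frame(anchor_kb, fold)`: loops injected
#'   multiplicatively over the decay at existing anchors.
#' @param cq_noise_sd_3c,cq_noise_sd_expression,cq_noise_sd_chip Additive
#'   Gaussian Cq noise (cycles).
#' @param replicates qPCR replicates per well group.
#' @param expression Named list: sample -> named vector of true fold changes
#'   vs the fibroblast calibrator, one entry per reference gene.
#' @param chip `data.frame(cell_line, region, fold, baseline_pct)`: true
#'   H3K27ac fold over IgG and the IgG percent-input baseline.
#' @param chip_experiments Independent ChIP experiments simulated.
#' @param input_fraction Fraction of chromatin saved as ChIP input.
#' @param ddpcr List: `samples` (named true ratios vs calibrator), `wells`
#'   (duplicates), `total` droplets/well, `lambda_target_cal`, `lambda_ref`,
#'   `sampling` (`"binomial"` or `"expected"`).
#' @param digestion_efficiency True per-site digestion efficiency (fraction).
#' @return An object of class `scenario`.
#' @seealso [preset_scenario()] for the bundled presets.
#' @export
scenario <- function(name = "custom", seed = 1L,
                     locus_length_bp = 201000L, tss = 80500L,
                     gene_strand = "+", motif = "AAGCTT",
                     anchors_kb = .default_anchors_kb,
                     decay = .default_decay,
                     loops = data.frame(anchor_kb = numeric(0),
                                        fold = numeric(0)),
                     cq_noise_sd_3c = 0.15,
                     cq_noise_sd_expression = 0.12,
                     cq_noise_sd_chip = 0.15,
                     replicates = 3L,
                     expression = list(),
                     chip = NULL,
                     chip_experiments = 2L,
                     input_fraction = 0.01,
                     ddpcr = list(samples = numeric(0), wells = 2L,
                                  total = 15000L, lambda_target_cal = 0.15,
                                  lambda_ref = 0.8, sampling = "binomial"),
                     digestion_efficiency = 0.92) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (nrow(loops) > 0 && !all(loops$anchor_kb %in% anchors_kb))
    stop("loops must reference existing anchors")
  if (nrow(loops) > 0 && any(loops$fold <= 0))
    stop("loop folds must be positive")
  if (!gene_strand %in% c("+", "-")) stop("gene_strand must be '+' or '-'")
  structure(
    list(name = name, seed = as.integer(seed),
         locus_length_bp = as.integer(locus_length_bp),
         tss = as.integer(tss), gene_strand = gene_strand, motif = motif,
         anchors_kb = anchors_kb, decay = decay, loops = loops,
         cq_noise_sd_3c = cq_noise_sd_3c,
         cq_noise_sd_expression = cq_noise_sd_expression,
         cq_noise_sd_chip = cq_noise_sd_chip,
         replicates = as.integer(replicates),
         expression = expression, chip = chip,
         chip_experiments = as.integer(chip_experiments),
         input_fraction = input_fraction,
         ddpcr = ddpcr,
         digestion_efficiency = digestion_efficiency),
    class = "scenario"
  )
}

#' Bundled scenario presets
#'
#' Four presets encode the cell-line conditions the pipeline is exercised
#' on:
#' \describe{
#'   \item{`pc3m`}{High-expressing line: loops at -63.2 kb (9x over
#'     background) and +48.4 kb (6x); expression folds 4.5 (GAPDH) / 3.0
#'     (PBGD); ChIP folds 30x (-63 kb) / 60x (+48 kb); ddPCR ratio 2.5.}
#'   \item{`pc3`}{Moderate line: one loop at -63.2 kb (9x); expression fold
#'     2.0 on both references; ChIP folds 5x / 3x; ddPCR ratio 1.4.}
#'   \item{`fibroblast`}{Non-expressing control (VH10-like): no loops, all
#'     folds 1.}
#'   \item{`null`}{Alias geometry of `fibroblast` for specificity studies:
#'     no loops, unit folds.}
#' }
#'
#' @param name One of `"pc3m"`, `"pc3"`, `"fibroblast"`, `"null"`.
#' @param seed Integer RNG seed.
#' @param ... Overrides passed on to [scenario()].
#' @return A [scenario()].
#' @export
preset_scenario <- function(name = c("pc3m", "pc3", "fibroblast", "null"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    pc3m = list(
      loops = data.frame(anchor_kb = c(-63.2, 48.4), fold = c(9, 6)),
      expression = list(PC3M = c(GAPDH = 4.5, PBGD = 3.0)),
      chip = data.frame(cell_line = "PC3M",
                        region = c("minus63kb", "plus48kb"),
                        fold = c(30, 60), baseline_pct = 0.05),
      ddpcr = list(samples = c(PC3M = 2.5), wells = 2L, total = 15000L,
                   lambda_target_cal = 0.15, lambda_ref = 0.8,
                   sampling = "binomial")
    ),
    pc3 = list(
      loops = data.frame(anchor_kb = -63.2, fold = 9),
      expression = list(PC3 = c(GAPDH = 2.0, PBGD = 2.0)),
      chip = data.frame(cell_line = "PC3",
                        region = c("minus63kb", "plus48kb"),
                        fold = c(5, 3), baseline_pct = 0.05),
      ddpcr = list(samples = c(PC3 = 1.4), wells = 2L, total = 15000L,
                   lambda_target_cal = 0.15, lambda_ref = 0.8,
                   sampling = "binomial")
    ),
    fibroblast = list(
      expression = list(VH10 = c(GAPDH = 1.0, PBGD = 1.0)),
      chip = data.frame(cell_line = "VH10",
                        region = c("minus63kb", "plus48kb"),
                        fold = c(1, 1), baseline_pct = 0.05),
      ddpcr = list(samples = c(VH10 = 1.0), wells = 2L, total = 15000L,
                   lambda_target_cal = 0.15, lambda_ref = 0.8,
                   sampling = "binomial")
    ),
    null = list()
  )
  do.call(scenario, c(list(name = name, seed = seed), args,
                      list(...)))
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario '", x$name, "' (seed ", x$seed, ")\n", sep = "")
  cat("  locus: ", x$locus_length_bp, " bp, TSS at ", x$tss,
      ", strand ", x$gene_strand, ", ", length(x$anchors_kb),
      " anchors\n", sep = "")
  cat(sprintf("  decay: rel = %.3g * |d|^-%.3g; %d loop(s)\n",
              x$decay[["a"]], x$decay[["b"]], nrow(x$loops)))
  invisible(x)
}

# Planted cut positions (0-based motif starts) implied by the scenario
# geometry: an anchor fragment [pos-600, pos+600) around every anchor, a
# bait fragment around the TSS, and filler sites between anchors so the map
# resembles a real HindIII digest rather than an anchor-only tiling.
scenario_cut_positions <- function(sc) {
  sign <- if (sc$gene_strand == "+") 1 else -1
  anchor_pos <- sc$tss + sign * sc$anchors_kb * 1000
  if (any(anchor_pos - 600 < 0) || any(anchor_pos + 600 > sc$locus_length_bp))
    stop("invalid scenario: anchors fall outside the locus span")
  bait <- c(sc$tss - 500, sc$tss + 700)
  filler_frac <- c(0.025, 0.1, 0.2, 0.3, 0.35, 0.5, 0.6, 0.8, 0.9)
  filler <- round(sc$locus_length_bp * filler_frac)
  # drop fillers colliding with anchor or bait windows
  windows <- rbind(cbind(anchor_pos - 600, anchor_pos + 600),
                   matrix(bait, ncol = 2))
  clear <- vapply(filler, function(p)
    all(p < windows[, 1] - 50 | p > windows[, 2] + 50), logical(1))
  cuts <- sort(unique(c(anchor_pos - 600, anchor_pos + 600, bait,
                        filler[clear])))
  if (any(diff(cuts) < 2 * nchar(sc$motif)))
    stop("invalid scenario: planted sites closer than two motif lengths")
  as.integer(cuts)
}

# Fragment map implied by the scenario, built without generating sequence.
scenario_locus <- function(sc) {
  cuts <- scenario_cut_positions(sc)
  bounds <- c(0L, cuts, sc$locus_length_bp)
  fragments <- data.frame(
    fragment_id = seq_len(length(bounds) - 1L),
    chrom = "locus",
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    length = diff(bounds),
    stringsAsFactors = FALSE
  )
  locus_model(fragments = fragments, tss = sc$tss,
              gene_strand = sc$gene_strand)
}

# Anchor ground truth: anchor -> fragment id and exact TSS distance.
scenario_anchor_truth <- function(sc, locus = scenario_locus(sc)) {
  sign <- if (sc$gene_strand == "+") 1 else -1
  pos <- sc$tss + sign * sc$anchors_kb * 1000
  fid <- vapply(pos, function(p) locate_fragment(locus, p), numeric(1))
  data.frame(
    anchor_kb = sc$anchors_kb,
    position = pos,
    fragment_id = fid,
    tss_distance_kb =
      locus$fragments$tss_distance_kb[match(fid,
                                            locus$fragments$fragment_id)],
    stringsAsFactors = FALSE
  )
}
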
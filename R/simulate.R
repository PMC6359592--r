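# Seeded generators for every input the pipeline consumes: locus FASTA,
# 3C / expression / ChIP Cq plates, and ddPCR droplet counts. Ground truth
# accompanies every output so downstream estimates can be checked without
# re-running the generator.

# Each generator draws from its own seed offset so outputs are reproducible
# independently of the order in which generators are invoked.
.with_scenario_seed <- function(sc, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sc$seed + offset)
  expr
}

#' Generate the synthetic locus sequence and its ground truth
#'
#' Builds a random A/C/G/T sequence with the restriction motif planted
#' exactly at the scenario's cut positions and nowhere else (spurious
#' occurrences are rejection-edited away). Each anchor gets a 1.2-kb
#' fragment whose midpoint falls exactly on the anchor; the bait fragment
#' contains the TSS; filler sites between anchors round the map out to a
#' digest-like tiling.
#'
#' @param sc A [scenario()].
#' @return A list: `sequence` (character), `locus` (a [locus_model()] built
#'   by digesting the sequence), `cut_positions` (0-based planted motif
#'   starts), `truth` (anchor table: `anchor_kb`, `position`, `fragment_id`,
#'   `tss_distance_kb`).
#' @export
make_locus <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  cuts <- scenario_cut_positions(sc)
  motif <- toupper(sc$motif)
  mlen <- nchar(motif)
  seq_vec <- .with_scenario_seed(sc, 0L, {
    v <- sample(c("A", "C", "G", "T"), sc$locus_length_bp, replace = TRUE)
    mchars <- strsplit(motif, "")[[1L]]
    for (p in cuts) v[(p + 1):(p + mlen)] <- mchars
    planted_cover <- unlist(lapply(cuts, function(p) (p + 1):(p + mlen)))
    for (iter in 1:50) {
      s <- paste(v, collapse = "")
      starts <- BiocGenerics::start(
        Biostrings::matchPattern(motif, Biostrings::DNAString(s),
                                 fixed = TRUE)) - 1L
      spurious <- setdiff(starts, cuts)
      if (length(spurious) == 0L) break
      for (p in spurious) {
        idx <- setdiff((p + 1):(p + mlen), planted_cover)
        i <- idx[1L]
        v[i] <- if (v[i] == "A") "C" else "A"
      }
    }
    if (length(spurious) > 0L)
      stop("could not eliminate spurious motif occurrences")
    v
  })
  sequence <- paste(seq_vec, collapse = "")
  locus <- locus_model(sequence = sequence, tss = sc$tss,
                       gene_strand = sc$gene_strand, motif = motif)
  list(sequence = sequence, locus = locus, cut_positions = cuts,
       truth = scenario_anchor_truth(sc, locus))
}

# True relative ligation frequency at each anchor: power-law decay times
# the loop fold where a loop is planted.
scenario_true_rel <- function(sc) {
  rel <- sc$decay[["a"]] * abs(sc$anchors_kb)^(-sc$decay[["b"]])
  fold <- rep(1, length(sc$anchors_kb))
  if (nrow(sc$loops) > 0) {
    i <- match(sc$loops$anchor_kb, sc$anchors_kb)
    fold[i] <- sc$loops$fold
  }
  data.frame(anchor_kb = sc$anchors_kb, decay_rel = rel, loop_fold = fold,
             true_rel = rel * fold)
}

.anchor_assay <- function(kb) sprintf("junction_%+.1fkb", kb)

#' Simulate 3C TaqMan Cq plates
#'
#' Emits junction wells whose Cq encodes the scenario's true relative
#' ligation frequency (`cq = cq_norm - log2(rel) + noise`), control-locus
#' normaliser wells, and SYBR digestion-QC wells (site/control assays on
#' digested and undigested templates) per anchor site.
#'
#' @param sc A [scenario()].
#' @param locus Optional pre-built locus (from [make_locus()] or internal
#'   geometry); defaults to the scenario's fragment map.
#' @param library_id Library label.
#' @return A list: `plates` (`sample`, `assay`, `replicate`, `cq`),
#'   `anchor_map` (`assay`, `fragment_id`), `qc` (`site`, `assay`,
#'   `template`, `cq`), `truth` (anchor table with `true_rel`, `loop_fold`,
#'   `digestion_efficiency`, `normalizer_cq`).
#' @export
simulate_3c_plates <- function(sc, locus = NULL, library_id = "lib1") {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(locus)) locus <- scenario_locus(sc)
  anchors <- scenario_anchor_truth(sc, locus)
  tr <- scenario_true_rel(sc)
  sd <- sc$cq_noise_sd_3c
  reps <- sc$replicates
  norm_cq <- 25
  .with_scenario_seed(sc, 1L, {
    junc <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      data.frame(sample = library_id,
                 assay = .anchor_assay(tr$anchor_kb[i]),
                 replicate = seq_len(reps),
                 cq = norm_cq - log2(tr$true_rel[i]) +
                   stats::rnorm(reps, 0, sd),
                 stringsAsFactors = FALSE)
    }))
    norm <- data.frame(sample = library_id, assay = "ERCC3",
                       replicate = seq_len(reps),
                       cq = norm_cq + stats::rnorm(reps, 0, sd),
                       stringsAsFactors = FALSE)
    eff <- sc$digestion_efficiency
    qc <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
      site <- sprintf("site_%+.1fkb", anchors$anchor_kb[i])
      base <- 24
      data.frame(
        site = site,
        assay = c("site", "ctrl", "site", "ctrl"),
        template = c("digested", "digested", "undigested", "undigested"),
        cq = c(base + log2(1 / (1 - eff)), base, base, base) +
          stats::rnorm(4, 0, sd),
        stringsAsFactors = FALSE)
    }))
    truth <- cbind(anchors, tr[, c("decay_rel", "loop_fold", "true_rel")])
    truth$digestion_efficiency <- eff
    truth$normalizer_cq <- norm_cq
    list(plates = rbind(junc, norm),
         anchor_map = data.frame(assay = .anchor_assay(anchors$anchor_kb),
                                 fragment_id = anchors$fragment_id,
                                 stringsAsFactors = FALSE),
         qc = qc,
         truth = truth)
  })
}

#' Per-site digestion efficiencies from a QC plate
#'
#' @param qc QC table from [simulate_3c_plates()] (columns `site`, `assay`,
#'   `template`, `cq`).
#' @return Named numeric vector of per-site efficiencies (percent), ready
#'   for [qc_digestion()].
#' @export
digestion_efficiencies <- function(qc) {
  sites <- unique(qc$site)
  vapply(stats::setNames(sites, sites), function(s) {
    g <- qc[qc$site == s, , drop = FALSE]
    pick <- function(a, t) mean(g$cq[g$assay == a & g$template == t])
    digestion_efficiency(pick("site", "digested"), pick("ctrl", "digested"),
                         pick("site", "undigested"),
                         pick("ctrl", "undigested"))
  }, numeric(1))
}

#' Simulate expression qPCR plates
#'
#' Emits Cq plates for the target and reference assays over the calibrator
#' (`fibroblast`) and the scenario's test samples. Per-sample loading
#' offsets are injected (they cancel in delta-delta-Ct); the target and
#' reference assay folds are chosen so that the delta-delta-Ct fold against
#' each reference gene equals the scenario's stated truth for that gene
#' exactly in the noiseless limit.
#'
#' @param sc A [scenario()].
#' @return A list: `plates` (`sample`, `assay`, `replicate`, `cq`),
#'   `truth` (`sample`, `reference_gene`, `true_fold`).
#' @export
simulate_expression_plates <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (length(sc$expression) == 0L)
    stop("scenario has no expression block")
  base_cq <- c(PTBP3 = 26, GAPDH = 18, PBGD = 27)
  refs <- names(sc$expression[[1L]])
  samples <- c("fibroblast", names(sc$expression))
  sd <- sc$cq_noise_sd_expression
  reps <- sc$replicates
  .with_scenario_seed(sc, 2L, {
    load_shift <- stats::setNames(stats::rnorm(length(samples), 0, 0.5),
                                  samples)
    rows <- list()
    truth <- list()
    for (s in samples) {
      # measured fold per reference gene; target fold anchored to the first
      # reference, remaining references absorb the rest of the shift
      folds <- if (s == "fibroblast")
        stats::setNames(rep(1, length(refs)), refs)
      else sc$expression[[s]]
      f_target <- folds[[1L]]
      f_assay <- c(stats::setNames(f_target, "PTBP3"), f_target / folds)
      for (a in c("PTBP3", refs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, assay = a, replicate = seq_len(reps),
          cq = base_cq[[a]] - log2(f_assay[[a]]) + load_shift[[s]] +
            stats::rnorm(reps, 0, sd),
          stringsAsFactors = FALSE)
      }
      if (s != "fibroblast")
        truth[[length(truth) + 1L]] <- data.frame(
          sample = s, reference_gene = refs,
          true_fold = unname(folds[refs]), stringsAsFactors = FALSE)
    }
    list(plates = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate ChIP-qPCR well sets
#'
#' For each (cell line, region) of the scenario's ChIP block, emits input,
#' specific-antibody and IgG wells for `chip_experiments` independent
#' experiments. The IgG percent-input baseline is shared within a region;
#' the specific antibody sits at `fold` times the baseline.
#'
#' @param sc A [scenario()].
#' @param antibody Specific antibody label (default `"H3K27ac"`).
#' @return A list: `wells` (`cell_line`, `region`, `antibody`, `experiment`,
#'   `cq`, `input_fraction`), `truth` (the scenario's ChIP block).
#' @export
simulate_chip_plates <- function(sc, antibody = "H3K27ac") {
  stopifnot(inherits(sc, "scenario"))
  if (is.null(sc$chip)) stop("scenario has no ChIP block")
  sd <- sc$cq_noise_sd_chip
  frac <- sc$input_fraction
  adj <- log2(1 / frac)
  .with_scenario_seed(sc, 3L, {
    rows <- list()
    for (i in seq_len(nrow(sc$chip))) {
      cl <- sc$chip$cell_line[i]; rg <- sc$chip$region[i]
      pct_igg <- sc$chip$baseline_pct[i]
      pct_ab <- pct_igg * sc$chip$fold[i]
      for (e in seq_len(sc$chip_experiments)) {
        cq_input_true <- 24 + stats::rnorm(1, 0, 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_line = cl, region = rg,
          antibody = c("input", antibody, "IgG"),
          experiment = e,
          cq = c(cq_input_true + stats::rnorm(1, 0, sd),
                 cq_input_true - adj - log2(pct_ab / 100) +
                   stats::rnorm(1, 0, sd),
                 cq_input_true - adj - log2(pct_igg / 100) +
                   stats::rnorm(1, 0, sd)),
          input_fraction = frac,
          stringsAsFactors = FALSE)
      }
    }
    list(wells = do.call(rbind, rows), truth = sc$chip)
  })
}

#' Simulate ddPCR droplet-count wells
#'
#' Target and reference wells for the calibrator (`fibroblast`) and each
#' test sample. Per-sample loading factors scale both assays (they cancel
#' in the normalised ratio); positives are drawn binomially with
#' `p = 1 - exp(-lambda)`, or set to the rounded expectation when the
#' scenario's `sampling` is `"expected"` (the deterministic mode).
#'
#' @param sc A [scenario()].
#' @return A list: `wells` (`sample`, `assay`, `positives`, `total`),
#'   `truth` (`sample`, `true_ratio`, `lambda_target`, `lambda_ref`).
#' @export
simulate_ddpcr_wells <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  dd <- sc$ddpcr
  if (length(dd$samples) == 0L) stop("scenario has no ddPCR block")
  samples <- c("fibroblast", names(dd$samples))
  ratios <- c(fibroblast = 1, dd$samples)
  .with_scenario_seed(sc, 4L, {
    loading <- stats::setNames(exp(stats::rnorm(length(samples), 0, 0.2)),
                               samples)
    draw <- function(lambda) {
      p <- -expm1(-lambda)
      if (identical(dd$sampling, "expected")) as.integer(round(dd$total * p))
      else stats::rbinom(dd$wells, dd$total, p)
    }
    rows <- list(); truth <- list()
    for (s in samples) {
      lam_t <- dd$lambda_target_cal * ratios[[s]] * loading[[s]]
      lam_r <- dd$lambda_ref * loading[[s]]
      pos_t <- draw(lam_t); pos_r <- draw(lam_r)
      n <- if (identical(dd$sampling, "expected")) 1L else dd$wells
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s,
        assay = rep(c("PTBP3", "PBGD"), each = n),
        positives = c(pos_t, pos_r),
        total = dd$total,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        sample = s, true_ratio = ratios[[s]],
        lambda_target = lam_t, lambda_ref = lam_r,
        stringsAsFactors = FALSE)
    }
    list(wells = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Write every synthetic input of a scenario to a directory
#'
#' Materialises the scenario as the plain-text files the file-based
#' pipeline consumes: locus FASTA, fragment BED/TSV, 3C plate CSV, anchor
#' map TSV, digestion-QC CSV, expression plate CSV, ChIP well CSV, ddPCR
#' well CSV, and per-generator ground-truth TSVs.
#'
#' @param sc A [scenario()].
#' @param dir Output directory (created if absent).
#' @param write_fasta Also generate and write the locus sequence (slower;
#'   the fragment map alone suffices for the Cq-level pipeline).
#' @return Invisibly, the named list of written paths.
#' @export
write_scenario_dir <- function(sc, dir, write_fasta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(x, name, sep = ",") {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = sep, quote = FALSE, row.names = FALSE)
    p
  }
  if (write_fasta) {
    ml <- make_locus(sc)
    paths$fasta <- write_locus_fasta(ml$sequence, file.path(dir, "locus.fa"))
    locus <- ml$locus
  } else {
    locus <- scenario_locus(sc)
  }
  paths$fragments_bed <- write_fragments_bed(
    locus$fragments, file.path(dir, "fragments.bed"),
    strand = sc$gene_strand)
  paths$fragments_tsv <- wr(locus$fragments, "fragments.tsv", "\t")
  tc <- simulate_3c_plates(sc)
  paths$threec_plates <- wr(tc$plates, "threec_plates.csv")
  paths$anchor_map <- wr(tc$anchor_map, "anchor_map.tsv", "\t")
  paths$digestion_qc <- wr(tc$qc, "digestion_qc.csv")
  paths$threec_truth <- wr(tc$truth, "threec_truth.tsv", "\t")
  if (length(sc$expression)) {
    ex <- simulate_expression_plates(sc)
    paths$expression_plates <- wr(ex$plates, "expression_plates.csv")
    paths$expression_truth <- wr(ex$truth, "expression_truth.tsv", "\t")
  }
  if (!is.null(sc$chip)) {
    ch <- simulate_chip_plates(sc)
    paths$chip_wells <- wr(ch$wells, "chip_wells.csv")
    paths$chip_truth <- wr(ch$truth, "chip_truth.tsv", "\t")
  }
  if (length(sc$ddpcr$samples)) {
    dd <- simulate_ddpcr_wells(sc)
    paths$ddpcr_wells <- wr(dd$wells, "ddpcr_wells.csv")
    paths$ddpcr_truth <- wr(dd$truth, "ddpcr_truth.tsv", "\t")
  }
  invisible(paths)
}
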
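# Independent oracles and small generators shared across tests.

# Naive quadratic substring scan: 0-based start positions of `motif` in
# `sequence`, N treated as never matching. Independent of digest_sequence.
naive_motif_scan <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# Fragment boundaries implied by cut-at-motif-start positions.
naive_fragments <- function(sequence, motif) {
  cuts <- naive_motif_scan(sequence, motif)
  cuts <- cuts[cuts > 0 & cuts < nchar(sequence)]
  bounds <- unique(c(0L, sort(cuts), nchar(sequence)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal expression plate with exact (noiseless) Cq values for a given
# fold change of the target between test and calibrator, E = 1.
exact_expression_plate <- function(fold, reps = 3,
                                   target = "T", ref = "R",
                                   test = "test", cal = "cal") {
  rows <- expand.grid(sample = c(test, cal), assay = c(target, ref),
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  rows$cq <- ifelse(rows$assay == ref, 20,
                    ifelse(rows$sample == cal, 25, 25 - log2(fold)))
  rows
}

# One full 3C stage on a preset seed: profile, background, enrichments.
threec_stage <- function(preset, seed, noise = NULL) {
  sc <- if (is.null(noise)) preset_scenario(preset, seed = seed)
        else preset_scenario(preset, seed = seed, cq_noise_sd_3c = noise)
  locus <- threeCquant:::scenario_locus(sc)
  tc <- simulate_3c_plates(sc, locus)
  profile <- build_profile(tc$plates, locus, tc$anchor_map)
  bg <- fit_background(profile)
  enr <- suppressWarnings(fold_enrichments(profile, bg,
                                           proximal_window_kb = 8))
  list(sc = sc, locus = locus, tc = tc, profile = profile, bg = bg,
       enr = enr)
}
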
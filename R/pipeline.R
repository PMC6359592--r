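# End-to-end orchestration: synthetic inputs -> digestion QC -> interaction
# profile -> background -> fold enrichments -> loop calls, plus the
# companion expression / ChIP / ddPCR stages.

#' Run the full analysis pipeline
#'
#' Executes the 3C analysis end to end on a scenario's synthetic inputs:
#' locus fragment map, digestion QC, bait-anchored interaction profile,
#' distance-decay background with iterative peak exclusion, fold
#' enrichments, and loop calls; then the optional expression
#' (delta-delta-Ct), ChIP (percent input / fold over IgG) and ddPCR
#' (Poisson ratio) stages. When `out_dir` is set, writes the profile and
#' loop-call TSVs, a BED of called loops, a JSON run summary, and the
#' effective configuration as YAML.
#'
#' @param config A configuration list or YAML path (see
#'   [read_run_config()]); keys: `preset`, `seed`, `out_dir`,
#'   `write_fasta`, `stages`, `qc`, `background`, `loops`.
#' @param scenario Optional pre-built [scenario()] overriding
#'   `preset`/`seed`.
#' @return Invisibly, a list with elements `config`, `scenario`, `locus`,
#'   `qc`, `profile`, `background`, `enrichments`, `loop_calls`,
#'   `expression`, `chip`, `ddpcr`, `summary`.
#' @export
run_pipeline <- function(config = list(), scenario = NULL) {
  cfg <- read_run_config(config)
  sc <- if (!is.null(scenario)) scenario
        else preset_scenario(cfg$preset, seed = cfg$seed)
  locus <- scenario_locus(sc)

  res <- list(config = cfg, scenario = sc, locus = locus)

  if (isTRUE(cfg$stages$threec)) {
    tc <- simulate_3c_plates(sc, locus)
    eff <- digestion_efficiencies(tc$qc)
    qc <- qc_digestion(eff, cfg$qc$threshold_percent)
    if (!qc$pass) {
      msg <- paste("digestion QC failed for site(s):",
                   paste(qc$failing_sites, collapse = ", "))
      if (isTRUE(cfg$qc$warn_only)) warning(msg) else stop(msg)
    }
    profile <- build_profile(tc$plates, locus, tc$anchor_map)
    bg <- fit_background(profile,
                         iterative = cfg$background$iterative,
                         z_threshold = cfg$background$z_threshold,
                         scale_floor = cfg$background$scale_floor,
                         max_rounds = cfg$background$max_rounds)
    enr <- fold_enrichments(profile, bg,
                            proximal_window_kb = cfg$loops$proximal_window_kb)
    calls <- call_loops(enr, cfg$loops$min_fold_bg, cfg$loops$min_fold_prox)
    res$threec_truth <- tc$truth
    res$qc <- qc
    res$profile <- profile
    res$background <- bg
    res$enrichments <- enr
    res$loop_calls <- calls
  }
  if (isTRUE(cfg$stages$expression) && length(sc$expression)) {
    ex <- simulate_expression_plates(sc)
    refs <- names(sc$expression[[1L]])
    res$expression <- do.call(rbind, lapply(names(sc$expression), function(s)
      delta_delta_ct(ex$plates, "PTBP3", refs, s, "fibroblast")))
    res$expression_truth <- ex$truth
  }
  if (isTRUE(cfg$stages$chip) && !is.null(sc$chip)) {
    ch <- simulate_chip_plates(sc)
    res$chip <- chip_enrichment(ch$wells)
    res$chip_truth <- ch$truth
  }
  if (isTRUE(cfg$stages$ddpcr) && length(sc$ddpcr$samples)) {
    dd <- simulate_ddpcr_wells(sc)
    res$ddpcr <- do.call(rbind, lapply(names(sc$ddpcr$samples), function(s)
      normalized_ratio(dd$wells, "PTBP3", "PBGD", s, "fibroblast")))
    res$ddpcr_truth <- dd$truth
  }

  peaks <- if (!is.null(res$loop_calls))
    res$loop_calls[res$loop_calls$is_peak, , drop = FALSE]
  else NULL
  res$summary <- list(
    scenario = sc$name,
    seed = sc$seed,
    n_fragments = nrow(locus$fragments),
    digestion_qc_pass = if (!is.null(res$qc)) res$qc$pass else NA,
    n_loop_calls = if (!is.null(peaks)) nrow(peaks) else NA_integer_,
    loop_distances_kb = if (!is.null(peaks)) peaks$tss_distance_kb
                        else numeric(0)
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$profile))
      write_results_tsv(as.data.frame(res$profile),
                        file.path(cfg$out_dir, "profile.tsv"))
    if (!is.null(res$loop_calls)) {
      write_results_tsv(as.data.frame(res$loop_calls),
                        file.path(cfg$out_dir, "loop_calls.tsv"))
      if (nrow(peaks)) {
        fr <- locus$fragments[match(peaks$fragment_id,
                                    locus$fragments$fragment_id), ]
        write_fragments_bed(fr, file.path(cfg$out_dir, "loops.bed"),
                            strand = sc$gene_strand)
      }
    }
    for (nm in c("expression", "chip", "ddpcr"))
      if (!is.null(res[[nm]]))
        write_results_tsv(res[[nm]],
                          file.path(cfg$out_dir, paste0(nm, ".tsv")))
    jsonlite::write_json(res$summary,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_out <- cfg
    cfg_out$out_dir <- as.character(cfg$out_dir)
    yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "config.yaml"))
  }
  invisible(res)
}
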
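test_that("scenarios validate their geometry and loop references", {
  expect_error(scenario(loops = data.frame(anchor_kb = -10, fold = 3)),
               "existing anchors")
  expect_error(scenario(loops = data.frame(anchor_kb = -63.2, fold = -1)),
               "positive")
  expect_error(preset_scenario("pc3m", anchors_kb = c(-300, 48.4)),
               "outside the locus|existing anchors")
})

test_that("the synthetic locus plants the motif map it claims", {
  sc <- preset_scenario("pc3m", seed = 13)
  ml <- make_locus(sc)
  # digesting the generated sequence recovers exactly the planted cuts
  fr <- ml$locus$fragments
  expect_equal(sort(unique(c(fr$start, fr$end))),
               sort(c(0L, ml$cut_positions, sc$locus_length_bp)))
  expect_equal(nrow(fr), length(ml$cut_positions) + 1L)
  # no spurious occurrences anywhere
  expect_equal(naive_motif_scan(ml$sequence, sc$motif), ml$cut_positions)
  # seven anchors map to seven distinct fragments, midpoints within 1 kb
  expect_equal(length(unique(ml$truth$fragment_id)), 7L)
  expect_true(all(abs(ml$truth$tss_distance_kb - ml$truth$anchor_kb) <= 1))
  # the bait fragment contains the TSS
  expect_equal(locate_fragment(ml$locus, sc$tss),
               ml$locus$bait_fragment_id)
})

test_that("a motif-free sequence yields a single fragment", {
  set.seed(99)
  s <- gsub("AAGCTT", "AAGCTA", random_dna(5000), fixed = TRUE)
  while (grepl("AAGCTT", s, fixed = TRUE))
    s <- gsub("AAGCTT", "AAGCTA", s, fixed = TRUE)
  expect_equal(nrow(digest_sequence(s)), 1L)
})

test_that("identical scenario and seed reproduce identical outputs", {
  a <- preset_scenario("pc3m", seed = 21)
  b <- preset_scenario("pc3m", seed = 21)
  expect_identical(simulate_3c_plates(a), simulate_3c_plates(b))
  expect_identical(simulate_expression_plates(a),
                   simulate_expression_plates(b))
  expect_identical(simulate_chip_plates(a), simulate_chip_plates(b))
  expect_identical(simulate_ddpcr_wells(a), simulate_ddpcr_wells(b))
  c <- preset_scenario("pc3m", seed = 22)
  expect_false(identical(simulate_3c_plates(a)$plates$cq,
                         simulate_3c_plates(c)$plates$cq))
})

test_that("generator order does not disturb per-generator streams", {
  a <- preset_scenario("pc3m", seed = 31)
  first <- simulate_chip_plates(a)
  invisible(simulate_3c_plates(a))
  invisible(simulate_ddpcr_wells(a))
  expect_identical(simulate_chip_plates(a), first)
})

test_that("noiseless 3C plates round-trip to the exact planted profile", {
  s <- threec_stage("pc3m", seed = 1, noise = 0)
  truth <- s$tc$truth[order(s$tc$truth$tss_distance_kb), ]
  expect_equal(s$profile$rel_frequency, truth$true_rel, tolerance = 1e-12)
  expect_equal(s$profile$sd, rep(0, 7))
  # fold over background equals the planted loop fold exactly
  enr <- s$enr
  i <- match(truth$fragment_id[truth$loop_fold > 1], enr$fragment_id)
  expect_equal(enr$fold_over_background[i], c(9, 6), tolerance = 1e-9)
})

test_that("noiseless expression plates round-trip to the exact folds", {
  sc <- preset_scenario("pc3m", seed = 1, cq_noise_sd_expression = 0)
  ex <- simulate_expression_plates(sc)
  r <- delta_delta_ct(ex$plates, "PTBP3", c("GAPDH", "PBGD"),
                      "PC3M", "fibroblast")
  expect_equal(r$fold_change, c(4.5, 3.0), tolerance = 1e-12)
})

test_that("deterministic ddPCR wells round-trip to the preset ratio", {
  sc <- preset_scenario("pc3", seed = 1)
  sc$ddpcr$sampling <- "expected"
  dd <- simulate_ddpcr_wells(sc)
  r <- normalized_ratio(dd$wells, "PTBP3", "PBGD", "PC3", "fibroblast")
  expect_equal(r$fold_change, 1.4, tolerance = 1e-3)
})

test_that("scenario directories contain every input the pipeline reads", {
  dir <- withr::local_tempdir()
  paths <- write_scenario_dir(preset_scenario("pc3m", seed = 2), dir)
  expect_true(all(file.exists(unlist(paths))))
  plates <- read_plate_csv(paths$threec_plates)
  expect_equal(sort(unique(plates$assay)),
               sort(c("ERCC3", unique(utils::read.delim(
                 paths$anchor_map)$assay))))
  # truth files alone reproduce the expected profile values
  truth <- utils::read.delim(paths$threec_truth)
  expect_true(all(c("true_rel", "loop_fold", "fragment_id") %in%
                    names(truth)))
})
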
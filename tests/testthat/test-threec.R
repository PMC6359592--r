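test_that("interaction frequency is the normalised junction quantity", {
  expect_equal(interaction_frequency(25, 25)$rel_frequency, 1)
  expect_equal(interaction_frequency(28, 25)$rel_frequency, 0.125)
  r <- interaction_frequency(c(25, 26, 24), c(25, 25, 25))
  expect_equal(r$n, 3)
  expect_equal(r$rel_frequency, mean(c(1, 0.5, 2)))
  expect_equal(interaction_frequency(25, 25, calibration = 2)$rel_frequency, 2)
  expect_error(interaction_frequency(25, numeric(0)), "normalizer")
})

test_that("profiles hold one ordered point per anchor, bait excluded", {
  s <- threec_stage("pc3m", seed = 3)
  expect_s3_class(s$profile, "interaction_profile")
  expect_equal(nrow(s$profile), 7L)
  expect_equal(s$profile$tss_distance_kb,
               sort(s$profile$tss_distance_kb))
  expect_equal(s$profile$tss_distance_kb, s$sc$anchors_kb[
    order(s$sc$anchors_kb)])
  expect_false(attr(s$profile, "bait_fragment_id") %in%
                 s$profile$fragment_id)
  expect_true(all(s$profile$n == s$sc$replicates))

  expect_error(build_profile(s$tc$plates[0, ], s$locus, s$tc$anchor_map),
               "empty plate")
  bad_map <- s$tc$anchor_map[-1, ]
  expect_error(build_profile(s$tc$plates, s$locus, bad_map),
               "no fragment mapping")
  noname <- s$tc$plates[s$tc$plates$assay != "ERCC3", ]
  expect_error(build_profile(noname, s$locus, s$tc$anchor_map),
               "normalizer")
})

test_that("profiles are invariant to a global Cq shift of the plate", {
  s <- threec_stage("pc3m", seed = 9)
  shifted <- s$tc$plates
  shifted$cq <- shifted$cq + 2.13
  p2 <- build_profile(shifted, s$locus, s$tc$anchor_map)
  expect_equal(p2$rel_frequency, s$profile$rel_frequency,
               tolerance = 1e-12)
})

test_that("replicate libraries of one scenario agree pointwise", {
  a <- threec_stage("pc3m", seed = 101)$profile
  b <- threec_stage("pc3m", seed = 202)$profile
  lr <- log(a$rel_frequency) - log(b$rel_frequency)
  expect_lt(abs(mean(lr)), 0.35)
  comb <- combine_profiles(list(a, b))
  expect_equal(log(comb$rel_frequency),
               (log(a$rel_frequency) + log(b$rel_frequency)) / 2)
})

test_that("background fit recovers an exact power law", {
  d <- c(-80, -60, -30, -7, 50, 70, 120)
  prof <- data.frame(fragment_id = 1:7, tss_distance_kb = d,
                     rel_frequency = 3.2 * abs(d)^(-1.2))
  bg <- fit_background(prof)
  expect_equal(bg$b, 1.2, tolerance = 1e-9)
  expect_equal(exp(bg$log_a), 3.2, tolerance = 1e-9)
  expect_equal(length(bg$excluded_fragments), 0L)
  expect_equal(predict(bg, -60), 3.2 * 60^-1.2, tolerance = 1e-9)
  expect_error(fit_background(prof[1:3, ]), ">= 4 usable points")
})

test_that("background falls back to flat when there is no decay", {
  d <- c(-80, -60, -30, -7, 50, 70, 120)
  prof <- data.frame(fragment_id = 1:7, tss_distance_kb = d,
                     rel_frequency = 0.5 * abs(d)^(0.4))  # increasing
  expect_warning(bg <- fit_background(prof), "flat background")
  expect_true(bg$flat)
  expect_equal(bg$b, 0)
  expect_true(all(predict(bg, d) > 0))
})

test_that("iterative exclusion removes loop fragments, not quiet points", {
  # noiseless loop profile: exactly the two planted loops are excluded
  s0 <- threec_stage("pc3m", seed = 1, noise = 0)
  loop_fids <- s0$tc$truth$fragment_id[s0$tc$truth$loop_fold > 1]
  expect_setequal(s0$bg$excluded_fragments, loop_fids)
  expect_equal(s0$bg$b, unname(s0$sc$decay["b"]), tolerance = 1e-9)

  # under noise: both loops out in >= 90% of seeds, none on null profiles
  hit <- 0L; null_excl <- 0L
  for (seed in 1:40) {
    s <- threec_stage("pc3m", seed = seed)
    fids <- s$tc$truth$fragment_id[s$tc$truth$loop_fold > 1]
    if (setequal(s$bg$excluded_fragments, fids)) hit <- hit + 1L
    n <- threec_stage("null", seed = seed)
    if (length(n$bg$excluded_fragments) > 0) null_excl <- null_excl + 1L
  }
  expect_gte(hit / 40, 0.9)
  expect_lte(null_excl / 40, 0.1)
})

test_that("fitted decay exponent is recovered within 10% under noise", {
  bs <- vapply(1:20, function(seed) threec_stage("null", seed)$bg$b,
               numeric(1))
  truth <- unname(preset_scenario("null")$decay["b"])
  expect_lt(abs(mean(bs) - truth) / truth, 0.10)
})

test_that("fold enrichments are ratios to background and proximal", {
  d <- c(-80, -60, -30, -3, 50, 70, 120)
  prof <- data.frame(fragment_id = 1:7, tss_distance_kb = d,
                     rel_frequency = 2.6 * abs(d)^(-0.8))
  bg <- fit_background(prof)
  enr <- fold_enrichments(prof, bg)      # -3 kb point is inside the window
  expect_equal(enr$fold_over_background, rep(1, 7), tolerance = 1e-9)
  expect_equal(enr$proximal_fragment_id, rep(4L, 7))
  expect_equal(enr$fold_over_proximal[4], 1)

  # no point within the window: nearest fragment with a warning
  prof2 <- prof
  prof2$tss_distance_kb[4] <- -6.8
  prof2$rel_frequency <- 2.6 * abs(prof2$tss_distance_kb)^(-0.8)
  bg2 <- fit_background(prof2)
  expect_warning(enr2 <- fold_enrichments(prof2, bg2), "nearest fragment")
  expect_equal(enr2$proximal_fragment_id, rep(4L, 7))

  prof2$rel_frequency[4] <- 0
  expect_warning(expect_error(
    fold_enrichments(prof2, bg2), "degenerate"))
})

test_that("loop calling applies both fold thresholds", {
  flat <- data.frame(fragment_id = 1:5, tss_distance_kb = c(-50, -20, -3, 30, 60),
                     rel_frequency = 1, fold_over_background = 1,
                     fold_over_proximal = 1, proximal_fragment_id = 3L,
                     is_peak = NA)
  expect_equal(sum(call_loops(flat)$is_peak), 0L)
  up <- flat
  up$fold_over_background <- c(1, 4, 1, 4, 1)
  up$fold_over_proximal <- c(1, 2, 1, 1.2, 1)
  called <- call_loops(up)
  expect_equal(which(called$is_peak), 2L)   # needs both thresholds
  expect_equal(which(call_loops(up, min_fold_prox = 1.1)$is_peak),
               c(2L, 4L))
})

test_that("library concentration interpolates a log-linear standard curve", {
  std <- data.frame(ng = c(100, 10), cq = c(20, 23.3219280948874))
  r <- library_concentration(21.6609640474437, std)
  expect_equal(r$ng, 10^1.5, tolerance = 1e-6)
  expect_false(r$extrapolated)
  expect_equal(library_concentration(20, std)$ng, 100, tolerance = 1e-6)
  ex <- library_concentration(25, std)
  expect_true(ex$extrapolated)
  expect_error(library_concentration(21, data.frame(ng = c(10, 10),
                                                    cq = c(20, 21))),
               "distinct concentrations")
})
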
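test_that("relative quantity follows (1+E)^-cq", {
  expect_equal(relative_quantity(0), 1)
  expect_equal(relative_quantity(1), 0.5)
  expect_equal(relative_quantity(10, 0.9), 1.9^-10)
  expect_true(all(diff(relative_quantity(1:10)) < 0))
  expect_error(relative_quantity(5, 0), "efficiency")
  expect_error(relative_quantity(5, 1.2), "efficiency")
  expect_error(relative_quantity(Inf), "finite")
})

test_that("digestion efficiency is the ratio-of-ratios percent", {
  expect_equal(digestion_efficiency(20, 20, 20, 20), 0)    # ddCq = 0
  expect_equal(digestion_efficiency(21, 20, 20, 20), 50)   # one doubling
  expect_equal(digestion_efficiency(20 + log2(10), 20, 20, 20), 90)
  # monotone increasing in ddCq, bounded above by 100
  eff <- vapply(seq(-2, 8, by = 0.5),
                function(dd) digestion_efficiency(20 + dd, 20, 20, 20),
                numeric(1))
  expect_true(all(diff(eff) > 0))
  expect_true(all(eff <= 100))
})

test_that("library digestion QC fails on any site at or below threshold", {
  expect_true(qc_digestion(c(90, 92, 88))$pass)
  qc <- qc_digestion(c(s1 = 90, s2 = 80))
  expect_false(qc$pass)
  expect_equal(qc$failing_sites, "s2")
  expect_equal(qc_digestion(c(a = -5, b = 90))$anomalies, "a")
  expect_error(qc_digestion(numeric(0)), "at least one")
})

test_that("significance stars follow the three-tier scheme", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
  expect_equal(significance_stars(0.03, thresholds = c(0.05, 0.001)), "*")
  expect_error(significance_stars(1.5), "\\[0, 1\\]")
})

test_that("delta-delta-Ct recovers exact folds from noiseless plates", {
  # no change
  expect_equal(delta_delta_ct(exact_expression_plate(1), "T", "R",
                              "test", "cal")$fold_change, 1)
  # ddCq = -2: two doublings
  expect_equal(delta_delta_ct(exact_expression_plate(4), "T", "R",
                              "test", "cal")$fold_change, 4)
  r <- delta_delta_ct(exact_expression_plate(4.5), "T", "R", "test", "cal")
  expect_equal(r$fold_change, 4.5)
  expect_true(r$ci_low <= r$fold_change && r$fold_change <= r$ci_high)
  expect_equal(r$reference_gene, "R")
})

test_that("delta-delta-Ct fold changes are invariant to a global Cq shift", {
  sc <- preset_scenario("pc3m", seed = 5)
  ex <- simulate_expression_plates(sc)
  base <- delta_delta_ct(ex$plates, "PTBP3", c("GAPDH", "PBGD"),
                         "PC3M", "fibroblast")
  shifted <- ex$plates
  shifted$cq <- shifted$cq + 3.7
  moved <- delta_delta_ct(shifted, "PTBP3", c("GAPDH", "PBGD"),
                          "PC3M", "fibroblast")
  expect_equal(moved$fold_change, base$fold_change, tolerance = 1e-12)
  expect_equal(moved$p_value, base$p_value, tolerance = 1e-12)
})

test_that("delta-delta-Ct validates inputs and supports dual references", {
  plate <- exact_expression_plate(2)
  expect_error(delta_delta_ct(plate, "T", "R", "absent", "cal"),
               "no Cq records")
  one_rep <- plate[plate$replicate == 1 | plate$sample == "cal", ]
  expect_error(delta_delta_ct(one_rep, "T", "R", "test", "cal"),
               "fewer than 2 replicates")
  # separate mode: one row per reference; geometric mode: a single row
  plate2 <- rbind(plate,
                  transform(plate[plate$assay == "R", ], assay = "R2"))
  sep <- delta_delta_ct(plate2, "T", c("R", "R2"), "test", "cal")
  expect_equal(nrow(sep), 2L)
  expect_equal(sep$fold_change, c(2, 2))
  geo <- delta_delta_ct(plate2, "T", c("R", "R2"), "test", "cal",
                        reference_mode = "geometric")
  expect_equal(nrow(geo), 1L)
  expect_equal(geo$fold_change, 2)
  expect_equal(geo$reference_gene, "R+R2")
})

test_that("efficiency-corrected fold uses the per-assay efficiencies", {
  plate <- exact_expression_plate(4)  # ddCq(target) = -2, ref unchanged
  plate$efficiency <- ifelse(plate$assay == "T", 0.9, 1.0)
  r <- delta_delta_ct(plate, "T", "R", "test", "cal")
  expect_equal(r$fold_change, 1.9^2)
})
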
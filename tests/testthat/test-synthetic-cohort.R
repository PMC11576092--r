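test_that("cohort construction returns the requested sex composition", {
  co <- build_cohort(18, 16, seed = 1)
  expect_equal(nrow(co), 34)
  expect_equal(sum(co$sex == "male"), 18)
  expect_equal(sum(co$sex == "female"), 16)
  expect_equal(anyDuplicated(co$subject_id), 0)

  solo <- build_cohort(1, 0, seed = 7)
  expect_equal(nrow(solo), 1)
  expect_equal(solo$sex, "male")

  expect_identical(build_cohort(2, 2, seed = 5), build_cohort(2, 2, seed = 5))
  expect_error(build_cohort(0, 0), "at least one")
})

test_that("spec construction enforces the baseline knot and positive effects", {
  expect_error(
    metabolite_spec("X", "u", 1, 1, knots = c("3h" = 1.2)),
    "baseline knot"
  )
  expect_error(
    metabolite_spec("X", "u", 1, 1, knots = c(baseline = 1.01, "24h" = 2)),
    "must equal 1"
  )
  expect_error(
    metabolite_spec("X", "u", 1, 1, knots = c(baseline = 1, "24h" = -2)),
    "> 0"
  )
  expect_error(metabolite_spec("X", "u", 1, 1, between_gsd = 0.9,
    knots = c(baseline = 1, "24h" = 2)
  ))
})

test_that("noise-free simulation reproduces the response curve exactly", {
  cohort <- build_cohort(3, 2, seed = 1)
  rec <- simulate_trajectories(cohort, tag_spec(), seed = 9)
  expect_equal(nrow(rec), 5 * 14) # balanced: subjects x timepoints
  ratios <- subject_ratios(rec, "TAG")
  at3h <- ratios$ratio[ratios$timepoint == "3h"]
  expect_equal(at3h, rep(1.27, 5))
  at10h <- ratios$ratio[ratios$timepoint == "10h"]
  expect_equal(at10h, rep(0.83, 5))
  # sex enters only as a baseline multiplier
  base <- rec[rec$timepoint == "baseline", ]
  expect_equal(unique(base$concentration[base$sex == "male"]), 1.0)
  expect_equal(unique(base$concentration[base$sex == "female"]), 0.8)
})

test_that("effects between knots are log-linear in minutes", {
  cohort <- build_cohort(1, 0, seed = 1)
  rec <- simulate_trajectories(cohort, tag_spec(), seed = 1)
  # 6h lies between the 3h (1.27) and 10h (0.83) knots
  f <- (360 - 180) / (600 - 180)
  expected <- exp((1 - f) * log(1.27) + f * log(0.83))
  expect_equal(
    rec$concentration[rec$timepoint == "6h"] / rec$concentration[rec$timepoint == "baseline"],
    expected
  )
})

test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  cohort <- build_cohort(4, 4, seed = 3)
  a <- simulate_trajectories(cohort, tag_spec(1.3, 1.2), seed = 17)
  b <- simulate_trajectories(cohort, tag_spec(1.3, 1.2), seed = 17)
  expect_identical(a, b)
  c <- simulate_trajectories(cohort, tag_spec(1.3, 1.2), seed = 18)
  expect_false(identical(a$concentration, c$concentration))
})

test_that("log concentrations are normal and the baseline gSD is recovered", {
  cohort <- build_cohort(2500, 2500, seed = 2)
  spec <- tag_spec(between_gsd = 1.32, within_gsd = 1)
  grid <- timepoint_grid()[c(1, 14), ] # baseline and 24 h suffice
  rec <- simulate_trajectories(cohort, spec, grid = grid, seed = 4)
  base_m <- rec$concentration[rec$timepoint == "baseline" & rec$sex == "male"]
  expect_equal(gsd(base_m), 1.32, tolerance = 0.02)
  expect_gt(shapiro.test(log(sample(base_m, 1000)))$p.value, 0.01)
  # raw concentrations are right-skewed, not normal
  expect_lt(shapiro.test(sample(base_m, 1000))$p.value, 0.01)
})

test_that("LOD censoring uses a strict inequality and preserves order", {
  cohort <- build_cohort(2, 0, seed = 1)
  spec <- tag_spec()
  rec <- simulate_trajectories(cohort, spec, seed = 1)
  expect_identical(apply_lod_censoring(rec, spec), rec) # lod = 0 disables

  rec2 <- rec
  rec2$concentration[1] <- 0.08
  rec2$concentration[2] <- 0.10
  spec_lod <- tag_spec(lod = 0.10)
  out <- apply_lod_censoring(rec2, spec_lod)
  expect_true(out$below_lod[1])
  expect_true(is.na(out$concentration[1]))
  expect_false(out$below_lod[2]) # boundary value retained
  expect_equal(out$concentration[2], 0.10)
  expect_identical(out[-1, ], rec2[-1, ] |> apply_lod_censoring(spec_lod))
})

test_that("default panel is calibrated to the published relative changes", {
  panel <- default_metabolite_panel()
  knot_effect <- function(met, label) {
    kn <- panel$knots[[which(panel$metabolite_id == met)]]
    kn$effect[kn$label == label]
  }
  expect_equal(knot_effect("TAG", "3h"), 1.27)
  expect_equal(knot_effect("TAG", "10h"), 0.83)
  expect_equal(knot_effect("C8", "60m"), 0.30)
  expect_equal(knot_effect("bHB", "24h"), 7.33)
  expect_equal(knot_effect("AcAc", "24h"), 5.33)
  expect_equal(knot_effect("C2", "2h"), 0.60)
  # every spec anchors its curve at baseline = 1
  for (kn in panel$knots) expect_equal(kn$effect[kn$label == "baseline"], 1)
  # sex offsets: females lower for carnitines/TAG/LDL, higher for HDL
  with_panel <- function(met) panel[panel$metabolite_id == met, ]
  for (met in c("C0", "C2", "C8", "TAG", "LDL-C")) {
    expect_lt(with_panel(met)$baseline_female, with_panel(met)$baseline_male)
  }
  expect_gt(with_panel("HDL-C")$baseline_female, with_panel("HDL-C")$baseline_male)
})
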
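test_that("per-subject ratios use each subject's own baseline", {
  rec <- small_records()
  ratios <- subject_ratios(rec, "TAG")
  expect_equal(unique(ratios$ratio[ratios$timepoint == "baseline"]), 1)
  one <- rec[rec$subject_id == "S001" & rec$metabolite == "TAG", ]
  b <- one$concentration[one$timepoint == "baseline"]
  expect_equal(
    ratios$ratio[ratios$subject_id == "S001" & ratios$timepoint == "3h"],
    one$concentration[one$timepoint == "3h"] / b
  )
})

test_that("duplicate and baseline-less subjects are handled per contract", {
  rec <- small_records()
  expect_error(subject_ratios(rbind(rec, rec[1, ]), "TAG"), "duplicate")
  drop_base <- rec[!(rec$subject_id == "S002" & rec$timepoint == "baseline"), ]
  expect_warning(r <- subject_ratios(drop_base, "TAG"), "without a baseline")
  expect_false("S002" %in% r$subject_id)
})

test_that("cohort percent change is the geometric mean of subject ratios", {
  ratios <- tibble::tibble(
    metabolite = "X", subject_id = c("a", "b"),
    timepoint = "3h", minutes = 180L, ratio = c(1.2, 1.3)
  )
  agg <- aggregate_relative(ratios)
  expect_equal(agg$pct_change, 100 * (sqrt(1.2 * 1.3) - 1))
  expect_equal(round(agg$pct_change, 2), 24.9)

  flat <- tibble::tibble(
    metabolite = "X", subject_id = c("a", "b", "c"),
    timepoint = "2h", minutes = 120L, ratio = c(1, 1, 1)
  )
  aggf <- aggregate_relative(flat)
  expect_equal(aggf$pct_change, 0)
  expect_equal(aggf$gci_lower_pct, 0)
  expect_equal(aggf$gci_upper_pct, 0)
})

test_that("gMean of ratios equals ratio of gMeans on complete paired data", {
  rec <- small_records(n_male = 6, n_female = 6, specs = tag_spec(1.4, 1.3))
  ratios <- subject_ratios(rec, "TAG")
  agg <- aggregate_relative(ratios)
  tag <- rec[rec$metabolite == "TAG", ]
  base <- tag[tag$timepoint == "baseline", ]
  for (tp in unique(agg$timepoint)) {
    direct <- gmean(tag$concentration[tag$timepoint == tp]) /
      gmean(base$concentration)
    expect_equal(agg$pct_change[agg$timepoint == tp], 100 * (direct - 1),
      tolerance = 1e-12
    )
  }
})

test_that("extrema are found among post-meal timepoints with earliest-tie rule", {
  rec <- small_records(specs = tag_spec()) # noise-free TAG curve
  agg <- aggregate_relative(subject_ratios(rec, "TAG"))
  ex <- find_extrema(agg)
  expect_equal(ex$timepoint[ex$kind == "peak"], "3h")
  expect_equal(ex$timepoint[ex$kind == "nadir"], "10h")

  flat <- agg
  flat$pct_change <- 0
  exf <- find_extrema(flat)
  expect_equal(exf$timepoint, c("15m", "15m")) # ties broken by earliest
})

test_that("summary table reproduces a noise-free panel exactly", {
  rec <- small_records(specs = tag_spec())
  tab <- relative_change_table(rec, include_icc = FALSE)
  expect_equal(tab$pct_change[tab$timepoint == "3h"], 27)
  expect_equal(tab$pct_change[tab$timepoint == "10h"], -17)
  expect_equal(tab$pct_change[tab$timepoint == "24h"], 13)
  # 4 male at 1.0 and 4 female at 0.8: reference gMean = sqrt(0.8)
  expect_equal(tab$reference_gmean[1], sqrt(1.0 * 0.8))
})

test_that("sex-stratified tables show the baseline offset but shared response", {
  rec <- small_records(n_male = 5, n_female = 5, specs = tag_spec(1.2, 1.1))
  tab <- relative_change_table(rec, stratify_by_sex = TRUE, include_icc = FALSE)
  expect_setequal(unique(tab$stratum), c("all", "male", "female"))
  ref <- tapply(tab$reference_gmean, tab$stratum, unique)
  expect_lt(ref[["female"]], ref[["male"]])
  # pooled gMean ratio lies between the stratum gMean ratios
  for (tp in c("3h", "10h", "24h")) {
    sl <- tab[tab$timepoint == tp, ]
    pooled <- sl$pct_change[sl$stratum == "all"]
    rng <- range(sl$pct_change[sl$stratum != "all"])
    expect_gte(pooled, rng[1] - 1e-9)
    expect_lte(pooled, rng[2] + 1e-9)
  }
})

test_that("a single-subject cohort yields point estimates without intervals", {
  rec <- small_records(n_male = 1, n_female = 0, specs = tag_spec(1.2, 1.1))
  tab <- relative_change_table(rec, include_icc = FALSE)
  expect_true(all(is.finite(tab$pct_change)))
  expect_true(all(is.na(tab$gci_lower_pct)))
  expect_true(all(is.na(tab$gci_upper_pct)))
})

test_that("concentration table matches direct geometric summaries", {
  rec <- small_records()
  tab <- concentration_table(rec)
  tag3h <- rec$concentration[rec$metabolite == "TAG" & rec$timepoint == "3h"]
  row <- tab[tab$metabolite == "TAG" & tab$timepoint == "3h", ]
  expect_equal(row$gmean, gmean(tag3h))
  expect_equal(row$gsd, gsd(tag3h))
})
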
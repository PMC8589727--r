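fu_tbl <- function(id = "p1", drug = "warfarin", end_day = 400) {
  tibble::tibble(
    patient_id = id, drug = drug, followup_end = origin_date + end_day
  )
}

test_that("the 90-day gap rule fires from the end of assumed supply", {
  ep <- build_supply_episodes(mk_rx(c(0, 30)))
  # supply runs to day 60; no further issue; follow-up to day 400
  disc <- detect_discontinuation(ep, fu_tbl(end_day = 400))
  expect_equal(disc$discontinuation_date, origin_date + 60)

  # next issue at day 130: gap 130 - 60 = 70 < 90, no discontinuation there
  ep2 <- build_supply_episodes(mk_rx(c(0, 30, 130)))
  disc2 <- detect_discontinuation(ep2, fu_tbl(end_day = 170))
  expect_true(is.na(disc2$discontinuation_date))

  # continuous refills to the end of follow-up: never discontinues
  ep3 <- build_supply_episodes(mk_rx(seq(0, 360, by = 30)))
  disc3 <- detect_discontinuation(ep3, fu_tbl(end_day = 400))
  expect_true(is.na(disc3$discontinuation_date))

  # boundary: gap of exactly 90 days reaches the threshold
  ep4 <- build_supply_episodes(mk_rx(c(0, 120)))
  disc4 <- detect_discontinuation(ep4, fu_tbl(end_day = 400))
  expect_equal(disc4$discontinuation_date, origin_date + 30)
})

test_that("the issue-anchored gap variant measures from the issue date", {
  ep <- build_supply_episodes(mk_rx(c(0, 85)))
  # supply-end anchor: gap 85 - 30 = 55 < 90 at the first episode
  a <- detect_discontinuation(ep, fu_tbl(end_day = 120), gap_from = "supply_end")
  expect_true(is.na(a$discontinuation_date))
  # issue anchor: gap 85 - 0 = 85 < 90 still, but 95 would fire
  ep2 <- build_supply_episodes(mk_rx(c(0, 95)))
  b <- detect_discontinuation(ep2, fu_tbl(end_day = 100), gap_from = "issue")
  expect_equal(b$discontinuation_date, origin_date + 30)
})

test_that("switches are the first in-class issue of a different drug", {
  rx <- validate_ehr_table(dplyr::bind_rows(
    mk_rx(0, "warfarin"), mk_rx(70, "rivaroxaban")
  ), "prescriptions")
  idx <- tibble::tibble(
    patient_id = "p1", index_drug = "warfarin",
    followup_end = origin_date + 365
  )
  expect_equal(detect_switch(rx, idx)$switch_date, origin_date + 70)

  # no switch when only the index drug appears
  expect_true(is.na(detect_switch(mk_rx(c(0, 30)), idx)$switch_date))

  # a switch after follow-up end does not count
  rx_late <- validate_ehr_table(dplyr::bind_rows(
    mk_rx(0, "aspirin"), mk_rx(400, "clopidogrel")
  ), "prescriptions")
  idx_ap <- tibble::tibble(
    patient_id = "p1", index_drug = "aspirin",
    followup_end = origin_date + 365
  )
  expect_true(is.na(detect_switch(rx_late, idx_ap)$switch_date))
})

test_that("the landmark status ranks discontinuation, switch and censoring", {
  expect_equal(landmark_status(60, NA, 400, 183), "non_persistent")
  expect_equal(landmark_status(NA, 70, 400, 183), "censored_switch")
  expect_equal(landmark_status(NA, NA, 100, 183), "censored_followup")
  expect_equal(landmark_status(NA, NA, 400, 365), "persistent")
  # a switch before the qualifying gap censors rather than discontinues
  expect_equal(landmark_status(200, 70, 400, 183), "censored_switch")
  # same-day tie: switch dominates
  expect_equal(landmark_status(100, 100, 400, 183), "censored_switch")
  # events at or after the landmark leave the patient persistent
  expect_equal(landmark_status(183, NA, 400, 183), "persistent")
})

test_that("persistence summaries censor switches instead of flagging events", {
  members <- mk_members("p1", followup_day = 400)
  rx <- validate_ehr_table(dplyr::bind_rows(
    mk_rx(0, "warfarin"), mk_rx(70, "rivaroxaban")
  ), "prescriptions")
  per <- persistence_summary(members, rx)
  expect_equal(per$switch_days, 70)
  expect_equal(per$status_6m, "censored_switch")
  expect_false(per$event_flag)
  expect_equal(per$event_time_days, 70)
})

test_that("raising the gap threshold never decreases the persistent count", {
  withr::with_seed(55, {
    streams <- purrr::map(1:40, ~ random_stream(sample(2:15, 1), max_gap = 150))
    members <- mk_members(sprintf("p%02d", 1:40), followup_day = 800)
    rx <- validate_ehr_table(
      dplyr::bind_rows(purrr::imap(
        streams, ~ mk_rx(.x, id = sprintf("p%02d", .y))
      )),
      "prescriptions"
    )
    counts <- purrr::map_int(c(60, 90, 120, 200), function(thr) {
      cfg <- study_config(gap_threshold_days = thr)
      per <- persistence_summary(members, rx, cfg)
      sum(per$status_12m == "persistent")
    })
    expect_true(all(diff(counts) >= 0))
  })
})

test_that("persistence is non-increasing from the 6- to the 12-month landmark", {
  sim <- simulate_ehr(generator_config(n_patients = 500, seed = 61))
  for (cls in drug_classes) {
    m <- build_cohort(sim[ehr_table_kinds], cls)
    per <- persistence_summary(m, sim$prescriptions)
    eligible <- per[per$followup_days >= 365 & !per$primary_nonadherent, ]
    p6 <- mean(eligible$status_6m == "persistent")
    p12 <- mean(eligible$status_12m == "persistent")
    expect_lte(p12, p6)
  }
})

test_that("early discontinuers converge to full non-persistence", {
  cfg <- generator_config(
    n_patients = 300, seed = 71,
    p_prescribed_liver = 1, p_prescribed_nonliver = 1,
    archetype_weights = c(
      primary_nonadherent = 0, steady_refiller = 0,
      irregular_refiller = 0, early_discontinuer = 1
    ),
    early_stop_p = 0.8, switch_probability = 0
  )
  sim <- simulate_ehr(cfg)
  res <- purrr::map(drug_classes, function(cls) {
    m <- build_cohort(sim[ehr_table_kinds], cls)
    per <- persistence_summary(m, sim$prescriptions)
    per[per$followup_days >= 365 & !per$primary_nonadherent, ]
  })
  eligible <- dplyr::bind_rows(res)
  expect_gt(nrow(eligible), 50)
  expect_gt(mean(eligible$status_12m == "non_persistent"), 0.95)
})

test_that("joint cells partition the landmark-eligible denominator", {
  sim <- simulate_ehr(generator_config(n_patients = 600, seed = 83))
  for (cls in drug_classes) {
    m <- build_cohort(sim[ehr_table_kinds], cls)
    adh <- adherence_summary(m, sim$prescriptions, window = "12m")
    per <- persistence_summary(m, sim$prescriptions)
    joint <- joint_classification(adh, per, "12m", by = NULL)
    expect_equal(sum(joint$k), sum(adh$eligible))
    expect_equal(unique(joint$n), sum(adh$eligible))
    expect_equal(sum(joint$percent), 100, tolerance = 1e-9)
  }
})
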
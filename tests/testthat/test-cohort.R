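dx <- function(id, cond, date, source = "primary_care") {
  tibble::tibble(
    patient_id = id, event_date = as.Date(date), condition = cond,
    source = source
  )
}

test_that("liver status aggregates subtypes and takes the earliest date", {
  d <- dplyr::bind_rows(
    dx("p1", "cirrhosis", "2010-03-01"),
    dx("p1", "NAFLD", "2012-06-01"),
    dx("p2", "hypertension", "2011-01-01")
  )
  out <- classify_liver_status(validate_ehr_table(d, "diagnoses"))
  p1 <- out[out$patient_id == "p1", ]
  expect_equal(p1$liver_status, "with_liver_disease")
  expect_setequal(p1$liver_subtypes[[1]], c("cirrhosis", "NAFLD"))
  expect_equal(p1$liver_first_date, as.Date("2010-03-01"))
  p2 <- out[out$patient_id == "p2", ]
  expect_equal(p2$liver_status, "without_liver_disease")
  expect_true(is.na(p2$liver_first_date))
})

test_that("indications must be incident to prevalent liver disease", {
  d <- dplyr::bind_rows(
    dx("p1", "cirrhosis", "2010-01-01"),
    dx("p1", "atrial_fibrillation", "2012-01-01"),
    dx("p2", "cirrhosis", "2010-01-01"),
    dx("p2", "atrial_fibrillation", "2008-01-01"),
    dx("p3", "atrial_fibrillation", "2009-01-01")
  )
  d <- validate_ehr_table(d, "diagnoses")
  li <- classify_liver_status(d)
  ind <- find_incident_indication(d, li, "anticoagulant")
  expect_equal(ind$patient_id, c("p1", "p3")) # p2's AF precedes liver disease
  expect_equal(
    ind$indication_date[ind$patient_id == "p1"],
    as.Date("2012-01-01")
  )
})

test_that("the earliest qualifying antiplatelet indication is selected", {
  d <- dplyr::bind_rows(
    dx("p1", "cirrhosis", "2011-01-01"),
    dx("p1", "myocardial_infarction", "2015-05-01"),
    dx("p1", "transient_ischaemic_attack", "2013-02-01")
  )
  d <- validate_ehr_table(d, "diagnoses")
  ind <- find_incident_indication(d, classify_liver_status(d), "antiplatelet")
  expect_equal(ind$indication_condition, "transient_ischaemic_attack")
  expect_equal(ind$indication_date, as.Date("2013-02-01"))

  # exhaustive-scan oracle on a randomised event set
  withr::with_seed(42, {
    conds <- c(
      "myocardial_infarction", "peripheral_arterial_disease",
      "unstable_angina", "transient_ischaemic_attack", "hypertension"
    )
    events <- tibble::tibble(
      patient_id = "px",
      event_date = as.Date("2012-01-01") + sample.int(2000, 30),
      condition = sample(conds, 30, replace = TRUE),
      source = "primary_care"
    )
    liver_row <- dx("px", "NAFLD", "2011-06-01")
    d2 <- validate_ehr_table(dplyr::bind_rows(liver_row, events), "diagnoses")
    got <- find_incident_indication(d2, classify_liver_status(d2), "antiplatelet")
    qualifying <- events[events$condition != "hypertension" &
      events$event_date > as.Date("2011-06-01"), ]
    expect_equal(got$indication_date, min(qualifying$event_date))
  })
})

test_that("the drug-naive filter is class-specific and strict", {
  members <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    indication_class = "anticoagulant",
    indication_date = as.Date("2015-01-01")
  )
  rx <- validate_ehr_table(dplyr::bind_rows(
    mk_rx(0, "warfarin", "p1", as.Date("2013-01-01")), # prior same class
    mk_rx(0, "aspirin", "p2", as.Date("2013-01-01")), # prior other class
    mk_rx(0, "warfarin", "p3", as.Date("2015-01-01")) # on the index day
  ), "prescriptions")
  kept <- apply_drug_naive_filter(members, rx)
  expect_setequal(kept$patient_id, c("p2", "p3"))
})

test_that("planted pre-indication prescriptions are removed exactly", {
  sim <- simulate_ehr(generator_config(
    n_patients = 600, seed = 13, p_pre_indication_rx = 0.1
  ))
  tables <- sim[ehr_table_kinds]
  for (cls in drug_classes) {
    unfiltered <- build_cohort(tables, cls, drug_naive = FALSE)
    filtered <- build_cohort(tables, cls, drug_naive = TRUE)
    removed <- setdiff(unfiltered$patient_id, filtered$patient_id)
    planted <- sim$truth$patient_id[sim$truth$pre_indication_rx &
      sim$truth$indication_class == cls]
    expect_setequal(removed, intersect(planted, unfiltered$patient_id))
  }
})

test_that("classified liver prevalence matches the generator bookkeeping", {
  sim <- simulate_ehr(generator_config(n_patients = 1000, seed = 3, liver_prevalence = 0.3))
  li <- classify_liver_status(sim$diagnoses)
  expect_equal(
    sum(li$liver_status == "with_liver_disease"),
    sum(sim$truth$liver)
  )
})

test_that("follow-up ends at the earliest anchor with the stated tie priority", {
  ac <- as.Date("2020-06-30")
  # death before admin censor
  fe <- resolve_followup_end(
    death_date = as.Date("2018-05-01"),
    admin_censor_date = ac
  )
  expect_equal(fe$followup_end, as.Date("2018-05-01"))
  expect_equal(fe$followup_end_reason, "death")

  # nothing else: admin censoring
  fe2 <- resolve_followup_end(admin_censor_date = ac)
  expect_equal(fe2$followup_end, ac)
  expect_equal(fe2$followup_end_reason, "admin_censor")

  # same-day ties resolve by the reason priority, for every pair
  reasons <- c("endpoint", "death", "last_collection", "deregistration")
  args <- c(
    "endpoint_date", "death_date", "last_collection_date",
    "deregistration_date"
  )
  tie_day <- as.Date("2016-01-01")
  for (i in seq_along(reasons)) {
    for (j in seq_along(reasons)) {
      if (i == j) next
      a <- list(admin_censor_date = ac)
      a[[args[i]]] <- tie_day
      a[[args[j]]] <- tie_day
      fe <- do.call(resolve_followup_end, a)
      expect_equal(fe$followup_end, tie_day)
      expect_equal(fe$followup_end_reason, reasons[min(i, j)])
    }
  }
})

test_that("liver and non-liver members partition each class cohort", {
  sim <- simulate_ehr(generator_config(n_patients = 500, seed = 19))
  for (cls in drug_classes) {
    m <- build_cohort(sim[ehr_table_kinds], cls)
    expect_equal(
      sum(m$liver_status == "with_liver_disease") +
        sum(m$liver_status == "without_liver_disease"),
      nrow(m)
    )
  }
})
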
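lex <- default_lexicon()

# ten monthly visits starting at `from` — passes the visit-count gate
dates10 <- function(from = "2000-01-15") {
  seq(as.Date(from), by = "month", length.out = 10)
}

patients_df <- function(ids, birth_years) {
  data.frame(
    patient_id = ids, sex = "F", birth_year = birth_years,
    stringsAsFactors = FALSE
  )
}

test_that("patients with fewer than 10 visits in any window are dropped", {
  rec <- rbind(
    make_records("P1", dates10()), # 10 visits -> kept
    make_records("P2", dates10()[1:9]) # 9 visits -> dropped
  )
  tl <- build_timelines(rec, lex, patients = patients_df(c("P1", "P2"), 1950))
  out <- apply_inclusion(tl)
  expect_equal(unique(out$timelines$records$patient_id), "P1")
  aud <- as.data.frame(out$audit)
  expect_equal(
    aud$patients_removed[aud$stage == "sparse_patients"], 1L
  )
})

test_that("visits spread too thin fail the sliding 10-year window", {
  # 12 visits over 22 years, never 10 inside one decade
  sparse_dates <- seq(as.Date("1997-01-01"), by = "22 month", length.out = 12)
  rec <- make_records("P1", sparse_dates)
  tl <- build_timelines(rec, lex, patients = patients_df("P1", 1950))
  out <- apply_inclusion(tl)
  expect_equal(nrow(out$timelines$records), 0L)
})

test_that("the text gate is strict: exactly 100 characters is excluded", {
  note100 <- strrep("x", 100)
  note101 <- strrep("x", 101)
  rec <- rbind(
    make_records("P1", dates10(), note = note100),
    make_records("P2", dates10(), note = note101)
  )
  tl <- build_timelines(rec, lex, patients = patients_df(c("P1", "P2"), 1950))
  out <- apply_inclusion(tl)
  expect_equal(unique(out$timelines$records$patient_id), "P2")
  aud <- as.data.frame(out$audit)
  expect_equal(aud$records_removed[aud$stage == "short_text_records"], 10L)
})

test_that("O24 removes the whole patient before the E11 gate", {
  rec <- rbind(
    make_records("P1", dates10(), diagnoses = "O24.4;E11.9"),
    make_records("P2", dates10(), diagnoses = "E11.9")
  )
  tl <- build_timelines(rec, lex, patients = patients_df(c("P1", "P2"), 1950))
  out <- apply_inclusion(tl)
  aud <- as.data.frame(out$audit)
  expect_equal(aud$patients_removed[aud$stage == "o24_patients"], 1L)
  expect_equal(aud$patients_removed[aud$stage == "e11_records"], 0L)
  expect_equal(unique(out$timelines$records$patient_id), "P2")
})

test_that("records without an E11-branch diagnosis are dropped record-wise", {
  d <- dates10()
  rec <- make_records("P1", d, diagnoses = "E11.5;I10")
  rec$diagnoses[3] <- "I10;K21.0" # one non-diabetic record
  # still >= 10 records needed to survive the visit gate: add one more
  rec <- rbind(rec, make_records("P1", max(d) + 30, diagnoses = "E11"))
  tl <- build_timelines(rec, lex, patients = patients_df("P1", 1950))
  out <- apply_inclusion(tl)
  expect_equal(nrow(out$timelines$records), 10L)
  aud <- as.data.frame(out$audit)
  expect_equal(aud$records_removed[aud$stage == "e11_records"], 1L)
})

test_that("audit conserves records and patients through the cascade", {
  cfg <- cohort_config(150,
    seed = 11, frac_non_e11 = 0.2, frac_o24 = 0.1,
    frac_short_text = 0.1, frac_sparse = 0.15, frac_under30 = 0.05
  )
  coh <- generate_cohort(cfg)
  tl <- build_timelines(coh$records, lex, patients = coh$patients)
  out <- apply_inclusion(tl)
  aud <- as.data.frame(out$audit)
  first <- aud[aud$stage == "input", ]
  last <- aud[nrow(aud), ]
  expect_equal(
    first$records_left - sum(aud$records_removed),
    last$records_left
  )
  expect_equal(
    first$patients_left - sum(aud$patients_removed),
    last$patients_left
  )
  expect_equal(last$records_left, nrow(out$timelines$records))
  # monotone non-increasing counts
  expect_true(all(diff(aud$records_left) <= 0))
  expect_true(all(diff(aud$patients_left) <= 0))

  # patient-level removals match the planted decoy roles exactly
  roles <- table(coh$truth$roles$role)
  stage_of <- c(
    o24 = "o24_patients", non_e11 = "e11_records",
    short_text = "short_text_records", sparse = "sparse_patients",
    under30 = "under_age_patients"
  )
  for (role in names(stage_of)) {
    planted <- if (role %in% names(roles)) as.integer(roles[[role]]) else 0L
    expect_equal(
      aud$patients_removed[aud$stage == stage_of[[role]]],
      planted,
      info = role
    )
  }
  expect_equal(last$patients_left, as.integer(roles["clean"]))
})

test_that("the cascade is idempotent", {
  coh <- generate_cohort(cohort_config(60, seed = 2, frac_non_e11 = 0.2))
  tl <- build_timelines(coh$records, lex, patients = coh$patients)
  once <- apply_inclusion(tl)
  twice <- apply_inclusion(once$timelines)
  expect_equal(twice$timelines$records, once$timelines$records)
  aud2 <- as.data.frame(twice$audit)
  expect_true(all(aud2$records_removed == 0L))
  expect_true(all(aud2$patients_removed == 0L))
})

test_that("age groups assign by completed age at first surviving record", {
  rec <- make_records("P1", c(as.Date("1999-06-01"), dates10("2000-01-15")))
  tl <- build_timelines(rec, lex, patients = patients_df("P1", 1950))
  out <- apply_inclusion(tl)
  ag <- assign_age_group(out$timelines)
  expect_equal(ag$entry_age, 49L)
  expect_equal(ag$age_group, "40-49")
})

test_that("age-group bounds are inclusive and 80+ is unbounded", {
  expect_equal(age_group_of(30), "30-39")
  expect_equal(age_group_of(39), "30-39")
  expect_equal(age_group_of(40), "40-49")
  expect_equal(age_group_of(80), "80+")
  expect_equal(age_group_of(95), "80+")
  expect_true(is.na(age_group_of(29)))
  expect_error(
    assign_age_group(
      build_timelines(make_records("P1", "2000-01-01")[0, ], lex)
    ),
    "no surviving record"
  )
})

test_that("long follow-up splits records across several age groups", {
  d <- c(
    seq(as.Date("1999-03-01"), by = "month", length.out = 10),
    as.Date(c("2004-06-01", "2011-06-01", "2012-06-01"))
  )
  rec <- make_records("P1", d)
  tl <- build_timelines(rec, lex, patients = patients_df("P1", 1950))
  out <- apply_inclusion(tl)
  mem <- age_group_membership(out$timelines)
  expect_setequal(unique(mem$age_group), c("40-49", "50-59", "60-69"))
  # single-visit membership (unfiltered timeline) lands in one group
  tl1 <- build_timelines(make_records("P9", "2000-07-01"), lex,
    patients = patients_df("P9", 1940)
  )
  expect_equal(unique(age_group_membership(tl1)$age_group), "60-69")
})

test_that("patients followed over ten years appear in two or more groups", {
  coh <- generate_cohort(cohort_config(50, seed = 9))
  tl <- build_timelines(coh$records, lex, patients = coh$patients)
  out <- apply_inclusion(tl)
  mem <- age_group_membership(out$timelines)
  span <- tapply(
    as.numeric(mem$visit_date), mem$patient_id,
    function(x) diff(range(x)) / 365.25
  )
  groups <- tapply(
    mem$age_group, mem$patient_id,
    function(g) length(unique(g))
  )
  long <- names(span)[span > 10]
  expect_true(all(groups[long] >= 2))
})
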
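rx_row <- function(id, dates, cls) {
  data.frame(patient_id = id, fill_date = dates, drug_class = cls)
}

test_that("sustained-use rule picks the earliest confirmed class", {
  # second fill at day 200: inside the 183-365 day window
  a <- assign_treatment_group(rx_row("p1", c(0, 200), "A"), "A")
  expect_equal(a$arm_class, "A")
  expect_equal(a$index_date, 0L)
  # second fill at ~3 months: outside the window
  a <- assign_treatment_group(rx_row("p1", c(0, 90), "A"), "A")
  expect_true(is.na(a$arm_class))
  # single fill: never sustained
  a <- assign_treatment_group(rx_row("p1", 0, "A"), "A")
  expect_true(is.na(a$arm_class))
  # window bounds are inclusive
  a <- assign_treatment_group(rx_row("p1", c(0, 183), "A"), "A")
  expect_equal(a$arm_class, "A")
  a <- assign_treatment_group(rx_row("p1", c(0, 365), "A"), "A")
  expect_equal(a$arm_class, "A")
  a <- assign_treatment_group(rx_row("p1", c(0, 366), "A"), "A")
  expect_true(is.na(a$arm_class))
})

test_that("competing sustained classes: earliest first fill wins, ties by priority", {
  rx <- rbind(rx_row("p1", c(0, 210), "B"), rx_row("p1", c(30, 250), "A"))
  a <- assign_treatment_group(rx, c("A", "B"))
  expect_equal(a$arm_class, "B")
  expect_equal(a$index_date, 0L)
  # identical first-fill dates: the first label in classes_of_interest wins
  rx <- rbind(rx_row("p1", c(0, 200), "B"), rx_row("p1", c(0, 250), "A"))
  expect_equal(assign_treatment_group(rx, c("A", "B"))$arm_class, "A")
  expect_equal(assign_treatment_group(rx, c("B", "A"))$arm_class, "B")
})

test_that("empty and unknown inputs are handled", {
  rx <- rx_row("p1", c(0, 200), "A")
  expect_warning(a <- assign_treatment_group(rx, c("A", "Z")), "Z")
  expect_equal(a$arm_class, "A")
  # a patient with fills of only out-of-interest classes gets no arm
  a <- assign_treatment_group(rx_row("p2", c(0, 200), "C"), c("A"),
                              window = c(183L, 365L)) |>
    suppressWarnings()
  expect_true(is.na(a$arm_class))
})

make_mini_stream <- function() {
  # three patients: p1 eligible, p2 no HbA1c, p3 prior HF
  patients <- data.frame(patient_id = c("p1", "p2", "p3"),
                         birth_year = c(1950, 1955, 1948),
                         sex = c("M", "F", "M"),
                         last_followup_date = c(2000L, 1900L, 1800L))
  rx <- rbind(rx_row("p1", c(100, 300), "insulin"),
              rx_row("p2", c(100, 300), "insulin"),
              rx_row("p3", c(100, 300), "glp1ra"))
  dx <- data.frame(
    patient_id = c("p1", "p2", "p3", "p3", "p1"),
    date = c(20L, 20L, 20L, 70L, 900L),
    code = c("icd_250.2", "icd_250.2", "icd_250.2", "icd_428.2", "icd_428.1"))
  labs <- data.frame(patient_id = c("p1", "p3"), date = c(50L, 60L),
                     lab_name = "hba1c", value = c(8.1, 7.5))
  coverage <- data.frame(patient_id = c("p1", "p2", "p3"),
                         start_date = 0L, end_date = 1500L,
                         plan_type = "MAPD")
  structure(list(patients = patients, rx_claims = rx, dx_claims = dx,
                 labs = labs, coverage = coverage,
                 code_map = default_code_map(5)),
            class = "claim_stream")
}

test_that("inclusion/exclusion attributes first-failing reasons and tallies attrition", {
  st <- make_mini_stream()
  asg <- assign_treatment_group(st$rx_claims, c("insulin", "glp1ra"))
  res <- apply_inclusion_exclusion(st, asg, st$code_map)
  el <- res$eligibility
  expect_true(is.na(el$reason[el$patient_id == "p1"]))
  expect_equal(el$reason[el$patient_id == "p2"], "no_hba1c")
  expect_equal(el$reason[el$patient_id == "p3"], "prior_hf")
  at <- res$attrition
  expect_equal(unname(at["input"]),
               unname(at["retained"] +
                        sum(at[c("no_arm", "no_hba1c", "coverage", "t1dm",
                                 "prior_hf")])))
  # a map without the HF phecodes is a configuration error
  bad_map <- data.frame(code = "icd_250.2", phecode = "250.2")
  expect_error(apply_inclusion_exclusion(st, asg, bad_map), "428")
})

test_that("follow-up takes the earlier of first HF and last follow-up", {
  el <- data.frame(patient_id = c("a", "b", "c"), arm_class = "insulin",
                   index_date = c(100L, 100L, 100L), arm = 1L,
                   reason = NA_character_)
  dx <- data.frame(patient_id = c("a", "c", "c"),
                   date = c(500L, 400L, 600L),
                   code = "icd_428.3")
  lf <- data.frame(patient_id = c("a", "b", "c"),
                   last_followup_date = c(2100L, 1600L, 2100L))
  cmap <- default_code_map(2)
  fu <- compute_follow_up(el, dx, cmap, lf)
  expect_equal(fu$follow_up_days[fu$patient_id == "a"], 400)
  expect_equal(fu$event[fu$patient_id == "a"], 1L)
  expect_equal(fu$follow_up_days[fu$patient_id == "b"], 1500)
  expect_equal(fu$event[fu$patient_id == "b"], 0L)
  # first occurrence wins when there are several HF codes
  expect_equal(fu$follow_up_days[fu$patient_id == "c"], 300)
  # same-day events get a positive half-day
  dx0 <- data.frame(patient_id = "a", date = 100L, code = "icd_428.1")
  fu0 <- compute_follow_up(el[1, ], dx0, cmap, lf)
  expect_equal(fu0$follow_up_days, 0.5)
  # inconsistent follow-up dates are a data error naming the patient
  bad <- data.frame(patient_id = "a", last_followup_date = 50L)
  expect_error(compute_follow_up(el[1, ], dx, cmap, bad), "a")
})

test_that("baseline features respect the one-year lookback window", {
  st <- make_mini_stream()
  # p1: two HbA1c results in window -> most recent wins; dx claims around
  # the boundary; a post-index statin fill must not count
  st$labs <- rbind(st$labs,
                   data.frame(patient_id = "p1", date = 70L,
                              lab_name = "hba1c", value = 9.9))
  st$dx_claims <- rbind(st$dx_claims, data.frame(
    patient_id = "p1", date = c(90L, 1L, 105L), code = "icd_phe_001"))
  st$rx_claims <- rbind(st$rx_claims,
                        rx_row("p1", c(95, 120), "statins"))
  el <- data.frame(patient_id = "p1", arm_class = "insulin",
                   index_date = 100L, arm = 1L, reason = NA_character_)
  f <- extract_baseline_features(el, st, st$code_map)
  expect_equal(f$hba1c, 9.9)           # date 70 beats date 50
  expect_true(is.na(f$ldl))            # never measured
  expect_equal(f$phe.phe_001, 2L)      # day 105 is post-index
  expect_equal(f$statins, 1L)          # day 120 is post-index
  expect_equal(f$disease_duration, round(80 / (365 / 12), 1))
})

test_that("cohort construction round-trips the generator's recorded truths", {
  cfg <- sim_config(n_patients = 400, seed = 31)
  st <- generate_claim_stream(cfg)
  b <- build_cohort(st, comparator = cfg$comparator_class)
  el <- b$eligibility
  m <- match(st$expected$patient_id, el$patient_id)
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  expect_true(all(same(st$expected$expected_arm, el$arm_class[m])))
  expect_true(all(same(st$expected$expected_index, el$index_date[m])))
  expect_true(all(same(st$expected$expected_reason, el$reason[m])))
  co <- b$cohort
  m2 <- match(co$patient_id, st$expected$patient_id)
  expect_equal(co$time * 365, st$expected$expected_time_days[m2])
  expect_equal(co$event, st$expected$expected_event[m2])
  at <- b$attrition
  expect_equal(unname(at["input"]),
               unname(at["retained"] +
                        sum(at[c("no_arm", "no_hba1c", "coverage", "t1dm",
                                 "prior_hf")])))
})

test_that("cohort construction is invariant to claim-row order", {
  cfg <- sim_config(n_patients = 150, seed = 32)
  st <- generate_claim_stream(cfg)
  st2 <- st
  set.seed(1)
  for (nm in c("rx_claims", "dx_claims", "labs", "coverage")) {
    st2[[nm]] <- st2[[nm]][sample(nrow(st2[[nm]])), , drop = FALSE]
    rownames(st2[[nm]]) <- NULL
  }
  b1 <- build_cohort(st, comparator = cfg$comparator_class)
  b2 <- build_cohort(st2, comparator = cfg$comparator_class)
  expect_equal(b1$cohort, b2$cohort, ignore_attr = TRUE)
  expect_equal(b1$attrition, b2$attrition)
})
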
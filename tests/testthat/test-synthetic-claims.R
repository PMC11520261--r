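test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(frac_male = 1.2), "frac_male")
  expect_error(sim_config(hazard_scale_by_arm = c(insulin = -1, comparator = 2)),
               "hazard_scale_by_arm")
  expect_error(sim_config(admin_end = 3, horizon_t = 5), "admin_end")
  expect_error(sim_config(ps_coefficients = c(bmi = 1)), "ps_coefficients")
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_patients = 300, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  s1 <- generate_claim_stream(cfg)
  s2 <- generate_claim_stream(cfg)
  expect_identical(s1[names(s1) != "config"], s2[names(s2) != "config"])
  cfg2 <- sim_config(n_patients = 300, seed = 12)
  expect_false(identical(generate_cohort(cfg)$time, generate_cohort(cfg2)$time))
})

test_that("null treatment model gives a balanced arm split", {
  cfg <- sim_config(n_patients = 10000, ps_coefficients = c(intercept = 0),
                    seed = 4)
  co <- generate_cohort(cfg)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(co$arm) - 0.5), 3 * se)
})

test_that("null-covariate exponential hazard matches the Weibull closed form", {
  cfg <- sim_config(
    n_patients = 10000, hazard_shape = 1,
    hazard_scale_by_arm = c(insulin = 5, comparator = 5),
    log_hazard_coefficients_by_arm = list(insulin = c(age = 0),
                                          comparator = c(age = 0)),
    censor_rate = 0, admin_end = 50, seed = 5)
  co <- generate_cohort(cfg)
  frac_free <- mean(co$time > 5)
  p <- exp(-1)
  expect_lt(abs(frac_free - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("generated covariate moments match the configuration", {
  cfg <- sim_config(n_patients = 10000, seed = 6)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$age) - cfg$age_mean), 3 * cfg$age_sd / 100)
  expect_lt(abs(mean(co$male) - cfg$frac_male), 3 * sqrt(0.25 / 10000))
  hb <- attr(co, "true_labs")$hba1c
  expect_lt(abs(mean(hb) - cfg$lab_means[["hba1c"]]),
            3 * cfg$lab_sds[["hba1c"]] / 100)
  expect_lt(abs(mean(is.na(co$cholesterol)) -
                  cfg$lab_missing_rates[["cholesterol"]]),
            3 * sqrt(0.15 * 0.85 / 10000))
})

test_that("true_survival oracle: closed form, boundaries, monotonicity, MC", {
  cfg0 <- sim_config(hazard_shape = 1,
                     hazard_scale_by_arm = c(insulin = 5, comparator = 5),
                     log_hazard_coefficients_by_arm =
                       list(insulin = c(age = 0), comparator = c(age = 0)))
  expect_equal(true_survival(cfg0, 1, 5)$value, exp(-1), tolerance = 1e-12)
  expect_equal(true_survival(cfg0, 1, 0)$value, 1.0)
  expect_error(true_survival(cfg0, 1, -1), "t must be")

  cfg <- sim_config(seed = 2)
  ts <- vapply(c(0, 1, 2, 5), function(t0)
    true_survival(cfg, 1, t0, n_draws = 5e4)$value, numeric(1))
  expect_true(all(diff(ts) <= 0))
  a <- true_survival(cfg, 0, 5, n_draws = 1e6, seed = 101)
  b <- true_survival(cfg, 0, 5, n_draws = 1e6, seed = 202)
  expect_lt(abs(a$value - b$value), 3 * sqrt(a$mc_se^2 + b$mc_se^2))
})

test_that("ground truth carries both effect scales with consistent signs", {
  cfg <- sim_config(seed = 3)
  gt <- ground_truth(cfg, 5, n_draws = 1e5)
  expect_equal(gt$ate_rate, -(gt$ate_surv), tolerance = 1e-12)
  expect_true(gt$S1_t >= 0 && gt$S1_t <= 1 && gt$S0_t >= 0 && gt$S0_t <= 1)
  # insulin arm has the shorter Weibull scale, hence the higher HF rate
  expect_gt(gt$ate_rate, 0)
  cov <- data.frame(age = c(60, 70), male = c(0, 1), hba1c = c(8, 9),
                    cholesterol = c(170, 170), hdl = c(45, 45),
                    ldl = c(90, 90))
  expect_length(gt$cate_fn(cov), 2)
})

test_that("claim streams script the documented fill and exclusion patterns", {
  cfg <- sim_config(n_patients = 2000, seed = 9)
  st <- generate_claim_stream(cfg)
  exp_ <- st$expected
  expect_setequal(
    unique(exp_$scenario),
    c("sustained", "nonsustained", "single", "other", "two_class", "tied"))
  # fraction of patients scripted with a pre-index HF code ~ configured
  # fraction (checked among patients with a recorded index date)
  p <- cfg$frac_prior_hf
  with_idx <- exp_[!is.na(exp_$expected_index), ]
  hf_codes <- paste0("icd_", c("428.1", "428.2", "428.3", "428.4"))
  idx_of <- with_idx$expected_index[match(st$dx_claims$patient_id,
                                          with_idx$patient_id)]
  pre_hf <- st$dx_claims$code %in% hf_codes & !is.na(idx_of) &
    st$dx_claims$date < idx_of
  frac_prior <- mean(with_idx$patient_id %in%
                       unique(st$dx_claims$patient_id[pre_hf]))
  expect_lt(abs(frac_prior - p), 3 * sqrt(p * (1 - p) / nrow(with_idx)))
  # non-sustained scripts place the second fill outside the 183-365 window
  ns <- exp_$patient_id[exp_$scenario == "nonsustained"]
  expect_true(all(is.na(exp_$expected_arm[exp_$scenario == "nonsustained"])))
  # sustained scripts have an expected index equal to their first class fill
  su <- exp_[exp_$scenario == "sustained", ]
  rx1 <- st$rx_claims[st$rx_claims$patient_id %in% su$patient_id &
                        st$rx_claims$drug_class %in%
                        c("insulin", cfg$comparator_class), ]
  first <- tapply(rx1$fill_date, rx1$patient_id, min)
  expect_equal(as.numeric(first[su$patient_id]),
               as.numeric(su$expected_index))
})

test_that("claim streams survive a write/read round trip", {
  cfg <- sim_config(n_patients = 120, seed = 14)
  st <- generate_claim_stream(cfg)
  dir <- withr::local_tempdir()
  write_claim_stream(st, dir)
  st2 <- read_claim_stream(dir)
  for (nm in c("patients", "rx_claims", "dx_claims", "labs", "coverage")) {
    expect_equal(st2[[nm]], st[[nm]], ignore_attr = TRUE)
  }
  b1 <- build_cohort(st, comparator = cfg$comparator_class)
  b2 <- build_cohort(st2, comparator = cfg$comparator_class)
  expect_equal(b1$cohort, b2$cohort, ignore_attr = TRUE)
})
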
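# Claim-stream mode of the synthetic generator. All dates are integer days
# from the study epoch (day 0 = study start, nominally 2016-01-01); windows
# use 1 year = 365 days, 6 months = 183 days.

DAYS_YEAR <- 365L
SUSTAIN_WINDOW <- c(183L, 365L)
HF_PHECODES <- c("428.1", "428.2", "428.3", "428.4")
T2DM_PHECODE <- "250.2"
T1DM_PHECODE <- "250.1"
QUALIFYING_PLANS <- c("Commercial, FI", "MAPD")

#' Default diagnosis-code to phecode map for synthetic streams
#'
#' The synthetic generator emits ICD-like codes of the form `icd_<phecode>`;
#' real analyses supply their own two-column map.
#'
#' @param n_phecode_features number of comorbidity features in the stream.
#' @return data.frame with columns `code` and `phecode`, covering the four
#'   heart-failure phecodes (428.1-428.4), type 1/2 diabetes, and the
#'   synthetic comorbidity features.
#' @export
default_code_map <- function(n_phecode_features = 40) {
  phe <- c(HF_PHECODES, T2DM_PHECODE, T1DM_PHECODE,
           sprintf("phe_%03d", seq_len(n_phecode_features)))
  data.frame(code = paste0("icd_", phe), phecode = phe,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic claim stream (raw-claims mode)
#'
#' Emits the five flat claims tables (patients, pharmacy claims, diagnosis
#' claims, labs, coverage spans) with scripted fill patterns — sustained use,
#' quick-switch (second fill at ~3 months), single fills, sustained use of an
#' out-of-comparison class, competing sustained classes, and exact first-fill
#' ties — plus scripted exclusion conditions (pre-index heart failure, no
#' HbA1c result, insufficient coverage, likely type 1 diabetes). The
#' generator records, for every patient, the arm, index date, exclusion
#' reason, and follow-up outcome that the curation rules *should* produce, so
#' cohort construction can be round-trip tested against an independent hand
#' application of the rules.
#'
#' @param config a [sim_config()].
#' @return object of class `claim_stream`: a list with data.frames
#'   `patients` (`patient_id`, `birth_year`, `sex`, `last_followup_date`),
#'   `rx_claims` (`patient_id`, `fill_date`, `drug_class`), `dx_claims`
#'   (`patient_id`, `date`, `code`), `labs`
#'   (`patient_id`, `date`, `lab_name`, `value`), `coverage` (`patient_id`,
#'   `start_date`, `end_date`, `plan_type`), plus `expected` (the recorded
#'   curation truths), `code_map`, and the `config`.
#' @export
generate_claim_stream <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 13L)
  n <- as.integer(config$n_patients)
  comp <- config$comparator_class
  classes <- c("insulin", comp)

  cov <- sim_draw_covariates(config, n)
  z <- sim_standardize(cov, config)
  pi_true <- stats::plogis(sim_lp(z, config$ps_coefficients))
  arm_bin <- stats::rbinom(n, 1, pi_true)          # arm if sustained normally

  scen_p <- c(nonsustained = config$frac_nonsustained,
              single = config$frac_single_fill,
              other = config$frac_other_class,
              two_class = config$frac_two_class,
              tied = config$frac_tied_first_fill)
  if (sum(scen_p) > 1) stop("scripted fill-pattern fractions sum to > 1")
  scen <- sample(c(names(scen_p), "sustained"), n, replace = TRUE,
                 prob = c(scen_p, 1 - sum(scen_p)))

  flag_prior_hf <- stats::runif(n) < config$frac_prior_hf
  flag_no_hba1c <- stats::runif(n) < config$frac_no_hba1c
  flag_short_cov <- stats::runif(n) < config$frac_short_coverage
  flag_t1dm <- stats::runif(n) < config$frac_t1dm

  enroll <- sample(0:400, n, replace = TRUE)
  index <- enroll + sample(0:60, n, replace = TRUE)
  gap <- sample(SUSTAIN_WINDOW[1]:SUSTAIN_WINDOW[2], n, replace = TRUE)

  # expected arm label from the fill pattern alone (hand rule application)
  arm_class <- ifelse(arm_bin == 1, "insulin", comp)
  two_first <- ifelse(stats::runif(n) < 0.5, "insulin", comp) # winner in two_class
  expected_arm <- character(n)
  expected_arm[scen == "sustained"] <- arm_class[scen == "sustained"]
  expected_arm[scen %in% c("nonsustained", "single", "other")] <- NA_character_
  expected_arm[scen == "two_class"] <- two_first[scen == "two_class"]
  expected_arm[scen == "tied"] <- "insulin"  # fixed priority: insulin first
  eff_arm_bin <- ifelse(is.na(expected_arm), arm_bin,
                        as.integer(expected_arm == "insulin"))

  # first-failing exclusion reason, in the documented attribution order
  expected_reason <- rep(NA_character_, n)
  expected_reason[flag_prior_hf] <- "prior_hf"
  expected_reason[flag_t1dm] <- "t1dm"
  expected_reason[flag_short_cov] <- "coverage"
  expected_reason[flag_no_hba1c] <- "no_hba1c"
  expected_reason[is.na(expected_arm)] <- "no_arm"
  eligible <- is.na(expected_reason)

  # outcome under the arm the curation should assign
  k <- config$hazard_shape
  lam <- ifelse(eff_arm_bin == 1, config$hazard_scale_by_arm[["insulin"]],
                config$hazard_scale_by_arm[["comparator"]])
  eta1 <- sim_lp(z, config$log_hazard_coefficients_by_arm$insulin)
  eta0 <- sim_lp(z, config$log_hazard_coefficients_by_arm$comparator)
  eta <- ifelse(eff_arm_bin == 1, eta1, eta0)
  t_event <- lam * (-log(stats::runif(n)) / exp(eta))^(1 / k)
  t_cens <- if (config$censor_rate > 0)
    stats::rexp(n, config$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, config$admin_end)
  event <- as.integer(t_event <= t_cens)
  fu_days <- pmax(1L, as.integer(round(DAYS_YEAR * pmin(t_event, t_cens))))

  expected <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    scenario = scen,
    expected_arm = expected_arm,
    expected_index = ifelse(is.na(expected_arm), NA_integer_, index),
    expected_reason = expected_reason,
    expected_time_days = ifelse(eligible, fu_days, NA_integer_),
    expected_event = ifelse(eligible, event, NA_integer_),
    stringsAsFactors = FALSE)
  pid <- expected$patient_id

  ## pharmacy claims -------------------------------------------------------
  rx <- vector("list", n)
  for (i in seq_len(n)) {
    cl <- arm_class[i]
    fills <- switch(scen[i],
      sustained = data.frame(fill_date = c(index[i], index[i] + gap[i]),
                             drug_class = cl),
      nonsustained = data.frame(fill_date = c(index[i], index[i] + 90L),
                                drug_class = cl),
      single = data.frame(fill_date = index[i], drug_class = cl),
      other = data.frame(fill_date = c(index[i], index[i] + gap[i]),
                         drug_class = "dpp4i_other"),
      two_class = {
        loser <- setdiff(classes, two_first[i])
        data.frame(
          fill_date = c(index[i], index[i] + gap[i],
                        index[i] + 30L, index[i] + 30L + gap[i]),
          drug_class = c(two_first[i], two_first[i], loser, loser))
      },
      tied = data.frame(
        fill_date = rep(c(index[i], index[i] + gap[i]), 2),
        drug_class = rep(classes, each = 2)))
    fills$patient_id <- pid[i]
    rx[[i]] <- fills
  }
  rx <- do.call(rbind, rx)
  # auxiliary medication fills in the baseline year (and a decoy after index)
  aux <- c(metformin = 0.7, statins = 0.8, sulfonylureas = 0.4,
           thiazolidinediones = 0.1)
  aux_rows <- list()
  for (m in names(aux)) {
    cnt <- stats::rpois(n, aux[[m]])
    idx <- rep(seq_len(n), cnt)
    if (length(idx)) {
      aux_rows[[m]] <- data.frame(
        patient_id = pid[idx],
        fill_date = index[idx] - sample(1:364, length(idx), replace = TRUE),
        drug_class = m)
    }
  }
  decoy <- data.frame(patient_id = pid, fill_date = index + 30L,
                      drug_class = "statins")
  rx <- rbind(rx[c("patient_id", "fill_date", "drug_class")],
              do.call(rbind, aux_rows), decoy)
  rownames(rx) <- NULL

  ## diagnosis claims ------------------------------------------------------
  dx <- list()
  dd_days <- pmax(0L, as.integer(round(30.4 * stats::rgamma(n, 0.5, scale = 8))))
  n_t2 <- ifelse(flag_t1dm, 1L, 1L + stats::rpois(n, 1))
  idx2 <- rep(seq_len(n), n_t2)
  dx$t2dm <- data.frame(
    patient_id = pid[idx2],
    date = pmax(0L, index[idx2] - dd_days[idx2] -
                  sample(0:60, length(idx2), replace = TRUE) *
                  (duplicated(idx2))),
    code = paste0("icd_", T2DM_PHECODE))
  # earliest T2DM dx defines disease duration; make it exactly index - dd
  first_t2 <- !duplicated(idx2)
  dx$t2dm$date[first_t2] <- pmax(0L, index[idx2[first_t2]] - dd_days[idx2[first_t2]])
  if (any(flag_t1dm)) {
    w <- which(flag_t1dm)
    idx1 <- rep(w, 3L)
    dx$t1dm <- data.frame(
      patient_id = pid[idx1],
      date = pmax(0L, index[idx1] - sample(30:300, length(idx1), replace = TRUE)),
      code = paste0("icd_", T1DM_PHECODE))
  }
  if (any(flag_prior_hf)) {
    w <- which(flag_prior_hf)
    dx$prior_hf <- data.frame(
      patient_id = pid[w],
      date = index[w] - 30L,
      code = paste0("icd_", sample(HF_PHECODES, length(w), replace = TRUE)))
  }
  ev <- which(eligible & event == 1)
  if (length(ev)) {
    dx$hf_event <- data.frame(
      patient_id = pid[ev],
      date = index[ev] + fu_days[ev],
      code = paste0("icd_", sample(HF_PHECODES, length(ev), replace = TRUE)))
  }
  # sparse comorbidity claims in the baseline year, plus post-index decoys
  phe <- sim_draw_phecodes(config, n)
  if (ncol(phe)) {
    cnt_mat <- as.matrix(phe)
    nz <- which(cnt_mat > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      idxp <- rep(nz[, 1], cnt_mat[nz])
      phe_name <- rep(colnames(cnt_mat)[nz[, 2]], cnt_mat[nz])
      dx$comorb <- data.frame(
        patient_id = pid[idxp],
        date = index[idxp] - sample(1:364, length(idxp), replace = TRUE),
        code = paste0("icd_", phe_name))
      post <- seq_len(nrow(nz)) %% 7 == 0
      if (any(post)) {
        dx$comorb_post <- data.frame(
          patient_id = pid[nz[post, 1]],
          date = index[nz[post, 1]] + 10L,
          code = paste0("icd_", colnames(cnt_mat)[nz[post, 2]]))
      }
    }
  }
  dx <- do.call(rbind, dx)
  rownames(dx) <- NULL

  ## labs -------------------------------------------------------------------
  labs <- list()
  w_h <- which(!flag_no_hba1c)
  labs$hba1c <- data.frame(
    patient_id = pid[w_h],
    date = index[w_h] - sample(30:300, length(w_h), replace = TRUE),
    lab_name = "hba1c", value = round(cov$hba1c[w_h], 2))
  for (nm in c("cholesterol", "hdl", "ldl")) {
    obs <- stats::runif(n) >= config$lab_missing_rates[[nm]]
    w <- which(obs)
    labs[[nm]] <- data.frame(
      patient_id = pid[w],
      date = index[w] - sample(1:364, length(w), replace = TRUE),
      lab_name = nm, value = round(cov[[nm]][w], 2))
  }
  labs <- do.call(rbind, labs)
  rownames(labs) <- NULL

  ## coverage ---------------------------------------------------------------
  last_fu <- ifelse(eligible, index + fu_days,
                    index + sample(100:1500, n, replace = TRUE))
  coverage <- data.frame(
    patient_id = pid,
    start_date = ifelse(flag_short_cov, enroll, pmax(0L, enroll - 200L)),
    end_date = ifelse(flag_short_cov, enroll + 179L,
                      as.integer(last_fu) + 400L),
    plan_type = sample(QUALIFYING_PLANS, n, replace = TRUE))

  patients <- data.frame(
    patient_id = pid,
    birth_year = as.integer(round(2016 + index / DAYS_YEAR - cov$age)),
    sex = ifelse(cov$male == 1, "M", "F"),
    last_followup_date = as.integer(last_fu),
    stringsAsFactors = FALSE)

  out <- list(patients = patients, rx_claims = rx, dx_claims = dx,
              labs = labs, coverage = coverage, expected = expected,
              code_map = default_code_map(config$n_phecode_features),
              config = config)
  class(out) <- "claim_stream"
  out
}

#' Write a claim stream to delimited flat files
#'
#' One tab-separated file per table (`patients.tsv`, `rx_claims.tsv`,
#' `dx_claims.tsv`, `labs.tsv`, `coverage.tsv`, `expected.tsv`,
#' `code_map.tsv`).
#'
#' @param stream a `claim_stream`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claim_stream <- function(stream, dir) {
  stopifnot(inherits(stream, "claim_stream"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "rx_claims", "dx_claims", "labs", "coverage",
               "expected", "code_map")) {
    utils::write.table(stream[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a claim stream from delimited flat files
#'
#' Counterpart of [write_claim_stream()]; `expected.tsv` and `code_map.tsv`
#' are optional.
#'
#' @param dir directory containing the tables.
#' @return a `claim_stream` (without a `config`).
#' @export
read_claim_stream <- function(dir) {
  rd <- function(nm, required = TRUE) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) {
      if (required) stop("missing claims table: ", f)
      return(NULL)
    }
    utils::read.delim(f, stringsAsFactors = FALSE)
  }
  out <- list(patients = rd("patients"), rx_claims = rd("rx_claims"),
              dx_claims = rd("dx_claims"), labs = rd("labs"),
              coverage = rd("coverage"),
              expected = rd("expected", required = FALSE),
              code_map = rd("code_map", required = FALSE))
  class(out) <- "claim_stream"
  out
}
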
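# Cohort construction from raw claim streams: new-user, active-comparator
# design. Windows are half-open: baseline lookback [index-365, index),
# follow-up [index, end]; an index-day diagnosis counts as post-index.

#' Assign each patient to their earliest sustained drug class
#'
#' A class is *sustained* for a patient if the first fill of that class has
#' another fill of the same class between 183 and 365 days later
#' (inclusive). Among sustained classes the earliest first fill wins; exact
#' first-fill-date ties are broken by the order of `classes_of_interest`
#' (a fixed, documented priority). Patients with no sustained class of
#' interest get `arm_class = NA`.
#'
#' @param rx_claims data.frame with `patient_id`, `fill_date` (integer
#'   days), `drug_class`.
#' @param classes_of_interest character vector of candidate classes, in
#'   priority order (first = tie-break winner).
#' @param window length-2 integer vector: the sustained-use confirmation
#'   window in days after the first fill (default `c(183, 365)`).
#' @return data.frame `patient_id`, `arm_class`, `index_date` — one row per
#'   patient appearing in `rx_claims`.
#' @export
assign_treatment_group <- function(rx_claims,
                                   classes_of_interest,
                                   window = c(183L, 365L)) {
  stopifnot(all(c("patient_id", "fill_date", "drug_class") %in%
                  names(rx_claims)))
  if (length(classes_of_interest) < 1) stop("no classes_of_interest given")
  all_pat <- unique(rx_claims$patient_id)
  missing_cls <- setdiff(classes_of_interest, unique(rx_claims$drug_class))
  if (length(missing_cls))
    warning("classes_of_interest absent from rx_claims: ",
            paste(missing_cls, collapse = ", "))
  rx <- rx_claims[rx_claims$drug_class %in% classes_of_interest, , drop = FALSE]
  if (nrow(rx) == 0) {
    return(data.frame(patient_id = all_pat, arm_class = NA_character_,
                      index_date = NA_integer_, stringsAsFactors = FALSE))
  }
  key <- paste(rx$patient_id, rx$drug_class, sep = "\r")
  first_fill <- tapply(rx$fill_date, key, min)
  ff <- first_fill[key]
  confirmed <- rx$fill_date >= ff + window[1] & rx$fill_date <= ff + window[2]
  sust_key <- unique(key[confirmed])
  cand <- data.frame(
    patient_id = sub("\r.*", "", sust_key),
    arm_class = sub(".*\r", "", sust_key),
    index_date = as.integer(first_fill[sust_key]),
    stringsAsFactors = FALSE)
  cand$priority <- match(cand$arm_class, classes_of_interest)
  cand <- cand[order(cand$patient_id, cand$index_date, cand$priority), ]
  cand <- cand[!duplicated(cand$patient_id), c("patient_id", "arm_class",
                                               "index_date")]
  out <- merge(data.frame(patient_id = all_pat, stringsAsFactors = FALSE),
               cand, by = "patient_id", all.x = TRUE)
  out[order(out$patient_id), , drop = FALSE]
}

# Map raw diagnosis codes to phecodes; unmapped codes are dropped.
map_dx_phecodes <- function(dx_claims, code_map) {
  ph <- code_map$phecode[match(dx_claims$code, code_map$code)]
  out <- dx_claims
  out$phecode <- ph
  out[!is.na(ph), , drop = FALSE]
}

#' Apply inclusion and exclusion criteria
#'
#' Retains patients with a sustained arm among `c("insulin", comparator)`,
#' at least one HbA1c lab result, at least 365 cumulative days of qualifying
#' insurance coverage, no likely type 1 diabetes, and no heart-failure
#' phecode (428.1-428.4) strictly before the index date. Exclusion reasons
#' are attributed first-failing in the fixed order
#' `no_arm -> no_hba1c -> coverage -> t1dm -> prior_hf`, so attrition counts
#' sum exactly to the input patient count.
#'
#' The likely-type-1 rule is a transparent proxy: exclude when the type 1
#' diagnosis-code count exceeds the type 2 count, or type 1 codes are
#' present with no type 2 codes at all.
#'
#' @param stream a `claim_stream` (or list with the five claims tables).
#' @param assignments output of [assign_treatment_group()].
#' @param hf_code_map data.frame `code`, `phecode` covering at least the
#'   heart-failure phecodes; a configuration error is raised otherwise.
#' @param comparator comparator class label.
#' @param qualifying_plans plan types counting toward the coverage
#'   requirement.
#' @param min_coverage_days cumulative qualifying-coverage requirement.
#' @return list with `eligibility` (per-patient `patient_id`, `arm_class`,
#'   `index_date`, `arm`, `reason` — `NA` reason means retained) and
#'   `attrition` (reason counts plus `retained` and `input`).
#' @export
apply_inclusion_exclusion <- function(stream, assignments, hf_code_map,
                                      comparator = "glp1ra",
                                      qualifying_plans = QUALIFYING_PLANS,
                                      min_coverage_days = 365L) {
  if (!all(paste0("icd_", HF_PHECODES) %in% hf_code_map$code) &&
      !all(HF_PHECODES %in% hf_code_map$phecode))
    stop("hf_code_map does not cover the heart-failure phecodes 428.1-428.4")
  classes <- c("insulin", comparator)
  el <- assignments
  el$arm <- ifelse(is.na(el$arm_class), NA_integer_,
                   as.integer(el$arm_class == "insulin"))
  dx <- map_dx_phecodes(stream$dx_claims, hf_code_map)

  has_hba1c <- unique(stream$labs$patient_id[stream$labs$lab_name == "hba1c"])
  cov <- stream$coverage
  cov <- cov[cov$plan_type %in% qualifying_plans, , drop = FALSE]
  cov_days <- tapply(cov$end_date - cov$start_date + 1, cov$patient_id, sum)

  t1_cnt <- tapply(dx$phecode == T1DM_PHECODE, dx$patient_id, sum)
  t2_cnt <- tapply(dx$phecode == T2DM_PHECODE, dx$patient_id, sum)
  g0 <- function(v, ids) ifelse(is.na(v[ids]), 0, v[ids])
  t1 <- g0(t1_cnt, el$patient_id)
  t2 <- g0(t2_cnt, el$patient_id)

  hf <- dx[dx$phecode %in% HF_PHECODES, , drop = FALSE]
  idx_of <- el$index_date[match(hf$patient_id, el$patient_id)]
  prior_hf_ids <- unique(hf$patient_id[!is.na(idx_of) & hf$date < idx_of])

  reason <- rep(NA_character_, nrow(el))
  reason[!is.na(el$arm_class) & el$patient_id %in% prior_hf_ids] <- "prior_hf"
  reason[t1 > t2 | (t1 > 0 & t2 == 0)] <- "t1dm"
  reason[g0(cov_days, el$patient_id) < min_coverage_days] <- "coverage"
  reason[!el$patient_id %in% has_hba1c] <- "no_hba1c"
  reason[is.na(el$arm_class) | !el$arm_class %in% classes] <- "no_arm"
  el$reason <- reason

  attrition <- c(input = nrow(el),
                 no_arm = sum(reason == "no_arm", na.rm = TRUE),
                 no_hba1c = sum(reason == "no_hba1c", na.rm = TRUE),
                 coverage = sum(reason == "coverage", na.rm = TRUE),
                 t1dm = sum(reason == "t1dm", na.rm = TRUE),
                 prior_hf = sum(reason == "prior_hf", na.rm = TRUE),
                 retained = sum(is.na(reason)))
  list(eligibility = el, attrition = attrition)
}

#' Compute follow-up time and heart-failure event indicator
#'
#' Follow-up runs from the index date to the first post-index heart-failure
#' phecode (event = 1) or the patient's last follow-up date (event = 0),
#' whichever is earlier. An event on the index day itself gets time 0.5 day
#' so times stay strictly positive.
#'
#' @param eligibility retained rows of the `eligibility` table from
#'   [apply_inclusion_exclusion()].
#' @param dx_claims raw diagnosis claims.
#' @param hf_code_map code-to-phecode map.
#' @param last_followup data.frame `patient_id`, `last_followup_date`.
#' @return the eligibility table with `follow_up_days` and `event` added.
#' @export
compute_follow_up <- function(eligibility, dx_claims, hf_code_map,
                              last_followup) {
  el <- eligibility[is.na(eligibility$reason), , drop = FALSE]
  dx <- map_dx_phecodes(dx_claims, hf_code_map)
  hf <- dx[dx$phecode %in% HF_PHECODES, , drop = FALSE]
  m <- match(hf$patient_id, el$patient_id)
  hf <- hf[!is.na(m) & hf$date >= el$index_date[m], , drop = FALSE]
  first_hf <- tapply(hf$date, hf$patient_id, min)
  lf <- last_followup$last_followup_date[match(el$patient_id,
                                               last_followup$patient_id)]
  if (any(is.na(lf)))
    stop("missing last_followup_date for: ",
         paste(utils::head(el$patient_id[is.na(lf)]), collapse = ", "))
  if (any(lf < el$index_date))
    stop("last_followup_date before index_date for: ",
         paste(utils::head(el$patient_id[lf < el$index_date]), collapse = ", "))
  ev_date <- first_hf[el$patient_id]
  has_ev <- !is.na(ev_date) & ev_date <= lf
  el$event <- as.integer(has_ev)
  el$follow_up_days <- ifelse(has_ev, ev_date - el$index_date,
                              lf - el$index_date)
  el$follow_up_days[el$follow_up_days == 0] <- 0.5
  el
}

#' Extract baseline covariates from the claim stream
#'
#' For each retained patient: the most recent lab value in the 1-year
#' baseline window `[index-365, index)` per lab (missing if none), per-
#' phecode diagnosis counts in the same window, fill counts of the auxiliary
#' medication groups (metformin, statins, sulfonylureas,
#' thiazolidinediones), age at index, sex, and disease duration in months
#' (index date minus first type 2 diabetes diagnosis date).
#'
#' @param eligibility table with `patient_id`, `index_date` for retained
#'   patients.
#' @param stream the `claim_stream`.
#' @param code_map code-to-phecode map for comorbidity counting.
#' @param phecode_features optional character vector fixing which phecode
#'   count columns to emit (default: all non-outcome, non-diabetes phecodes
#'   in the map).
#' @return data.frame of baseline covariates, row-aligned with
#'   `eligibility`.
#' @export
extract_baseline_features <- function(eligibility, stream, code_map,
                                      phecode_features = NULL) {
  el <- eligibility
  n <- nrow(el)
  idx <- el$index_date

  # most recent lab in [index-365, index)
  labs <- stream$labs
  lab_names <- c("hba1c", "cholesterol", "hdl", "ldl")
  lab_out <- matrix(NA_real_, n, length(lab_names),
                    dimnames = list(NULL, lab_names))
  li <- match(labs$patient_id, el$patient_id)
  keep <- !is.na(li) & labs$date >= idx[li] - 365 & labs$date < idx[li]
  lb <- labs[keep, , drop = FALSE]
  li <- li[keep]
  ord <- order(lb$date)  # ascending; later assignments overwrite -> most recent
  for (nm in lab_names) {
    sel <- ord[lb$lab_name[ord] == nm]
    lab_out[li[sel], nm] <- lb$value[sel]
  }

  dx <- map_dx_phecodes(stream$dx_claims, code_map)
  di <- match(dx$patient_id, el$patient_id)
  in_win <- !is.na(di) & dx$date >= idx[di] - 365 & dx$date < idx[di]
  dxw <- dx[in_win, , drop = FALSE]
  if (is.null(phecode_features))
    phecode_features <- setdiff(unique(code_map$phecode),
                                c(HF_PHECODES, T2DM_PHECODE, T1DM_PHECODE))
  phe_out <- matrix(0L, n, length(phecode_features),
                    dimnames = list(NULL, phecode_features))
  dxc <- dxw[dxw$phecode %in% phecode_features, , drop = FALSE]
  if (nrow(dxc)) {
    tb <- table(factor(dxc$patient_id, levels = el$patient_id),
                factor(dxc$phecode, levels = phecode_features))
    phe_out <- matrix(as.integer(tb), nrow = n,
                      dimnames = list(NULL, phecode_features))
  }

  rx <- stream$rx_claims
  aux <- c("metformin", "statins", "sulfonylureas", "thiazolidinediones")
  ri <- match(rx$patient_id, el$patient_id)
  rin <- !is.na(ri) & rx$fill_date >= idx[ri] - 365 & rx$fill_date < idx[ri]
  rxw <- rx[rin & rx$drug_class %in% aux, , drop = FALSE]
  med_out <- matrix(0L, n, length(aux), dimnames = list(NULL, aux))
  if (nrow(rxw)) {
    tb <- table(factor(rxw$patient_id, levels = el$patient_id),
                factor(rxw$drug_class, levels = aux))
    med_out <- matrix(as.integer(tb), nrow = n, dimnames = list(NULL, aux))
  }

  t2 <- dx[dx$phecode == T2DM_PHECODE, , drop = FALSE]
  first_t2 <- tapply(t2$date, t2$patient_id, min)
  dd_days <- idx - first_t2[el$patient_id]
  dd_days[is.na(dd_days) | dd_days < 0] <- 0

  pat <- stream$patients
  pi_ <- match(el$patient_id, pat$patient_id)
  age <- (2016 + idx / DAYS_YEAR) - pat$birth_year[pi_]
  male <- as.integer(pat$sex[pi_] == "M")

  out <- data.frame(age = age, male = male, lab_out,
                    disease_duration = round(as.numeric(dd_days) / (365 / 12), 1),
                    med_out, check.names = FALSE)
  phe_df <- as.data.frame(phe_out)
  names(phe_df) <- make.names(paste0("phe.", phecode_features))
  cbind(out, phe_df)
}

#' Build the analytic cohort from a claim stream
#'
#' Runs arm assignment, inclusion/exclusion, follow-up construction, and
#' baseline feature extraction, returning one row per eligible patient in
#' the same schema as [generate_cohort()] (time in years).
#'
#' @param stream a `claim_stream`.
#' @param comparator comparator drug-class label.
#' @param code_map code-to-phecode map (default: the stream's own, if any).
#' @return list with `cohort` (data.frame), `attrition` (named counts), and
#'   `eligibility` (per-patient reasons).
#' @export
build_cohort <- function(stream, comparator = "glp1ra",
                         code_map = stream$code_map) {
  if (is.null(code_map)) stop("no code_map available")
  asg <- assign_treatment_group(stream$rx_claims,
                                classes_of_interest = c("insulin", comparator))
  incl <- apply_inclusion_exclusion(stream, asg, code_map,
                                    comparator = comparator)
  fu <- compute_follow_up(incl$eligibility, stream$dx_claims, code_map,
                          stream$patients)
  feats <- extract_baseline_features(fu, stream, code_map)
  cohort <- data.frame(patient_id = fu$patient_id, arm = fu$arm,
                       index_date = fu$index_date,
                       time = fu$follow_up_days / DAYS_YEAR,
                       event = fu$event,
                       feats, stringsAsFactors = FALSE, check.names = FALSE)
  list(cohort = cohort, attrition = incl$attrition,
       eligibility = incl$eligibility)
}
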
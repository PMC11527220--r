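# Target-trial emulation on longitudinal patient tables: eligibility,
# index/baseline dates, ATC-L3 comparator cohorts, ridge-logistic propensity
# scores with 1:1 nearest-neighbor matching and SMD balance gates, and Cox
# hazard-ratio estimation with patient-level bootstrap CIs.
#
# Expected tables (all plain tibbles/CSVs):
#   patients(id, birth_date, sex, race)
#   diagnoses(id, icd, date)
#   prescriptions(id, ingredient, atc, date)
# ICD matching is by code prefix, so "G20" matches "G20", "G20.9", ...

icd_match <- function(icd, codes) {
  if (length(codes) == 0) {
    return(rep(FALSE, length(icd)))
  }
  Reduce(`|`, lapply(codes, function(cd) startsWith(icd, cd)))
}

#' Apply trial eligibility criteria
#'
#' Keeps patients with at least one qualifying (index-condition) diagnosis,
#' aged at least `min_age` years at the first such diagnosis, and with no
#' exclusion diagnosis strictly before it. Patients without a birth date are
#' excluded and counted in the `n_missing_birth` attribute.
#'
#' @param patients Tibble `id`, `birth_date`, `sex`, `race`.
#' @param diagnoses Tibble `id`, `icd`, `date`.
#' @param codes List with elements `condition` (ICD prefixes defining the
#'   disease, e.g. `c("G20", "332.0")`) and `exclusion` (prior diagnoses
#'   that disqualify).
#' @param min_age Minimum age in years at first qualifying diagnosis
#'   (default 50).
#' @return Tibble `id`, `first_dx_date`, `age_at_dx` of eligible patients,
#'   with attribute `n_missing_birth`.
#' @export
apply_eligibility <- function(patients, diagnoses, codes, min_age = 50) {
  assert_cols(patients, c("id", "birth_date"), "patients")
  assert_cols(diagnoses, c("id", "icd", "date"), "diagnoses")
  stopifnot(!is.null(codes$condition))

  dx <- diagnoses |> mutate(date = as.Date(.data$date))
  first_dx <- dx |>
    filter(icd_match(.data$icd, codes$condition)) |>
    group_by(.data$id) |>
    summarise(first_dx_date = min(.data$date), .groups = "drop")

  out <- patients |>
    mutate(birth_date = as.Date(.data$birth_date)) |>
    inner_join(first_dx, by = "id")
  n_missing <- sum(is.na(out$birth_date))
  out <- out |>
    filter(!is.na(.data$birth_date)) |>
    mutate(age_at_dx = as.numeric(.data$first_dx_date - .data$birth_date) /
      365.25) |>
    filter(.data$age_at_dx >= min_age)

  excl <- dx |>
    filter(icd_match(.data$icd, codes$exclusion %||% character(0))) |>
    inner_join(out |> select("id", "first_dx_date"), by = "id") |>
    filter(.data$date < .data$first_dx_date) |>
    distinct(.data$id)
  out <- out |>
    anti_join(excl, by = "id") |>
    select("id", "first_dx_date", "age_at_dx")
  attr(out, "n_missing_birth") <- n_missing
  out
}

#' Assign initiation, index and baseline-window dates for one drug arm
#'
#' The disease initiation date is six calendar months before the first
#' qualifying diagnosis (latent disease is assumed present before formal
#' diagnosis). The index date is the first prescription of any of the arm's
#' ingredients. Patients are kept only if the index date is strictly after
#' initiation and the first outcome (if any) is strictly after the index
#' date; the baseline window is `[initiation, index)`.
#'
#' @param eligible Output of [apply_eligibility()].
#' @param prescriptions Tibble `id`, `ingredient`, `atc`, `date`.
#' @param arm_ingredients Ingredient codes defining the arm's exposure.
#' @param diagnoses Diagnosis tibble, used to locate outcomes.
#' @param outcome_codes ICD prefixes of the outcome.
#' @return Tibble `id`, `initiation`, `index_date`, `first_outcome` (`NA`
#'   if none), `censor_date` (last recorded event of any kind).
#' @export
assign_dates <- function(eligible, prescriptions, arm_ingredients, diagnoses,
                         outcome_codes) {
  rx <- prescriptions |> mutate(date = as.Date(.data$date))
  dx <- diagnoses |> mutate(date = as.Date(.data$date))

  idx <- rx |>
    filter(.data$ingredient %in% arm_ingredients) |>
    group_by(.data$id) |>
    summarise(index_date = min(.data$date), .groups = "drop")

  outc <- dx |>
    filter(icd_match(.data$icd, outcome_codes)) |>
    group_by(.data$id) |>
    summarise(first_outcome = min(.data$date), .groups = "drop")

  last_seen <- bind_rows(
    dx |> select("id", "date"),
    rx |> select("id", "date")
  ) |>
    group_by(.data$id) |>
    summarise(censor_date = max(.data$date), .groups = "drop")

  eligible |>
    mutate(
      initiation = lubridate::add_with_rollback(
        .data$first_dx_date, -lubridate::period(6, "months")
      )
    ) |>
    inner_join(idx, by = "id") |>
    left_join(outc, by = "id") |>
    left_join(last_seen, by = "id") |>
    filter(.data$index_date > .data$initiation) |>
    filter(is.na(.data$first_outcome) |
      .data$first_outcome > .data$index_date) |>
    select(
      "id", "first_dx_date", "age_at_dx", "initiation", "index_date",
      "first_outcome", "censor_date"
    )
}

atc_level3 <- function(atc) substr(atc, 1, 4)

#' Build treated and candidate-control cohorts for a tested drug
#'
#' The treated arm is the eligible patients exposed to the tested drug; the
#' candidate-control pool is the eligible patients exposed to any other drug
#' sharing an ATC level-3 class with it. A patient exposed to both is
#' assigned to the treated arm. Drugs (tested or comparator) used by fewer
#' than `min_users` patients are skipped entirely.
#'
#' @param eligible Output of [apply_eligibility()].
#' @param prescriptions Tibble `id`, `ingredient`, `atc`, `date`.
#' @param drug Ingredient code of the tested drug.
#' @param min_users Minimum distinct users for a drug to enter the analysis
#'   (default 100).
#' @return List with `treated_ingredients`, `comparator_ingredients`,
#'   `treated_ids`, `control_ids`.
#' @export
build_trial_cohorts <- function(eligible, prescriptions, drug,
                                min_users = 100L) {
  assert_cols(prescriptions, c("id", "ingredient", "atc", "date"),
    "prescriptions")
  catalog <- prescriptions |>
    distinct(.data$ingredient, .data$atc)
  if (!drug %in% catalog$ingredient) {
    abort(sprintf("drug '%s' absent from the prescription catalog", drug))
  }
  users <- prescriptions |>
    distinct(.data$ingredient, .data$id) |>
    count(.data$ingredient, name = "n_users")

  drug_l3 <- unique(atc_level3(catalog$atc[catalog$ingredient == drug]))
  comparators <- catalog |>
    mutate(l3 = atc_level3(.data$atc)) |>
    filter(.data$l3 %in% drug_l3, .data$ingredient != drug) |>
    distinct(.data$ingredient) |>
    inner_join(users, by = "ingredient") |>
    filter(.data$n_users >= min_users) |>
    pull("ingredient")
  drug_users <- users$n_users[users$ingredient == drug]
  if (length(drug_users) == 0 || drug_users < min_users) {
    warn(sprintf(
      "tested drug '%s' has fewer than %d users; cohorts are empty",
      drug, min_users
    ))
    return(list(
      treated_ingredients = drug, comparator_ingredients = comparators,
      treated_ids = character(0), control_ids = character(0)
    ))
  }

  exposed <- function(ingredients) {
    ids <- prescriptions |>
      filter(.data$ingredient %in% ingredients) |>
      distinct(.data$id) |>
      pull("id")
    intersect(eligible$id, ids)
  }
  treated_ids <- exposed(drug)
  control_ids <- setdiff(exposed(comparators), treated_ids)
  list(
    treated_ingredients = drug,
    comparator_ingredients = comparators,
    treated_ids = treated_ids,
    control_ids = control_ids
  )
}

#' Extract baseline covariate vectors
#'
#' Builds the covariate matrix used for propensity modeling: binary
#' comorbidity flags (ICD-prefix defined, from diagnoses in the baseline
#' window `[initiation, index)`), binary medication flags (ingredients
#' prescribed in the window), male sex, race dummies, and two continuous
#' covariates -- age at the index date and days from initiation to index.
#' Absent binary evidence is encoded 0 rather than missing.
#'
#' @param dates Output of [assign_dates()] for the arm.
#' @param patients Patient tibble.
#' @param diagnoses Diagnosis tibble.
#' @param prescriptions Prescription tibble.
#' @param covariate_spec List with `comorbidities` (named list of ICD prefix
#'   vectors) and `medications` (character vector of ingredient codes).
#' @return Tibble with `id` followed by one column per covariate.
#' @export
extract_covariates <- function(dates, patients, diagnoses, prescriptions,
                               covariate_spec) {
  dx <- diagnoses |>
    mutate(date = as.Date(.data$date)) |>
    inner_join(dates |> select("id", "initiation", "index_date"), by = "id") |>
    filter(.data$date >= .data$initiation, .data$date < .data$index_date)
  rx <- prescriptions |>
    mutate(date = as.Date(.data$date)) |>
    inner_join(dates |> select("id", "initiation", "index_date"), by = "id") |>
    filter(.data$date >= .data$initiation, .data$date < .data$index_date)

  out <- dates |> select("id", "initiation", "index_date")
  for (nm in names(covariate_spec$comorbidities %||% list())) {
    ids <- unique(dx$id[icd_match(dx$icd, covariate_spec$comorbidities[[nm]])])
    out[[paste0("cm_", nm)]] <- as.numeric(out$id %in% ids)
  }
  for (med in covariate_spec$medications %||% character(0)) {
    ids <- unique(rx$id[rx$ingredient == med])
    out[[paste0("rx_", med)]] <- as.numeric(out$id %in% ids)
  }
  demo <- patients |>
    mutate(birth_date = as.Date(.data$birth_date)) |>
    select("id", "birth_date", "sex", "race")
  out <- out |> left_join(demo, by = "id")
  out$sex_male <- as.numeric(out$sex %in% c("M", "male", "Male"))
  races <- sort(unique(out$race))
  for (r in races[-1]) { # first level is the reference
    out[[paste0("race_", r)]] <- as.numeric(out$race == r)
  }
  out$age <- as.numeric(out$index_date - out$birth_date) / 365.25
  out$time_to_index <- as.numeric(out$index_date - out$initiation)
  out |> select(-"initiation", -"index_date", -"birth_date", -"sex", -"race")
}

smd <- function(x1, x0) {
  v <- (stats::var(x1) + stats::var(x0)) / 2
  if (v == 0) {
    return(if (mean(x1) == mean(x0)) 0 else Inf)
  }
  abs(mean(x1) - mean(x0)) / sqrt(v)
}

#' Propensity-score estimation and 1:1 nearest-neighbor matching
#'
#' Fits a ridge-penalized logistic regression of treatment on the baseline
#' covariates (the penalty stabilizes the fit in the presence of many
#' correlated binary flags), then performs greedy 1:1 nearest-neighbor
#' matching without replacement on the logit-propensity scale, treated
#' patients visited in seeded random order (a deterministic order such as
#' decreasing score makes caliper exclusions systematically selective and
#' can imbalance covariates that feed the score). Matches farther apart than
#' the caliper (default 0.2 standard deviations of the logit propensity, the
#' conventional choice) are refused, so treated patients without a
#' comparable control drop out rather than forcing a bad pair. Balance is
#' assessed on the matched sample with the absolute standardized mean
#' difference \eqn{|m_1 - m_0| / \sqrt{(v_1 + v_0)/2}} per covariate; the
#' trial is balanced when at most 2% of covariates exceed SMD 0.2. Inverse
#' probability of treatment weights are also returned for diagnostics.
#'
#' @param treated_cov,control_cov Covariate tibbles from
#'   [extract_covariates()] (first column `id`).
#' @param lambda Ridge penalty (default 0.01).
#' @param caliper Maximum logit-propensity distance for a match:
#'   `"auto"` (0.2 SD of the logit propensity), a number, or `NULL` to
#'   disable.
#' @param seed Seed for the random visiting order of treated patients.
#' @param smd_cutoff Per-covariate balance limit (default 0.2).
#' @param max_unbalanced_frac Maximum tolerated fraction of unbalanced
#'   covariates (default 0.02).
#' @return A `matched_trial` list: `pairs` (treated/control id pairs with
#'   scores), `smd` tibble, `balanced` flag, `n_unmatched` treated left
#'   without a match, `propensity` per-patient tibble with IPTW weights.
#' @export
estimate_propensity_and_match <- function(treated_cov, control_cov,
                                          lambda = 0.01, caliper = "auto",
                                          smd_cutoff = 0.2,
                                          max_unbalanced_frac = 0.02,
                                          seed = 1L) {
  stopifnot(nrow(treated_cov) > 0, nrow(control_cov) > 0)
  stopifnot(identical(names(treated_cov), names(control_cov)))
  covs <- setdiff(names(treated_cov), "id")
  X <- as.matrix(bind_rows(treated_cov, control_cov)[covs])
  y <- c(rep(1, nrow(treated_cov)), rep(0, nrow(control_cov)))
  ids <- c(treated_cov$id, control_cov$id)

  fit <- glmnet::glmnet(
    X, y,
    family = "binomial", alpha = 0, lambda = lambda,
    standardize = TRUE
  )
  ps <- as.vector(predict(fit, newx = X, type = "response"))
  iptw <- ifelse(y == 1, 1 / ps, 1 / (1 - ps))
  lp <- stats::qlogis(pmin(pmax(ps, 1e-12), 1 - 1e-12))
  if (identical(caliper, "auto")) caliper <- 0.2 * sd(lp)

  lp_t <- lp[y == 1]
  lp_c <- lp[y == 0]
  ps_t <- ps[y == 1]
  ps_c <- ps[y == 0]
  ord <- with_seed(seed, sample.int(length(lp_t)))
  available <- rep(TRUE, length(lp_c))
  match_idx <- rep(NA_integer_, length(lp_t))
  for (i in ord) {
    cand <- which(available)
    if (length(cand) == 0) break
    j <- cand[which.min(abs(lp_c[cand] - lp_t[i]))]
    if (!is.null(caliper) && abs(lp_c[j] - lp_t[i]) > caliper) next
    match_idx[i] <- j
    available[j] <- FALSE
  }
  matched <- which(!is.na(match_idx))
  pairs <- tibble(
    treated_id = treated_cov$id[matched],
    control_id = control_cov$id[match_idx[matched]],
    ps_treated = ps_t[matched],
    ps_control = ps_c[match_idx[matched]]
  )

  Xt <- as.matrix(treated_cov[matched, covs, drop = FALSE])
  Xc <- as.matrix(control_cov[match_idx[matched], covs, drop = FALSE])
  smd_tbl <- tibble(
    covariate = covs,
    smd = vapply(seq_along(covs), function(k) smd(Xt[, k], Xc[, k]),
      numeric(1))
  )
  balanced <- mean(smd_tbl$smd > smd_cutoff) <= max_unbalanced_frac

  structure(
    list(
      pairs = pairs,
      smd = smd_tbl,
      balanced = balanced,
      n_unmatched = sum(is.na(match_idx)),
      propensity = tibble(id = ids, treated = y, ps = ps, iptw = iptw)
    ),
    class = "matched_trial"
  )
}

#' @export
print.matched_trial <- function(x, ...) {
  cat(sprintf(
    "<matched_trial> %d pairs (%d treated unmatched); max SMD %.3f; %s\n",
    nrow(x$pairs), x$n_unmatched, max(x$smd$smd),
    if (x$balanced) "balanced" else "NOT balanced"
  ))
  invisible(x)
}

#' Follow-up times from assigned dates
#'
#' Follow-up runs from the index date to the first outcome event or to the
#' censoring date (last recorded encounter), whichever comes first.
#'
#' @param dates Output of [assign_dates()].
#' @return Tibble `id`, `time` (days), `event` (0/1).
#' @export
followup_times <- function(dates) {
  dates |>
    transmute(
      id = .data$id,
      event = as.integer(!is.na(.data$first_outcome)),
      time = as.numeric(
        ifelse(is.na(.data$first_outcome),
          .data$censor_date - .data$index_date,
          .data$first_outcome - .data$index_date
        )
      )
    ) |>
    filter(.data$time > 0)
}

#' Hazard ratio of treatment on the matched sample
#'
#' Fits a Cox proportional-hazards model with treatment as the sole
#' covariate on the 1:1-matched sample and reports the hazard ratio with a
#' patient-level bootstrap confidence interval (patients resampled with
#' replacement, model refit per replicate). A trial with no outcome events
#' in one arm is flagged inestimable.
#'
#' @param matched A `matched_trial`.
#' @param followup Tibble `id`, `time`, `event` from [followup_times()]
#'   covering both arms.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `hr`, `ci_low`, `ci_high`, `p_value`, `n_pairs`,
#'   `n_events`, `estimable`.
#' @export
estimate_treatment_effect <- function(matched, followup, n_boot = 1000L,
                                      seed = 1L, conf_level = 0.95) {
  stopifnot(inherits(matched, "matched_trial"))
  df <- bind_rows(
    tibble(id = matched$pairs$treated_id, treated = 1),
    tibble(id = matched$pairs$control_id, treated = 0)
  ) |>
    inner_join(followup, by = "id")
  ev_by_arm <- df |>
    group_by(.data$treated) |>
    summarise(ev = sum(.data$event), .groups = "drop")
  if (nrow(ev_by_arm) < 2 || any(ev_by_arm$ev == 0)) {
    return(tibble(
      hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, n_pairs = nrow(matched$pairs),
      n_events = sum(df$event), estimable = FALSE
    ))
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ treated,
    data = df
  )
  hr <- unname(exp(coef(fit)))
  p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(nrow(df), nrow(df), replace = TRUE)
      dd <- df[take, ]
      if (length(unique(dd$treated)) < 2 || sum(dd$event) == 0) {
        return(NA_real_)
      }
      f <- tryCatch(
        survival::coxph(survival::Surv(time, event) ~ treated, data = dd),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (is.null(f)) NA_real_ else unname(exp(coef(f)))
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)
  tibble(
    hr = hr, ci_low = unname(qs[1]), ci_high = unname(qs[2]),
    p_value = p, n_pairs = nrow(matched$pairs),
    n_events = sum(df$event), estimable = TRUE
  )
}

#' Run a full set of emulated trials for one drug
#'
#' End-to-end emulation: eligibility, cohort construction against ATC-L3
#' comparators, then `n_emulations` trials that each subsample the control
#' pool (fraction `control_frac`), fit the propensity model, match 1:1,
#' gate on covariate balance, and estimate the hazard ratio on balanced
#' trials. The drug-level estimate is the median HR across balanced trials
#' with the medians of the per-trial bootstrap CI bounds; drugs with fewer
#' than `min_balanced` balanced trials are flagged excluded.
#'
#' @param patients,diagnoses,prescriptions The longitudinal tables.
#' @param drug Tested ingredient code.
#' @param codes List with `condition`, `exclusion` and `outcome` ICD prefix
#'   vectors.
#' @param covariate_spec Covariate definition, see [extract_covariates()].
#' @param n_emulations Number of emulated trials (default 100).
#' @param control_frac Fraction of the control pool drawn per trial.
#' @param n_boot Bootstrap replicates per trial.
#' @param min_balanced Minimum balanced trials for a reportable drug.
#' @param min_users Minimum users per drug.
#' @param lambda Ridge penalty of the propensity model.
#' @param seed Master seed; per-trial seeds are derived substreams.
#' @return An `emulation_result` list: `trials` tibble (one row per trial),
#'   `summary` one-row tibble with the median HR and CI, `drug`,
#'   `n_balanced` and the cohort sizes.
#' @export
emulate_trials <- function(patients, diagnoses, prescriptions, drug, codes,
                           covariate_spec, n_emulations = 100L,
                           control_frac = 0.8, n_boot = 1000L,
                           min_balanced = 10L, min_users = 100L,
                           lambda = 0.01, seed = 1L) {
  eligible <- apply_eligibility(patients, diagnoses, codes)
  cohorts <- build_trial_cohorts(eligible, prescriptions, drug,
    min_users = min_users)
  if (length(cohorts$treated_ids) == 0 || length(cohorts$control_ids) == 0) {
    abort("empty treated or control pool; cannot emulate trials")
  }

  arm_dates <- function(ids, ingredients) {
    assign_dates(
      eligible |> filter(.data$id %in% ids),
      prescriptions, ingredients, diagnoses, codes$outcome
    )
  }
  treated_dates <- arm_dates(cohorts$treated_ids, cohorts$treated_ingredients)
  control_dates <- arm_dates(
    cohorts$control_ids, cohorts$comparator_ingredients
  )
  if (nrow(treated_dates) == 0 || nrow(control_dates) == 0) {
    abort("no patients satisfy the date requirements in one of the arms")
  }

  treated_cov <- extract_covariates(
    treated_dates, patients, diagnoses, prescriptions, covariate_spec
  )
  control_cov <- extract_covariates(
    control_dates, patients, diagnoses, prescriptions, covariate_spec
  )
  fu <- bind_rows(
    followup_times(treated_dates),
    followup_times(control_dates)
  )

  trials <- purrr::map(seq_len(n_emulations), function(k) {
    sub_seed <- derive_seed(seed, paste0(drug, "/trial", k))
    ctrl_sub <- with_seed(sub_seed, {
      take <- sample.int(
        nrow(control_cov),
        max(1L, floor(control_frac * nrow(control_cov)))
      )
      control_cov[take, , drop = FALSE]
    })
    m <- estimate_propensity_and_match(treated_cov, ctrl_sub,
      lambda = lambda, seed = sub_seed)
    eff <- if (m$balanced) {
      estimate_treatment_effect(m, fu, n_boot = n_boot, seed = sub_seed)
    } else {
      tibble(
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = NA_real_, n_pairs = nrow(m$pairs),
        n_events = NA_integer_, estimable = FALSE
      )
    }
    bind_cols(
      tibble(
        trial = k, balanced = m$balanced,
        max_smd = max(m$smd$smd),
        frac_unbalanced = mean(m$smd$smd > 0.2)
      ),
      eff
    )
  }) |>
    bind_rows()

  ok <- trials |> filter(.data$balanced, .data$estimable)
  n_balanced <- nrow(ok)
  summary_row <- tibble(
    drug = drug,
    n_trials = n_emulations,
    n_balanced = n_balanced,
    excluded = n_balanced < min_balanced,
    median_hr = if (n_balanced > 0) stats::median(ok$hr) else NA_real_,
    median_ci_low = if (n_balanced > 0) stats::median(ok$ci_low) else NA_real_,
    median_ci_high = if (n_balanced > 0) {
      stats::median(ok$ci_high)
    } else {
      NA_real_
    },
    median_p = if (n_balanced > 0) stats::median(ok$p_value) else NA_real_
  )
  structure(
    list(
      drug = drug,
      trials = trials,
      summary = summary_row,
      n_treated = nrow(treated_cov),
      n_control_pool = nrow(control_cov),
      seed = seed
    ),
    class = "emulation_result"
  )
}

#' @export
print.emulation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<emulation_result> drug %s: %d/%d balanced trials; median HR %.3f [%.3f, %.3f]%s\n",
    x$drug, s$n_balanced, s$n_trials, s$median_hr, s$median_ci_low,
    s$median_ci_high, if (s$excluded) " (EXCLUDED: too few balanced)" else ""
  ))
  invisible(x)
}

#' @describeIn emulate_trials Per-trial tibble.
#' @param x An `emulation_result`.
#' @param ... Unused.
#' @method tidy emulation_result
#' @export
tidy.emulation_result <- function(x, ...) x$trials

#' @describeIn emulate_trials One-row drug-level summary.
#' @method glance emulation_result
#' @export
glance.emulation_result <- function(x, ...) x$summary
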
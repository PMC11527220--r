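# Hand-built micro-cohorts exercising every eligibility, dating and matching
# rule, plus small simulations for the statistical properties.

toy_codes <- list(condition = "G20", exclusion = "G30", outcome = "F03")

toy_patients <- function() {
  tibble::tibble(
    id = sprintf("P%02d", 1:10),
    birth_date = as.Date(c(
      "1950-01-01", # P01 eligible (age 60)
      "1968-06-01", # P02 too young at dx (age ~42)
      "1940-01-01", # P03 prior exclusion dx
      "1930-05-05", # P04 eligible
      "1945-12-31", # P05 eligible
      NA, # P06 missing birth date
      "1955-03-03", # P07 eligible
      "1949-10-10", # P08 eligible
      "1960-01-02", # P09 eligible (age exactly ~50)
      "1952-07-07" # P10 eligible
    )),
    sex = rep(c("F", "M"), 5),
    race = "white"
  )
}

toy_diagnoses <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      id = sprintf("P%02d", 1:10), icd = "G20",
      date = as.Date("2010-06-01")
    ),
    tibble::tibble(id = "P03", icd = "G30", date = as.Date("2008-01-01")),
    tibble::tibble(id = "P09", icd = "G20", date = as.Date("2010-01-02"))
  )
}

test_that("eligibility applies diagnosis, age and exclusion rules", {
  el <- apply_eligibility(toy_patients(), toy_diagnoses(), toy_codes)
  # P02 (young), P03 (prior exclusion), P06 (no birth date) are out
  expect_setequal(
    el$id, c("P01", "P04", "P05", "P07", "P08", "P09", "P10")
  )
  expect_equal(attr(el, "n_missing_birth"), 1L)
  # P09's first qualifying dx is the earlier record
  expect_equal(el$first_dx_date[el$id == "P09"], as.Date("2010-01-02"))
  # boundary: exactly 50 at dx is eligible
  expect_gte(min(el$age_at_dx), 50)

  p49 <- tibble::tibble(
    id = "Q1", birth_date = as.Date("1961-01-01"), sex = "F", race = "w"
  )
  d49 <- tibble::tibble(id = "Q1", icd = "G20", date = as.Date("2010-06-01"))
  expect_equal(nrow(apply_eligibility(p49, d49, toy_codes)), 0L)
})

test_that("date assignment uses calendar months and strict inequalities", {
  el <- tibble::tibble(
    id = "P1", first_dx_date = as.Date("2015-07-01"), age_at_dx = 60
  )
  rx <- tibble::tibble(
    id = "P1", ingredient = "drugA", atc = "C10AA01",
    date = as.Date("2015-03-01")
  )
  dx <- tibble::tibble(id = "P1", icd = "F03", date = as.Date("2016-01-01"))
  d <- assign_dates(el, rx, "drugA", dx, "F03")
  expect_equal(d$initiation, as.Date("2015-01-01")) # six calendar months
  expect_equal(d$index_date, as.Date("2015-03-01"))
  expect_equal(d$first_outcome, as.Date("2016-01-01"))

  # index on/before initiation -> dropped
  rx_early <- rx |> dplyr::mutate(date = as.Date("2015-01-01"))
  expect_equal(nrow(assign_dates(el, rx_early, "drugA", dx, "F03")), 0L)

  # outcome on the index date -> dropped (strictly later required)
  dx_same <- dx |> dplyr::mutate(date = as.Date("2015-03-01"))
  expect_equal(nrow(assign_dates(el, rx, "drugA", dx_same, "F03")), 0L)
})

test_that("cohorts are built from ATC-L3 comparators with user minimums", {
  el <- tibble::tibble(
    id = sprintf("P%02d", 1:8),
    first_dx_date = as.Date("2010-06-01"), age_at_dx = 60
  )
  rx <- tibble::tibble(
    id = c("P01", "P02", "P03", "P04", "P05", "P06", "P07", "P08", "P01"),
    ingredient = c(
      "tested", "tested", "tested", "altA", "altA", "altB",
      "other", "rare", "altA"
    ),
    atc = c(
      "C10AA01", "C10AA01", "C10AA01", "C10AA02", "C10AA02", "C10AA03",
      "N02BA01", "C10AA09", "C10AA02"
    ),
    date = as.Date("2010-07-01")
  )
  co <- build_trial_cohorts(el, rx, "tested", min_users = 2)
  expect_setequal(co$comparator_ingredients, "altA")
  expect_false("rare" %in% co$comparator_ingredients) # one user < 2
  expect_false("altB" %in% co$comparator_ingredients) # one user < 2
  expect_false("other" %in% co$comparator_ingredients) # other ATC-L3
  expect_setequal(co$treated_ids, c("P01", "P02", "P03"))
  # P01 took both tested and altA: treated takes precedence
  expect_false("P01" %in% co$control_ids)
  expect_setequal(co$control_ids, c("P04", "P05"))

  # with min_users = 1 the single-user comparators join the pool
  co1 <- build_trial_cohorts(el, rx, "tested", min_users = 1)
  expect_setequal(co1$comparator_ingredients, c("altA", "altB", "rare"))
  expect_setequal(co1$control_ids, c("P04", "P05", "P06", "P08"))

  expect_error(build_trial_cohorts(el, rx, "absent"), "absent")
  expect_warning(
    build_trial_cohorts(el, rx, "tested", min_users = 50),
    "fewer than"
  )
})

test_that("covariate extraction is confined to the baseline window", {
  dates <- tibble::tibble(
    id = c("P1", "P2"),
    initiation = as.Date("2010-01-01"),
    index_date = as.Date("2010-06-01")
  )
  patients <- tibble::tibble(
    id = c("P1", "P2"), birth_date = as.Date("1950-06-01"),
    sex = c("M", "F"), race = c("white", "black")
  )
  dx <- tibble::tibble(
    id = c("P1", "P1", "P2"),
    icd = c("I10", "E11", "I10"),
    date = as.Date(c("2010-02-01", "2010-08-01", "2009-12-01"))
  )
  rx <- tibble::tibble(
    id = "P1", ingredient = "aspirin", atc = "B01AC06",
    date = as.Date("2010-03-01")
  )
  spec <- list(
    comorbidities = list(hypertension = "I10", diabetes = "E11"),
    medications = "aspirin"
  )
  cov <- extract_covariates(dates, patients, dx, rx, spec)
  p1 <- cov[cov$id == "P1", ]
  p2 <- cov[cov$id == "P2", ]
  expect_equal(p1$cm_hypertension, 1) # inside the window
  expect_equal(p1$cm_diabetes, 0) # after index: baseline only
  expect_equal(p2$cm_hypertension, 0) # before initiation
  expect_equal(p1$rx_aspirin, 1)
  expect_equal(p2$rx_aspirin, 0) # no baseline events at all
  expect_equal(p1$sex_male, 1)
  expect_equal(p1$time_to_index, 151)
  expect_equal(p1$age, as.numeric(
    as.Date("2010-06-01") - as.Date("1950-06-01")
  ) / 365.25)
})

make_cov <- function(ids, conf, noise_seed) {
  withr::with_seed(noise_seed, tibble::tibble(
    id = ids,
    cm_conf = conf,
    cm_noise = rbinom(length(ids), 1, 0.3),
    age = rnorm(length(ids), 70, 5),
    time_to_index = runif(length(ids), 30, 300)
  ))
}

test_that("identical arms yield zero SMD and a balanced verdict", {
  tc <- make_cov(sprintf("T%02d", 1:40), rep(c(0, 1), 20), 1)
  cc <- tc |> dplyr::mutate(id = sprintf("C%02d", 1:40))
  m <- estimate_propensity_and_match(tc, cc)
  expect_true(m$balanced)
  expect_true(all(m$smd$smd < 0.05))
  expect_equal(nrow(m$pairs), 40L)
  # no control is used twice
  expect_equal(anyDuplicated(m$pairs$control_id), 0L)
})

test_that("matching reduces confounder imbalance in most seeded runs", {
  wins <- 0L
  for (s in 1:10) {
    dat <- withr::with_seed(s, {
      n_t <- 60
      n_c <- 150
      conf_t <- rbinom(n_t, 1, 0.7)
      conf_c <- rbinom(n_c, 1, 0.3)
      list(
        tc = make_cov(sprintf("T%03d", 1:n_t), conf_t, s + 100),
        cc = make_cov(sprintf("C%03d", 1:n_c), conf_c, s + 200)
      )
    })
    pre <- abs(mean(dat$tc$cm_conf) - mean(dat$cc$cm_conf)) /
      sqrt((var(dat$tc$cm_conf) + var(dat$cc$cm_conf)) / 2)
    m <- estimate_propensity_and_match(dat$tc, dat$cc)
    post <- m$smd$smd[m$smd$covariate == "cm_conf"]
    if (post < pre) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("null survival data give HR near 1 with a covering CI", {
  dat <- withr::with_seed(21, {
    n <- 300
    tibble::tibble(
      id = sprintf("P%03d", 1:n),
      time = rexp(n, 0.01),
      event = as.integer(runif(n) < 0.8)
    )
  })
  pairs <- tibble::tibble(
    treated_id = dat$id[1:150], control_id = dat$id[151:300],
    ps_treated = 0.5, ps_control = 0.5
  )
  m <- structure(
    list(pairs = pairs, smd = tibble::tibble(covariate = "x", smd = 0),
      balanced = TRUE, n_unmatched = 0L),
    class = "matched_trial"
  )
  eff <- estimate_treatment_effect(m, dat, n_boot = 200, seed = 2)
  expect_true(eff$estimable)
  expect_gt(eff$hr, 0.7)
  expect_lt(eff$hr, 1.4)
  expect_lte(eff$ci_low, 1)
  expect_gte(eff$ci_high, 1)
})

test_that("permuting treatment labels centers the log-HR at zero", {
  dat <- withr::with_seed(31, tibble::tibble(
    id = sprintf("P%03d", 1:200),
    time = rexp(200, 0.02),
    event = as.integer(runif(200) < 0.9)
  ))
  log_hrs <- withr::with_seed(32, vapply(1:100, function(i) {
    ids <- sample(dat$id)
    pairs <- tibble::tibble(
      treated_id = ids[1:100], control_id = ids[101:200],
      ps_treated = 0.5, ps_control = 0.5
    )
    m <- structure(
      list(pairs = pairs, smd = tibble::tibble(covariate = "x", smd = 0),
        balanced = TRUE, n_unmatched = 0L),
      class = "matched_trial"
    )
    df <- dplyr::bind_rows(
      tibble::tibble(id = pairs$treated_id, treated = 1),
      tibble::tibble(id = pairs$control_id, treated = 0)
    ) |> dplyr::inner_join(dat, by = "id")
    fit <- survival::coxph(survival::Surv(time, event) ~ treated, data = df)
    unname(coef(fit))
  }, numeric(1)))
  expect_lt(abs(mean(log_hrs)), 0.1)
})

test_that("followup times censor at the last encounter", {
  dates <- tibble::tibble(
    id = c("A", "B"),
    first_dx_date = as.Date("2010-06-01"),
    age_at_dx = 60,
    initiation = as.Date("2010-01-01"),
    index_date = as.Date("2010-03-01"),
    first_outcome = as.Date(c("2010-05-01", NA)),
    censor_date = as.Date(c("2011-01-01", "2010-09-01"))
  )
  fu <- followup_times(dates)
  expect_equal(fu$time[fu$id == "A"], 61)
  expect_equal(fu$event[fu$id == "A"], 1L)
  expect_equal(fu$time[fu$id == "B"], 184)
  expect_equal(fu$event[fu$id == "B"], 0L)
})
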
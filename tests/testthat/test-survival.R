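hist_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    individual_id = sprintf("I%02d", seq_along(rows)),
    group = "wild",
    sex = "M",
    birth_year = vapply(rows, function(r) r$birth, numeric(1)),
    detection_years = lapply(rows, function(r) r$det),
    study_end_year = vapply(rows, function(r) r$end, numeric(1))
  )
}

test_that("return probability counts internal and terminal gaps correctly", {
  # every eligible 2-year gap is internal and followed by a return
  h <- hist_tbl(
    list(birth = 1, det = c(1, 2, 5, 6, 9, 10), end = 10),
    list(birth = 1, det = c(1, 4, 5), end = 5)
  )
  expect_equal(return_probability(h, gap = 2), 1.0)
  # terminal gaps never return
  h2 <- hist_tbl(
    list(birth = 1, det = c(1, 2, 3), end = 10),
    list(birth = 1, det = c(1, 2), end = 10)
  )
  expect_equal(return_probability(h2, gap = 2), 0.0)
  # mixture: one internal return, two terminal non-returns
  h3 <- hist_tbl(
    list(birth = 1, det = c(1, 5), end = 12),
    list(birth = 1, det = c(1, 2), end = 12)
  )
  expect_equal(return_probability(h3, gap = 2), 1 / 3)
  # no eligible gap
  h4 <- hist_tbl(list(birth = 1, det = c(9, 10), end = 10))
  expect_error(return_probability(h4, gap = 2), "eligible")
})

test_that("with perfect detection, dead wild birds never return", {
  sim <- simulate_detection_histories(500, 50, detection_prob = 1,
                                      study_years = 25, seed = 4)
  expect_equal(return_probability(sim$histories, gap = 2), 0)
})

test_that("fates follow the gap rule and zoo records pass through", {
  h <- hist_tbl(
    list(birth = 1, det = 2:6, end = 12),    # silent 6 y -> dead at age 6
    list(birth = 1, det = c(2, 12), end = 12)  # seen in final year -> censored
  )
  zoo <- tibble::tibble(
    individual_id = c("Z1", "Z2"), sex = "F",
    hatch_year = c(1, 1), death_year = c(8, NA), censor_year = c(NA, 12)
  )
  # with only two toy histories the empirical return probability is 0.5
  # (one internal return, one terminal silence), so set the cutoff above it
  fates <- assign_fates(h, zoo, gap_threshold = 2, return_prob_cutoff = 0.6)
  f1 <- fates[fates$individual_id == "I01", ]
  expect_true(f1$event)
  expect_equal(f1$exit_age, 6)  # last detection age 5 + 1
  f2 <- fates[fates$individual_id == "I02", ]
  expect_false(f2$event)
  expect_equal(f2$exit_age, 11)
  expect_true(fates$event[fates$individual_id == "Z1"])
  expect_equal(fates$exit_age[fates$individual_id == "Z1"], 7)
  expect_false(fates$event[fates$individual_id == "Z2"])
  expect_true(all(fates$exit_age > fates$entry_age))
})

test_that("with perfect detection assigned deaths equal truth plus the offset", {
  sim <- simulate_detection_histories(400, 100, detection_prob = 1,
                                      study_years = 30, seed = 6)
  fates <- assign_fates(sim$histories, sim$zoo_records)
  truth <- sim$truth
  wd <- dplyr::inner_join(fates[fates$group == "wild" & fates$event, ],
                          truth, by = "individual_id")
  # died in year d (last alive year d-1): last detection at age d-1-birth+...
  birth <- sim$histories$birth_year[match(wd$individual_id,
                                          sim$histories$individual_id)]
  expect_equal(wd$exit_age, wd$death_year - birth)
})

test_that("Cox fit matches a hand-written partial likelihood on 4 subjects", {
  rec <- tibble::tibble(
    individual_id = c("a", "b", "c", "d"),
    group = c("zoo", "wild", "zoo", "wild"),
    sex = "M",
    entry_age = 0,
    exit_age = c(1, 2, 3, 4),
    event = TRUE
  )
  fit <- fit_cox(rec)
  # interleaved event order keeps the likelihood bounded; risk sets at the
  # four event times are {a,b,c,d}, {b,c,d}, {c,d}, {d}; zoo z = (1,0,1,0)
  nll <- function(beta) {
    z <- c(1, 0, 1, 0)
    ll <- 0
    for (k in 1:4) {
      risk <- k:4
      ll <- ll + beta * z[k] - log(sum(exp(beta * z[risk])))
    }
    -ll
  }
  beta_hat <- optimize(nll, c(-10, 10), tol = 1e-9)$minimum
  expect_lt(abs(fit$beta - beta_hat), 1e-4)
  # a perfectly separated event order is flagged as monotone likelihood
  rec2 <- dplyr::mutate(rec, group = c("zoo", "zoo", "wild", "wild"))
  fit2 <- suppressWarnings(fit_cox(rec2))
  expect_true(fit2$monotone_flag)
})

test_that("hazard ratio is recovered from exponential survival times", {
  rec <- simulate_survival_times(2000, 2000, hazard_wild = 0.15, hr = 0.5,
                                 censor_age = 30, seed = 9)
  fit <- fit_cox(rec)
  expect_gt(fit$hr, 0.42)
  expect_lt(fit$hr, 0.60)
  expect_true(fit$ci[1] < 0.5 && fit$ci[2] > 0.5)
})

test_that("HR is invariant to time-unit rescaling", {
  rec <- simulate_survival_times(300, 300, seed = 10)
  fit_y <- fit_cox(rec)
  rec_m <- dplyr::mutate(rec, exit_age = exit_age * 12)
  fit_m <- fit_cox(rec_m)
  expect_equal(fit_y$hr, fit_m$hr, tolerance = 1e-8)
})

test_that("all-censored input gives unit survival and no Cox fit", {
  rec <- tibble::tibble(
    individual_id = as.character(1:6), group = rep(c("wild", "zoo"), 3),
    sex = "M", entry_age = 0, exit_age = 1:6, event = FALSE
  )
  km <- survival::survfit(survival::Surv(exit_age, event) ~ 1, data = rec)
  expect_true(all(km$surv == 1))
  expect_error(fit_cox(rec), "event")
})

test_that("survival quantiles read off the fitted curves", {
  rec <- simulate_survival_times(1000, 1000, hazard_wild = 0.15, hr = 0.5,
                                 censor_age = 60, seed = 11)
  fit <- fit_cox(rec)
  q <- survival_quantiles(fit, group = "wild", sex = "M")
  # exponential with rate ~0.15: median ~ log(2)/0.15 = 4.6
  expect_equal(q$age[q$prob == 0.5], log(2) / 0.15, tolerance = 0.15)
  expect_true(all(diff(q$age) > 0))
  # a stratum whose curve never falls below 0.5 has no median
  rec2 <- tibble::tibble(
    individual_id = as.character(1:40),
    group = rep(c("wild", "zoo"), 20), sex = "M", entry_age = 0,
    exit_age = c(rep(10, 38), 5, 5),
    event = c(rep(FALSE, 38), TRUE, TRUE)
  )
  fit2 <- fit_cox(rec2)
  q2 <- survival_quantiles(fit2, group = "wild", probs = 0.9)
  expect_true(is.na(q2$age))
})

test_that("pooled-baseline invariant: zero group coefficient reproduces KM", {
  rec <- simulate_survival_times(200, 200, seed = 12)
  # force the group coefficient to zero by fitting without the covariate
  km <- survival::survfit(survival::Surv(exit_age, event) ~ 1, data = rec)
  fit <- survival::coxph(survival::Surv(exit_age, event) ~ 1, data = rec)
  base <- survival::survfit(fit)
  expect_equal(base$surv, km$surv, tolerance = 0.02)
})

test_that("detection pipeline HR matches the analytic discrete-hazard ratio", {
  # yearly survival 0.85 vs 0.93 implies a hazard ratio of
  # log(0.93)/log(0.85) ~ 0.45 on the continuous scale
  sim <- simulate_detection_histories(2000, 2000,
                                      annual_survival_wild = 0.85,
                                      annual_survival_zoo = 0.93,
                                      detection_prob = 1,
                                      study_years = 30, seed = 21)
  fates <- assign_fates(sim$histories, sim$zoo_records)
  fit <- fit_cox(fates)
  expect_equal(fit$hr, log(0.93) / log(0.85), tolerance = 0.12)
})
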
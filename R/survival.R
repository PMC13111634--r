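#' Probability of later return after a detection gap
#'
#' Among maximal undetected runs of at least `gap` consecutive years that
#' start after at least one detection and leave at least `gap` observable
#' years before the study end, the fraction that are followed by a later
#' detection. A very small value justifies treating long-silent individuals
#' as dead.
#'
#' @param histories Detection-history tibble (see
#'   [simulate_detection_histories()]): `individual_id`, `birth_year`,
#'   list-column `detection_years`, `study_end_year`.
#' @param gap Gap length in years.
#' @return A fraction in \[0, 1\].
#' @export
return_probability <- function(histories, gap = 2) {
  n_eligible <- 0L
  n_return <- 0L
  for (i in seq_len(nrow(histories))) {
    det <- sort(unique(histories$detection_years[[i]]))
    if (length(det) == 0) next
    end <- histories$study_end_year[i]
    # internal gaps between consecutive detections
    if (length(det) > 1) {
      gl <- diff(det) - 1L
      internal <- gl[gl >= gap]
      n_eligible <- n_eligible + length(internal)
      n_return <- n_return + length(internal)
    }
    # terminal gap: must be observable for >= gap years
    tail_gap <- end - det[length(det)]
    if (tail_gap >= gap) {
      n_eligible <- n_eligible + 1L
      # never seen again
    }
  }
  if (n_eligible == 0) stop("no eligible detection gaps of length >= ", gap)
  n_return / n_eligible
}

#' Assign survival fates from detection histories and zoo records
#'
#' Wild individuals unseen for at least `gap_threshold` years at the study
#' end are treated as dead at `last detection age + death_offset` provided
#' the estimated probability of later return after such a gap is below
#' `return_prob_cutoff`; otherwise they are censored at their age in the
#' final study year. Zoo records carry explicit death or censoring dates.
#' Individuals with no detections (or non-positive exit age) are excluded
#' and counted.
#'
#' @param histories Wild detection histories.
#' @param zoo_records Zoo record tibble (`individual_id`, `sex`,
#'   `hatch_year`, `death_year`, `censor_year`).
#' @param gap_threshold Years of silence required to infer death.
#' @param return_prob_cutoff Maximum acceptable return probability.
#' @param death_offset Years added to the last detection age (detection is
#'   annual).
#' @return A fate-record tibble: `individual_id`, `group`, `sex`,
#'   `entry_age`, `exit_age`, `event` (TRUE = death), with an `excluded`
#'   attribute counting dropped individuals.
#' @export
assign_fates <- function(histories, zoo_records, gap_threshold = 2,
                         return_prob_cutoff = 0.01, death_offset = 1) {
  rp <- return_probability(histories, gap = gap_threshold)
  excluded <- 0L
  wild <- purrr::map_dfr(seq_len(nrow(histories)), function(i) {
    det <- sort(unique(histories$detection_years[[i]]))
    if (length(det) == 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    end <- histories$study_end_year[i]
    birth <- histories$birth_year[i]
    last_age <- det[length(det)] - birth
    silent <- end - det[length(det)]
    if (silent >= gap_threshold && rp < return_prob_cutoff) {
      tibble::tibble(
        individual_id = histories$individual_id[i],
        group = "wild", sex = histories$sex[i],
        entry_age = 0, exit_age = last_age + death_offset, event = TRUE
      )
    } else {
      tibble::tibble(
        individual_id = histories$individual_id[i],
        group = "wild", sex = histories$sex[i],
        entry_age = 0, exit_age = end - birth, event = FALSE
      )
    }
  })
  zoo <- purrr::map_dfr(seq_len(nrow(zoo_records)), function(i) {
    death <- zoo_records$death_year[i]
    censor <- zoo_records$censor_year[i]
    exit <- if (!is.na(death)) death - zoo_records$hatch_year[i]
            else censor - zoo_records$hatch_year[i]
    tibble::tibble(
      individual_id = zoo_records$individual_id[i], group = "zoo",
      sex = zoo_records$sex[i], entry_age = 0, exit_age = exit,
      event = !is.na(death)
    )
  })
  out <- dplyr::bind_rows(wild, zoo)
  bad <- out$exit_age <= out$entry_age
  excluded <- excluded + sum(bad)
  out <- out[!bad, ]
  attr(out, "excluded") <- excluded
  attr(out, "return_probability") <- rp
  out
}

#' Proportional-hazards contrast of wild and zoo survival
#'
#' Cox proportional-hazards partial-likelihood fit (Efron ties) with group
#' and, when it varies, sex as covariates; reports the zoo/wild hazard
#' ratio with its 95% confidence interval and per-stratum survival curves.
#'
#' @param records A fate-record tibble (`group`, `sex`, `entry_age`,
#'   `exit_age`, `event`).
#' @return A `cox_contrast`: `fit` (the `coxph` object), `hr`, `ci`,
#'   `coefficients` tibble, `curves` (per-stratum survival tibble),
#'   `n_events` per group, `monotone_flag`.
#' @export
fit_cox <- function(records) {
  records$group <- factor(records$group, levels = c("wild", "zoo"))
  if (!all(tapply(records$event, records$group, sum) >= 1)) {
    stop("need at least one event per group")
  }
  use_sex <- length(unique(records$sex)) > 1
  fml <- if (use_sex) {
    survival::Surv(exit_age, event) ~ group + sex
  } else {
    survival::Surv(exit_age, event) ~ group
  }
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  row <- grep("^group", rownames(sm$coefficients))
  beta <- sm$coefficients[row, "coef"]
  se <- sm$coefficients[row, "se(coef)"]
  hr <- exp(beta)
  ci <- exp(beta + c(-1, 1) * 1.96 * se)
  strata <- expand.grid(
    group = levels(records$group),
    sex = if (use_sex) sort(unique(records$sex)) else unique(records$sex),
    stringsAsFactors = FALSE
  )
  sf <- survival::survfit(fit, newdata = strata)
  surv <- if (is.matrix(sf$surv)) sf$surv else matrix(sf$surv, ncol = 1)
  curves <- purrr::map_dfr(seq_len(nrow(strata)), function(k) {
    tibble::tibble(
      group = strata$group[k], sex = strata$sex[k],
      time = sf$time, survival = surv[, k]
    )
  })
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "coef"],
    std.error = sm$coefficients[, "se(coef)"],
    p.value = sm$coefficients[, "Pr(>|z|)"]
  )
  structure(
    list(
      fit = fit, hr = unname(hr), ci = unname(ci), beta = unname(beta),
      se = unname(se), coefficients = coefs, curves = curves,
      n_events = table(records$group[records$event]),
      n = table(records$group), monotone_flag = monotone
    ),
    class = "cox_contrast"
  )
}

#' @export
print.cox_contrast <- function(x, ...) {
  cat(sprintf(
    "<cox_contrast> HR (zoo vs wild) = %.3f [%.3f-%.3f]%s\n",
    x$hr, x$ci[1], x$ci[2],
    if (x$monotone_flag) " [monotone likelihood]" else ""
  ))
  invisible(x)
}

#' @export
tidy.cox_contrast <- function(x, ...) x$coefficients

#' @export
glance.cox_contrast <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_low = x$ci[1], ci_high = x$ci[2],
                 n = sum(x$n), n_events = sum(x$n_events),
                 monotone = x$monotone_flag)
}

#' Survival quantiles from a fitted contrast
#'
#' Smallest age at which the stratum's survival falls to `1 - prob` or
#' below; quantiles the curve never reaches are `NA`.
#'
#' @param x A `cox_contrast`.
#' @param group,sex Stratum selectors (sex optional).
#' @param probs Quantiles of the lifetime distribution (0.5 = median age at
#'   death).
#' @return A tibble: `prob`, `age`.
#' @export
survival_quantiles <- function(x, group, sex = NULL,
                               probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(x, "cox_contrast"))
  cur <- x$curves[x$curves$group == group, ]
  if (!is.null(sex)) cur <- cur[cur$sex == sex, ]
  cur <- cur[order(cur$time), ]
  cur <- cur[!duplicated(cur$time), ]
  age <- vapply(probs, function(p) {
    hit <- which(cur$survival <= 1 - p)
    if (length(hit) == 0) NA_real_ else cur$time[hit[1]]
  }, numeric(1))
  tibble::tibble(prob = probs, age = age)
}
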
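#' Select CpG sites whose methylation tracks age
#'
#' Computes the Pearson correlation between per-site methylation level and
#' age, and keeps sites with squared correlation at least `r2_min` and
#' two-sided p-value (t approximation, n - 2 df) at most `p_max`. With
#' `sign = "negative"` only sites with negative correlation are kept (the
#' selection rule of the unweighted age estimator).
#'
#' @param x A [methylome] (no missing data among candidate sites) or a
#'   numeric level matrix (sites x samples).
#' @param ages Numeric vector of calendar ages, one per sample.
#' @param r2_min,p_max Selection thresholds.
#' @param sign `"any"` or `"negative"`.
#' @return A tibble: `idx` (row index into `x`), `chrom`, `pos` (when
#'   available), `r`, `r2`, `p`, sorted by `idx`.
#' @export
select_age_correlated_sites <- function(x, ages, r2_min = 0.2,
                                        p_max = 0.05,
                                        sign = c("any", "negative")) {
  sign <- match.arg(sign)
  lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
  n <- length(ages)
  if (n < 3) stop("need at least 3 samples to correlate with age")
  if (ncol(lev) != n) stop("ages must match the number of samples")
  r <- suppressWarnings(as.vector(cor(t(lev), ages,
                                      use = "pairwise.complete.obs")))
  r[is.na(r)] <- 0
  r2 <- r^2
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  keep <- r2 >= r2_min & p <= p_max
  if (sign == "negative") keep <- keep & r < 0
  idx <- which(keep)
  out <- tibble::tibble(idx = idx, r = r[idx], r2 = r2[idx], p = p[idx])
  if (inherits(x, "methylome")) {
    out <- dplyr::mutate(out, chrom = x$sites$chrom[idx],
                         pos = x$sites$pos[idx], .after = "idx")
  }
  out
}

#' Principal components of methylation variation
#'
#' Centred (not variance-scaled) PCA of the samples-by-sites level matrix;
#' up to `n_samples - 1` components are retained. Component signs are fixed
#' by convention: the loading entry of largest magnitude is made positive.
#'
#' @param x A [methylome] or a level matrix (sites x samples), without
#'   missing values among the supplied sites.
#' @param sites Optional integer vector of site rows to use (e.g. the `idx`
#'   column of [select_age_correlated_sites()]).
#' @return A `meth_pca` object: `scores` (samples x k), `loadings`
#'   (sites x k), `center`, `sdev`, `sites`.
#' @export
compute_pcs <- function(x, sites = NULL) {
  lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
  if (!is.null(sites)) lev <- lev[sites, , drop = FALSE]
  if (anyNA(lev)) stop("compute_pcs requires complete data; filter first")
  m <- t(lev)  # samples x sites
  if (all(apply(m, 2, sd) < 1e-12)) stop("constant matrix: no variation")
  k <- min(nrow(m) - 1, ncol(m))
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  # sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(
    list(scores = pc$x, loadings = pc$rotation, center = pc$center,
         sdev = pc$sdev, sites = sites),
    class = "meth_pca"
  )
}

#' Project new samples onto an existing PCA
#'
#' @param pca A `meth_pca` from [compute_pcs()].
#' @param x A [methylome] or level matrix holding the new samples (same
#'   site set and order as used for the PCA).
#' @param sites Optional site rows (as in [compute_pcs()]).
#' @return A scores matrix (new samples x k).
#' @export
project_pcs <- function(pca, x, sites = NULL) {
  lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
  sites <- sites %||% pca$sites
  if (!is.null(sites)) lev <- lev[sites, , drop = FALSE]
  m <- t(lev)
  sweep(m, 2, pca$center, `-`) %*% pca$loadings
}

#' Transform calendar ages with a candidate slope/intercept
#'
#' Wild ages are untouched; zoo ages become `2^s * age + b`. This is the
#' two-group linearisation the grid search optimises over.
#'
#' @param ages Calendar ages (years).
#' @param groups Character/factor vector with levels `wild` / `zoo`.
#' @param s Log2 slope ratio.
#' @param b Intercept offset (years).
#' @return Transformed ages.
#' @export
transform_ages <- function(ages, groups, s, b) {
  zoo <- groups == "zoo"
  out <- ages
  out[zoo] <- 2^s * ages[zoo] + b
  out
}

#' Leave-one-out elastic-net age prediction
#'
#' For each sample, an elastic net of the (transformed) ages on the PC
#' scores is trained on the other samples, with the penalty strength chosen
#' by leave-one-out cross-validation within the training set over a fixed
#' 100-point log-spaced lambda path; the held-out sample is then predicted.
#' The inner LOO uses the exact closed form of the active-set-restricted
#' problem (`inner_method = "alo"`, the default) or brute-force refits
#' (`"exact"`; much slower, for validation).
#'
#' @param scores Numeric matrix of predictors (samples x components).
#' @param y Response (transformed ages).
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param nlambda,lambda_min_ratio Lambda path settings: number of points
#'   and ratio of smallest to largest penalty.
#' @param inner_method `"alo"` or `"exact"`.
#' @param dfmax Overfit guard: with `"alo"`, path points with more than this
#'   many active components are excluded from penalty selection (0 = no
#'   cap).
#' @return A tibble: `sample` (row index), `predicted`, `lambda` (selected
#'   penalty). If the training response is essentially constant the
#'   predictions equal the training mean and a `degenerate` attribute is
#'   set.
#' @export
loo_predict <- function(scores, y, alpha = 0.5, nlambda = 100,
                        lambda_min_ratio = 0.01,
                        inner_method = c("alo", "exact"), dfmax = 0) {
  inner_method <- match.arg(inner_method)
  scores <- as.matrix(scores)
  if (nrow(scores) < 10) stop("need at least 10 samples for LOO prediction")
  stopifnot(length(y) == nrow(scores), alpha >= 0, alpha <= 1)
  degenerate <- sd(y) < 1e-10
  res <- if (inner_method == "alo") {
    .cpp_loo_predict(scores, y, alpha, nlambda, lambda_min_ratio, dfmax)
  } else {
    .cpp_loo_predict_exact(scores, y, alpha, nlambda, lambda_min_ratio)
  }
  out <- tibble::tibble(
    sample = seq_len(nrow(scores)),
    predicted = as.vector(res$pred),
    lambda = as.vector(res$lambda)
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Grid schedule for the two-group clock search
#'
#' Round 1 spans slopes -1..1 (log2, step 0.25), intercepts -15..15 years
#' (step 1.5) and five mixing values; each refinement round re-centres on
#' the incumbent with range +/- one previous step and halved steps, and the
#' schedule stops once the intercept step would fall below `min_b_step`.
#'
#' @param s_range,s_step Slope range (log2) and initial step.
#' @param b_range,b_step Intercept range (years) and initial step.
#' @param alphas Elastic-net mixing values for round 1.
#' @param refine_rounds Maximum number of refinement rounds.
#' @param min_b_step Stop refining when the intercept step would drop below
#'   this (years).
#' @param nlambda,lambda_min_ratio Lambda path settings.
#' @param dfmax Overfit guard for the inner CV: path points with more than
#'   this many active components are excluded from penalty selection
#'   (0 disables the cap).
#' @return A `grid_config` list.
#' @export
grid_config <- function(s_range = c(-1, 1), s_step = 0.25,
                        b_range = c(-15, 15), b_step = 1.5,
                        alphas = c(0, 0.25, 0.5, 0.75, 1),
                        refine_rounds = 2, min_b_step = 0.25,
                        nlambda = 100, lambda_min_ratio = 0.01,
                        dfmax = 32) {
  structure(as.list(environment()), class = "grid_config")
}

#' Coarse grid used inside permutation refits
#'
#' A thinned single-round grid (slope step 0.5, intercept step 3, ridge
#' mixing only, no refinement) that keeps the permutation null affordable
#' while still spanning the full parameter box.
#'
#' @inheritParams grid_config
#' @return A `grid_config` with `refine_rounds = 0`.
#' @export
coarse_grid_config <- function(s_range = c(-1, 1), s_step = 0.5,
                               b_range = c(-15, 15), b_step = 3,
                               alphas = 0,
                               nlambda = 100, lambda_min_ratio = 0.01) {
  grid_config(
    s_range = s_range, s_step = s_step, b_range = b_range, b_step = b_step,
    alphas = alphas, refine_rounds = 0, min_b_step = 0.25,
    nlambda = nlambda, lambda_min_ratio = lambda_min_ratio, dfmax = 32
  )
}

make_grid_points <- function(s_vals, b_vals, alphas) {
  g <- expand.grid(s = s_vals, b = b_vals, alpha = alphas,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g)
}

# Winner selection with a one-standard-error-style parsimony rule.
#
# The (s, b) surface has a structural trade-off ridge (compressing the zoo
# ages and compensating with the intercept changes the score by far less
# than the sampling error of a squared correlation at these sample sizes),
# so grid points within half a standard error of the maximum are treated
# as statistically tied.  Among ties the most parsimonious slope wins,
# then the best score, then the smaller |b| and alpha.
pick_best <- function(grid_tbl, n_samples, tie_se_factor = 0.5) {
  r2max <- max(grid_tbl$r2)
  se <- sqrt(max(r2max, 0)) * (1 - r2max) / sqrt(n_samples)
  tol <- max(1e-9, tie_se_factor * 2 * se)
  cand <- grid_tbl[grid_tbl$r2 >= r2max - tol, , drop = FALSE]
  cand <- cand[abs(cand$s) <= min(abs(cand$s)) + 1e-12, , drop = FALSE]
  cand <- cand[order(-cand$r2, abs(cand$b), cand$alpha), , drop = FALSE]
  cand[1, ]
}

#' Fit the two-group epigenetic clock by grid approximation
#'
#' Because the group contrast makes age acceleration bimodal (which violates
#' the residual assumptions of a single elastic-net fit), the zoo ages are
#' linearised with a candidate slope and intercept before each fit. For
#' every grid point `(s, b, alpha)` the leave-one-out predicted ages are
#' regressed on the transformed ages and the squared correlation is the
#' point's score; the grid is then refined around the maximum with halved
#' steps. PCA and site selection are performed once, on all samples,
#' without using group labels.
#'
#' @param x A clock-filtered [methylome] (no missing data), a level matrix,
#'   or directly a PC score matrix (samples x components).
#' @param metadata Metadata tibble with `sample_id`, `group`, `age`.
#' @param grid A [grid_config()].
#' @param r2_min,p_max Site-selection thresholds (used when `x` holds
#'   levels).
#' @return A `grid_fit` object: `best` (one-row tibble `s`, `b`, `alpha`,
#'   `r2`), `grid` (all evaluated points with their round), `trace`
#'   (per-round ranges and steps), `predictions` (per-sample tibble with
#'   leave-one-out `predicted_age` and `eaa = predicted_age - age`), `pca`,
#'   `n_sites_selected`.
#' @export
grid_fit <- function(x, metadata, grid = grid_config(), r2_min = 0.2,
                     p_max = 0.05) {
  stopifnot(inherits(grid, "grid_config"))
  if (!all(c("wild", "zoo") %in% metadata$group)) {
    stop("both groups (wild, zoo) must be present")
  }
  prep <- prepare_clock_scores(x, metadata, r2_min, p_max)
  scores <- prep$scores
  ages <- metadata$age
  zoo <- as.numeric(metadata$group == "zoo")

  s_vals <- seq(grid$s_range[1], grid$s_range[2], by = grid$s_step)
  b_vals <- seq(grid$b_range[1], grid$b_range[2], by = grid$b_step)
  alphas <- grid$alphas
  s_step <- grid$s_step
  b_step <- grid$b_step
  a_step <- if (length(alphas) > 1) diff(sort(alphas))[1] else 0.25

  all_grid <- list()
  trace <- list()
  best <- NULL
  round_i <- 1
  repeat {
    pts <- make_grid_points(s_vals, b_vals, alphas)
    r2 <- .cpp_grid_search(scores, ages, zoo, as.matrix(pts),
                           grid$nlambda, grid$lambda_min_ratio,
                           grid$dfmax %||% 0)$r2
    pts$r2 <- as.vector(r2)
    pts$round <- round_i
    all_grid[[round_i]] <- pts
    trace[[round_i]] <- tibble::tibble(
      round = round_i, s_step = s_step, b_step = b_step,
      n_points = nrow(pts), best_r2 = max(pts$r2)
    )
    cand <- pick_best(dplyr::bind_rows(all_grid), nrow(metadata))
    best <- cand
    if (round_i > grid$refine_rounds) break
    new_b_step <- b_step / 2
    if (new_b_step < grid$min_b_step) break
    s_vals <- seq(best$s - s_step, best$s + s_step, by = s_step / 2)
    b_vals <- seq(best$b - b_step, best$b + b_step, by = new_b_step)
    s_vals <- pmin(pmax(s_vals, -1), 1)
    b_vals <- pmin(pmax(b_vals, -15), 15)
    alphas <- sort(unique(pmin(pmax(
      seq(best$alpha - a_step, best$alpha + a_step, by = a_step / 2), 0
    ), 1)))
    s_step <- s_step / 2
    b_step <- new_b_step
    a_step <- a_step / 2
    round_i <- round_i + 1
  }
  grid_tbl <- dplyr::bind_rows(all_grid)
  # leave-one-out predictions at the winning grid point
  t_best <- transform_ages(ages, metadata$group, best$s, best$b)
  pred <- loo_predict(scores, t_best, alpha = best$alpha,
                      nlambda = grid$nlambda,
                      lambda_min_ratio = grid$lambda_min_ratio,
                      dfmax = grid$dfmax %||% 0)
  predictions <- tibble::tibble(
    sample_id = metadata$sample_id,
    individual_id = metadata$individual_id %||% metadata$sample_id,
    group = metadata$group,
    age = ages,
    transformed_age = t_best,
    predicted_age = pred$predicted,
    eaa = pred$predicted - ages
  )
  structure(
    list(
      best = best[c("s", "b", "alpha", "r2")],
      grid = grid_tbl,
      trace = dplyr::bind_rows(trace),
      predictions = predictions,
      pca = prep$pca,
      n_sites_selected = prep$n_sites
    ),
    class = "grid_fit"
  )
}

prepare_clock_scores <- function(x, metadata, r2_min, p_max) {
  if (inherits(x, "methylome") ||
      (is.matrix(x) && nrow(x) != nrow(metadata))) {
    lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
    # the clock site filter admits no missing data; enforce it here so a
    # handful of zero-coverage cells cannot abort the pipeline
    complete <- which(rowSums(is.na(lev)) == 0)
    sel <- select_age_correlated_sites(lev[complete, , drop = FALSE],
                                       metadata$age, r2_min = r2_min,
                                       p_max = p_max, sign = "any")
    if (nrow(sel) < 2) stop("fewer than 2 age-correlated sites selected")
    pca <- compute_pcs(lev, sites = complete[sel$idx])
    list(scores = pca$scores, pca = pca, n_sites = nrow(sel))
  } else {
    list(scores = as.matrix(x), pca = NULL, n_sites = NA_integer_)
  }
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf(
    "<grid_fit> best: s = %.3f, b = %.2f y, alpha = %.2f (R2 = %.3f); %d grid points, %d sites\n",
    x$best$s, x$best$b, x$best$alpha, x$best$r2, nrow(x$grid),
    x$n_sites_selected
  ))
  invisible(x)
}

#' @export
tidy.grid_fit <- function(x, ...) x$grid

#' @export
glance.grid_fit <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble::tibble(
    n_points = nrow(x$grid), n_rounds = max(x$grid$round),
    n_sites = x$n_sites_selected
  ))
}

#' Group effect on epigenetic age
#'
#' Models predicted age as a function of calendar age and living conditions,
#' correcting for conversion efficiency and genome-wide mean methylation,
#' with a random intercept per individual when repeated samples exist. The
#' group effect is the marginal-mean difference (zoo - wild) at covariate
#' means; with `allow_slope = TRUE` an age-by-group interaction is added
#' and the slope difference reported.
#'
#' @param x A `grid_fit`, or a predictions tibble with `sample_id`,
#'   `age`, `predicted_age`.
#' @param metadata Metadata with `sample_id`, `group`, `individual_id`, and
#'   (when available) `conversion_efficiency`, `genome_wide_mean`.
#' @param allow_slope Also estimate a group difference in slope.
#' @return An `eaa_effect` object; see [tidy.eaa_effect()].
#' @export
group_effect <- function(x, metadata, allow_slope = FALSE) {
  preds <- if (inherits(x, "grid_fit")) x$predictions else tibble::as_tibble(x)
  df <- dplyr::inner_join(
    preds[c("sample_id", "age", "predicted_age")],
    metadata, by = "sample_id", suffix = c("", ".md")
  )
  if (nrow(df) != nrow(preds)) stop("predictions and metadata do not align")
  df$group <- factor(df$group, levels = c("wild", "zoo"))
  covars <- intersect(c("conversion_efficiency", "genome_wide_mean"),
                      names(df))
  keep <- df[c("predicted_age", "age", "group", covars)]
  keep <- drop_constant_covariates(keep, keep = c("predicted_age", "age",
                                                  "group"))
  covars <- intersect(covars, names(keep))
  # true collinearity among retained covariates is an error
  if (length(covars) == 2) {
    if (abs(cor(keep[[covars[1]]], keep[[covars[2]]])) > 0.999) {
      stop("collinear covariates: ", paste(covars, collapse = " ~ "))
    }
  }
  rhs <- c("age", "group", covars)
  if (allow_slope) rhs <- c(rhs, "age:group")
  fml <- paste("predicted_age ~", paste(rhs, collapse = " + "))
  has_repeats <- "individual_id" %in% names(df) &&
    any(duplicated(df$individual_id))
  if (has_repeats) {
    keep$individual_id <- df$individual_id
    fit <- lme4::lmer(as.formula(paste(fml, "+ (1 | individual_id)")),
                      data = keep, REML = TRUE)
  } else {
    fit <- lm(as.formula(fml), data = keep)
  }
  emm <- emmeans::emmeans(fit, "group")
  ctr <- emmeans::contrast(emm, method = "revpairwise")  # zoo - wild
  ctr_df <- as.data.frame(ctr)
  delta <- ctr_df$estimate[1]
  se <- ctr_df$SE[1]
  pval <- ctr_df$p.value[1]
  slope_diff <- slope_se <- slope_p <- NA_real_
  if (allow_slope) {
    cf <- if (has_repeats) summary(fit)$coefficients else summary(fit)$coefficients
    row <- grep("age:group", rownames(cf))
    if (length(row) == 1) {
      slope_diff <- cf[row, "Estimate"]
      slope_se <- cf[row, "Std. Error"]
      tcol <- grep("^t value$", colnames(cf))
      slope_p <- 2 * pt(-abs(cf[row, tcol]),
                        df = nrow(keep) - nrow(cf))
    }
  }
  fitted_v <- fitted(fit)
  obs <- keep$predicted_age
  rmse <- sqrt(mean((obs - fitted_v)^2))
  r2 <- if (sd(fitted_v) > 0) cor(obs, fitted_v)^2 else 0
  structure(
    list(
      delta = delta, se = se, p = pval,
      slope_diff = slope_diff, slope_se = slope_se, slope_p = slope_p,
      rmse = rmse, r2 = r2, model = fit, random_effect = has_repeats,
      n = nrow(keep)
    ),
    class = "eaa_effect"
  )
}

#' @export
print.eaa_effect <- function(x, ...) {
  cat(sprintf(
    "<eaa_effect> group effect (zoo - wild): %.2f y (SE %.2f, p = %.2g); RMSE %.2f, R2 %.3f\n",
    x$delta, x$se, x$p, x$rmse, x$r2
  ))
  invisible(x)
}

#' Tidy an EAA group-effect estimate
#'
#' @param x An `eaa_effect`.
#' @param ... Unused.
#' @return A tibble with one row per reported term.
#' @export
tidy.eaa_effect <- function(x, ...) {
  out <- tibble::tibble(
    term = "group (zoo - wild)", estimate = x$delta,
    std.error = x$se, p.value = x$p
  )
  if (!is.na(x$slope_diff)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "age x group slope difference", estimate = x$slope_diff,
      std.error = x$slope_se, p.value = x$slope_p
    ))
  }
  out
}

#' @export
glance.eaa_effect <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, r.squared = x$r2, n = x$n,
                 random_effect = x$random_effect)
}

#' Cross-group training control
#'
#' Fits the PC-elastic-net clock on one group only (site selection, PCA and
#' penalty selection all restricted to the training group, with
#' untransformed ages), predicts epigenetic age for the held-out group, and
#' estimates the group difference from a linear model of predicted age on
#' calendar age with group as a fixed factor. Training-group predictions
#' are leave-one-out, held-out-group predictions come from the full
#' training fit.
#'
#' @param x A clock-filtered [methylome] or level matrix (sites x samples).
#' @param metadata Metadata with `sample_id`, `group`, `age`.
#' @param train_group `"wild"` or `"zoo"`.
#' @param alphas Mixing values searched by inner LOO.
#' @param r2_min,p_max Site-selection thresholds (training samples only).
#' @param nlambda,lambda_min_ratio Lambda path settings.
#' @return An `eaa_effect`-like object of class `crossfit_effect` with the
#'   per-sample predictions in `$predictions`.
#' @export
cross_group_validation <- function(x, metadata,
                                   train_group = c("wild", "zoo"),
                                   alphas = c(0, 0.25, 0.5, 0.75, 1),
                                   r2_min = 0.2, p_max = 0.05,
                                   nlambda = 100, lambda_min_ratio = 0.01) {
  train_group <- match.arg(train_group)
  lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
  tr <- which(metadata$group == train_group)
  te <- which(metadata$group != train_group)
  if (length(tr) < 10) stop("training group has fewer than 10 samples")
  if (length(te) == 0) stop("both groups must be present")
  complete <- which(rowSums(is.na(lev)) == 0)
  sel <- select_age_correlated_sites(lev[complete, tr, drop = FALSE],
                                     metadata$age[tr], r2_min = r2_min,
                                     p_max = p_max, sign = "any")
  if (nrow(sel) < 2) stop("fewer than 2 age-correlated sites selected")
  sel$idx <- complete[sel$idx]
  pca <- compute_pcs(lev[, tr, drop = FALSE], sites = sel$idx)
  y_tr <- metadata$age[tr]
  # choose (alpha, lambda) by inner LOO on the training group
  best <- NULL
  for (a in alphas) {
    cv <- .cpp_enet_alo_cv(pca$scores, y_tr, a, nlambda, lambda_min_ratio)
    l <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[l] < best$cvm) {
      best <- list(alpha = a, lambda = cv$lambda[l], cvm = cv$cvm[l],
                   beta = cv$beta[, l], b0 = cv$b0[l])
    }
  }
  te_scores <- project_pcs(pca, lev[, te, drop = FALSE], sites = sel$idx)
  pred_te <- as.vector(te_scores %*% best$beta) + best$b0
  pred_tr <- loo_predict(pca$scores, y_tr, alpha = best$alpha,
                         nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio)$predicted
  preds <- tibble::tibble(
    sample_id = metadata$sample_id[c(tr, te)],
    group = metadata$group[c(tr, te)],
    age = metadata$age[c(tr, te)],
    predicted_age = c(pred_tr, pred_te),
    role = rep(c("train", "test"), c(length(tr), length(te)))
  )
  preds$eaa <- preds$predicted_age - preds$age
  fit <- lm(predicted_age ~ age + group,
            data = dplyr::mutate(preds,
                                 group = factor(.data$group,
                                                levels = c("wild", "zoo"))))
  cf <- summary(fit)$coefficients
  row <- grep("^group", rownames(cf))
  structure(
    list(
      delta = cf[row, "Estimate"], se = cf[row, "Std. Error"],
      p = cf[row, "Pr(>|t|)"],
      train_group = train_group, alpha = best$alpha, lambda = best$lambda,
      predictions = preds, model = fit,
      rmse = sqrt(mean(resid(fit)^2)),
      r2 = summary(fit)$r.squared, n = nrow(preds)
    ),
    class = c("crossfit_effect")
  )
}

#' @export
print.crossfit_effect <- function(x, ...) {
  cat(sprintf(
    "<crossfit_effect> trained on %s: group effect %.2f y (SE %.2f, p = %.2g)\n",
    x$train_group, x$delta, x$se, x$p
  ))
  invisible(x)
}

#' @export
tidy.crossfit_effect <- function(x, ...) {
  tibble::tibble(term = "group (zoo - wild)", estimate = x$delta,
                 std.error = x$se, p.value = x$p,
                 train_group = x$train_group)
}

#' Unweighted age estimator over negatively age-correlated sites
#'
#' Selects the CpGs with strong negative Pearson correlation with age
#' (squared correlation at least `r2_min`), averages their methylation
#' levels per sample with equal weights, and scales the average linearly to
#' the observed age range (orientation reversed: the cohort's maximum mean
#' methylation maps to the youngest observed age). The group effect is
#' estimated from a linear model of the scaled age on calendar age, group,
#' conversion efficiency and genome-wide mean methylation. Every step of
#' the estimator ignores group labels.
#'
#' @param x A clock-filtered [methylome] or level matrix.
#' @param metadata Metadata with `sample_id`, `group`, `age`, and optionally
#'   `conversion_efficiency`, `genome_wide_mean`.
#' @param r2_min,p_max Selection thresholds.
#' @return An `adms_result`: `sites` (selection tibble), `samples`
#'   (per-sample mean and scaled age), `delta`, `se`, `p`, `scaling`.
#' @export
adms_estimator <- function(x, metadata, r2_min = 0.2, p_max = 0.05) {
  lev <- if (inherits(x, "methylome")) meth_level(x) else as.matrix(x)
  sel <- select_age_correlated_sites(lev, metadata$age, r2_min = r2_min,
                                     p_max = p_max, sign = "negative")
  if (nrow(sel) == 0) stop("no site passes the aDMS selection rule")
  mm <- colMeans(lev[sel$idx, , drop = FALSE], na.rm = TRUE)
  lo_m <- min(mm); hi_m <- max(mm)
  lo_a <- min(metadata$age); hi_a <- max(metadata$age)
  if (hi_m - lo_m < 1e-12) stop("constant mean methylation; cannot scale")
  # max methylation -> youngest age, min methylation -> oldest age
  scaled <- lo_a + (hi_m - mm) / (hi_m - lo_m) * (hi_a - lo_a)
  samples <- tibble::tibble(
    sample_id = metadata$sample_id, group = metadata$group,
    age = metadata$age, adms_mean = mm, adms_age = scaled,
    residual = NA_real_
  )
  df <- dplyr::left_join(samples, metadata, by = c("sample_id", "group",
                                                   "age"))
  df$group <- factor(df$group, levels = c("wild", "zoo"))
  covars <- intersect(c("conversion_efficiency", "genome_wide_mean"),
                      names(df))
  keep <- drop_constant_covariates(df[c("adms_age", "age", "group", covars)],
                                   keep = c("adms_age", "age", "group"))
  fml <- paste("adms_age ~",
               paste(setdiff(names(keep), "adms_age"), collapse = " + "))
  fit <- lm(as.formula(fml), data = keep)
  cf <- summary(fit)$coefficients
  row <- grep("^group", rownames(cf))
  samples$residual <- resid(fit)
  structure(
    list(
      sites = sel, samples = samples,
      delta = cf[row, "Estimate"], se = cf[row, "Std. Error"],
      p = cf[row, "Pr(>|t|)"], model = fit,
      scaling = list(meth_range = c(lo_m, hi_m), age_range = c(lo_a, hi_a))
    ),
    class = "adms_result"
  )
}

#' @export
print.adms_result <- function(x, ...) {
  cat(sprintf(
    "<adms_result> %d sites; group effect %.2f y (SE %.2f, p = %.2g)\n",
    nrow(x$sites), x$delta, x$se, x$p
  ))
  invisible(x)
}

#' @export
tidy.adms_result <- function(x, ...) {
  tibble::tibble(term = "group (zoo - wild)", estimate = x$delta,
                 std.error = x$se, p.value = x$p, n_sites = nrow(x$sites))
}
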
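#' Configuration for a synthetic methylation cohort
#'
#' Defines the study conditions a simulated cohort emulates: two lifestyle
#' groups (34 wild, 30 zoo-housed by default), known ages, a subset of
#' individuals sampled twice, binomial methylation counts around 30x pooled
#' depth, clock CpGs whose methylation declines with the logarithm of
#' effective age, a group offset planted on the effective-age scale,
#' age-independent group DMRs, inert background sites, and per-sample
#' conversion-efficiency noise.
#'
#' Clock site `i` in sample `j` has true level
#' `clip(m0_i + beta_i * log(1 + a_j + delta * zoo_j + eps_j), 0.01, 0.99)`,
#' where `eps_j ~ Normal(0, noise_sd)` is a per-sample biological jitter on
#' the effective-age scale (shared across sites within a sample: this is
#' what gives the clock a realistic residual error). DMR sites have
#' `clip(m0_i + dmr_effect * dir * zoo_j + eta_ij)` and inert sites
#' `clip(m0_i + eta_ij)` with per-cell noise
#' `eta ~ Normal(0, level_noise_sd)`. Observed levels are inflated by
#' incomplete conversion: `pi_obs = pi + (1 - pi) (1 - c_j)`.
#'
#' @param n_wild,n_zoo Samples per group.
#' @param age_range Uniform age range in years.
#' @param n_repeat_individuals Individuals sampled twice (split across
#'   groups), at ages at least one year apart.
#' @param n_clock_sites,n_dmr_regions,dmr_size_cpgs,n_inert_sites Site plan.
#' @param target_depth Mean pooled read depth per cell.
#' @param depth_dispersion Gamma shape of the per-cell depth mean (smaller =
#'   more overdispersed; depth is Poisson around a Gamma mean).
#' @param clock_baseline_range,clock_slope_range Ranges for per-clock-site
#'   baseline `m0` and slope `beta` (per log-year; negative). The wide
#'   defaults make many trajectories saturate at the \[0.01, 0.99\] bounds
#'   at site-specific ages, giving the cohort the heterogeneous, kinked
#'   trajectory mixture real clocks rely on (a single shared log shape
#'   would leave the effective age unidentifiable from a linear readout).
#' @param noise_sd Per-sample effective-age jitter, years.
#' @param level_noise_sd Per-cell level noise at DMR/inert sites.
#' @param true_intercept Planted zoo offset on the effective-age scale,
#'   years.
#' @param true_log2_slope Planted log2 slope ratio (0 = equal ageing rate).
#' @param dmr_effect_range Range of planted DMR effect sizes (absolute level
#'   difference); sign is drawn per region.
#' @param conversion_range Uniform range of per-sample conversion
#'   efficiencies.
#' @param seed Mandatory RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_wild = 34, n_zoo = 30,
                          age_range = c(2, 25),
                          n_repeat_individuals = 6,
                          n_clock_sites = 2000,
                          n_dmr_regions = 20,
                          dmr_size_cpgs = 15,
                          n_inert_sites = 3000,
                          target_depth = 30,
                          depth_dispersion = 8,
                          clock_baseline_range = c(0.25, 0.95),
                          clock_slope_range = c(-0.35, -0.04),
                          noise_sd = 1.5,
                          level_noise_sd = 0.10,
                          true_intercept = 6,
                          true_log2_slope = 0,
                          dmr_effect_range = c(0.2, 0.2),
                          conversion_range = c(0.97, 0.999),
                          seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(
    n_wild > 0, n_zoo > 0, diff(age_range) > 0,
    n_clock_sites > 0, target_depth > 0, is.finite(true_intercept)
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate sample metadata for a two-group cohort
#'
#' Ages are uniform over `age_range`; `n_repeat_individuals` (split across
#' the groups) are sampled twice at ages at least one year apart;
#' conversion efficiencies are uniform over `conversion_range`. Deterministic
#' given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble: `sample_id`, `individual_id`, `group`, `site_label`,
#'   `age`, `sex`, `conversion_efficiency`.
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_rep_wild <- ceiling(config$n_repeat_individuals / 2)
  n_rep_zoo <- config$n_repeat_individuals - n_rep_wild
  if (n_rep_wild > config$n_wild / 2 || n_rep_zoo > config$n_zoo / 2) {
    stop("n_repeat_individuals exceeds group capacity")
  }
  with_seed(config$seed, {
    one_group <- function(n_samples, n_rep, group, prefix) {
      n_ind <- n_samples - n_rep  # each repeat consumes one extra sample
      ind <- sprintf("%s%03d", prefix, seq_len(n_ind))
      rep_ind <- ind[seq_len(n_rep)]
      lo <- config$age_range[1]
      hi <- config$age_range[2]
      age1 <- runif(n_ind, lo, hi)
      # repeated individuals: first age drawn low enough to allow +1 year
      age1[seq_len(n_rep)] <- runif(n_rep, lo, hi - 1)
      rows <- tibble::tibble(individual_id = ind, group = group, age = age1)
      if (n_rep > 0) {
        gap <- runif(n_rep, 1, pmax(1, hi - age1[seq_len(n_rep)]))
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          individual_id = rep_ind, group = group,
          age = age1[seq_len(n_rep)] + gap
        ))
      }
      rows
    }
    wild <- one_group(config$n_wild, n_rep_wild, "wild", "W")
    zoo <- one_group(config$n_zoo, n_rep_zoo, "zoo", "Z")
    md <- dplyr::bind_rows(wild, zoo)
    n_zoo_a <- ceiling(config$n_zoo / 3)
    zoo_rows <- which(md$group == "zoo")
    md$site_label <- ifelse(
      md$group == "wild", "wild",
      NA_character_
    )
    md$site_label[zoo_rows] <- c(rep("zoo_A", n_zoo_a),
                                 rep("zoo_B", length(zoo_rows) - n_zoo_a))
    md$sex <- "M"
    md$conversion_efficiency <- runif(nrow(md), config$conversion_range[1],
                                      config$conversion_range[2])
    md$sample_id <- sprintf("S%03d", seq_len(nrow(md)))
    md[c("sample_id", "individual_id", "group", "site_label", "age", "sex",
         "conversion_efficiency")]
  })
}

# lay out clock, DMR and inert sites on a synthetic genome:
# clock sites widely spaced on their own contig; DMR and inert sites in
# clusters (in-cluster gaps 50-400 bp, between-cluster gaps >= 600 bp)
simulate_site_plan <- function(config) {
  n_dmr_sites <- config$n_dmr_regions * config$dmr_size_cpgs
  clock <- tibble::tibble(
    chrom = "clock_1",
    pos = cumsum(c(1000L, sample(900:1200, config$n_clock_sites - 1,
                                 replace = TRUE))),
    role = "clock", region = NA_integer_
  )
  # clusters on autosomal contigs: DMR regions first, then inert clusters
  inert_sizes <- integer(0)
  remaining <- config$n_inert_sites
  while (remaining > 0) {
    sz <- min(sample(10:20, 1), remaining)
    inert_sizes <- c(inert_sizes, sz)
    remaining <- remaining - sz
  }
  region_tbl <- tibble::tibble(
    role = c(rep("dmr", config$n_dmr_regions),
             rep("inert", length(inert_sizes))),
    size = c(rep(config$dmr_size_cpgs, config$n_dmr_regions), inert_sizes),
    region = seq_len(config$n_dmr_regions + length(inert_sizes))
  )
  # interleave regions so planted DMRs sit among inert clusters
  region_tbl <- region_tbl[sample(nrow(region_tbl)), ]
  n_contigs <- 5L
  region_tbl$chrom <- paste0("chr", rep_len(seq_len(n_contigs),
                                            nrow(region_tbl)))
  rows <- vector("list", nrow(region_tbl))
  cursor <- setNames(rep(1L, n_contigs), paste0("chr", seq_len(n_contigs)))
  for (i in seq_len(nrow(region_tbl))) {
    r <- region_tbl[i, ]
    start <- cursor[[r$chrom]] + sample(600:2000, 1)
    gaps <- sample(50:400, r$size - 1, replace = TRUE)
    pos <- cumsum(c(start, gaps))
    cursor[[r$chrom]] <- pos[length(pos)]
    rows[[i]] <- tibble::tibble(
      chrom = r$chrom, pos = as.integer(pos),
      role = r$role,
      region = if (r$role == "dmr") r$region else NA_integer_
    )
  }
  plan <- dplyr::bind_rows(clock, dplyr::bind_rows(rows))
  dplyr::arrange(plan, .data$chrom, .data$pos)
}

#' Simulate a methylome for a cohort
#'
#' Generates per-cell methylated/unmethylated counts with the trajectory
#' model described in [cohort_config()], and the ground truth needed to
#' score downstream recovery. Deterministic given the config seed.
#'
#' @param metadata Output of [simulate_metadata()].
#' @param config The same [cohort_config()].
#' @return A list: `methylome` (a [methylome]) and `truth` (list with
#'   `sites` — per-site role and parameters, `dmrs` — planted regions with
#'   chrom/span/effect/direction, `delta_true`, `slope_true`, and the
#'   per-sample effective-age jitter).
#' @export
simulate_methylome <- function(metadata, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 1L, {
    plan <- simulate_site_plan(config)
    n_sites <- nrow(plan)
    n_samp <- nrow(metadata)
    zoo <- as.numeric(metadata$group == "zoo")
    eps <- rnorm(n_samp, 0, config$noise_sd)
    eff_age <- metadata$age + config$true_intercept * zoo + eps
    eff_age <- pmax(eff_age, 0.1)
    # slope ratio: zoo effective ageing rate scaled by 2^s
    if (config$true_log2_slope != 0) {
      f <- 2^config$true_log2_slope
      eff_age <- ifelse(zoo > 0.5,
                        f * (metadata$age + eps) + config$true_intercept,
                        eff_age)
      eff_age <- pmax(eff_age, 0.1)
    }
    m0 <- numeric(n_sites)
    beta <- rep(NA_real_, n_sites)
    is_clock <- plan$role == "clock"
    is_dmr <- plan$role == "dmr"
    is_inert <- plan$role == "inert"
    m0[is_clock] <- runif(sum(is_clock), config$clock_baseline_range[1],
                          config$clock_baseline_range[2])
    beta[is_clock] <- runif(sum(is_clock), config$clock_slope_range[1],
                            config$clock_slope_range[2])
    m0[is_dmr | is_inert] <- runif(sum(is_dmr | is_inert), 0.2, 0.8)
    # per-DMR effect and direction
    dmr_ids <- sort(unique(plan$region[is_dmr]))
    dmr_eff <- runif(length(dmr_ids), config$dmr_effect_range[1],
                     config$dmr_effect_range[2])
    dmr_dir <- sample(c(-1, 1), length(dmr_ids), replace = TRUE)
    eff_by_region <- setNames(dmr_eff * dmr_dir, dmr_ids)

    pi_true <- matrix(0, n_sites, n_samp)
    log_eff <- log(1 + eff_age)
    pi_true[is_clock, ] <- clip01(
      outer(m0[is_clock], rep(1, n_samp)) +
        outer(beta[is_clock], log_eff)
    )
    if (any(is_dmr)) {
      delta_site <- eff_by_region[as.character(plan$region[is_dmr])]
      pi_true[is_dmr, ] <- clip01(
        outer(m0[is_dmr], rep(1, n_samp)) +
          outer(delta_site, zoo) +
          matrix(rnorm(sum(is_dmr) * n_samp, 0, config$level_noise_sd),
                 sum(is_dmr), n_samp)
      )
    }
    if (any(is_inert)) {
      pi_true[is_inert, ] <- clip01(
        outer(m0[is_inert], rep(1, n_samp)) +
          matrix(rnorm(sum(is_inert) * n_samp, 0, config$level_noise_sd),
                 sum(is_inert), n_samp)
      )
    }
    # conversion failure inflates apparent methylation
    conv <- metadata$conversion_efficiency
    pi_obs <- pi_true + sweep(1 - pi_true, 2, 1 - conv, `*`)
    # depth: Poisson around a Gamma mean (negative-binomial-like)
    shape <- config$depth_dispersion
    depth_mean <- matrix(
      rgamma(n_sites * n_samp, shape = shape,
             scale = config$target_depth / shape),
      n_sites, n_samp
    )
    depth <- matrix(rpois(n_sites * n_samp, depth_mean), n_sites, n_samp)
    meth <- matrix(rbinom(n_sites * n_samp, depth, pi_obs), n_sites, n_samp)
    unmeth <- depth - meth
    miss <- depth == 0
    meth[miss] <- NA_integer_
    unmeth[miss] <- NA_integer_
    storage.mode(meth) <- "integer"
    storage.mode(unmeth) <- "integer"
    m <- methylome(plan[c("chrom", "pos")], meth, unmeth,
                   samples = metadata$sample_id)
    dmr_truth <- plan[is_dmr, ] |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        chrom = .data$chrom[1], start = min(.data$pos),
        end = max(.data$pos) + 2L, n_cpgs = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(
        effect = dmr_eff[match(.data$region, dmr_ids)],
        direction = ifelse(dmr_dir[match(.data$region, dmr_ids)] > 0,
                           "hyper", "hypo")
      )
    truth <- list(
      sites = dplyr::mutate(plan, m0 = m0, beta = beta),
      dmrs = dmr_truth,
      delta_true = config$true_intercept,
      slope_true = config$true_log2_slope,
      effective_age_jitter = eps
    )
    list(methylome = m, truth = truth)
  })
}

#' Simulate a full cohort (metadata + methylome + covariates)
#'
#' Convenience wrapper: simulates metadata and counts, then attaches the
#' per-sample genome-wide mean methylation level to the metadata.
#'
#' @param config A [cohort_config()].
#' @return A list with `metadata` (including `genome_wide_mean`),
#'   `methylome`, `truth`.
#' @export
simulate_cohort <- function(config) {
  md <- simulate_metadata(config)
  sim <- simulate_methylome(md, config)
  gw <- genome_wide_mean(sim$methylome)
  md <- dplyr::left_join(md, gw, by = "sample_id")
  list(metadata = md, methylome = sim$methylome, truth = sim$truth)
}

#' Simulate capture-mark-recapture detection histories and zoo records
#'
#' Wild individuals survive each year with probability
#' `annual_survival_wild` and, while alive, are detected each year with
#' probability `detection_prob`; zoo individuals have exact death or
#' censoring dates. Birth years are staggered so censoring varies.
#'
#' @param n_wild_individuals,n_zoo_individuals Cohort sizes.
#' @param annual_survival_wild,annual_survival_zoo Yearly survival
#'   probabilities in (0, 1\].
#' @param detection_prob Yearly detection probability for live wild birds.
#'   The default 0.98 reproduces the ~0.3% empirical probability of
#'   resighting after a two-year silence that electronic monitoring
#'   achieves.
#' @param study_years Length of the monitoring window (years, >= 2).
#' @param seed RNG seed.
#' @return A list: `histories` (tibble with `individual_id`, `group`, `sex`,
#'   `birth_year`, list-column `detection_years`, `study_end_year`),
#'   `zoo_records` (tibble with `individual_id`, `sex`, `hatch_year`,
#'   `death_year`, `censor_year`), and `truth` (true death year per
#'   individual, `NA` if alive at study end).
#' @export
simulate_detection_histories <- function(n_wild_individuals,
                                         n_zoo_individuals,
                                         annual_survival_wild = 0.85,
                                         annual_survival_zoo = 0.922,
                                         detection_prob = 0.98,
                                         study_years = 30,
                                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(
    annual_survival_wild > 0, annual_survival_wild <= 1,
    annual_survival_zoo > 0, annual_survival_zoo <= 1,
    detection_prob > 0, detection_prob <= 1
  )
  if (study_years < 2) stop("study_years must be at least 2")
  with_seed(seed, {
    death_age <- function(n, s) {
      # age (in whole years) at which the individual dies; Inf if it
      # survives every year (geometric on the year of first failure)
      if (s >= 1) return(rep(Inf, n))
      rgeom_ <- stats::rgeom(n, prob = 1 - s)
      rgeom_ + 1L  # survives years 0..d-1, dies during year d
    }
    latest_birth <- max(1L, study_years - 15L)
    wild <- tibble::tibble(
      individual_id = sprintf("WI%05d", seq_len(n_wild_individuals)),
      group = "wild",
      sex = sample(c("M", "F"), n_wild_individuals, replace = TRUE),
      birth_year = sample(seq_len(latest_birth), n_wild_individuals,
                          replace = TRUE),
      d_age = death_age(n_wild_individuals, annual_survival_wild)
    )
    wild$detection_years <- lapply(seq_len(n_wild_individuals), function(i) {
      last_alive_year <- min(wild$birth_year[i] + wild$d_age[i] - 1,
                             study_years)
      yrs <- seq(wild$birth_year[i], last_alive_year)
      yrs[runif(length(yrs)) < detection_prob]
    })
    zoo <- tibble::tibble(
      individual_id = sprintf("ZI%05d", seq_len(n_zoo_individuals)),
      sex = sample(c("M", "F"), n_zoo_individuals, replace = TRUE),
      hatch_year = sample(seq_len(latest_birth), n_zoo_individuals,
                          replace = TRUE),
      d_age = death_age(n_zoo_individuals, annual_survival_zoo)
    )
    zoo$death_year <- ifelse(zoo$hatch_year + zoo$d_age <= study_years,
                             zoo$hatch_year + zoo$d_age, NA_real_)
    zoo$censor_year <- ifelse(is.na(zoo$death_year), study_years, NA_real_)
    truth <- dplyr::bind_rows(
      tibble::tibble(
        individual_id = wild$individual_id, group = "wild",
        death_year = ifelse(wild$birth_year + wild$d_age <= study_years,
                            wild$birth_year + wild$d_age, NA_real_)
      ),
      tibble::tibble(
        individual_id = zoo$individual_id, group = "zoo",
        death_year = zoo$death_year
      )
    )
    histories <- wild[c("individual_id", "group", "sex", "birth_year",
                        "detection_years")]
    histories$study_end_year <- study_years
    list(
      histories = histories,
      zoo_records = zoo[c("individual_id", "sex", "hatch_year",
                          "death_year", "censor_year")],
      truth = truth
    )
  })
}

#' Simulate exponential survival times under a target hazard ratio
#'
#' Draws continuous exponential event times for a wild (baseline hazard
#' `hazard_wild`) and a zoo group (hazard `hazard_wild * hr`), censored at
#' `censor_age`. Used to check hazard-ratio recovery of the proportional
#' hazards fit directly, without the detection-history machinery.
#'
#' @param n_wild,n_zoo Group sizes.
#' @param hazard_wild Baseline exponential hazard (per year).
#' @param hr True zoo/wild hazard ratio.
#' @param censor_age Administrative censoring age (years).
#' @param seed RNG seed.
#' @return A fate-record tibble (`individual_id`, `group`, `sex`,
#'   `entry_age`, `exit_age`, `event`).
#' @export
simulate_survival_times <- function(n_wild, n_zoo, hazard_wild = 0.15,
                                    hr = 0.5, censor_age = 30, seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    t_w <- rexp(n_wild, rate = hazard_wild)
    t_z <- rexp(n_zoo, rate = hazard_wild * hr)
    tibble::tibble(
      individual_id = c(sprintf("W%05d", seq_len(n_wild)),
                        sprintf("Z%05d", seq_len(n_zoo))),
      group = rep(c("wild", "zoo"), c(n_wild, n_zoo)),
      sex = rep_len(c("M", "F"), n_wild + n_zoo),
      entry_age = 0,
      exit_age = pmin(c(t_w, t_z), censor_age),
      event = c(t_w, t_z) < censor_age
    )
  })
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' One coverage file per sample (bismark dialect), a metadata TSV and a
#' ground-truth JSON; re-readable with [read_methylation_calls()] /
#' [build_methylome()] with bit-exact counts.
#'
#' @param methylome A [methylome].
#' @param metadata Metadata tibble.
#' @param truth Ground-truth list from [simulate_methylome()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
write_cohort_fixture <- function(methylome, metadata, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (s in methylome$samples) {
    ok <- !is.na(methylome$meth[, s])
    calls <- tibble::tibble(
      chrom = methylome$sites$chrom[ok],
      pos = methylome$sites$pos[ok],
      meth = methylome$meth[ok, s],
      unmeth = methylome$unmeth[ok, s]
    )
    f <- file.path(out_dir, paste0(s, ".cov"))
    write_methylation_calls(calls, f, dialect = "bismark_cov")
    files <- c(files, f)
  }
  md_file <- file.path(out_dir, "metadata.tsv")
  utils::write.table(metadata, md_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(
      delta_true = truth$delta_true,
      slope_true = truth$slope_true,
      dmrs = truth$dmrs,
      site_roles = as.list(table(truth$sites$role))
    ),
    truth_file, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(c(files, md_file, truth_file))
}
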
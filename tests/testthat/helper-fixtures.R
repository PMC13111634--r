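# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# a small but complete cohort: full sample size, reduced site count; the
# inert background dominates so the genome-wide mean covariate is not an
# age proxy (as in a real genome, where age-informative CpGs are a tiny
# fraction of all sites)
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- cohort_config(
      seed = 1, n_clock_sites = 400, n_dmr_regions = 6,
      dmr_size_cpgs = 15, n_inert_sites = 8000
    )
    .fixture_env$small <- c(simulate_cohort(cfg), list(config = cfg))
  }
  .fixture_env$small
}

# DMR-stage fixture: planted group DMRs but no planted age acceleration,
# so the EAA covariate is orthogonal to group and the planted differences
# survive the covariate correction (a planted acceleration makes EAA a
# group proxy and the correction legitimately removes most group signal)
small_dmr_cohort <- function() {
  if (is.null(.fixture_env$small_dmr)) {
    cfg <- cohort_config(
      seed = 1, n_clock_sites = 400, n_dmr_regions = 6,
      dmr_size_cpgs = 15, n_inert_sites = 8000,
      true_intercept = 0
    )
    .fixture_env$small_dmr <- c(simulate_cohort(cfg), list(config = cfg))
  }
  .fixture_env$small_dmr
}

# same size but no planted group signal at all
small_null_cohort <- function() {
  if (is.null(.fixture_env$small_null)) {
    cfg <- cohort_config(
      seed = 1, n_clock_sites = 400, n_dmr_regions = 6,
      dmr_size_cpgs = 15, n_inert_sites = 8000,
      true_intercept = 0, dmr_effect_range = c(0, 0)
    )
    .fixture_env$small_null <- c(simulate_cohort(cfg), list(config = cfg))
  }
  .fixture_env$small_null
}

# metadata with an eaa column for DMR-stage tests (true jitter as stand-in)
with_eaa <- function(cohort) {
  md <- cohort$metadata
  md$eaa <- cohort$truth$effective_age_jitter +
    ifelse(md$group == "zoo", cohort$truth$delta_true, 0)
  md
}

# deterministic toy methylome built by hand
toy_methylome <- function() {
  sites <- tibble::tibble(
    chrom = rep("chr1", 6),
    pos = c(100L, 200L, 300L, 1000L, 1100L, 1200L)
  )
  meth <- matrix(
    c(5L, 10L, 15L, 20L, 25L, 30L,
      6L, 12L, 18L, 24L, 30L, 36L,
      7L, 14L, 21L, 28L, 35L, 42L),
    nrow = 6
  )
  unmeth <- matrix(
    c(15L, 10L, 5L, 10L, 5L, 0L,
      14L, 8L, 2L, 6L, 0L, 4L,
      13L, 6L, 9L, 2L, 5L, 8L),
    nrow = 6
  )
  methylome(sites, meth, unmeth, samples = c("A", "B", "C"))
}
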
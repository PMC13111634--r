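# internal helpers

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x, lo = 0.01, hi = 0.99) pmin(pmax(x, lo), hi)

site_key <- function(chrom, pos) paste0(chrom, ":", pos)

# drop zero-variance columns from a model frame, error on true collinearity
drop_constant_covariates <- function(df, keep = character()) {
  num <- vapply(df, is.numeric, logical(1))
  const <- vapply(df, function(x) {
    if (is.numeric(x)) isTRUE(sd(x, na.rm = TRUE) < 1e-12) else length(unique(x)) < 2
  }, logical(1))
  const[names(df) %in% keep] <- FALSE
  df[!const]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
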
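#' Per-site binomial model of group differential methylation
#'
#' Logit-link binomial regression of the per-sample (methylated,
#' unmethylated) counts at one CpG on group, age, epigenetic age
#' acceleration, conversion efficiency and genome-wide mean methylation,
#' with a random intercept per individual when repeated samples exist. The
#' group coefficient is reported as a log2 odds ratio.
#'
#' @param counts A tibble with one row per sample: `sample_id`, `meth`,
#'   `unmeth` (missing cells dropped).
#' @param metadata Metadata with `sample_id`, `group`, `age`, and optionally
#'   `eaa`, `conversion_efficiency`, `genome_wide_mean`, `individual_id`.
#' @return A `site_model` list: `log2_or`, `se`, `p`, `coefficients`
#'   (tibble), `converged`, `separation`, `random_effect`.
#' @export
fit_site_binomial_model <- function(counts, metadata) {
  df <- dplyr::inner_join(counts, metadata, by = "sample_id")
  df <- df[!is.na(df$meth) & !is.na(df$unmeth) &
             (df$meth + df$unmeth) > 0, ]
  if (min(table(df$group)) < 2) {
    stop("need at least 2 covered samples per group")
  }
  df$group <- factor(df$group, levels = c("wild", "zoo"))
  covars <- intersect(c("age", "eaa", "conversion_efficiency",
                        "genome_wide_mean"), names(df))
  keep <- drop_constant_covariates(df[c("meth", "unmeth", "group", covars)],
                                   keep = c("meth", "unmeth", "group"))
  covars <- setdiff(names(keep), c("meth", "unmeth", "group"))
  fml <- paste("cbind(meth, unmeth) ~ group",
               if (length(covars) > 0) paste("+", paste(covars, collapse = " + ")) else "")
  has_repeats <- "individual_id" %in% names(df) &&
    any(duplicated(df$individual_id))
  converged <- TRUE
  random_effect <- FALSE
  if (has_repeats) {
    keep$individual_id <- df$individual_id
    fit <- tryCatch(
      lme4::glmer(as.formula(paste(fml, "+ (1 | individual_id)")),
                  data = keep, family = binomial()),
      warning = function(w) NULL, error = function(e) NULL
    )
    if (!is.null(fit) && !lme4::isSingular(fit)) {
      random_effect <- TRUE
      cf <- summary(fit)$coefficients
    } else {
      fit <- NULL
    }
  } else {
    fit <- NULL
  }
  if (is.null(fit) || !random_effect) {
    fit <- suppressWarnings(glm(as.formula(fml), data = keep,
                                family = binomial()))
    converged <- fit$converged
    cf <- summary(fit)$coefficients
  }
  row <- grep("^group", rownames(cf))
  est <- cf[row, "Estimate"]
  se <- cf[row, "Std. Error"]
  separation <- !converged || abs(est) > 15 || se > 15
  coef_tbl <- tibble::tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    p.value = cf[, ncol(cf)]
  )
  structure(
    list(
      log2_or = if (separation) NA_real_ else est / log(2),
      se = if (separation) NA_real_ else se / log(2),
      p = if (separation) NA_real_ else cf[row, ncol(cf)],
      coefficients = coef_tbl,
      converged = converged, separation = separation,
      random_effect = random_effect, n = nrow(keep)
    ),
    class = "site_model"
  )
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf(
    "<site_model> log2 OR (zoo/wild) = %s%s\n",
    ifelse(is.na(x$log2_or), "NA", sprintf("%.3f (SE %.3f, p = %.2g)",
                                           x$log2_or, x$se, x$p)),
    if (x$separation) " [separation]" else ""
  ))
  invisible(x)
}

#' @export
tidy.site_model <- function(x, ...) x$coefficients

# design matrix for the covariate-correction model (group excluded)
correction_design <- function(metadata) {
  covars <- intersect(c("age", "eaa", "conversion_efficiency",
                        "genome_wide_mean"), names(metadata))
  df <- metadata[covars]
  use <- vapply(df, function(v) sd(v, na.rm = TRUE) > 1e-12, logical(1))
  df <- df[use]
  X <- cbind(`(Intercept)` = 1, as.matrix(df))
  X
}

#' Remove nuisance-covariate signal from bounded methylation levels
#'
#' Fits a beta regression (logit mean link, constant precision, maximum
#' likelihood) of the per-sample methylation levels at one site on age,
#' epigenetic age acceleration, conversion efficiency and genome-wide mean
#' methylation — the group label is deliberately excluded so the group
#' signal survives. The corrected value is the fitted mean at covariate
#' means plus the response-scale residual, clipped to (0, 1). Boundary
#' levels are shrunk with `y' = (y (N - 1) + 0.5) / N` before fitting. If
#' the ML fit does not converge the correction falls back to linear-model
#' residualisation and is flagged.
#'
#' @param levels Numeric vector of methylation levels for one site (may
#'   contain `NA`, propagated).
#' @param metadata Metadata aligned with `levels` (same order), with the
#'   covariate columns above.
#' @return Numeric vector of corrected levels with attribute `method`
#'   (`"beta"` or `"linear"`).
#' @export
beta_correct <- function(levels, metadata) {
  ok <- !is.na(levels)
  if (sum(ok) < 10) stop("need at least 10 non-missing samples")
  y <- levels[ok]
  n_ok <- length(y)
  y_shrunk <- (y * (n_ok - 1) + 0.5) / n_ok
  out <- rep(NA_real_, length(levels))
  if (sd(y_shrunk) < 1e-10) {
    out[ok] <- y_shrunk
    attr(out, "method") <- "constant"
    return(out)
  }
  X <- correction_design(metadata[ok, , drop = FALSE])
  fit <- .cpp_betareg_fit(y_shrunk, X)
  xbar <- colMeans(X)
  if (isTRUE(fit$converged)) {
    mu_at_mean <- plogis(sum(xbar * fit$coefficients))
    corrected <- mu_at_mean + (y_shrunk - fit$fitted)
    method <- "beta"
  } else {
    lmfit <- lm.fit(X, y_shrunk)
    mu_at_mean <- sum(xbar * lmfit$coefficients)
    corrected <- mu_at_mean + lmfit$residuals
    method <- "linear"
  }
  out[ok] <- pmin(pmax(corrected, 1e-6), 1 - 1e-6)
  attr(out, "method") <- method
  out
}

#' Candidate DMR windows from CpG spacing and variability
#'
#' Maximal runs of CpGs that pass the pre-correction variability filter
#' (`sd >= min_sd`) with adjacent gaps at most `max_gap` bp; runs with fewer
#' than `min_cpgs` members are discarded.
#'
#' @param positions Integer positions (0-based), sorted within chromosome.
#' @param sds Per-site level standard deviation (pre-correction).
#' @param chrom Optional chromosome vector (windows never span
#'   chromosomes).
#' @param max_gap Maximum distance between adjacent member CpGs (bp).
#' @param min_cpgs Minimum CpGs per window.
#' @param min_sd Variability threshold.
#' @return A tibble of windows: `window`, `chrom`, `start_idx`, `end_idx`
#'   (indices into the input), `n_cpgs`.
#' @export
build_windows <- function(positions, sds, chrom = NULL, max_gap = 500,
                          min_cpgs = 10, min_sd = 0.1) {
  n <- length(positions)
  if (is.null(chrom)) chrom <- rep("chr", n)
  pass <- !is.na(sds) & sds >= min_sd
  # runs break at filter failures, chromosome changes and large gaps
  run_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!pass[i]) next
    start_new <- i == 1 || !pass[i - 1] || chrom[i] != chrom[i - 1] ||
      positions[i] - positions[i - 1] > max_gap ||
      positions[i] < positions[i - 1]
    if (start_new) cur <- cur + 1L
    run_id[i] <- cur
  }
  ok <- run_id > 0
  if (!any(ok)) {
    return(tibble::tibble(window = integer(), chrom = character(),
                          start_idx = integer(), end_idx = integer(),
                          n_cpgs = integer()))
  }
  tb <- tibble::tibble(idx = which(ok), run = run_id[ok],
                       chrom = chrom[ok]) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(chrom = .data$chrom[1], start_idx = min(.data$idx),
                     end_idx = max(.data$idx),
                     n_cpgs = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs)
  dplyr::mutate(tb, window = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"run")
}

#' Segment a window by the maximal group-difference sub-segment
#'
#' Recursive binary segmentation on the per-CpG group difference signal
#' `d_i = mean_zoo - mean_wild` of corrected levels: the contiguous
#' sub-segment of length at least `min_cpgs` maximising `|mean(d)|` is
#' emitted if that maximum exceeds `min_diff`, then both flanks are
#' segmented recursively. Deterministic; output segments are disjoint.
#'
#' @param d Per-CpG difference signal (zoo - wild) within one window.
#' @param min_cpgs Minimum segment length.
#' @param min_diff Minimum absolute mean difference to emit a segment.
#' @return A tibble of segments: `start_idx`, `end_idx` (1-based indices
#'   into `d`), `mean_diff`.
#' @export
segment_window <- function(d, min_cpgs = 10, min_diff = 0.1) {
  n <- length(d)
  out <- list()
  tol <- 1e-9
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < min_cpgs) return(invisible(NULL))
    seg <- d[lo:hi]
    cs <- c(0, cumsum(ifelse(is.na(seg), 0, seg)))
    cn <- c(0, cumsum(!is.na(seg)))
    # ties in |mean| (within tol) are broken toward the longer, then the
    # leftmost sub-segment, so a constant window is returned whole
    best <- c(NA_integer_, NA_integer_, 0)
    best_len <- 0L
    for (i in seq_len(len - min_cpgs + 1)) {
      for (j in (i + min_cpgs - 1):len) {
        k <- cn[j + 1] - cn[i]
        if (k == 0) next
        m <- (cs[j + 1] - cs[i]) / k
        seg_len <- j - i + 1L
        if (abs(m) > abs(best[3]) + tol ||
            (abs(m) > abs(best[3]) - tol && seg_len > best_len)) {
          best <- c(i, j, m)
          best_len <- seg_len
        }
      }
    }
    if (is.na(best[1]) || abs(best[3]) <= min_diff) return(invisible(NULL))
    i <- lo + best[1] - 1
    j <- lo + best[2] - 1
    out[[length(out) + 1]] <<- tibble::tibble(
      start_idx = i, end_idx = j, mean_diff = best[3]
    )
    recurse(lo, i - 1)
    recurse(j + 1, hi)
    invisible(NULL)
  }
  recurse(1, n)
  if (length(out) == 0) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          mean_diff = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start_idx)
}

#' Mann-Whitney U test of group separation
#'
#' Two-sided Mann-Whitney U comparing two samples: exact enumeration of all
#' group assignments when both groups have at most `exact_max` members
#' (handles ties), otherwise the normal approximation with tie correction
#' and continuity correction. Degenerate input (all pooled values equal)
#' returns p = 1.
#'
#' @param x,y Numeric vectors (e.g. per-sample segment means of the two
#'   groups).
#' @param exact_max Enumeration threshold per group.
#' @return A tibble: `U` (statistic for `x` relative to `y`), `p`, `method`.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (sd(pooled) < 1e-15) {
    return(tibble::tibble(U = n1 * n2 / 2, p = 1, method = "degenerate"))
  }
  rk <- rank(pooled)
  w1 <- sum(rk[seq_len(n1)])
  U <- w1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    wsums <- colSums(matrix(rk[combos], nrow = n1))
    us <- wsums - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(tibble::tibble(U = U, p = 1, method = "degenerate"))
    }
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(U = U, p = min(p, 1), method = method)
}

#' Score one candidate segment
#'
#' Per-sample mean of corrected levels over the segment's CpGs, compared
#' between groups with the Mann-Whitney U test.
#'
#' @param corrected Matrix of corrected levels (segment CpGs x samples).
#' @param groups Group vector aligned with the columns.
#' @return A tibble: `mean_diff` (zoo - wild of per-sample segment means),
#'   `U`, `p`, `method`.
#' @export
test_segment <- function(corrected, groups) {
  corrected <- rbind(corrected)
  sm <- colMeans(corrected, na.rm = TRUE)
  zoo <- sm[groups == "zoo"]
  wild <- sm[groups == "wild"]
  zoo <- zoo[!is.na(zoo)]; wild <- wild[!is.na(wild)]
  if (length(zoo) == 0 || length(wild) == 0) stop("both groups required")
  res <- mwu_test(zoo, wild)
  tibble::tibble(mean_diff = mean(zoo) - mean(wild), U = res$U, p = res$p,
                 method = res$method)
}

#' Benjamini-Hochberg correction with a rejection set
#'
#' Step-up false discovery rate control: `q_i` is the monotone-enforced
#' minimum of `m p_(j) / j` over `j` with `p_(j) >= p_(i)`; hypotheses with
#' `q <= alpha` are rejected.
#'
#' @param p Vector of p-values.
#' @param alpha FDR level.
#' @return A tibble: `p`, `q`, `reject`.
#' @export
bh_correct <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, reject = !is.na(q) & q <= alpha)
}

#' Call differentially methylated regions between groups
#'
#' Orchestrates the DMR pipeline: per-site covariate correction by beta
#' regression (group excluded), candidate windows from spacing and
#' pre-correction variability, recursive maximal-difference segmentation,
#' Mann-Whitney U scoring of per-sample segment means, one genome-wide
#' Benjamini-Hochberg correction, and the conservative final filters
#' (absolute difference > `min_diff`, at least `min_cpgs` CpGs,
#' `q <= alpha`).
#'
#' @param x A DMS-filtered [methylome].
#' @param metadata Metadata with `sample_id`, `group`, `age`, `eaa`,
#'   `conversion_efficiency`, `genome_wide_mean` (order must match the
#'   methylome's samples).
#' @param max_gap,min_cpgs,min_diff,min_sd,alpha Pipeline thresholds.
#' @return A tibble of candidate DMRs (class `dmr_calls`): `chrom`, `start`,
#'   `end` (0-based, half-open, end = last CpG + 2), `n_cpgs`, `mean_diff`,
#'   `U`, `p`, `q`, `direction` (`hyper`/`hypo` at the zoo), `significant`.
#' @export
call_dmrs <- function(x, metadata, max_gap = 500, min_cpgs = 10,
                      min_diff = 0.1, min_sd = 0.1, alpha = 0.05) {
  stopifnot(inherits(x, "methylome"))
  if (!identical(metadata$sample_id, x$samples)) {
    metadata <- metadata[match(x$samples, metadata$sample_id), ]
    if (anyNA(metadata$sample_id)) {
      stop("metadata does not cover all samples")
    }
  }
  lev <- meth_level(x)
  sds <- apply(lev, 1, sd, na.rm = TRUE)
  win <- build_windows(x$sites$pos, sds, chrom = x$sites$chrom,
                       max_gap = max_gap, min_cpgs = min_cpgs,
                       min_sd = min_sd)
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), mean_diff = numeric(), U = numeric(),
    p = numeric(), q = numeric(), direction = character(),
    significant = logical()
  )
  if (nrow(win) == 0) return(structure(empty, class = c("dmr_calls",
                                                        class(empty))))
  groups <- metadata$group
  zoo <- groups == "zoo"
  segs <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    rows <- win$start_idx[w]:win$end_idx[w]
    corr <- t(vapply(rows, function(r) beta_correct(lev[r, ], metadata),
                     numeric(ncol(lev))))
    d <- rowMeans(corr[, zoo, drop = FALSE], na.rm = TRUE) -
      rowMeans(corr[, !zoo, drop = FALSE], na.rm = TRUE)
    sg <- segment_window(d, min_cpgs = min_cpgs, min_diff = min_diff)
    if (nrow(sg) == 0) next
    res <- purrr::map_dfr(seq_len(nrow(sg)), function(k) {
      sel <- sg$start_idx[k]:sg$end_idx[k]
      ts <- test_segment(corr[sel, , drop = FALSE], groups)
      tibble::tibble(
        chrom = win$chrom[w],
        start = x$sites$pos[rows[sg$start_idx[k]]],
        end = x$sites$pos[rows[sg$end_idx[k]]] + 2L,
        n_cpgs = length(sel),
        mean_diff = ts$mean_diff, U = ts$U, p = ts$p
      )
    })
    segs[[w]] <- res
  }
  cand <- dplyr::bind_rows(segs)
  if (nrow(cand) == 0) return(structure(empty, class = c("dmr_calls",
                                                         class(empty))))
  bh <- bh_correct(cand$p, alpha = alpha)
  cand$q <- bh$q
  cand$direction <- ifelse(cand$mean_diff > 0, "hyper", "hypo")
  cand$significant <- bh$reject & abs(cand$mean_diff) > min_diff &
    cand$n_cpgs >= min_cpgs
  cand <- dplyr::arrange(cand, .data$chrom, .data$start)
  structure(cand, class = c("dmr_calls", class(cand)))
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, -log10(q) (capped at 1000), strand
#' ".", then n_cpgs, mean_diff, p, q.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param path Output path.
#' @param significant_only Write only significant DMRs.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path, significant_only = TRUE) {
  d <- if (significant_only) dmrs[dmrs$significant, ] else dmrs
  if (nrow(d) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(-log10(pmax(d$q, 1e-300)), 1000)
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t.\t%d\t%.4f\t%.3g\t%.3g",
                   d$chrom, d$start, d$end,
                   sprintf("DMR_%04d", seq_len(nrow(d))), score,
                   d$n_cpgs, d$mean_diff, d$p, d$q)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts gene spans, exons and UTRs into the tibble layout expected by
#' [annotate_dmrs()]. Coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `type`
#'   (`gene`, `exon`, `five_prime_UTR`, `three_prime_UTR`).
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_models requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  keep <- df$type %in% c("gene", "exon", "five_prime_UTR",
                         "three_prime_UTR")
  df <- df[keep, ]
  gid <- if ("gene_id" %in% names(df)) df$gene_id else df$ID
  if ("Parent" %in% names(df)) {
    par <- vapply(df$Parent, function(p) {
      if (length(p) > 0) as.character(p[[1]]) else NA_character_
    }, character(1))
    gid <- ifelse(df$type == "gene" | is.na(par), gid, par)
  }
  tibble::tibble(
    gene_id = as.character(gid),
    chrom = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = as.character(df$strand),
    type = as.character(df$type)
  )
}

#' Annotate DMRs against gene models
#'
#' Reports every gene whose span (gene body extended by a strand-aware
#' promoter window, 1500 bp upstream to 500 bp downstream of the TSS) lies
#' within `max_dist` bp of a DMR boundary. The feature is classified by
#' overlap priority promoter > UTR > exon > intron > flank, and the signed
#' distance is 0 for overlaps, negative when the DMR is upstream (5') of
#' the gene and positive when downstream.
#'
#' @param dmrs A [call_dmrs()] tibble (or any tibble with `chrom`, `start`,
#'   `end`).
#' @param gene_models A tibble from [read_gene_models()] or a GFF3 path.
#' @param max_dist Maximum distance from the DMR boundary (bp).
#' @param promoter_up,promoter_down Promoter window around the TSS (bp).
#' @return A tibble: `dmr` (row index), `chrom`, `start`, `end`, `gene_id`,
#'   `feature`, `distance`.
#' @export
annotate_dmrs <- function(dmrs, gene_models, max_dist = 5000,
                          promoter_up = 1500, promoter_down = 500) {
  if (is.character(gene_models)) gene_models <- read_gene_models(gene_models)
  gm <- tibble::as_tibble(gene_models)
  unknown <- !gm$strand %in% c("+", "-")
  if (any(unknown)) {
    warning("unknown strand treated as '+' for ", sum(unknown), " features")
    gm$strand[unknown] <- "+"
  }
  genes <- gm[gm$type == "gene", ]
  parts <- gm[gm$type != "gene", ]
  out <- list()
  for (i in seq_len(nrow(dmrs))) {
    dchrom <- dmrs$chrom[i]; dstart <- dmrs$start[i]; dend <- dmrs$end[i]
    g <- genes[genes$chrom == dchrom, ]
    if (nrow(g) == 0) next
    tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
    prom_start <- ifelse(g$strand == "+", tss - promoter_up,
                         tss - promoter_down + 1L)
    prom_end <- ifelse(g$strand == "+", tss + promoter_down,
                       tss + promoter_up + 1L)
    span_start <- pmin(g$start, prom_start)
    span_end <- pmax(g$end, prom_end)
    gap <- pmax(span_start - dend, dstart - span_end, 0)
    near <- which(gap <= max_dist)
    for (k in near) {
      overlaps <- function(s, e) dstart < e && dend > s
      feature <- "flank"
      if (overlaps(prom_start[k], prom_end[k])) {
        feature <- "promoter"
      } else if (overlaps(g$start[k], g$end[k])) {
        p <- parts[parts$gene_id == g$gene_id[k], ]
        utr <- p[p$type %in% c("five_prime_UTR", "three_prime_UTR"), ]
        ex <- p[p$type == "exon", ]
        if (nrow(utr) > 0 &&
            any(dstart < utr$end & dend > utr$start)) {
          feature <- "UTR"
        } else if (nrow(ex) > 0 &&
                   any(dstart < ex$end & dend > ex$start)) {
          feature <- "exon"
        } else {
          feature <- "intron"
        }
      }
      dist <- if (gap[k] == 0) 0L else {
        upstream_plus <- dend <= span_start[k]
        sgn <- if (g$strand[k] == "+") {
          if (upstream_plus) -1L else 1L
        } else {
          if (upstream_plus) 1L else -1L
        }
        sgn * as.integer(gap[k])
      }
      out[[length(out) + 1]] <- tibble::tibble(
        dmr = i, chrom = dchrom, start = dstart, end = dend,
        gene_id = g$gene_id[k], feature = feature, distance = dist
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(dmr = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          gene_id = character(), feature = character(),
                          distance = integer()))
  }
  dplyr::bind_rows(out)
}
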
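#' Construct a methylome count container
#'
#' A `methylome` bundles per-CpG methylated/unmethylated read counts for a
#' cohort: a site table (chromosome, 0-based position of the plus-strand C of
#' each CpG dinucleotide) and two integer matrices of identical shape
#' (sites x samples). Missing cells are `NA` in both matrices.
#'
#' @param sites A data frame with columns `chrom` and `pos` (0-based).
#' @param meth,unmeth Integer matrices, one row per site, one column per
#'   sample. Column names are sample ids.
#' @param samples Optional character vector of sample ids; defaults to the
#'   column names of `meth`.
#' @return An object of class `methylome`.
#' @export
methylome <- function(sites, meth, unmeth, samples = colnames(meth)) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  if (!all(dim(meth) == dim(unmeth))) {
    stop("meth and unmeth matrices must have identical dimensions")
  }
  if (nrow(meth) != nrow(sites)) {
    stop("count matrices must have one row per site")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(meth)))
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("negative counts are not allowed")
  }
  colnames(meth) <- samples
  colnames(unmeth) <- samples
  structure(
    list(sites = sites, meth = meth, unmeth = unmeth, samples = samples),
    class = "methylome"
  )
}

#' @export
print.methylome <- function(x, ...) {
  lev <- meth_level(x)
  cat(sprintf(
    "<methylome> %d CpG sites x %d samples (%.1f%% missing)\n",
    nrow(x$meth), ncol(x$meth), 100 * mean(is.na(lev))
  ))
  invisible(x)
}

#' @export
dim.methylome <- function(x) dim(x$meth)

#' Per-cell methylation level and sequencing depth
#'
#' `meth_level()` returns meth / (meth + unmeth) (`NA` where depth is zero or
#' the cell is missing); `meth_depth()` returns the pooled per-cell depth.
#'
#' @param x A [methylome].
#' @return A numeric matrix, sites x samples.
#' @export
meth_level <- function(x) {
  d <- x$meth + x$unmeth
  lev <- x$meth / d
  lev[!is.na(d) & d == 0] <- NA_real_
  lev
}

#' @rdname meth_level
#' @export
meth_depth <- function(x) x$meth + x$unmeth

#' Tidy a methylome into a long tibble
#'
#' @param x A [methylome].
#' @param ... Unused.
#' @return A tibble with one row per (site, sample) cell: `chrom`, `pos`,
#'   `sample_id`, `meth`, `unmeth`, `level`.
#' @export
tidy.methylome <- function(x, ...) {
  lev <- meth_level(x)
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = ncol(x$meth)),
    pos = rep(x$sites$pos, times = ncol(x$meth)),
    sample_id = rep(x$samples, each = nrow(x$meth)),
    meth = as.vector(x$meth),
    unmeth = as.vector(x$unmeth),
    level = as.vector(lev)
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.methylome <- function(x, ...) tidy.methylome(x, ...)

#' Read per-cytosine methylation calls
#'
#' Parses a text file of per-cytosine methylated/unmethylated counts into a
#' tidy call table. Two dialects are supported: `bismark_cov` (chrom,
#' 1-based start, end, percent methylation, count methylated, count
#' unmethylated) and `bedgraph_counts` (chrom, 0-based start, end, percent
#' methylation, count methylated, count unmethylated). Coordinates are
#' normalised to 0-based internally. Neither dialect carries strand or
#' context, so these default to `"+"` and `"CpG"`.
#'
#' @param path Path to the file.
#' @param dialect One of `"bismark_cov"`, `"bedgraph_counts"`.
#' @return A tibble of calls: `chrom`, `pos` (0-based), `strand`, `context`,
#'   `meth`, `unmeth`.
#' @export
read_methylation_calls <- function(path,
                                   dialect = c("bismark_cov",
                                               "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth = integer(), unmeth = integer()
    ))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    stop("malformed line ", bad, " in ", path, ": expected 6 fields, got ",
         nf[bad])
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad) > 0) {
    stop("malformed line ", bad[1], " in ", path, ": non-numeric field")
  }
  nonint <- which(meth != floor(meth) | unmeth != floor(unmeth))
  if (length(nonint) > 0) {
    stop("malformed line ", nonint[1], " in ", path,
         ": counts must be integers")
  }
  if (any(meth < 0 | unmeth < 0)) {
    bad <- which(meth < 0 | unmeth < 0)[1]
    stop("malformed line ", bad, " in ", path, ": negative count")
  }
  pos <- if (dialect == "bismark_cov") as.integer(start) - 1L
         else as.integer(start)
  tibble::tibble(
    chrom = m[, 1], pos = pos, strand = "+", context = "CpG",
    meth = as.integer(meth), unmeth = as.integer(unmeth)
  )
}

#' Write methylation calls in a coverage dialect
#'
#' Inverse of [read_methylation_calls()]: writes one line per call with the
#' dialect's coordinate convention (1-based start for `bismark_cov`,
#' 0-based for `bedgraph_counts`).
#'
#' @param calls A tibble with `chrom`, `pos` (0-based), `meth`, `unmeth`.
#' @param path Output path.
#' @inheritParams read_methylation_calls
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path,
                                    dialect = c("bismark_cov",
                                                "bedgraph_counts")) {
  dialect <- match.arg(dialect)
  depth <- calls$meth + calls$unmeth
  pct <- ifelse(depth > 0, 100 * calls$meth / depth, 0)
  start <- if (dialect == "bismark_cov") calls$pos + 1L else calls$pos
  end <- if (dialect == "bismark_cov") calls$pos + 1L else calls$pos + 1L
  out <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", calls$chrom, start, end,
                 format(pct, trim = TRUE), calls$meth, calls$unmeth)
  writeLines(out, path)
  invisible(path)
}

#' Pool methylation calls from both strands of each CpG dinucleotide
#'
#' CpG methylation is symmetric across strands in vertebrates, so calls for
#' the C on the plus strand and the C on the minus strand (offset +1) of the
#' same dinucleotide are summed. By default a minus-strand call at position
#' `p` maps to the plus-strand C at `p - 1`; an explicit `cpg_pairs` mapping
#' can override this. Calls without a mate contribute alone.
#'
#' @param calls A tibble of CpG-context calls (`chrom`, `pos`, `strand`,
#'   `meth`, `unmeth`).
#' @param cpg_pairs Optional tibble mapping `(chrom, pos, strand)` to the
#'   plus-strand key `cpg_pos`; calls not covered by the mapping are an
#'   error.
#' @return A tibble of pooled CpG sites: `chrom`, `pos`, `meth`, `unmeth`,
#'   `level`, sorted by (chrom, pos).
#' @export
pool_strands <- function(calls, cpg_pairs = NULL) {
  if ("context" %in% names(calls) && any(calls$context != "CpG")) {
    stop("pool_strands expects CpG-context calls only")
  }
  if (is.null(cpg_pairs)) {
    key_pos <- ifelse(calls$strand == "-", calls$pos - 1L, calls$pos)
    keyed <- dplyr::mutate(calls, cpg_pos = as.integer(key_pos))
  } else {
    keyed <- dplyr::left_join(
      calls, cpg_pairs,
      by = c("chrom", "pos", "strand")
    )
    if (anyNA(keyed$cpg_pos)) {
      stop("some calls map to no CpG key in cpg_pairs")
    }
  }
  out <- keyed |>
    dplyr::group_by(.data$chrom, pos = .data$cpg_pos) |>
    dplyr::summarise(
      meth = sum(.data$meth), unmeth = sum(.data$unmeth),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  dplyr::mutate(out, level = ifelse(
    .data$meth + .data$unmeth > 0,
    .data$meth / (.data$meth + .data$unmeth), NA_real_
  ))
}

#' Remove CpG sites overlapping known SNP positions
#'
#' C/T (or G/A) polymorphisms mimic unmethylated calls after conversion, so
#' CpG sites at known SNP positions are removed. Works on a site tibble or a
#' [methylome]; order is preserved.
#'
#' @param x A tibble with `chrom`, `pos`, or a [methylome].
#' @param snp_positions A tibble with `chrom`, `pos` (0-based), e.g. from
#'   [read_snp_mask()].
#' @return Same type as `x`, with masked sites removed.
#' @export
mask_snp_sites <- function(x, snp_positions) {
  UseMethod("mask_snp_sites")
}

#' @export
mask_snp_sites.data.frame <- function(x, snp_positions) {
  if (is.null(snp_positions) || nrow(snp_positions) == 0) return(x)
  dplyr::anti_join(x, snp_positions[c("chrom", "pos")],
                   by = c("chrom", "pos"))
}

#' @export
mask_snp_sites.methylome <- function(x, snp_positions) {
  if (is.null(snp_positions) || nrow(snp_positions) == 0) return(x)
  hit <- site_key(x$sites$chrom, x$sites$pos) %in%
    site_key(snp_positions$chrom, snp_positions$pos)
  methylome(x$sites[!hit, , drop = FALSE],
            x$meth[!hit, , drop = FALSE],
            x$unmeth[!hit, , drop = FALSE],
            samples = x$samples)
}

#' Read a SNP mask file
#'
#' @param path Two-column TSV (chrom, 0-based position), no header.
#' @return A tibble with `chrom`, `pos`.
#' @export
read_snp_mask <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos"),
                          colClasses = c("character", "integer"))
  tibble::as_tibble(df)
}

#' Estimate enzymatic conversion efficiency from telomeric false positives
#'
#' Telomeric repeats carry no CpG methylation, so any methylated call there
#' is a conversion failure. The efficiency is one minus the pooled
#' false-positive rate over the supplied calls.
#'
#' @param telomeric_calls A tibble of non-CpG calls restricted to telomeric
#'   repeat intervals, with `meth` and `unmeth` columns.
#' @return A fraction in \[0, 1\].
#' @export
estimate_conversion_efficiency <- function(telomeric_calls) {
  tot <- sum(telomeric_calls$meth) + sum(telomeric_calls$unmeth)
  if (tot == 0) stop("zero total depth in telomeric calls")
  1 - sum(telomeric_calls$meth) / tot
}

#' Genome-wide mean methylation level per sample
#'
#' Unweighted mean of per-site methylation levels over non-missing sites.
#'
#' @param x A [methylome], or a numeric vector of levels for one sample.
#' @return For a methylome, a tibble (`sample_id`, `genome_wide_mean`); for
#'   a vector, a single fraction.
#' @export
genome_wide_mean <- function(x) UseMethod("genome_wide_mean")

#' @export
genome_wide_mean.numeric <- function(x) {
  if (all(is.na(x))) stop("all levels missing")
  mean(x, na.rm = TRUE)
}

#' @export
genome_wide_mean.methylome <- function(x) {
  lev <- meth_level(x)
  if (any(colSums(!is.na(lev)) == 0)) {
    stop("at least one sample has no non-missing site")
  }
  tibble::tibble(
    sample_id = x$samples,
    genome_wide_mean = colMeans(lev, na.rm = TRUE)
  )
}

#' Site filtering criteria
#'
#' Depth and variability thresholds applied by [filter_sites()]. The
#' cross-sample mean-depth band is interpreted on the single-stranded scale
#' by default (pooled depth / 2), matching how depth is usually quoted for
#' strand-pooled CpG data; set `depth_basis = "pooled"` to apply it on the
#' pooled scale.
#'
#' @param mean_depth_range Cross-sample mean depth band (inclusive).
#' @param sample_depth_range Per-cell pooled depth band (inclusive); cells
#'   outside it are set missing.
#' @param max_missing_fraction Maximum tolerated fraction of missing cells
#'   per site.
#' @param min_sd Minimum standard deviation of methylation levels across
#'   non-missing samples.
#' @param depth_basis `"single_stranded"` or `"pooled"`.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(mean_depth_range = c(10, 25),
                            sample_depth_range = c(5, 50),
                            max_missing_fraction = 0,
                            min_sd = 0.1,
                            depth_basis = c("single_stranded", "pooled")) {
  depth_basis <- match.arg(depth_basis)
  stopifnot(
    length(mean_depth_range) == 2, diff(mean_depth_range) >= 0,
    length(sample_depth_range) == 2, diff(sample_depth_range) >= 0,
    max_missing_fraction >= 0, max_missing_fraction <= 1, min_sd >= 0
  )
  structure(
    list(
      mean_depth_range = mean_depth_range,
      sample_depth_range = sample_depth_range,
      max_missing_fraction = max_missing_fraction,
      min_sd = min_sd,
      depth_basis = depth_basis
    ),
    class = "filter_criteria"
  )
}

#' Filter a methylome by depth, missingness and variability
#'
#' Applies, in order: (1) per-cell depth bounds — cells with pooled depth
#' outside `sample_depth_range` are set missing; (2) a cross-sample mean
#' depth band; (3) a maximum missing fraction; (4) a minimum standard
#' deviation of methylation levels (computed over non-missing samples).
#' Site order is preserved and the operation is idempotent.
#'
#' @param x A [methylome].
#' @param criteria A [filter_criteria()] object.
#' @return A filtered [methylome] with a `provenance` attribute recording
#'   the criteria and site counts.
#' @export
filter_sites <- function(x, criteria = filter_criteria()) {
  stopifnot(inherits(x, "methylome"), inherits(criteria, "filter_criteria"))
  depth <- meth_depth(x)
  lo <- criteria$sample_depth_range[1]
  hi <- criteria$sample_depth_range[2]
  bad <- !is.na(depth) & (depth < lo | depth > hi)
  meth <- x$meth
  unmeth <- x$unmeth
  meth[bad] <- NA_integer_
  unmeth[bad] <- NA_integer_
  depth[bad] <- NA_real_

  mean_depth <- rowMeans(depth, na.rm = TRUE)
  if (criteria$depth_basis == "single_stranded") mean_depth <- mean_depth / 2
  miss_frac <- rowMeans(is.na(depth))
  lev <- meth / (meth + unmeth)
  lev[!is.na(depth) & depth == 0] <- NA_real_
  sds <- apply(lev, 1, sd, na.rm = TRUE)

  keep <- !is.na(mean_depth) &
    mean_depth >= criteria$mean_depth_range[1] &
    mean_depth <= criteria$mean_depth_range[2] &
    miss_frac <= criteria$max_missing_fraction &
    !is.na(sds) & sds >= criteria$min_sd
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no site passes the filter criteria")
  out <- methylome(
    x$sites[keep, , drop = FALSE],
    meth[keep, , drop = FALSE],
    unmeth[keep, , drop = FALSE],
    samples = x$samples
  )
  attr(out, "provenance") <- list(
    criteria = unclass(criteria),
    n_sites_in = nrow(x$meth),
    n_sites_out = sum(keep)
  )
  out
}

#' Assemble a methylome from pooled per-sample site tables
#'
#' @param site_tables Named list of pooled site tibbles (one per sample,
#'   as returned by [pool_strands()]).
#' @return A [methylome] over the union of sites; samples lacking coverage
#'   at a site get missing cells.
#' @export
build_methylome <- function(site_tables) {
  stopifnot(length(site_tables) > 0, !is.null(names(site_tables)))
  all_sites <- dplyr::distinct(
    dplyr::bind_rows(lapply(site_tables, function(t) t[c("chrom", "pos")])),
  ) |> dplyr::arrange(.data$chrom, .data$pos)
  key <- site_key(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  samples <- names(site_tables)
  meth <- matrix(NA_integer_, n, length(samples),
                 dimnames = list(NULL, samples))
  unmeth <- meth
  for (s in samples) {
    t <- site_tables[[s]]
    idx <- match(site_key(t$chrom, t$pos), key)
    meth[idx, s] <- as.integer(t$meth)
    unmeth[idx, s] <- as.integer(t$unmeth)
  }
  methylome(all_sites, meth, unmeth, samples = samples)
}

#' Write / read a methylome as TSV
#'
#' The TSV has one row per site (`chrom`, `pos`) and a pair of columns
#' (`meth_<sample>`, `unmeth_<sample>`) per sample. `write_methylome()` also
#' writes a JSON provenance sidecar (`<path>.provenance.json`) when the
#' object carries one. The round trip reproduces counts exactly.
#'
#' @param x A [methylome].
#' @param path Output TSV path.
#' @return `path` (write) or a [methylome] (read).
#' @export
write_methylome <- function(x, path) {
  df <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                   check.names = FALSE)
  for (s in x$samples) {
    df[[paste0("meth_", s)]] <- x$meth[, s]
    df[[paste0("unmeth_", s)]] <- x$unmeth[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_methylome
#' @export
read_methylome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = list(chrom = "character"))
  meth_cols <- grep("^meth_", names(df), value = TRUE)
  samples <- sub("^meth_", "", meth_cols)
  meth <- as.matrix(df[paste0("meth_", samples)])
  unmeth <- as.matrix(df[paste0("unmeth_", samples)])
  storage.mode(meth) <- "integer"
  storage.mode(unmeth) <- "integer"
  methylome(df[c("chrom", "pos")], meth, unmeth, samples = samples)
}

#' Read a sample metadata table
#'
#' @param path TSV with header; must contain `sample_id`, `individual_id`,
#'   `group`, `age`; typically also `site_label`, `sex`,
#'   `conversion_efficiency`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "group", "age")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(df)
}
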
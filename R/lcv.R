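#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of its count to the gene's geometric mean across samples.
#' Reference genes are those with nonzero counts in every sample; when none
#' exists the estimator falls back to library-size scaling (total counts
#' divided by their geometric mean).
#'
#' @param counts Count matrix with >= 2 samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- validate_counts(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (all(counts == 0)) stop("all-zero count matrix")
  ref <- rowSums(counts == 0) == 0
  if (any(ref)) {
    logc <- log(counts[ref, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(logc - loggeo, 2, function(r) exp(median(r)))
  } else {
    warning("no gene observed in all samples; falling back to library-size scaling")
    libs <- colSums(counts)
    if (any(libs == 0)) stop("sample(s) with zero total counts: ",
                             paste(colnames(counts)[libs == 0], collapse = ", "))
    sf <- libs / exp(mean(log(libs)))
  }
  setNames(sf, colnames(counts))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count matrix.
#' @param factors Positive factors, one per sample (default
#'   [size_factors()]).
#' @return Numeric matrix of normalized values; multiplying column `j` by
#'   `factors[j]` recovers the raw counts.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- validate_counts(counts)
  if (length(factors) != ncol(counts))
    stop("need one factor per sample (", ncol(counts), "), got ", length(factors))
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  sweep(counts + 0, 2, unname(factors), "/")
}

#' Per-group replicate mean, sd and coefficient of variation
#'
#' Groups are the cross-type x time-point combinations from the metadata.
#' The sd uses the n - 1 denominator. Genes with zero mean in a group have
#' an undefined CV there and are returned as NA.
#'
#' @param norm Normalized matrix (see [normalize_counts()]).
#' @param meta Sample metadata.
#' @return List of gene x group matrices `n`, `mean`, `sd`, `cv` plus the
#'   group labels used.
#' @export
group_cv <- function(norm, meta) {
  meta <- as_sample_metadata(meta)
  if (!all(colnames(norm) %in% meta$sample_id))
    stop("samples without metadata: ",
         paste(setdiff(colnames(norm), meta$sample_id), collapse = ", "))
  grp <- meta$group[match(colnames(norm), meta$sample_id)]
  groups <- sort(unique(grp))
  n_rep <- table(grp)
  if (any(n_rep < 2))
    stop("group(s) with < 2 replicates: ",
         paste(names(n_rep)[n_rep < 2], collapse = ", "))
  mk <- function() matrix(NA_real_, nrow(norm), length(groups),
                          dimnames = list(rownames(norm), groups))
  m <- mk(); s <- mk(); n <- mk()
  for (g in groups) {
    sub <- norm[, grp == g, drop = FALSE]
    m[, g] <- rowMeans(sub)
    s[, g] <- apply(sub, 1, sd)
    n[, g] <- ncol(sub)
  }
  cv <- s / m
  cv[m == 0] <- NA_real_
  list(n = n, mean = m, sd = s, cv = cv, groups = groups)
}

# Percentile of each focal CV among its sliding-window competitors, for one
# group. Direct implementation of the windowed tied-rank percentile.
.lcv_one_group <- function(mean_g, cv_g, window_size, gene_ids) {
  defined <- !is.na(cv_g)
  nd <- sum(defined)
  if (nd < 2) stop("fewer than 2 genes with defined CV in a group")
  w <- window_size
  if (nd < w) {
    warning(sprintf("only %d defined genes; window shrunk from %d", nd, w))
    w <- nd
  }
  # order by mean expression ascending, ties broken by gene id
  idx <- which(defined)[order(mean_g[defined], gene_ids[defined])]
  cv_sorted <- cv_g[idx]
  out <- rep(NA_real_, length(cv_g))
  half <- (w - 1L) %/% 2L
  for (r in seq_len(nd)) {
    lo <- r - half
    lo <- max(1L, min(lo, nd - w + 1L))  # clamp so every window has w members
    win <- cv_sorted[lo:(lo + w - 1L)]
    rk <- rank(win)[r - lo + 1L]  # tied CVs share their mean rank
    out[idx[r]] <- 100 * (rk - 1) / (w - 1)
  }
  out
}

#' Local Coefficient of Variation (LCV) scores
#'
#' For each group independently, genes are ordered by group mean expression
#' (ascending, ties broken by gene id) and each gene's CV is ranked among
#' the CVs of the `window_size` genes in the window centred on its rank
#' (windows are clamped at the ends so every window has exactly
#' `window_size` members). The score is the percentile
#' `100 * (rank - 1) / (window_size - 1)` with tied CVs sharing their mean
#' rank: 0 marks the least variable gene in its expression neighbourhood,
#' 100 the most variable. Ranking within a window of similar-expression
#' genes controls the variability estimate for expression level.
#'
#' @param stats Output of [group_cv()].
#' @param window_size Window size in genes (default 500).
#' @return Gene x group matrix of LCV scores in \[0, 100\]; genes with
#'   undefined CV in a group are NA there. Attribute `window_size` records
#'   the window used.
#' @export
lcv_scores <- function(stats, window_size = 500L) {
  if (window_size < 2) stop("window_size must be >= 2")
  lcv <- stats$cv
  lcv[] <- NA_real_
  ids <- rownames(stats$cv)
  for (g in stats$groups)
    lcv[, g] <- .lcv_one_group(stats$mean[, g], stats$cv[, g],
                               as.integer(window_size), ids)
  structure(lcv, window_size = as.integer(window_size))
}

#' One-call LCV pipeline
#'
#' Normalizes counts (median-of-ratios), computes per-group CVs and returns
#' LCV scores.
#'
#' @inheritParams group_cv
#' @inheritParams lcv_scores
#' @param counts Count matrix.
#' @return List with `lcv` matrix, `stats` ([group_cv()] output) and
#'   `size_factors`.
#' @export
lcv_pipeline <- function(counts, meta, window_size = 500L) {
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  stats <- group_cv(norm, meta)
  list(lcv = lcv_scores(stats, window_size), stats = stats, size_factors = sf)
}
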
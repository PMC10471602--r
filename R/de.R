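#' Remove genes with fewer than `min_total` reads overall
#'
#' @param counts Count matrix.
#' @param min_total Minimum total count across all samples for a gene to be
#'   kept (default 10).
#' @return Filtered matrix with attributes `n_removed` and `blocked`
#'   (TRUE when no gene survives, which blocks downstream testing).
#' @export
filter_low_counts <- function(counts, min_total = 10L) {
  counts <- validate_counts(counts)
  keep <- rowSums(counts) >= min_total
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "blocked") <- nrow(out) == 0L
  if (nrow(out) == 0L)
    warning("all genes fall below the ", min_total, "-read filter; ",
            "downstream testing is blocked")
  out
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments on normalized counts: the pooled within-group variance
#' s^2 (group means removed, n - K denominator) and grand mean m give the
#' raw estimate `phi = max(0, (s^2 - m)/m^2)`; raw estimates are then shrunk
#' toward a fitted `a0/mu + a1` mean-dispersion trend with weight
#' `df / (df + n0)` (df = residual degrees of freedom, `n0` default 5) and
#' floored at 1e-8. Constant genes sit at the floor and are flagged.
#'
#' @param counts Count matrix (filtered).
#' @param meta Sample metadata; groups = cross-type x time point, each with
#'   >= 2 replicates.
#' @param n0 Shrinkage prior weight in pseudo-observations.
#' @param factors Optional size factors (default [size_factors()]).
#' @return Named numeric vector of dispersions with attributes `raw`,
#'   `trend` and `flagged_constant`.
#' @export
estimate_dispersion <- function(counts, meta, n0 = 5, factors = NULL) {
  counts <- validate_counts(counts)
  meta <- as_sample_metadata(meta)
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- normalize_counts(counts, factors)
  grp <- meta$group[match(colnames(norm), meta$sample_id)]
  tab <- table(grp)
  if (any(tab < 2))
    stop("group(s) with < 2 replicates: ", paste(names(tab)[tab < 2], collapse = ", "))
  K <- length(tab); N <- ncol(norm); df <- N - K
  ss <- 0
  for (g in names(tab)) {
    sub <- norm[, grp == g, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ss / df
  m <- rowMeans(norm)
  raw <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  # mean-dispersion trend phi = a0/mu + a1, least squares on the raw
  # estimates; with too few genes to anchor a trend the raw values stand
  usable <- m > 0
  trend <- raw
  if (sum(usable) >= 10) {
    fit <- stats::lm(raw[usable] ~ I(1 / m[usable]))
    a1 <- max(coef(fit)[1], 0); a0 <- max(coef(fit)[2], 0)
    trend <- ifelse(m > 0, a0 / m + a1, 0)
  }
  w <- df / (df + n0)
  phi <- pmax(w * raw + (1 - w) * trend, 1e-8)
  flagged <- s2 == 0
  phi[flagged] <- 1e-8
  structure(setNames(phi, rownames(counts)), raw = raw, trend = trend,
            flagged_constant = rownames(counts)[flagged])
}

#' Negative-binomial Wald test between two cross-types
#'
#' Per-gene NB generalized linear model with log link, design
#' `~ group (+ batch)` with log size factors as offsets and gene-wise
#' dispersions from [estimate_dispersion()] held fixed. The Wald statistic
#' is log2FC / SE with a two-sided standard-normal p-value;
#' Benjamini-Hochberg adjustment runs across the converged genes only
#' (non-converged fits are reported NA and excluded from the denominator).
#'
#' @param counts Filtered count matrix.
#' @param meta Sample metadata.
#' @param contrast Character pair `c(numerator, denominator)` of cross-types;
#'   the log2 fold change is numerator over denominator.
#' @param time_point Optional single time point to restrict to.
#' @param use_batch Include `batch` as a fixed effect (default FALSE).
#' @param dispersions Optional named dispersion vector; estimated from the
#'   full matrix when NULL.
#' @param padj_threshold Adjusted-p significance cutoff (default 0.1).
#' @return Data frame per gene: `gene_id`, `log2fc`, `se`, `wald`, `pvalue`,
#'   `padj`, `significant`, fitted normalized means `mean_<num>` and
#'   `mean_<den>`, and `phi`.
#' @export
de_wald_test <- function(counts, meta, contrast, time_point = NULL,
                         use_batch = FALSE, dispersions = NULL,
                         padj_threshold = 0.1) {
  counts <- validate_counts(counts)
  meta <- as_sample_metadata(meta)
  stopifnot(length(contrast) == 2, all(contrast %in% meta$cross_type))
  if (isTRUE(attr(counts, "blocked"))) stop("count matrix is empty after filtering")
  sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, meta, factors = sf)
  sel <- meta$cross_type %in% contrast
  if (!is.null(time_point)) sel <- sel & meta$time_point == time_point
  meta_s <- meta[sel, , drop = FALSE]
  if (!all(contrast %in% meta_s$cross_type))
    stop("contrast group(s) absent after subsetting")
  sub <- counts[, meta_s$sample_id, drop = FALSE]
  off <- log(sf[meta_s$sample_id])
  fgrp <- factor(meta_s$cross_type, levels = c(contrast[2], contrast[1]))
  use_batch <- use_batch && length(unique(meta_s$batch[!is.na(meta_s$batch)])) > 1
  X <- if (use_batch) {
    stats::model.matrix(~ fgrp + factor(meta_s$batch))
  } else stats::model.matrix(~ fgrp)

  G <- nrow(sub)
  log2fc <- se <- rep(NA_real_, G)
  mean_num <- mean_den <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- sub[g, ]
    theta <- 1 / max(dispersions[rownames(sub)[g]], 1e-8)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = MASS::negative.binomial(theta),
                               offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || any(!is.finite(coef(fit)))) next
    # Wald SE from the observed information of the working model
    w <- fit$weights
    XtWX <- crossprod(X * w, X)
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V)) next
    b <- coef(fit)[2]             # contrast coefficient (natural log)
    log2fc[g] <- b / log(2)
    se[g] <- sqrt(V[2, 2]) / log(2)
    eta0 <- drop(X %*% coef(fit)) # linear predictor without offsets
    mu_norm <- exp(eta0)
    mean_num[g] <- mean(mu_norm[fgrp == contrast[1]])
    mean_den[g] <- mean(mu_norm[fgrp == contrast[2]])
  }
  wald <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(wald))
  padj <- rep(NA_real_, G)
  ok <- !is.na(pvalue)
  padj[ok] <- bh_adjust(pvalue[ok])
  out <- data.frame(gene_id = rownames(sub), log2fc = log2fc, se = se,
                    wald = wald, pvalue = pvalue, padj = padj,
                    significant = !is.na(padj) & padj < padj_threshold,
                    phi = unname(dispersions[rownames(sub)]),
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", contrast[1])]] <- mean_num
  out[[paste0("mean_", contrast[2])]] <- mean_den
  attr(out, "contrast") <- contrast
  attr(out, "n_nonconverged") <- sum(!ok)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated front-end to `p.adjust(method = "BH")`:
#' `adjusted_(i) = min over j >= i of min(1, p_(j) * m / j)` with the
#' original order restored.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-sample proportion chi-squared test with Yates correction
#'
#' 2x2 chi-squared statistic `sum(max(|O - E| - 0.5, 0)^2 / E)` with a
#' 1-df reference distribution, as used to compare the proportion of
#' differentially expressed genes between contrasts.
#'
#' @param count1,n1 Successes and total of sample 1.
#' @param count2,n2 Successes and total of sample 2.
#' @return List `chi2`, `p_value`.
#' @export
proportion_chi2 <- function(count1, n1, count2, n2) {
  stopifnot(n1 > 0, n2 > 0, count1 >= 0, count2 >= 0, count1 <= n1, count2 <= n2)
  if (count1 + count2 == 0 || (n1 - count1) + (n2 - count2) == 0)
    stop("degenerate 2x2 table: a column margin is zero")
  ht <- suppressWarnings(prop.test(c(count1, count2), c(n1, n2), correct = TRUE))
  list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons.
#' @return List `exact` = alpha/m and `rounded` to 3 decimals, half away
#'   from zero (the convention used when thresholds are printed).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  exact <- alpha / m
  list(exact = exact, rounded = sign(exact) * floor(abs(exact) * 1000 + 0.5) / 1000)
}
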
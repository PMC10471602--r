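PATTERNS <- c("INTERMEDIATE", "MATERNAL", "PL_BIASED", "SB_BIASED",
              "OVERDOMINANT", "UNDERDOMINANT", "TRANSGRESSIVE_VARIABILITY",
              "CONSERVED", "AMBIGUOUS")

# canonical key for an unordered cross-type pair, e.g. "PLxPL.SBxSB"
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = ".")

#' @rdname classify_mean_inheritance
#' @export
mean_pattern_pairs <- function() {
  c(pair_key("PLxPL", "SBxSB"), pair_key("PLxSB", "PLxPL"),
    pair_key("PLxSB", "SBxSB"), pair_key("SBxPL", "PLxPL"),
    pair_key("SBxPL", "SBxSB"), pair_key("PLxSB", "SBxPL"))
}

# Deterministic rule cascade shared by both classifiers.
# sig: named logical over the 6 pair keys (TRUE = groups distinguishable);
# value: named numeric estimate per cross-type (fitted mean or posterior
# mode). Returns a single pattern label.
.classify_cascade <- function(sig, value, transgressive_label = "OVERDOMINANT",
                              extra_transgressive = NULL) {
  D <- function(a, b) unname(sig[pair_key(a, b)])
  v <- value
  pures_distinct <- D("PLxPL", "SBxSB")
  hyb <- c("PLxSB", "SBxPL")
  above <- function(h) D(h, "PLxPL") && D(h, "SBxSB") &&
    v[h] > v["PLxPL"] && v[h] > v["SBxSB"]
  below <- function(h) D(h, "PLxPL") && D(h, "SBxSB") &&
    v[h] < v["PLxPL"] && v[h] < v["SBxSB"]
  if (!is.null(extra_transgressive) && extra_transgressive(sig, value))
    return("TRANSGRESSIVE_VARIABILITY")
  if (is.null(extra_transgressive)) {
    if (all(vapply(hyb, above, logical(1)))) return("OVERDOMINANT")
    if (all(vapply(hyb, below, logical(1)))) return("UNDERDOMINANT")
  }
  if (pures_distinct) {
    maternal_of <- c(PLxSB = "PLxPL", SBxPL = "SBxSB")
    other_of <- c(PLxSB = "SBxSB", SBxPL = "PLxPL")
    like_mother <- vapply(hyb, function(h)
      !D(h, maternal_of[h]) && D(h, other_of[h]), logical(1))
    if (all(like_mother)) return("MATERNAL")
    like_pl <- vapply(hyb, function(h) !D(h, "PLxPL") && D(h, "SBxSB"), logical(1))
    if (all(like_pl)) return("PL_BIASED")
    like_sb <- vapply(hyb, function(h) !D(h, "SBxSB") && D(h, "PLxPL"), logical(1))
    if (all(like_sb)) return("SB_BIASED")
    lo <- min(v["PLxPL"], v["SBxSB"]); hi <- max(v["PLxPL"], v["SBxSB"])
    between <- vapply(hyb, function(h)
      D(h, "PLxPL") && D(h, "SBxSB") && v[h] > lo && v[h] < hi, logical(1))
    if (all(between)) return("INTERMEDIATE")
  }
  if (!any(sig)) return("CONSERVED")
  "AMBIGUOUS"
}

#' Classify mean-expression inheritance patterns per gene
#'
#' Applies a deterministic rule cascade to the significance flags of all six
#' pairwise cross-type contrasts and the fitted group means of each gene:
#' OVERDOMINANT / UNDERDOMINANT (each hybrid significantly outside both pure
#' crosses, same direction), MATERNAL (each hybrid indistinguishable from
#' its maternal pure cross and distinct from the other, pure crosses
#' distinct), PL_BIASED / SB_BIASED (both hybrids match one pure cross),
#' INTERMEDIATE (hybrids distinct from both pures with means strictly
#' between), CONSERVED (no significant contrast), else AMBIGUOUS. The
#' patterns are mutually exclusive and exhaustive.
#'
#' @param contrasts Named list of the six [de_wald_test()] results, one per
#'   unordered cross-type pair (any order; matched by their `contrast`
#'   attribute).
#' @return Data frame `gene_id`, `pattern`, the six `sig_<pair>` evidence
#'   flags and the four fitted means used, from which the pattern can be
#'   re-derived.
#' @export
classify_mean_inheritance <- function(contrasts) {
  keys <- vapply(contrasts, function(x) {
    ct <- attr(x, "contrast")
    if (is.null(ct)) stop("contrast result lacks its 'contrast' attribute")
    pair_key(ct[1], ct[2])
  }, character(1))
  names(contrasts) <- keys
  missing_pairs <- setdiff(mean_pattern_pairs(), keys)
  if (length(missing_pairs))
    stop("missing contrast(s): ", paste(missing_pairs, collapse = ", "))
  genes <- contrasts[[1]]$gene_id
  for (x in contrasts) if (!identical(x$gene_id, genes))
    stop("contrast results cover different gene sets")

  sig_mat <- vapply(mean_pattern_pairs(), function(k) contrasts[[k]]$significant,
                    logical(length(genes)))
  if (length(genes) == 1L) sig_mat <- matrix(sig_mat, 1, dimnames = list(NULL, mean_pattern_pairs()))
  # fitted mean of each cross-type, averaged over the contrasts that fit it
  means <- sapply(CROSS_TYPES, function(ct) {
    cols <- lapply(contrasts, function(x) x[[paste0("mean_", ct)]])
    rowMeans(do.call(cbind, Filter(Negate(is.null), cols)), na.rm = TRUE)
  })
  if (length(genes) == 1L) means <- matrix(means, 1, dimnames = list(NULL, CROSS_TYPES))

  pattern <- vapply(seq_along(genes), function(i)
    .classify_cascade(setNames(sig_mat[i, ], colnames(sig_mat)),
                      setNames(means[i, ], colnames(means))),
    character(1))
  out <- data.frame(gene_id = genes, pattern = pattern, stringsAsFactors = FALSE)
  colnames(sig_mat) <- paste0("sig_", gsub("\\.", "_", colnames(sig_mat)))
  cbind(out, as.data.frame(sig_mat), setNames(as.data.frame(means), paste0("mean_", CROSS_TYPES)))
}

#' Classify expression-variability inheritance patterns per cluster
#'
#' Applies the same rule cascade as [classify_mean_inheritance()] to the
#' per-cluster posterior summaries: distinguishability = non-overlap of the
#' 95% HPD intervals and the posterior modes play the role of the means.
#' In place of over-/underdominance, a cluster is TRANSGRESSIVE_VARIABILITY
#' when a hybrid's interval is disjoint from, and entirely outside the span
#' of, both pure crosses' intervals (either direction).
#'
#' @param posteriors Output of [cluster_posteriors()] with cross-type
#'   groups.
#' @return Data frame `cluster`, `pattern`, posterior modes and HPD bounds
#'   per cross-type.
#' @export
classify_variability_inheritance <- function(posteriors) {
  do.call(rbind, lapply(names(posteriors), function(nm) {
    summ <- posteriors[[nm]]$summary
    if (!all(CROSS_TYPES %in% summ$group))
      stop("cluster ", nm, ": need posterior summaries for all four cross-types")
    summ <- summ[match(CROSS_TYPES, summ$group), ]
    ov <- posteriors[[nm]]$overlap[CROSS_TYPES, CROSS_TYPES]
    sig <- setNames(vapply(mean_pattern_pairs(), function(k) {
      ab <- strsplit(k, ".", fixed = TRUE)[[1]]
      !ov[ab[1], ab[2]]
    }, logical(1)), mean_pattern_pairs())
    modes <- setNames(summ$mode, summ$group)
    lower <- setNames(summ$lower, summ$group)
    upper <- setNames(summ$upper, summ$group)
    transgressive <- function(sig, value) {
      any(vapply(c("PLxSB", "SBxPL"), function(h) {
        lower[h] > max(upper["PLxPL"], upper["SBxSB"]) ||
          upper[h] < min(lower["PLxPL"], lower["SBxSB"])
      }, logical(1)))
    }
    pat <- .classify_cascade(sig, modes, extra_transgressive = transgressive)
    row <- data.frame(cluster = nm, pattern = pat, stringsAsFactors = FALSE)
    for (ct in CROSS_TYPES) {
      row[[paste0("mode_", ct)]] <- modes[ct]
      row[[paste0("lower_", ct)]] <- lower[ct]
      row[[paste0("upper_", ct)]] <- upper[ct]
    }
    row
  }))
}
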
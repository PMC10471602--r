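# Small programmatic fixtures and independent brute-force oracles.

random_counts <- function(n_genes = 5, n_samples = 4, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# metadata for an arbitrary sample set split over the given cross-types
two_group_meta <- function(sample_ids, cross_types = c("PLxPL", "SBxSB"),
                           time_point = 150L) {
  ct <- rep(cross_types, length.out = length(sample_ids))
  as_sample_metadata(data.frame(
    sample_id = sample_ids,
    maternal_morph = substr(ct, 1, 2),
    paternal_morph = substr(ct, 4, 5),
    time_point = time_point,
    family_id = "famA",
    stringsAsFactors = FALSE))
}

full_design_meta <- function(reps = 9L) {
  simulate_experiment(simulation_config(n_genes = 1, replicates_per_group = reps,
                                        seed = 1))$metadata
}

# Brute-force LCV enumerator: for each gene, explicitly lists its window
# membership after ordering by mean (ties by id) and counts smaller and
# tied CVs. Independent of the package implementation.
brute_force_lcv <- function(mean_vec, cv_vec, window, ids = names(mean_vec)) {
  defined <- !is.na(cv_vec)
  ord <- order(mean_vec[defined], ids[defined])
  idx <- which(defined)[ord]
  nd <- length(idx)
  w <- min(window, nd)
  out <- rep(NA_real_, length(cv_vec))
  for (pos in seq_len(nd)) {
    start <- pos - (w - 1) %/% 2
    start <- max(1, min(start, nd - w + 1))
    members <- idx[start:(start + w - 1)]
    focal <- cv_vec[idx[pos]]
    smaller <- sum(cv_vec[members] < focal)
    ties <- sum(cv_vec[members] == focal)  # includes the focal gene
    mean_rank <- smaller + (ties + 1) / 2
    out[idx[pos]] <- 100 * (mean_rank - 1) / (w - 1)
  }
  out
}

# Brute-force silhouette widths from labels and a point matrix.
brute_force_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# LCV matrix built from archetype profiles plus Gaussian jitter.
archetype_lcv <- function(profiles, n_per, jitter_sd = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(i) {
    matrix(rep(profiles[i, ], each = n_per), n_per) +
      matrix(rnorm(n_per * ncol(profiles), 0, jitter_sd), n_per)
  }))
  x <- pmin(pmax(x, 0), 100)
  dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))), colnames(profiles))
  x
}

# Hand-built posterior summary for classifier tests.
fake_posterior <- function(intervals) {
  summ <- data.frame(group = names(intervals),
                     mode = vapply(intervals, mean, numeric(1)),
                     lower = vapply(intervals, `[`, numeric(1), 1),
                     upper = vapply(intervals, `[`, numeric(1), 2),
                     n_draws = 1000L, acf1 = 0, ess = 1000,
                     stringsAsFactors = FALSE)
  list(summary = summ, overlap = cri_overlap(summ))
}
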
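MEAN_PATTERNS <- c("intermediate", "maternal", "pl_biased", "sb_biased",
                   "overdominant", "underdominant")
VAR_PATTERNS <- c("maternal", "pl_biased", "sb_biased", "transgressive")

#' Configuration for the reciprocal-cross count simulator
#'
#' Defaults emulate the study design the pipeline targets: 4 cross-types
#' (PLxPL, PLxSB, SBxPL, SBxSB) x 2 time points (150, 200 tau-somites) x
#' 9 replicates (3 families x 3 embryos) = 72 samples, negative-binomial
#' counts with log-normal baseline means and a 1/mu + constant
#' dispersion-mean trend.
#'
#' Mean-expression inheritance patterns are planted as log2 shifts of the
#' group mean: pure crosses are split +/- `delta/2` log2 units around the
#' baseline and hybrids placed according to the pattern (intermediate at the
#' midpoint, maternal at their maternal pure cross, morph-biased at one pure
#' cross, over-/underdominant `delta` log2 units outside the pure-cross
#' range). Variability patterns are planted as dispersion scaling by `rho`
#' (never as mean shifts), so the level-controlled LCV statistic is what
#' should detect them: the high-variability groups of a pattern get
#' `rho * phi`, the others `phi`, and transgressive genes have both hybrids
#' at `rho * phi` with both pure crosses at `phi`. The default variability
#' fractions make the maternal pattern predominate, emulating the observed
#' predominance of maternally controlled expression variability in
#' reciprocal-cross data; with maternal patterns dominant, the group
#' dendrogram of LCV profiles pairs cross-types by maternal morph.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_group Embryos per cross-type x time-point group
#'   (default 9 = 3 families x 3 embryos).
#' @param baseline_log_mean Natural-log mean and sd of the log-normal
#'   baseline gene means; default `c(meanlog = log(100), sdlog = 1)`,
#'   a typical expressed-gene depth distribution for bulk RNA-seq.
#' @param dispersion_trend Coefficients `a0`, `a1` of the trend
#'   `phi = a0 / mu + a1` (defaults 3 and 0.05, a standard bulk shape).
#' @param mean_fractions Named fractions of genes per planted mean pattern
#'   (names among `"intermediate"`, `"maternal"`, `"pl_biased"`,
#'   `"sb_biased"`, `"overdominant"`, `"underdominant"`); remainder is
#'   conserved. Must sum to <= 1.
#' @param var_fractions Named fractions per planted variability pattern
#'   (names among `"maternal"`, `"pl_biased"`, `"sb_biased"`,
#'   `"transgressive"`); remainder conserved.
#' @param delta Log2 fold change separating the pure crosses for planted
#'   mean patterns (default 2).
#' @param rho Dispersion ratio for planted variability patterns (default 4).
#' @param library_size_range Per-sample scale factors drawn log-uniform in
#'   this range (default `c(0.7, 1.4)`), exercising normalization.
#' @param time_effect List `fraction`, `log2fc`: a global multiplicative
#'   shift applied to a random gene fraction at 200 tau-somites, mimicking a
#'   strong developmental-stage signal (defaults 0.3 and 1).
#' @param seed Integer seed.
#'
#' @details Each patterned gene is independently assigned a direction: which
#' morph lineage carries the high value (mean patterns and
#' maternal/morph-biased variability patterns) or whether hybrids lie above
#' or below the pure-cross span (transgressive variability). Balancing
#' directions keeps the transcriptome-wide composition symmetric between
#' morphs, which matters for the percentile-based LCV: a one-sided design
#' would depress the scores of unperturbed genes in the loaded groups.
#'
#' @return A validated configuration list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              replicates_per_group = 9L,
                              baseline_log_mean = c(meanlog = log(100), sdlog = 1),
                              dispersion_trend = c(a0 = 3, a1 = 0.05),
                              mean_fractions = c(intermediate = 0.05, maternal = 0.10,
                                                 pl_biased = 0.05, sb_biased = 0.05,
                                                 overdominant = 0.025, underdominant = 0.025),
                              var_fractions = c(maternal = 0.20, pl_biased = 0.06,
                                                sb_biased = 0.06, transgressive = 0.08),
                              delta = 2,
                              rho = 4,
                              library_size_range = c(0.7, 1.4),
                              time_effect = list(fraction = 0.3, log2fc = 1),
                              seed = 1L) {
  stopifnot(n_genes >= 1, replicates_per_group >= 2)
  if (length(bad <- setdiff(names(mean_fractions), MEAN_PATTERNS)))
    stop("unknown mean pattern(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(names(var_fractions), VAR_PATTERNS)))
    stop("unknown variability pattern(s): ", paste(bad, collapse = ", "))
  if (any(mean_fractions < 0) || sum(mean_fractions) > 1)
    stop("mean_fractions must be non-negative and sum to <= 1")
  if (any(var_fractions < 0) || sum(var_fractions) > 1)
    stop("var_fractions must be non-negative and sum to <= 1")
  if (rho <= 0) stop("rho must be positive")
  if (!is.finite(delta)) stop("delta must be finite")
  if (dispersion_trend[["a0"]] < 0 || dispersion_trend[["a1"]] < 0)
    stop("dispersion trend coefficients must be non-negative")
  if (any(library_size_range <= 0) || diff(library_size_range) < 0)
    stop("library_size_range must be positive and increasing")
  structure(list(
    n_genes = as.integer(n_genes),
    replicates_per_group = as.integer(replicates_per_group),
    baseline_log_mean = baseline_log_mean,
    dispersion_trend = dispersion_trend,
    mean_fractions = mean_fractions,
    var_fractions = var_fractions,
    delta = delta, rho = rho,
    library_size_range = library_size_range,
    time_effect = time_effect,
    seed = as.integer(seed)), class = "sim_config")
}

#' Theoretical negative-binomial coefficient of variation
#'
#' For NB counts with mean `mu` and dispersion `phi`
#' (variance = mu + phi * mu^2), CV = sqrt(1/mu + phi).
#'
#' @param mu Positive mean.
#' @param phi Non-negative dispersion.
#' @return The coefficient of variation.
#' @export
theoretical_cv <- function(mu, phi) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(phi < 0)) stop("phi must be non-negative")
  sqrt(1 / mu + phi)
}

# Per-pattern multiplicative mean factors for the four cross-types, given
# the pure-cross separation delta (log2) and which morph side is high.
# Assigning the high side per gene keeps the transcriptome-wide composition
# symmetric between morphs, as in real data.
.mean_factors <- function(pattern, delta, side = "PL") {
  hi <- 2^(delta / 2); lo <- 2^(-delta / 2)
  if (side == "SB") { tmp <- hi; hi <- lo; lo <- tmp }
  switch(pattern,
    conserved     = c(PLxPL = 1,  PLxSB = 1,  SBxPL = 1,  SBxSB = 1),
    intermediate  = c(PLxPL = hi, PLxSB = 1,  SBxPL = 1,  SBxSB = lo),
    maternal      = c(PLxPL = hi, PLxSB = hi, SBxPL = lo, SBxSB = lo),
    pl_biased     = c(PLxPL = hi, PLxSB = hi, SBxPL = hi, SBxSB = lo),
    sb_biased     = c(PLxPL = hi, PLxSB = lo, SBxPL = lo, SBxSB = lo),
    overdominant  = c(PLxPL = hi, PLxSB = 2^delta, SBxPL = 2^delta, SBxSB = lo),
    underdominant = c(PLxPL = hi, PLxSB = 2^-delta, SBxPL = 2^-delta, SBxSB = lo),
    stop("unknown mean pattern: ", pattern))
}

# Per-pattern dispersion scale factors; the high-variability groups of the
# pattern get rho. `side` picks which pure-morph lineage carries the high
# variability; transgressive genes take side "up" (hybrids at rho) or
# "down" (hybrids at 1/rho), outside the pure-cross span either way.
.phi_factors <- function(pattern, rho, side = "PL") {
  hi <- rho; lo <- 1
  if (side == "SB") { hi <- 1; lo <- rho }
  switch(pattern,
    conserved     = c(PLxPL = 1,  PLxSB = 1,  SBxPL = 1,  SBxSB = 1),
    maternal      = c(PLxPL = hi, PLxSB = hi, SBxPL = lo, SBxSB = lo),
    pl_biased     = c(PLxPL = hi, PLxSB = hi, SBxPL = hi, SBxSB = lo),
    sb_biased     = c(PLxPL = hi, PLxSB = lo, SBxPL = lo, SBxSB = lo),
    transgressive = {
      h <- if (side == "down") 1 / rho else rho
      c(PLxPL = 1, PLxSB = h, SBxPL = h, SBxSB = 1)
    },
    stop("unknown variability pattern: ", pattern))
}

#' Simulate a reciprocal-cross count experiment with planted patterns
#'
#' Draws NB counts with mean `s_j * mu_gk` for sample `j` in group `k`
#' (variance = mean + phi_gk * mean^2) and returns the counts, the sample
#' metadata and a truth table recording every planted label and the exact
#' per-group mean and dispersion used for each gene.
#'
#' @param config A [simulation_config()].
#' @return List with elements `counts` (integer matrix), `metadata`
#'   (data frame) and `truth` (data frame with columns `gene_id`,
#'   `mean_pattern`, `var_pattern`, `delta`, `rho`, `time_shifted` and
#'   `mean_<group>` / `phi_<group>` for the 8 groups).
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))

  # metadata: 3 families per cross-type, embryos split over both time points
  n_rep <- config$replicates_per_group
  fam_of_rep <- ((seq_len(n_rep) - 1L) %% 3L) + 1L
  meta <- do.call(rbind, lapply(CROSS_TYPES, function(ct) {
    do.call(rbind, lapply(TIME_POINTS, function(tp) {
      data.frame(
        sample_id = sprintf("%s_%d_f%d_e%d", ct, tp, fam_of_rep, seq_len(n_rep)),
        maternal_morph = substr(ct, 1, 2), paternal_morph = substr(ct, 4, 5),
        time_point = tp, family_id = sprintf("%s_f%d", ct, fam_of_rep),
        stringsAsFactors = FALSE)
    }))
  }))
  meta <- as_sample_metadata(meta)

  mu0 <- rlnorm(G, config$baseline_log_mean[["meanlog"]],
                config$baseline_log_mean[["sdlog"]])
  phi0 <- config$dispersion_trend[["a0"]] / mu0 + config$dispersion_trend[["a1"]]

  assign_labels <- function(fracs) {
    n_per <- floor(fracs * G)
    labels <- rep("conserved", G)
    idx <- sample.int(G, sum(n_per))
    labels[idx] <- rep(names(n_per), n_per)
    labels
  }
  mean_pattern <- assign_labels(config$mean_fractions)
  var_pattern <- assign_labels(config$var_fractions)
  mean_side <- ifelse(mean_pattern == "conserved", NA,
                      sample(c("PL", "SB"), G, replace = TRUE))
  var_side <- ifelse(var_pattern == "conserved", NA,
                     ifelse(var_pattern == "transgressive",
                            sample(c("up", "down"), G, replace = TRUE),
                            sample(c("PL", "SB"), G, replace = TRUE)))
  time_shifted <- runif(G) < config$time_effect$fraction

  groups <- analysis_groups()
  mu_mat <- matrix(NA_real_, G, length(groups), dimnames = list(gene_ids, groups))
  phi_mat <- mu_mat
  for (g in seq_len(G)) {
    mf <- .mean_factors(mean_pattern[g], config$delta,
                        if (is.na(mean_side[g])) "PL" else mean_side[g])
    pf <- .phi_factors(var_pattern[g], config$rho,
                       if (is.na(var_side[g])) "PL" else var_side[g])
    for (ct in CROSS_TYPES) for (tp in TIME_POINTS) {
      shift <- if (time_shifted[g] && tp == 200L) 2^config$time_effect$log2fc else 1
      grp <- paste(ct, tp, sep = "_")
      mu_mat[g, grp] <- mu0[g] * mf[[ct]] * shift
      phi_mat[g, grp] <- phi0[g] * pf[[ct]]
    }
  }
  if (any(mu_mat <= 0)) stop("infeasible config: non-positive expected mean")

  sf <- exp(runif(nrow(meta), log(config$library_size_range[1]),
                  log(config$library_size_range[2])))
  counts <- matrix(0L, G, nrow(meta), dimnames = list(gene_ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    grp <- meta$group[j]
    size <- 1 / pmax(phi_mat[, grp], 1e-12)
    counts[, j] <- rnbinom(G, mu = sf[j] * mu_mat[, grp], size = size)
  }

  truth <- data.frame(gene_id = gene_ids, mean_pattern = mean_pattern,
                      mean_side = mean_side, var_pattern = var_pattern,
                      var_side = var_side, delta = config$delta,
                      rho = config$rho, time_shifted = time_shifted,
                      stringsAsFactors = FALSE)
  colnames(mu_mat) <- paste0("mean_", groups)
  colnames(phi_mat) <- paste0("phi_", sub("^mean_", "", groups))
  truth <- cbind(truth, as.data.frame(mu_mat), as.data.frame(phi_mat))
  rownames(truth) <- NULL

  list(counts = validate_counts(counts), metadata = meta, truth = truth,
       size_factors_true = setNames(sf, meta$sample_id))
}

#' Planted variability clusters from a simulation truth table
#'
#' Groups genes by planted variability pattern and direction — the gene
#' sets that covary by construction and that an ideal profile clustering
#' would recover — and returns them as a cluster assignment usable with
#' [cluster_posteriors()], together with the inheritance label each cluster
#' should receive.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param gene_ids Optional subset of genes to keep (e.g. after filtering).
#' @return List: `assignment` (class `lcv_clusters`) and `expected`
#'   (data frame `cluster`, `planted`, `expected_label`, `n_genes`).
#' @export
planted_variability_clusters <- function(truth, gene_ids = NULL) {
  if (!is.null(gene_ids)) truth <- truth[truth$gene_id %in% gene_ids, ]
  key <- ifelse(is.na(truth$var_side), truth$var_pattern,
                paste(truth$var_pattern, truth$var_side, sep = "_"))
  sets <- sort(unique(key))
  lab <- match(key, sets)
  label_map <- c(conserved = "CONSERVED", maternal = "MATERNAL",
                 pl_biased = "PL_BIASED", sb_biased = "SB_BIASED",
                 transgressive = "TRANSGRESSIVE_VARIABILITY")
  expected <- data.frame(
    cluster = paste0("cluster", seq_along(sets)),
    planted = sets,
    expected_label = unname(label_map[sub("_(PL|SB|up|down)$", "", sets)]),
    n_genes = tabulate(lab, length(sets)),
    stringsAsFactors = FALSE)
  assignment <- structure(list(
    cluster = setNames(lab, truth$gene_id), k = length(sets),
    sizes = tabulate(lab, length(sets)), centers = NULL,
    tot_withinss = NA_real_, excluded = character(),
    seed = NA_integer_, n_restarts = 0L), class = "lcv_clusters")
  list(assignment = assignment, expected = expected)
}
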
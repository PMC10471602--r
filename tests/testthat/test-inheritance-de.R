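test_that("low-count filtering keeps genes at or above the read threshold", {
  m <- matrix(c(3L, 3L, 3L, 4L, 3L, 3L, 5L, 3L, 3L), 3, 3, byrow = TRUE,
              dimnames = list(c("g9", "g10", "g11"), c("s1", "s2", "s3")))
  flt <- filter_low_counts(m, 10)
  expect_identical(rownames(flt), c("g10", "g11"))
  expect_identical(attr(flt, "n_removed"), 1L)

  expect_identical(rownames(filter_low_counts(m, 0)), rownames(m))

  expect_warning(empty <- filter_low_counts(m, 1000), "blocked")
  expect_identical(nrow(empty), 0L)
  expect_true(attr(empty, "blocked"))
  meta <- two_group_meta(colnames(m))
  expect_error(de_wald_test(empty, meta, c("PLxPL", "SBxSB")))
})

test_that("dispersion estimation recovers planted values and handles edge cases", {
  set.seed(41)
  n <- 1000
  meta <- two_group_meta(sprintf("s%04d", 1:n))
  counts <- t(sapply(1:40, function(i) rnbinom(n, mu = 100, size = 1 / 0.2)))
  dimnames(counts) <- list(sprintf("g%02d", 1:40), meta$sample_id)
  storage.mode(counts) <- "integer"
  phi <- estimate_dispersion(counts, meta)
  expect_true(all(abs(phi - 0.2) / 0.2 < 0.2))

  # Poisson genes: dispersion collapses toward zero
  pois <- t(sapply(1:40, function(i) rpois(n, 100)))
  dimnames(pois) <- dimnames(counts); storage.mode(pois) <- "integer"
  phi0 <- estimate_dispersion(pois, meta)
  expect_true(all(phi0 < 0.02))

  # constant gene (in normalized units) pinned at the floor and flagged
  const <- counts
  const[1, ] <- 50L
  phic <- estimate_dispersion(const, meta,
                              factors = setNames(rep(1, n), meta$sample_id))
  expect_identical(unname(phic["g01"]), 1e-8)
  expect_identical(attr(phic, "flagged_constant"), "g01")
})

test_that("the NB Wald test is antisymmetric in the contrast direction", {
  sim <- simulate_experiment(simulation_config(n_genes = 150, seed = 31))
  flt <- filter_low_counts(sim$counts)
  disp <- estimate_dispersion(flt, sim$metadata)
  a <- de_wald_test(flt, sim$metadata, c("PLxPL", "SBxSB"), time_point = 150,
                    dispersions = disp)
  b <- de_wald_test(flt, sim$metadata, c("SBxSB", "PLxPL"), time_point = 150,
                    dispersions = disp)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-6)
  expect_equal(a$mean_PLxPL, b$mean_PLxPL, tolerance = 1e-6)
  expect_true(all(a$padj >= a$pvalue - 1e-12, na.rm = TRUE))
})

test_that("planted fold changes are detected and their size estimated", {
  sim <- simulate_experiment(simulation_config(n_genes = 500, seed = 61))
  flt <- filter_low_counts(sim$counts)
  de <- de_wald_test(flt, sim$metadata, c("PLxPL", "SBxSB"), time_point = 200)
  tr <- sim$truth[match(de$gene_id, sim$truth$gene_id), ]
  planted <- tr$mean_pattern %in% c("maternal", "intermediate", "pl_biased",
                                    "sb_biased")
  expect_gte(mean(de$significant[planted]), 0.95)
  # log2FC direction follows the planted side; magnitude ~ delta = 2
  sgn <- ifelse(tr$mean_side[planted] == "PL", 1, -1)
  expect_equal(median(de$log2fc[planted] * sgn), 2, tolerance = 0.2)
  # conserved genes rarely called
  expect_lt(mean(de$significant[tr$mean_pattern == "conserved"]), 0.1)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(51)
  p <- runif(200)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the mean-expression rule cascade reproduces its defining examples", {
  mk_contrast <- function(pair, sig, mean1, mean2) {
    df <- data.frame(gene_id = "g1", log2fc = log2(mean1 / mean2), se = 0.1,
                     wald = 0, pvalue = ifelse(sig, 0.001, 0.5),
                     padj = ifelse(sig, 0.001, 0.5), significant = sig,
                     phi = 0.05, stringsAsFactors = FALSE)
    df[[paste0("mean_", pair[1])]] <- mean1
    df[[paste0("mean_", pair[2])]] <- mean2
    attr(df, "contrast") <- pair
    df
  }
  # maternal: hybrids track their mother; pure crosses differ
  means <- c(PLxPL = 40, PLxSB = 41, SBxPL = 10, SBxSB = 11)
  sig <- list(c("PLxPL", "SBxSB", TRUE), c("PLxSB", "PLxPL", FALSE),
              c("PLxSB", "SBxSB", TRUE), c("SBxPL", "PLxPL", TRUE),
              c("SBxPL", "SBxSB", FALSE), c("PLxSB", "SBxPL", TRUE))
  ctr <- lapply(sig, function(s)
    mk_contrast(c(s[1], s[2]), as.logical(s[3]), means[[s[1]]], means[[s[2]]]))
  expect_identical(classify_mean_inheritance(ctr)$pattern, "MATERNAL")

  # overdominant: both hybrids significantly above both pures
  means2 <- c(PLxPL = 5, PLxSB = 12, SBxPL = 11, SBxSB = 6)
  sig2 <- lapply(sig, function(s) { s[3] <- TRUE; s })
  sig2[[6]][3] <- FALSE
  ctr2 <- lapply(sig2, function(s)
    mk_contrast(c(s[1], s[2]), as.logical(s[3]), means2[[s[1]]], means2[[s[2]]]))
  expect_identical(classify_mean_inheritance(ctr2)$pattern, "OVERDOMINANT")

  # no significant contrast anywhere: conserved
  ctr3 <- lapply(sig, function(s)
    mk_contrast(c(s[1], s[2]), FALSE, means[[s[1]]], means[[s[2]]]))
  expect_identical(classify_mean_inheritance(ctr3)$pattern, "CONSERVED")

  expect_error(classify_mean_inheritance(ctr[1:5]), "missing contrast")
})

test_that("the cascade is exhaustive, exclusive and morph-symmetric", {
  pairs <- mean_pattern_pairs()
  set.seed(71)
  cross <- c("PLxPL", "PLxSB", "SBxPL", "SBxSB")
  swap_name <- function(x) chartr("PSLB", "SPBL", x)  # PL <-> SB everywhere
  relabel_pattern <- c(INTERMEDIATE = "INTERMEDIATE", MATERNAL = "MATERNAL",
                       PL_BIASED = "SB_BIASED", SB_BIASED = "PL_BIASED",
                       OVERDOMINANT = "OVERDOMINANT",
                       UNDERDOMINANT = "UNDERDOMINANT",
                       CONSERVED = "CONSERVED", AMBIGUOUS = "AMBIGUOUS")
  for (bits in 0:63) {
    sig <- setNames(as.logical(bitwAnd(bits, 2^(0:5))), pairs)
    for (rep in 1:3) {
      value <- setNames(sample(c(3, 7, 11, 19)), cross)
      pat <- canalex:::.classify_cascade(sig, value)
      expect_true(pat %in% c("INTERMEDIATE", "MATERNAL", "PL_BIASED",
                             "SB_BIASED", "OVERDOMINANT", "UNDERDOMINANT",
                             "CONSERVED", "AMBIGUOUS"))
      # relabelling the morphs maps the call through the expected involution
      sig_sw <- setNames(sig, vapply(names(sig), function(k) {
        ab <- swap_name(strsplit(k, ".", fixed = TRUE)[[1]])
        paste(sort(ab), collapse = ".")
      }, character(1)))[pairs]
      value_sw <- setNames(value, swap_name(names(value)))[cross]
      pat_sw <- canalex:::.classify_cascade(sig_sw, value_sw)
      expect_identical(pat_sw, unname(relabel_pattern[pat]))
    }
  }
})

test_that("variability patterns are read off posterior interval geometry", {
  post <- list(cluster1 = fake_posterior(list(
    PLxPL = c(40, 50), PLxSB = c(41, 51), SBxPL = c(69, 79), SBxSB = c(70, 80))))
  expect_identical(classify_variability_inheritance(post)$pattern, "MATERNAL")

  post2 <- list(cluster1 = fake_posterior(list(
    PLxPL = c(40, 50), PLxSB = c(39, 50), SBxPL = c(41, 52), SBxSB = c(70, 80))))
  expect_identical(classify_variability_inheritance(post2)$pattern, "PL_BIASED")

  post3 <- list(cluster1 = fake_posterior(list(
    PLxPL = c(40, 50), PLxSB = c(90, 95), SBxPL = c(88, 96), SBxSB = c(55, 65))))
  expect_identical(classify_variability_inheritance(post3)$pattern,
                   "TRANSGRESSIVE_VARIABILITY")

  post4 <- list(cluster1 = fake_posterior(list(
    PLxPL = c(40, 50), PLxSB = c(42, 49), SBxPL = c(44, 52), SBxSB = c(41, 51))))
  expect_identical(classify_variability_inheritance(post4)$pattern, "CONSERVED")

  broken <- post
  broken$cluster1$summary <- broken$cluster1$summary[-2, ]
  expect_error(classify_variability_inheritance(broken), "all four")
})

test_that("proportion tests reproduce worked chi-squared values", {
  # equal large totals: near-identical counts give a vanishing statistic
  expect_equal(proportion_chi2(13, 41098, 14, 41098)$chi2, 0, tolerance = 5e-4)
  # 44 vs 33: statistic stable across any equal totals >= 20,000
  for (n in c(20000, 41098, 100000)) {
    expect_equal(proportion_chi2(44, n, 33, n)$chi2, 1.299, tolerance = 2e-3)
  }
  got <- proportion_chi2(337, 41098, 192, 41098)
  expect_equal(got$chi2, 39.449, tolerance = 0.01)
  expect_lt(got$p_value, 0.001)

  # symmetry and exact zero for identical samples
  expect_equal(proportion_chi2(44, 41098, 33, 41098)$chi2,
               proportion_chi2(33, 41098, 44, 41098)$chi2)
  expect_equal(proportion_chi2(25, 1000, 25, 1000)$chi2, 0)
  expect_error(proportion_chi2(0, 100, 0, 100), "margin")
})

test_that("Bonferroni thresholds are exact and printed to three decimals", {
  th <- bonferroni_threshold(0.05, 4)
  expect_equal(th$exact, 0.0125)
  expect_equal(th$rounded, 0.013)
  expect_equal(bonferroni_threshold(0.037, 1)$exact, 0.037)
  expect_equal(bonferroni_threshold(0.05, 5)$exact, 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})
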
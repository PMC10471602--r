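test_that("median-of-ratios size factors match closed forms", {
  m <- random_counts(10, 2, seed = 4, lambda = 50) + 1L  # no zeros
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- m
  m2[, 2] <- 2L * m2[, 1]
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  # all-zero genes are excluded from the reference set
  m3 <- rbind(m2, zero = c(0L, 0L))
  expect_equal(size_factors(m3), size_factors(m2))

  zeros <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_error(size_factors(zeros), "all-zero")
})

test_that("normalization divides by factors and round-trips", {
  m <- random_counts(6, 3, seed = 5)
  expect_equal(normalize_counts(m, c(1, 1, 1)), m + 0, ignore_attr = TRUE)
  one <- matrix(10L, 1, 1, dimnames = list("g", "s"))
  expect_error(normalize_counts(one, c(2, 2)), "one factor per sample")
  expect_equal(unname(normalize_counts(one, 2)[1, 1]), 5)
  f <- c(0.5, 1.3, 2.1)
  norm <- normalize_counts(m, f)
  expect_equal(sweep(norm, 2, f, "*"), m + 0, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("group statistics use the n-1 sd and flag zero means", {
  norm <- matrix(c(5, 5, 5, 1, 2, 3, 0, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("ga", "gb", "gc"), c("s1", "s2", "s3")))
  meta <- two_group_meta(colnames(norm), "PLxPL")
  st <- group_cv(norm, meta)
  expect_equal(unname(st$cv["ga", 1]), 0)
  expect_equal(unname(st$mean["gb", 1]), 2)
  expect_equal(unname(st$sd["gb", 1]), 1)
  expect_equal(unname(st$cv["gb", 1]), 0.5)
  expect_true(is.na(st$cv["gc", 1]))

  perm <- c("s3", "s1", "s2")
  expect_equal(group_cv(norm[, perm], meta), st)

  expect_error(group_cv(norm[, 1, drop = FALSE], meta[1, ]), "< 2 replicates")
})

test_that("LCV endpoints are attained by window extremes", {
  # 10 genes, one group; focal with smallest cv -> 0, largest -> 100
  n <- 10
  mean_g <- matrix(seq_len(n), n, 1, dimnames = list(sprintf("g%02d", 1:n), "PLxPL_150"))
  cv_g <- matrix(c(0.01, rep(0.5, n - 2), 0.99), n, 1,
                 dimnames = dimnames(mean_g))
  st <- list(mean = mean_g, cv = cv_g, groups = "PLxPL_150")
  lcv <- lcv_scores(st, window_size = n)
  expect_equal(unname(lcv[1, 1]), 0)
  expect_equal(unname(lcv[n, 1]), 100)
  expect_true(all(lcv >= 0 & lcv <= 100))
})

test_that("LCV equals the brute-force window enumerator exactly", {
  set.seed(31)
  for (case in list(c(20, 5), c(120, 2), c(120, 20), c(500, 20), c(57, 8))) {
    n <- case[1]; w <- case[2]
    mean_g <- matrix(rlnorm(n, 3, 1), n, 1,
                     dimnames = list(sprintf("g%04d", 1:n), "PLxPL_150"))
    cv_g <- matrix(sample(round(runif(n), 2)), n, 1, dimnames = dimnames(mean_g))
    st <- list(mean = mean_g, cv = cv_g, groups = "PLxPL_150")
    got <- lcv_scores(st, w)[, 1]
    want <- brute_force_lcv(mean_g[, 1], cv_g[, 1], w,
                            ids = rownames(mean_g))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("tied CVs in one window share their score", {
  mean_g <- matrix(1:6, 6, 1, dimnames = list(letters[1:6], "PLxPL_150"))
  cv_g <- matrix(c(0.2, 0.4, 0.4, 0.4, 0.1, 0.9), 6, 1, dimnames = dimnames(mean_g))
  st <- list(mean = mean_g, cv = cv_g, groups = "PLxPL_150")
  lcv <- lcv_scores(st, 6)
  expect_equal(lcv["b", 1], lcv["c", 1])
  expect_equal(lcv["c", 1], lcv["d", 1])
})

test_that("LCV is invariant to rescaling a group and monotone in the focal CV", {
  set.seed(17)
  n <- 60
  base_mean <- rlnorm(n, 4, 1)
  base_cv <- runif(n, 0.05, 1)
  ids <- sprintf("g%03d", 1:n)
  mk <- function(mean_v, cv_v)
    list(mean = matrix(mean_v, n, 1, dimnames = list(ids, "PLxPL_150")),
         cv = matrix(cv_v, n, 1, dimnames = list(ids, "PLxPL_150")),
         groups = "PLxPL_150")
  l1 <- lcv_scores(mk(base_mean, base_cv), 11)
  # multiplying every normalized value by c scales mean and sd alike: cv fixed
  l2 <- lcv_scores(mk(base_mean * 3.7, base_cv), 11)
  expect_equal(l1, l2)

  # raising the focal cv never lowers its score
  for (focal in c(1, 25, 60)) {
    cv_up <- base_cv
    cv_up[focal] <- cv_up[focal] * 1.5
    l3 <- lcv_scores(mk(base_mean, cv_up), 11)
    expect_gte(l3[focal, 1], l1[focal, 1])
  }
})

test_that("windows shrink with warning and tiny groups error", {
  mean_g <- matrix(1:4, 4, 1, dimnames = list(letters[1:4], "PLxPL_150"))
  cv_g <- matrix(c(0.1, 0.2, NA, 0.4), 4, 1, dimnames = dimnames(mean_g))
  st <- list(mean = mean_g, cv = cv_g, groups = "PLxPL_150")
  expect_warning(lcv <- lcv_scores(st, 5), "window shrunk")
  expect_true(is.na(lcv["c", 1]))
  expect_equal(sort(unname(lcv[!is.na(lcv[, 1]), 1])), c(0, 50, 100))

  cv1 <- matrix(c(0.1, NA, NA, NA), 4, 1, dimnames = dimnames(mean_g))
  expect_error(lcv_scores(list(mean = mean_g, cv = cv1, groups = "PLxPL_150"), 5),
               "fewer than 2")
})

test_that("planted high-dispersion genes score higher LCV in their group", {
  cfg <- simulation_config(n_genes = 600, mean_fractions = c(maternal = 0),
                           var_fractions = c(pl_biased = 0.15), seed = 77)
  sim <- simulate_experiment(cfg)
  res <- lcv_pipeline(sim$counts, sim$metadata, window_size = 100)
  planted <- sim$truth$var_pattern == "pl_biased" & sim$truth$var_side == "PL"
  high <- res$lcv[planted, c("PLxPL_150", "PLxPL_200")]
  low <- res$lcv[planted, c("SBxSB_150", "SBxSB_200")]
  expect_gt(median(high, na.rm = TRUE), median(low, na.rm = TRUE))
})
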
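test_that("standardization uses the n-1 denominator and is invertible", {
  z <- standardize_features(matrix(c(0, 2), ncol = 1,
                                   dimnames = list(NULL, "a")))
  expect_equal(as.numeric(z), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(11)
  x <- matrix(rnorm(60, 5, 3), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  z <- standardize_features(x)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  # idempotent and invertible
  z2 <- standardize_features(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unstandardize_features(z), x, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("standardization rejects constant columns and imputes NaN with warning", {
  x <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(standardize_features(x), "constant feature column.*a")
  x2 <- cbind(a = c(1, NaN, 3), b = c(1, 2, 4))
  expect_warning(z <- standardize_features(x2), "mean-imputing.*a")
  expect_equal(attr(z, "center")[["a"]], 2)  # imputed with the column mean
})

test_that("Ward clustering produces monotone dendrograms with sane first merges", {
  # two identical rows merge at height zero
  x <- rbind(c(0, 0), c(0, 0), c(3, 4))
  hc <- ward_cluster(x)
  expect_equal(hc$height[1], 0)
  # three points on a line at 0, 1, 10: cheapest merge is {0, 1}
  x3 <- matrix(c(0, 1, 10), ncol = 1)
  hc3 <- ward_cluster(x3)
  expect_setequal(-hc3$merge[1, ], c(1, 2))
  # merge heights are non-decreasing on random matrices
  set.seed(22)
  for (rep in 1:20) {
    hcr <- ward_cluster(matrix(rnorm(20 * 5), 20))
    expect_true(all(diff(hcr$height) >= -1e-9))
  }
  expect_error(ward_cluster(matrix(0, 1, 2)), "at least 2")
})

test_that("silhouette selects the constructed number of well-separated blobs", {
  set.seed(33)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(10, 0, 0.5), ncol = 2), 2, centers[k, ], `+`)))
  truth <- rep(1:3, each = 5)
  hc <- ward_cluster(x)
  asg <- silhouette_select_k(x, hc)
  expect_equal(asg$k, 3L)
  expect_gt(asg$mean_silhouette, 0.7)
  expect_equal(mclust::adjustedRandIndex(asg$labels, truth), 1)
  # an unseparated blob scores below the separated construction
  x0 <- matrix(rnorm(30, 0, 0.5), ncol = 2)
  hc0 <- ward_cluster(x0)
  asg0 <- silhouette_select_k(x0, hc0)
  expect_lt(asg0$mean_silhouette, asg$mean_silhouette)
})

test_that("the dendrogram exports as Newick with merge heights", {
  x <- matrix(rnorm(10 * 3), 10, dimnames = list(paste0("n", 1:10), NULL))
  hc <- ward_cluster(x)
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  export_dendrogram(hc, f1, f2)
  phy <- ape::read.tree(f1)
  expect_equal(sort(phy$tip.label), sort(paste0("n", 1:10)))
  merges <- read.csv(f2)
  expect_equal(nrow(merges), 9L)
  expect_true(all(diff(merges$height) >= -1e-9))
})

test_that("Pearson correlation matches closed-form arithmetic", {
  # exact linear relation
  r1 <- correlation_terminals(1:10, 2 * (1:10))
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-12)
  # hand table {(1,2),(2,1),(3,3)}: r = 0.5
  r2 <- correlation_terminals(c(1, 2, 3), c(2, 1, 3))
  expect_equal(r2$r, 0.5, tolerance = 1e-12)
  tstat <- 0.5 * sqrt(1) / sqrt(1 - 0.25)
  expect_equal(r2$p, 2 * pt(-tstat, df = 1), tolerance = 1e-12)
  expect_error(correlation_terminals(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlation_terminals(1:2, 1:2), "length")
})

test_that("the anteroposterior trend test reports F, p and slope sign", {
  pos <- seq(-300, 100, length.out = 12)
  # perfectly linear negative slope (R warns about the perfect fit)
  tr <- suppressWarnings(trend_test(5000 - 10 * pos, pos))
  expect_lt(tr$p, 1e-12)
  expect_lt(tr$slope, 0)
  # constant response: no trend
  tr0 <- trend_test(rep(100, 12), pos)
  expect_equal(tr0$F, 0)
  expect_equal(tr0$p, 1)
  # exclusion variant drops the labelled neurons
  lab <- rep(c("HB", "RB"), 6)
  tr2 <- suppressWarnings(trend_test(5000 - 10 * pos, pos,
                                     labels = lab, exclude = "RB"))
  expect_equal(tr2$n, 6L)
  expect_error(trend_test(1:5, rep(1, 5)), "constant predictor")
})

test_that("the length comparison implements the printed chi-square plus an alternative", {
  eq <- length_comparison(c(10, 20, 20), c(20, 10, 20))
  expect_equal(eq$chi_square$statistic, 0)
  expect_equal(eq$chi_square$p, 1)
  # totals (75, 25) against equal expectation: (25^2/50)*2 = 25
  lc <- length_comparison(75, 25)
  expect_equal(lc$chi_square$statistic, 25)
  expect_equal(lc$chi_square$p, pchisq(25, 1, lower.tail = FALSE))
  expect_true(!is.null(lc$wilcoxon$p))
  expect_error(length_comparison(c(0, 0), c(0, 0)), "zero")
})

test_that("clustering the full synthetic cohort recovers the growth regimes", {
  cfg <- small_config(seed = 3, n = c(10, 7, 3), n_unbranched = 0)
  co <- generate_cohort(cfg)
  feats <- cohort_features(co)
  m <- as.matrix(feats[, feature_columns()])
  rownames(m) <- feats$neuron_id
  z <- standardize_features(m)
  hc <- ward_cluster(z)
  lab <- cutree(hc, k = 3)
  expect_equal(mclust::adjustedRandIndex(lab, co$regime[feats$neuron_id]), 1)
})

test_that("leave-one-feature-out stability reports one row per feature", {
  set.seed(44)
  gf <- generate_feature_cohort(c(8, 6, 4), separation = 4)
  st <- loo_feature_stability(gf$x, k = 3)
  expect_equal(nrow(st), 13L)
  expect_true(all(st$ari >= -1 & st$ari <= 1))
  # with this separation, dropping any single feature preserves the clusters
  expect_true(mean(st$ari == 1) >= 0.9)
})
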
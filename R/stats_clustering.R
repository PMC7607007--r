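# Feature standardization, Ward agglomerative clustering with silhouette
# model selection, and the cohort-level statistical comparisons (Pearson
# correlation of terminal counts, anteroposterior trend ANOVA, axial-vs-fin
# length comparison).

#' Standardize a feature matrix
#'
#' Scales every column to mean 0 and standard deviation 1 (n - 1
#' denominator). `NaN`/`NA` cells (the sentinel values a non-branching arbor
#' produces) are imputed with the column mean of the observed values, with a
#' warning naming the columns. Constant columns are rejected. The scaling
#' parameters are retained as attributes `center` and `scale` so the
#' transform is invertible.
#'
#' @param x Numeric matrix or data frame (rows = neurons).
#' @return Standardized numeric matrix with attributes `center`, `scale`.
#' @export
standardize_features <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 rows to standardize")
  nas <- colSums(!is.finite(m))
  if (any(nas > 0)) {
    warning("mean-imputing missing values in column(s): ",
            paste(colnames(m)[nas > 0], collapse = ", "))
    for (j in which(nas > 0)) {
      ok <- is.finite(m[, j])
      if (!any(ok)) stop("column has no observed values: ", colnames(m)[j])
      m[!ok, j] <- mean(m[ok, j])
    }
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  ctr <- colMeans(m)
  z <- sweep(sweep(m, 2, ctr), 2, sds, `/`)
  attr(z, "center") <- ctr
  attr(z, "scale") <- sds
  z
}

#' Invert a standardization
#'
#' @param z Matrix produced by [standardize_features()].
#' @return Matrix on the original scale.
#' @export
unstandardize_features <- function(z) {
  ctr <- attr(z, "center"); sds <- attr(z, "scale")
  if (is.null(ctr) || is.null(sds)) stop("no scaling parameters attached")
  out <- sweep(sweep(unclass(z), 2, sds, `*`), 2, ctr, `+`)
  attributes(out)$center <- NULL; attributes(out)$scale <- NULL
  out
}

#' Ward agglomerative clustering of neurons
#'
#' Hierarchical clustering of the standardized feature matrix on the
#' Euclidean dissimilarity matrix, with Ward's linkage. The default
#' `"ward.D2"` is the textbook Ward criterion on Euclidean distances;
#' `"ward.D"` is exposed for auditability.
#'
#' @param x Standardized numeric matrix (rows = neurons).
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return An [stats::hclust] object (the dendrogram: merge sequence with
#'   non-decreasing heights).
#' @export
ward_cluster <- function(x, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(x), method = method)
}

#' Select the number of clusters by average silhouette width
#'
#' Cuts the dendrogram at each k in `k_range`, computes the mean silhouette
#' width on the Euclidean distances (singleton clusters contribute width 0,
#' the standard convention), and picks the k maximising it; ties break
#' toward the smaller k.
#'
#' @param x Standardized numeric matrix used for clustering.
#' @param hc The [ward_cluster()] dendrogram.
#' @param k_range Candidate cluster counts, default `2:min(8, n - 1)`.
#' @return Object of class `cluster_assignment`: list with `k`, `labels`
#'   (integer vector in 1..k), `mean_silhouette`, and `silhouette_by_k`
#'   (data frame k, mean_sil).
#' @export
silhouette_select_k <- function(x, hc, k_range = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(k_range)) k_range <- 2:min(8L, n - 1L)
  if (any(k_range >= n) || any(k_range < 2L)) {
    stop("k_range must lie in 2..(n-1)")
  }
  d <- stats::dist(x)
  msil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    sil <- cluster::silhouette(lab, d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  best <- k_range[which.max(msil)]  # which.max returns first max: smaller k wins ties
  structure(list(k = best,
                 labels = stats::cutree(hc, k = best),
                 mean_silhouette = max(msil),
                 silhouette_by_k = data.frame(k = k_range, mean_sil = msil)),
            class = "cluster_assignment")
}

#' Export a dendrogram as Newick and a merge table
#'
#' @param hc An [stats::hclust] object.
#' @param newick_path Optional path for the Newick file (merge heights
#'   encoded as branch lengths via [ape::as.phylo]).
#' @param merge_path Optional path for a CSV of the merge sequence.
#' @return The Newick string, invisibly.
#' @export
export_dendrogram <- function(hc, newick_path = NULL, merge_path = NULL) {
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(merge_path)) {
    utils::write.csv(data.frame(step = seq_len(nrow(hc$merge)),
                                left = hc$merge[, 1], right = hc$merge[, 2],
                                height = hc$height),
                     merge_path, row.names = FALSE)
  }
  invisible(nwk)
}

#' Pearson correlation of terminal counts
#'
#' Two-sided Pearson correlation test (t transform with n - 2 degrees of
#' freedom), as used to relate medial-surface fin terminal counts to
#' terminal counts on the axial surface under the fin.
#'
#' @param x,y Equal-length numeric vectors (counts), n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
correlation_terminals <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Anteroposterior trend test
#'
#' Single-predictor linear model of fin afferent length on anteroposterior
#' soma position, with the regression ANOVA F-test (two-sided) and the slope
#' sign, so "more anterior (more negative position) implies higher length"
#' is checkable as a negative slope. Neurons whose label is in `exclude`
#' (e.g. `"RB"`) are dropped first, supporting the with/without-RB variants.
#'
#' @param lengths Total fin afferent length per neuron (um).
#' @param positions Anteroposterior soma positions (um, signed).
#' @param labels Optional per-neuron population labels.
#' @param exclude Labels to drop (default none).
#' @return List with `F`, `p`, `slope`, `n`.
#' @export
trend_test <- function(lengths, positions, labels = NULL, exclude = NULL) {
  keep <- rep(TRUE, length(lengths))
  if (!is.null(exclude) && !is.null(labels)) keep <- !(labels %in% exclude)
  lengths <- lengths[keep]; positions <- positions[keep]
  if (length(lengths) < 3L) stop("need at least 3 neurons after exclusion")
  if (stats::sd(positions) == 0) stop("constant predictor; trend undefined")
  if (stats::sd(lengths) == 0) {
    # constant response: no trend by definition
    return(list(F = 0, p = 1, slope = 0, n = length(lengths)))
  }
  fit <- stats::lm(lengths ~ positions)
  av <- stats::anova(fit)
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
       slope = unname(stats::coef(fit)[2]), n = length(lengths))
}

#' Compare total axial vs total fin afferent length
#'
#' Implements the printed comparison — a chi-square goodness-of-fit of the
#' summed axial and summed fin lengths against equal expectation — and, as
#' a clearly labelled alternative better suited to paired continuous totals,
#' a paired Wilcoxon signed-rank test.
#'
#' @param total_axial,total_fin Paired per-neuron totals (um), non-negative.
#' @return List with `chi_square` (list statistic, df, p) and `wilcoxon`
#'   (list statistic, p).
#' @export
length_comparison <- function(total_axial, total_fin) {
  if (length(total_axial) != length(total_fin)) stop("paired totals required")
  O <- c(axial = sum(total_axial), fin = sum(total_fin))
  if (sum(O) <= 0) stop("all totals zero; comparison undefined")
  E <- rep(sum(O) / 2, 2)
  stat <- sum((O - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(total_axial, total_fin,
                                            paired = TRUE, exact = FALSE))
  list(chi_square = list(statistic = stat, df = 1L, p = p),
       wilcoxon = list(statistic = unname(wt$statistic), p = wt$p.value))
}

#' Leave-one-feature-out cluster stability report
#'
#' Re-clusters the matrix with each feature column removed in turn and
#' reports the adjusted Rand agreement of the k-cluster cut with the
#' full-feature labels (a stability report, not a pass/fail test).
#'
#' @param z Standardized feature matrix.
#' @param k Number of clusters to cut at.
#' @param method Ward variant, see [ward_cluster()].
#' @return Data frame with `dropped_feature` and `ari`.
#' @export
loo_feature_stability <- function(z, k, method = "ward.D2") {
  z <- as.matrix(z)
  full <- stats::cutree(ward_cluster(z, method), k = k)
  ari <- vapply(seq_len(ncol(z)), function(j) {
    lab <- stats::cutree(ward_cluster(z[, -j, drop = FALSE], method), k = k)
    mclust::adjustedRandIndex(full, lab)
  }, numeric(1))
  data.frame(dropped_feature = colnames(z), ari = ari)
}
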
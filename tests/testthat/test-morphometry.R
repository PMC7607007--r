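test_that("re-segmentation isolates interbranch segments", {
  # unbranched path: one segment, no branch points, one terminal
  p <- path_tree(3)
  segs <- resegment(p)
  expect_length(segs, 1L)
  topo <- topology_metrics(p)
  expect_equal(topo$n_branch_points, 0L)
  expect_equal(topo$strahler, 1L)
  expect_equal(topo$max_branch_order, 1L)
  expect_true(is.nan(topo$mean_partition_asymmetry))
  # stem + bifurcation: terminals(2) + branch points(1) = 3 segments
  yt <- y_tree()
  expect_length(resegment(yt), 3L)
})

test_that("segment count equals terminals plus branch points on random binary trees", {
  set.seed(303)
  for (rep in 1:100) {
    tr <- random_bin_tree(sample(2:50, 1))
    cnt <- bf_counts(tr)
    expect_equal(length(resegment(tr)), cnt$tips + cnt$branch_points)
  }
})

test_that("restriction selecting a disconnected node set is an error", {
  # two separate fin-labeled patches hanging off an axial path
  tr <- make_tree(1:5, c(-1L, 1L, 2L, 3L, 2L),
                  x = c(0, 1, 2, 3, 1), y = c(0, 0, 0, 0, 1),
                  labels = c("axial", "axial", "axial", "fin_medial",
                             "fin_medial"))
  expect_error(resegment(tr, fin_labels()), "disconnected")
})

test_that("Strahler, order and asymmetry match hand-computed small trees", {
  # perfectly balanced 4-tip tree
  bal <- make_tree(1:8, c(-1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
                   x = c(0, 0, -2, 2, -3, -1, 1, 3),
                   y = c(0, 1, 2, 2, 3, 3, 3, 3))
  topo <- topology_metrics(bal)
  expect_equal(topo$strahler, 3L)
  expect_equal(topo$max_branch_order, 3L)
  expect_equal(topo$mean_partition_asymmetry, 0)
  # caterpillar: three bifurcations each bearing one tip
  cat_parent <- c(-1L, 1L, 2L, 2L, 4L, 4L, 6L, 6L)
  cat <- make_tree(1:8, cat_parent,
                   x = c(0, 0, -1, 1, 0, 2, 1, 3),
                   y = c(0, 1, 2, 2, 3, 3, 4, 4))
  topo <- topology_metrics(cat)
  expect_equal(topo$strahler, 2L)
  # asymmetries: (1,3) -> 1, (1,2) -> 1, (1,1) excluded
  expect_equal(topo$mean_partition_asymmetry, 1)
  expect_equal(topo$n_branch_points, 3L)
})

test_that("Strahler and partition asymmetry match brute-force recursions", {
  set.seed(404)
  for (rep in 1:100) {
    tr <- random_bin_tree(sample(2:50, 1))
    topo <- topology_metrics(tr)
    expect_identical(topo$strahler, bf_strahler(tr))
    bfa <- bf_mean_asymmetry(tr)
    if (is.nan(bfa)) {
      expect_true(is.nan(topo$mean_partition_asymmetry))
    } else {
      expect_equal(topo$mean_partition_asymmetry, bfa, tolerance = 1e-12)
    }
    cnt <- bf_counts(tr)
    expect_equal(topo$n_branch_points, cnt$branch_points)
  }
})

test_that("geometric metrics reproduce closed-form cases", {
  # straight segment, 10 steps of 2 um
  p <- path_tree(11, step = 2)
  g <- geometry_metrics(p)
  expect_equal(g$mean_contraction, 1)
  expect_equal(g$mean_fractal_dimension, 1, tolerance = 1e-12)
  expect_equal(g$total_length, 20)
  expect_equal(g$max_path_distance, 20)
  # planar right-angle L of two 1 um legs: contraction sqrt(2)/2
  L <- make_tree(1:3, c(-1L, 1L, 2L), x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(geometry_metrics(L)$mean_contraction, sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("total length matches an independent edge-sum oracle", {
  set.seed(505)
  for (rep in 1:25) {
    tr <- random_bin_tree(sample(2:50, 1))
    expect_equal(geometry_metrics(tr)$total_length, bf_total_length(tr),
                 tolerance = 1e-9)
  }
})

test_that("contraction lies in (0,1] and equals 1 exactly for collinear segments", {
  straight <- path_tree(20, step = 1.5)
  expect_identical(geometry_metrics(straight)$mean_contraction, 1)
  set.seed(606)
  for (rep in 1:20) {
    tr <- random_bin_tree(sample(3:30, 1))
    mc <- geometry_metrics(tr)$mean_contraction
    expect_true(mc > 0 && mc <= 1)
  }
  # a bent path must be strictly below 1
  bent <- make_tree(1:3, c(-1L, 1L, 2L), x = c(0, 1, 1), y = c(0, 0, 1))
  expect_lt(geometry_metrics(bent)$mean_contraction, 1)
})

test_that("angle metrics reproduce constructed geometries", {
  # symmetric straight Y, daughters 90 degrees apart
  yt <- y_tree(half_angle = 45)
  a <- angle_metrics(yt)
  expect_equal(a$mean_branch_angle, 90, tolerance = 1e-9)
  expect_equal(a$mean_local_angle, 90, tolerance = 1e-9)
  expect_equal(a$mean_remote_angle, 90, tolerance = 1e-9)
  # collinear, opposite daughters
  opp <- y_tree(half_angle = 90)
  expect_equal(angle_metrics(opp)$mean_branch_angle, 180, tolerance = 1e-9)
  # no bifurcation -> NaN sentinels
  a0 <- angle_metrics(path_tree(5))
  expect_true(is.nan(a0$mean_branch_angle))
  expect_true(is.nan(a0$mean_local_angle))
  expect_true(is.nan(a0$mean_remote_angle))
})

test_that("local angle reads 10 nodes in; remote angle reads the endpoint", {
  # daughter 1: straight +x, 12 nodes; daughter 2: +y for exactly 10 nodes
  # then bends to +x for 5 more
  stem_n <- 2L
  d2x <- c(rep(0, 10), 1:5); d2y <- c(1:10, rep(10, 5))
  id <- 1:(stem_n + 12 + 15)
  parent <- c(-1L, 1L,
              2L, stem_n + seq_len(11),
              2L, stem_n + 12L + seq_len(14))
  tr <- make_tree(id, parent,
                  x = c(0, 0, 1:12, d2x),
                  y = c(-1, 0, rep(0, 12), d2y))
  a <- angle_metrics(tr, local_offset = 10L)
  expect_equal(a$mean_local_angle, 90, tolerance = 1e-9)
  # remote: endpoint vectors (12,0) and (5,10): acos(5/sqrt(125)) in degrees
  expect_equal(a$mean_remote_angle, acos(5 / sqrt(125)) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(a$mean_branch_angle, a$mean_remote_angle)
  expect_false(isTRUE(all.equal(a$mean_local_angle, a$mean_remote_angle)))
  # offset clamps to the segment end for short daughters
  short <- y_tree(d_n = 4, half_angle = 30)
  expect_equal(angle_metrics(short, local_offset = 10L)$mean_local_angle, 60,
               tolerance = 1e-9)
})

test_that("tree metrics are invariant under rigid motion", {
  co <- generate_cohort(small_config(seed = 5, n = c(1, 1, 0), n_unbranched = 0))
  tr <- co$trees[[1]]
  meta <- co$metadata[1, , drop = FALSE]
  base <- feature_vector(tr, meta)
  set.seed(707)
  for (rep in 1:5) {
    R <- random_rotation()
    tvec <- rnorm(3, 0, 100)
    fv <- feature_vector(transform_tree(tr, R, tvec), meta)
    for (col in feature_columns()) {
      expect_equal(fv[[col]], base[[col]], tolerance = 1e-9,
                   label = paste("metric", col))
    }
  }
})

test_that("restricted totals are additive over a label partition", {
  co <- generate_cohort(small_config(seed = 6, n = c(1, 1, 0), n_unbranched = 0))
  for (tr in co$trees) {
    tot <- geometry_metrics(tr, "all")$total_length
    fin <- geometry_metrics(tr, fin_labels())$total_length
    axial <- geometry_metrics(tr, "axial")$total_length
    expect_equal(tot, fin + axial, tolerance = 1e-9)
  }
})

test_that("the feature vector assembles all 13 parameters", {
  co <- generate_cohort(small_config(seed = 8, n = c(1, 0, 0), n_unbranched = 1))
  # the unbranched neuron mirrors the excluded non-branching cell
  unb <- names(co$regime)[co$regime == "unbranched"]
  tr <- co$trees[[unb]]
  meta <- co$metadata[co$metadata$neuron_id == unb, , drop = FALSE]
  fv <- feature_vector(tr, meta)
  expect_equal(fv$n_branch_points, 0L)
  expect_equal(fv$strahler, 1L)
  expect_true(is.nan(fv$mean_partition_asymmetry))
  expect_true(is.nan(fv$mean_branch_angle))
  # soma parameters pass through unchanged
  meta2 <- neuron_metadata(unb, 93.77, -120, "RB")
  fv2 <- feature_vector(tr, meta2)
  expect_identical(fv2$soma_area, 93.77)
  expect_identical(fv2$ap_position, -120)
  # total length includes the stem leading to the fin
  truth <- co$truth[[unb]]
  expect_equal(fv$total_length, truth$fin_length + truth$stem_length,
               tolerance = 1e-9)
  # missing metadata errors
  expect_error(feature_vector(tr, meta[0, , drop = FALSE]), "metadata")
})
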
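test_that("the plane fit is exact for coplanar landmarks and oriented as asked", {
  lm <- clean_landmarks()
  pl <- fit_plane(lm)
  expect_lt(pl$rss, 1e-9)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  # basis is orthonormal and the normal is perpendicular to both axes
  expect_equal(sum(pl$e1 * pl$e2), 0, tolerance = 1e-12)
  expect_equal(sum(pl$e1 * pl$normal), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(pl$e1^2)), 1, tolerance = 1e-12)
  # medial orientation override
  pl2 <- fit_plane(lm, medial_point = c(0, 50, -10))
  expect_lt(pl2$normal[3], 0)
  expect_gt(signed_distance(c(0, 50, -10), pl2), 0)
})

test_that("points mirrored in pairs across z = 0 fit the z = 0 plane", {
  lm <- unclass(clean_landmarks())
  labs <- landmark_labels()
  non_base <- setdiff(labs, c("fb_base_1", "fb_base_2", "fm_base_1", "fm_base_2"))
  # FB non-base points at z = +4, FM at the same xy footprint scaled, z = -4
  lm[non_base[1:7], 3] <- 4
  lm[non_base[8:14], 3] <- -4
  lm[non_base[8:14], 1:2] <- lm[non_base[1:7], 1:2]
  pl <- fit_plane(fin_landmarks(lm))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(unname(pl$centroid[3]), 0, tolerance = 1e-9)
})

test_that("collinear landmark sets raise a rank error", {
  lm <- unclass(clean_landmarks())
  lm[, 2] <- 2 * lm[, 1] + seq_len(18) * 1e-12  # essentially a line
  lm[, 3] <- 0
  expect_error(fit_plane(fin_landmarks(lm)), "rank error")
})

test_that("the fitted plane beats the axis-aligned planes through the centroid", {
  set.seed(808)
  for (rep in 1:30) {
    cfg <- generator_config(seed = rep,
                            fin = list(r_fb = 80, band = 70,
                                       radial_noise = 5, z_noise = 10))
    lm <- generate_fin_landmarks(cfg)
    pl <- fit_plane(lm)
    pts <- unclass(lm)[setdiff(landmark_labels(),
                               c("fb_base_1", "fb_base_2",
                                 "fm_base_1", "fm_base_2")), ]
    ctr <- colMeans(pts)
    for (ax in 1:3) {
      expect_lte(pl$rss, sum((pts[, ax] - ctr[ax])^2) + 1e-9)
    }
  }
})

test_that("projection is idempotent and isometric for coplanar inputs", {
  lm <- clean_landmarks()
  pl <- fit_plane(lm)
  # a point on the plane projects to itself (re-projection identical)
  p <- pl$centroid + 10 * pl$e1 + 5 * pl$e2
  uv <- project_points(p, pl)
  p_back <- pl$centroid + uv[1] * pl$e1 + uv[2] * pl$e2
  expect_equal(as.numeric(project_points(p_back, pl)), as.numeric(uv),
               tolerance = 1e-12)
  # centroid + 5 * normal projects to the origin
  expect_equal(as.numeric(project_points(pl$centroid + 5 * pl$normal, pl)),
               c(0, 0), tolerance = 1e-9)
  # coplanar triangle: pairwise 2D distances equal the 3D distances
  tri <- rbind(pl$centroid + 3 * pl$e1,
               pl$centroid - 2 * pl$e1 + 7 * pl$e2,
               pl$centroid + 5 * pl$e2)
  uv3 <- project_points(tri, pl)
  expect_equal(as.numeric(dist(uv3)), as.numeric(dist(tri)), tolerance = 1e-9)
})

test_that("region partition tiles the footprint with the defined boundary", {
  lm <- clean_landmarks()
  pl <- fit_plane(lm)
  rg <- build_regions(lm, pl)
  # symmetric fin: dorsal and ventral areas match
  expect_equal(rg$areas[["DB"]], rg$areas[["VB"]], tolerance = 1e-6)
  expect_equal(rg$areas[["DM"]], rg$areas[["VM"]], tolerance = 1e-6)
  # the four regions tile the footprint
  fp_area <- abs(pracma::polyarea(rg$footprint[, 1], rg$footprint[, 2]))
  expect_equal(sum(rg$areas), fp_area, tolerance = 1e-6)
  # boundary: from the FB midpoint construction to the FM apex
  expect_true(pracma::inpolygon(rg$dv_point[1], rg$dv_point[2],
                                rg$fb_polygon[, 1], rg$fb_polygon[, 2],
                                boundary = TRUE))
  expect_equal(unname(rg$dv_boundary[2, ]),
               unname(rg$landmarks_2d["fm_apex", ]), tolerance = 1e-12)
})

test_that("single straight medial segment inside DM lands wholly in (DM, medial)", {
  lm <- clean_landmarks()
  rg <- build_regions(lm, fit_plane(lm))
  # canonical frame: dorsal = fb_base_1 side (x < 0), membrane band beyond 80
  tr <- segment_tree(c(0, -50, 0),
                     rbind(c(-55, 102, 3, -65, 98, 3)),
                     "fin_medial")
  ri <- assign_region_lengths(tr, rg)
  got <- ri$octants[ri$octants$region == "DM" & ri$octants$surface == "medial", ]
  expect_equal(got$length_um, sqrt(100 + 16), tolerance = 1e-9)
  expect_equal(sum(ri$octants$length_um), got$length_um, tolerance = 1e-12)
  expect_equal(got$terminals, 1L)
})

test_that("boundary-crossing segments match a dense sampling oracle", {
  lm <- clean_landmarks()
  rg <- build_regions(lm, fit_plane(lm))
  set.seed(909)
  for (rep in 1:20) {
    a <- c(runif(1, -140, 140), runif(1, 5, 145), 3)
    b <- c(runif(1, -140, 140), runif(1, 5, 145), 3)
    tr <- segment_tree(c(0, -50, 0), rbind(c(a, b)), "fin_medial")
    ri <- assign_region_lengths(tr, rg, outside_tol = 1)
    # oracle: 1e4 midpoint samples classified independently of the splitter
    ns <- 1e4
    tmid <- (seq_len(ns) - 0.5) / ns
    pts <- cbind(a[1] + tmid * (b[1] - a[1]), a[2] + tmid * (b[2] - a[2]),
                 a[3] + tmid * (b[3] - a[3]))
    uv <- project_points(pts, rg$plane)
    reg <- classify_region(uv, rg)
    len3 <- sqrt(sum((b - a)^2))
    oracle <- tapply(rep(len3 / ns, ns), reg, sum)
    for (r in c("DM", "DB", "VB", "VM")) {
      got <- ri$octants$length_um[ri$octants$region == r &
                                  ri$octants$surface == "medial"]
      want <- if (r %in% names(oracle)) unname(oracle[r]) else 0
      expect_lt(abs(got - want), 1e-3 * len3 + 1e-9,
                label = paste("region", r, "rep", rep))
    }
  }
})

test_that("octant lengths conserve the fin-restricted total on synthetic neurons", {
  co <- generate_cohort(small_config(seed = 10, n = c(2, 1, 1)))
  pl <- fit_plane(co$landmarks)
  rg <- build_regions(co$landmarks, pl)
  for (id in names(co$trees)) {
    tr <- co$trees[[id]]
    ri <- assign_region_lengths(tr, rg)
    fin_total <- geometry_metrics(tr, fin_labels(),
                                  include_stem = FALSE)$total_length
    expect_equal(sum(ri$octants$length_um), fin_total, tolerance = 1e-6)
    expect_lte(ri$axial$under_fin_um, ri$axial$length_um + 1e-9)
  }
})

test_that("mirroring the landmark set swaps dorsal and ventral lengths", {
  lm <- clean_landmarks()
  m <- unclass(lm); m[, 1] <- -m[, 1]
  lm_mirror <- fin_landmarks(m)
  rg <- build_regions(lm, fit_plane(lm))
  rg_m <- build_regions(lm_mirror, fit_plane(lm_mirror))
  tr <- segment_tree(c(0, -50, 0),
                     rbind(c(-55, 102, 3, -65, 98, 3),   # DM
                           c(-30, 40, -3, -20, 50, -3)), # DB, lateral
                     c("fin_medial", "fin_lateral"))
  ri <- assign_region_lengths(tr, rg)
  ri_m <- assign_region_lengths(tr, rg_m)
  key <- function(x, r, s) x$octants$length_um[x$octants$region == r &
                                               x$octants$surface == s]
  expect_equal(key(ri, "DM", "medial"), key(ri_m, "VM", "medial"),
               tolerance = 1e-9)
  expect_equal(key(ri, "DB", "lateral"), key(ri_m, "VB", "lateral"),
               tolerance = 1e-9)
  expect_equal(sum(ri$octants$length_um), sum(ri_m$octants$length_um),
               tolerance = 1e-9)
})

test_that("geometric surface fallback agrees with the labels on offset arbors", {
  # without surface switching every fin edge lies wholly on one side of the
  # plane, so tag-based and geometric assignment must agree
  co <- generate_cohort(small_config(seed = 12, n = c(1, 0, 0),
                                     n_unbranched = 0,
                                     surface_switch_prob = 0,
                                     fin = list(r_fb = 80, band = 70,
                                                radial_noise = 0, z_noise = 0)))
  pl <- fit_plane(co$landmarks, medial_point = c(0, 50, 10))
  rg <- build_regions(co$landmarks, pl)
  tr <- co$trees[[1]]
  by_label <- assign_region_lengths(tr, rg, surface = "labels")
  by_geom <- assign_region_lengths(tr, rg, surface = "geometric")
  expect_equal(by_label$octants$length_um, by_geom$octants$length_um,
               tolerance = 1e-6)
})

test_that("model fin registration is rigid and matches hand-rotated vertices", {
  lm <- clean_landmarks()
  model <- model_fin_from_cohort(list(lm))
  # identity placement
  placed <- register_model_fin(model, model$base_midpoint,
                               model$base_angle_deg)
  expect_equal(placed, model$polygon, tolerance = 1e-9)
  # 90 degree rotation about the base midpoint
  placed90 <- register_model_fin(model, model$base_midpoint,
                                 model$base_angle_deg + 90)
  ctr <- sweep(model$polygon, 2, model$base_midpoint)
  hand <- cbind(-ctr[, 2], ctr[, 1])
  hand <- sweep(hand, 2, model$base_midpoint, `+`)
  expect_equal(unname(placed90), unname(hand), tolerance = 1e-9)
  # areas and edge lengths preserved under an arbitrary placement
  placed2 <- register_model_fin(model, c(30, -40), 127)
  a1 <- abs(pracma::polyarea(model$polygon[, 1], model$polygon[, 2]))
  a2 <- abs(pracma::polyarea(placed2[, 1], placed2[, 2]))
  expect_equal(a1, a2, tolerance = 1e-9)
  e1 <- sqrt(rowSums((model$polygon - model$polygon[c(2:9, 1), ])^2))
  e2 <- sqrt(rowSums((placed2 - placed2[c(2:9, 1), ])^2))
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("axial overlap clips projected polylines correctly", {
  lm <- clean_landmarks()
  pl <- fit_plane(lm)
  # the clip polygon lives in the plane's (u, v) frame; build test trees by
  # mapping (u, v) back to 3D through the plane basis
  to3d <- function(u, v) {
    t(vapply(seq_along(u), function(i)
      pl$centroid + u[i] * pl$e1 + v[i] * pl$e2, numeric(3)))
  }
  square <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  # wholly inside
  p_in <- to3d(c(2, 5, 8), c(5, 5, 5))
  tr_in <- make_tree(1:3, c(-1L, 1L, 2L), x = p_in[, 1], y = p_in[, 2],
                     z = p_in[, 3], labels = rep("axial", 3))
  ov <- axial_overlap(tr_in, square, pl)
  expect_equal(ov$percent_of_axial, 100)
  # wholly outside
  p_out <- to3d(c(20, 30), c(50, 50))
  tr_out <- make_tree(1:2, c(-1L, 1L), x = p_out[, 1], y = p_out[, 2],
                      z = p_out[, 3], labels = rep("axial", 2))
  ov0 <- axial_overlap(tr_out, square, pl)
  expect_equal(ov0$length_within, 0)
  expect_equal(ov0$percent_of_axial, 0)
  # straight segment from (-5,5) to (15,5): exactly half its length crosses
  p_x <- to3d(c(-5, 15), c(5, 5))
  tr_x <- make_tree(1:2, c(-1L, 1L), x = p_x[, 1], y = p_x[, 2],
                    z = p_x[, 3], labels = rep("axial", 2))
  ovx <- axial_overlap(tr_x, square, pl)
  expect_equal(ovx$length_within, 10, tolerance = 1e-6)
  expect_equal(ovx$percent_of_axial, 50, tolerance = 1e-6)
  # no axial innervation -> zeros with a warning
  tr_fin <- make_tree(1:2, c(-1L, 1L), x = c(0, 1), y = c(0, 0),
                      labels = c("unlabeled", "fin_medial"))
  expect_warning(ov_na <- axial_overlap(tr_fin, square, pl), "no axial")
  expect_equal(ov_na$percent_of_axial, 0)
})

test_that("region lengths and overlap are invariant under rigid motion", {
  co <- generate_cohort(small_config(seed = 13, n = c(1, 1, 0), n_unbranched = 0))
  tr <- co$trees[[1]]
  rg <- build_regions(co$landmarks, fit_plane(co$landmarks))
  ri <- assign_region_lengths(tr, rg)
  set.seed(1010)
  for (rep in 1:3) {
    R <- random_rotation(); tvec <- rnorm(3, 0, 200)
    lm_t <- transform_landmarks(co$landmarks, R, tvec)
    tr_t <- transform_tree(tr, R, tvec)
    rg_t <- build_regions(lm_t, fit_plane(lm_t))
    ri_t <- assign_region_lengths(tr_t, rg_t)
    expect_equal(ri_t$octants$length_um, ri$octants$length_um,
                 tolerance = 1e-6)
    expect_equal(ri_t$axial$under_fin_um, ri$axial$under_fin_um,
                 tolerance = 1e-6)
  }
})

test_that("a tree without fin labels yields an all-zero octant table", {
  lm <- clean_landmarks()
  rg <- build_regions(lm, fit_plane(lm))
  tr <- make_tree(1:3, c(-1L, 1L, 2L), x = c(0, 10, 20), y = c(-50, -50, -50),
                  labels = rep("axial", 3))
  ri <- assign_region_lengths(tr, rg)
  expect_true(all(ri$octants$length_um == 0))
  expect_true(all(ri$octants$terminals == 0L))
  expect_gt(ri$axial$length_um, 0)
})
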
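# Fin-plane geometry: total-least-squares plane fit to the fin edge
# landmarks, orthogonal projection, quadrant/octant partition of the fin
# footprint, per-region afferent length and terminal quantification, model
# fin registration and axial-overlap estimation.
#
# All 2D work happens in the plane's (u, v) basis with u aligned to the fin
# base (body axis) and the medial side of the fin at positive signed
# distance. Polygon half-plane clipping and segment splitting are written
# here; point-in-polygon and polygon area come from pracma.

.cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

.poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3L) return(0)
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

.in_poly <- function(xy, poly, boundary = FALSE) {
  xy <- matrix(xy, ncol = 2)
  pracma::inpolygon(xy[, 1], xy[, 2], poly[, 1], poly[, 2], boundary = boundary)
}

# Sutherland-Hodgman clip of a simple polygon against the half-plane
# { p : sign * cross2(d, p - p0) >= 0 }.
.clip_halfplane <- function(poly, p0, d, sign = 1) {
  side <- function(p) sign * .cross2(d, p - p0)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    sa <- side(a); sb <- side(b)
    if (sa >= 0) out <- rbind(out, a)
    if ((sa > 0 && sb < 0) || (sa < 0 && sb > 0)) {
      t <- sa / (sa - sb)
      out <- rbind(out, a + t * (b - a))
    }
  }
  out
}

# O(n^2) simplicity check on a closed ring (non-adjacent edge intersections)
.is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- function(i) list(a = poly[i, ], b = poly[if (i == n) 1L else i + 1L, ])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      s1 <- seg(i); s2 <- seg(j)
      u <- s1$b - s1$a; w <- s2$b - s2$a
      den <- .cross2(u, w)
      if (abs(den) < 1e-12) next
      t <- .cross2(s2$a - s1$a, w) / den
      s <- .cross2(s2$a - s1$a, u) / den
      if (t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9) return(FALSE)
    }
  }
  TRUE
}

# Crossing parameters t in (0,1) of many 2D edges (A -> B, E x 2 matrices)
# with one boundary segment C-D (or the infinite line through C along w when
# infinite = TRUE). Returns a numeric vector of length E with NA where the
# edge does not cross.
.edge_crossings <- function(A, B, C, D = NULL, infinite = FALSE) {
  U <- B - A
  w <- if (infinite) D else D - C   # when infinite, D holds the direction
  den <- U[, 1] * w[2] - U[, 2] * w[1]
  dx <- C[1] - A[, 1]; dy <- C[2] - A[, 2]
  t <- (dx * w[2] - dy * w[1]) / den
  ok <- abs(den) > 1e-300 & t > 0 & t < 1
  if (!infinite) {
    s <- (dx * U[, 2] - dy * U[, 1]) / den
    ok <- ok & s >= 0 & s <= 1
  }
  t[!ok] <- NA_real_
  t
}

#' Fit the fin's best-fit plane
#'
#' Total-least-squares plane through the 14 non-base landmarks (the four
#' base points are excluded from the fit but remain projectable): the plane
#' minimising the sum of squared orthogonal distances, obtained from the SVD
#' of the centred point matrix. The in-plane basis is chosen with the first
#' axis along the fin base (the `fb_base_1 -> fb_base_2` direction projected
#' into the plane, i.e. the body axis) and the normal oriented so that the
#' medial side of the fin has positive signed distance (via `medial_point`
#' when supplied, otherwise a deterministic sign convention).
#'
#' @param landmarks A [fin_landmarks()] set.
#' @param medial_point Optional 3D point known to lie on the medial side,
#'   used to orient the normal.
#' @return Object of class `fit_plane`: list with `centroid`, `normal`,
#'   `e1`, `e2` (orthonormal), and `rss` (sum of squared orthogonal
#'   residuals of the 14 fitted points).
#' @export
fit_plane <- function(landmarks, medial_point = NULL) {
  stopifnot(inherits(landmarks, "fin_landmarks"))
  base_labs <- c("fb_base_1", "fb_base_2", "fm_base_1", "fm_base_2")
  pts <- unclass(landmarks)[setdiff(landmark_labels(), base_labs), , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-12)) {
    stop("rank error: landmark points are collinear or degenerate; no unique plane")
  }
  normal <- sv$v[, 3]
  if (!is.null(medial_point)) {
    if (sum((medial_point - ctr) * normal) < 0) normal <- -normal
  } else {
    k <- which.max(abs(normal))
    if (normal[k] < 0) normal <- -normal
  }
  b <- unclass(landmarks)["fb_base_2", ] - unclass(landmarks)["fb_base_1", ]
  b <- b - sum(b * normal) * normal
  nb <- sqrt(sum(b^2))
  e1 <- if (nb > 1e-9) b / nb else sv$v[, 1]
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  rss <- sum((sweep(pts, 2, ctr) %*% normal)^2)
  structure(list(centroid = ctr, normal = normal, e1 = e1, e2 = e2, rss = rss),
            class = "fit_plane")
}

#' Orthogonally project 3D points onto a fitted plane
#'
#' Maps each point to its in-plane (u, v) coordinates in the plane's basis
#' (centroid origin). The projection is idempotent and an isometry for
#' coplanar inputs.
#'
#' @param points 3D point (length-3 vector) or n x 3 matrix.
#' @param plane A [fit_plane()].
#' @return n x 2 matrix of in-plane coordinates (columns `u`, `v`).
#' @export
project_points <- function(points, plane) {
  stopifnot(inherits(plane, "fit_plane"))
  m <- matrix(points, ncol = 3)
  if (!all(is.finite(m))) stop("non-finite input point(s)")
  cmat <- sweep(m, 2, plane$centroid)
  out <- cbind(u = cmat %*% plane$e1, v = cmat %*% plane$e2)
  colnames(out) <- c("u", "v")
  rownames(out) <- rownames(points)
  out
}

#' Signed orthogonal distance of points from a fitted plane
#'
#' Positive on the medial side under the plane's orientation convention.
#'
#' @inheritParams project_points
#' @return Numeric vector of signed distances (um).
#' @export
signed_distance <- function(points, plane) {
  stopifnot(inherits(plane, "fit_plane"))
  m <- matrix(points, ncol = 3)
  as.numeric(sweep(m, 2, plane$centroid) %*% plane$normal)
}

#' Partition the projected fin into quadrants
#'
#' Projects the 18 landmarks, forms the fin footprint (the polygon through
#' the projected fin-membrane ring, closed along the base) and the fin-body
#' polygon (the projected FB ring, i.e. the blood-vessel boundary), and
#' splits both with the dorsoventral boundary: the line from the midpoint
#' between (a) the midpoint of the two FB base points and (b) the FB apex,
#' through the FM apex. The four resulting regions — dorsal membrane (DM),
#' dorsal base (DB), ventral base (VB), ventral membrane (VM) — tile the
#' footprint. Points exactly on a boundary belong to the dorsal / membrane
#' side.
#'
#' @param landmarks A [fin_landmarks()] set.
#' @param plane A [fit_plane()], typically `fit_plane(landmarks)`.
#' @return Object of class `fin_regions`: list with `plane`, `landmarks_2d`,
#'   `footprint`, `fb_polygon`, `regions` (named list of the four polygons),
#'   `areas`, `dv_point` (the defining midpoint), `dv_dir`, `dv_boundary`
#'   (segment from the midpoint to the FM apex) and `dorsal_sign`.
#' @export
build_regions <- function(landmarks, plane) {
  stopifnot(inherits(landmarks, "fin_landmarks"), inherits(plane, "fit_plane"))
  L2 <- project_points(unclass(landmarks), plane)
  rownames(L2) <- rownames(landmarks)
  labs <- landmark_labels()
  fb <- L2[labs[1:9], , drop = FALSE]
  fm <- L2[labs[10:18], , drop = FALSE]
  if (!.is_simple(fb)) stop("geometry error: projected FB ring is self-intersecting")
  if (!.is_simple(fm)) stop("geometry error: projected FM ring is self-intersecting")
  m_prox <- (L2["fb_base_1", ] + L2["fb_base_2", ]) / 2
  dv_point <- (m_prox + L2["fb_apex", ]) / 2
  dv_dir <- L2["fm_apex", ] - dv_point
  nd <- sqrt(sum(dv_dir^2))
  if (nd < 1e-9) stop("geometry error: degenerate dorsoventral boundary")
  dv_dir <- dv_dir / nd
  s1 <- .cross2(dv_dir, L2["fb_base_1", ] - dv_point)
  if (s1 == 0) s1 <- .cross2(dv_dir, L2["fm_base_1", ] - dv_point)
  dorsal_sign <- sign(s1)
  band <- rbind(fm, fb[9:1, , drop = FALSE])  # membrane annulus polygon
  regions <- list(
    DM = .clip_halfplane(band, dv_point, dv_dir, dorsal_sign),
    DB = .clip_halfplane(fb, dv_point, dv_dir, dorsal_sign),
    VB = .clip_halfplane(fb, dv_point, dv_dir, -dorsal_sign),
    VM = .clip_halfplane(band, dv_point, dv_dir, -dorsal_sign)
  )
  structure(list(
    plane = plane, landmarks_2d = L2, footprint = fm, fb_polygon = fb,
    regions = regions, areas = vapply(regions, .poly_area, numeric(1)),
    dv_point = dv_point, dv_dir = dv_dir,
    dv_boundary = rbind(dv_point, L2["fm_apex", ]), dorsal_sign = dorsal_sign
  ), class = "fin_regions")
}

#' Classify projected points into fin quadrants
#'
#' Membership in the fin-body polygon decides base vs membrane (boundary
#' points go to the membrane), the side of the dorsoventral boundary decides
#' dorsal vs ventral (boundary points go dorsal). Points outside the
#' footprint are still classified by the same rules (the nearest-region
#' convention for stray projections).
#'
#' @param xy n x 2 matrix of in-plane coordinates.
#' @param regions A [build_regions()] partition.
#' @return Character vector over `{"DM","DB","VB","VM"}`.
#' @export
classify_region <- function(xy, regions) {
  xy <- matrix(xy, ncol = 2)
  side <- regions$dorsal_sign *
    (regions$dv_dir[1] * (xy[, 2] - regions$dv_point[2]) -
     regions$dv_dir[2] * (xy[, 1] - regions$dv_point[1]))
  dv <- ifelse(side >= 0, "D", "V")
  inb <- .in_poly(xy, regions$fb_polygon, boundary = FALSE)
  paste0(dv, ifelse(inb, "B", "M"))
}

#' Test footprint membership of projected points
#'
#' @inheritParams classify_region
#' @return Logical vector; boundary points count as inside.
#' @export
in_footprint <- function(xy, regions) {
  .in_poly(matrix(xy, ncol = 2), regions$footprint, boundary = TRUE)
}

# split parameters for edges A2->B2 (E x 2) against all region boundaries:
# FB ring, footprint ring and the (infinite) dorsoventral line.
# Returns a list of sorted split parameter vectors, one per edge.
.region_split_params <- function(A2, B2, regions) {
  E <- nrow(A2)
  tmat <- NULL
  rings <- list(regions$fb_polygon, regions$footprint)
  for (ring in rings) {
    n <- nrow(ring)
    for (i in seq_len(n)) {
      C <- ring[i, ]; D <- ring[if (i == n) 1L else i + 1L, ]
      tmat <- cbind(tmat, .edge_crossings(A2, B2, C, D))
    }
  }
  tmat <- cbind(tmat, .edge_crossings(A2, B2, regions$dv_point,
                                      regions$dv_dir, infinite = TRUE))
  lapply(seq_len(E), function(i) {
    tv <- tmat[i, ]
    tv <- sort(tv[!is.na(tv)])
    if (length(tv) > 1L) tv <- tv[c(TRUE, diff(tv) > 1e-12)]
    tv
  })
}

# split one family of 3D edges at region boundaries; returns a data frame of
# sub-edges with 3D length, 2D length, midpoint region and footprint flag.
# All sub-edge midpoints are classified in one vectorized pass.
.split_edges <- function(A3, B3, plane, regions) {
  A2 <- project_points(A3, plane); B2 <- project_points(B3, plane)
  len3 <- sqrt(rowSums((B3 - A3)^2))
  len2 <- sqrt(rowSums((B2 - A2)^2))
  splits <- .region_split_params(A2, B2, regions)
  nseg <- lengths(splits) + 1L
  edge <- rep(seq_along(splits), nseg)
  t0 <- unlist(lapply(splits, function(s) c(0, s)), use.names = FALSE)
  t1 <- unlist(lapply(splits, function(s) c(s, 1)), use.names = FALSE)
  mid <- (t0 + t1) / 2
  dt <- t1 - t0
  mxy <- cbind(A2[edge, 1] + mid * (B2[edge, 1] - A2[edge, 1]),
               A2[edge, 2] + mid * (B2[edge, 2] - A2[edge, 2]))
  data.frame(edge = edge,
             region = classify_region(mxy, regions),
             in_fp = in_footprint(mxy, regions),
             len3 = len3[edge] * dt, len2 = len2[edge] * dt)
}

#' Quantify per-octant afferent length and terminals
#'
#' Assigns every fin-labeled edge of the tree to the fin regions by
#' projecting it onto the plane, splitting it where it crosses a region
#' boundary and classifying each sub-edge by its projected midpoint. The
#' length recorded is the 3D arc length of the sub-edge (so the eight
#' octants conserve the fin-restricted total length exactly); the projected
#' 2D length is reported alongside. Octant = region x surface, with the
#' surface (medial/lateral) taken from the child node's annotation (or the
#' sign of the signed plane distance when `surface = "geometric"`).
#' Terminals (leaf nodes) are counted per region and surface; axial-labeled
#' innervation is summarised as total length, the part whose projection
#' falls inside the fin footprint ("under the fin"), and the corresponding
#' terminal counts.
#'
#' @param tree An annotated [neuron_tree()].
#' @param regions A [build_regions()] partition.
#' @param surface `"labels"` (default) or `"geometric"`.
#' @param outside_tol Warn when more than this fraction of fin length
#'   projects outside the footprint (such length is still assigned, by the
#'   nearest-region rule of [classify_region()]).
#' @return Object of class `region_innervation`: list with `octants` (8-row
#'   data frame: region, surface, length_um, length2d_um, terminals),
#'   `axial` (1-row data frame: length_um, under_fin_um, terminals,
#'   terminals_under_fin) and `outside` (stray fin length, um).
#' @export
assign_region_lengths <- function(tree, regions, surface = c("labels", "geometric"),
                                  outside_tol = 0.01) {
  stopifnot(inherits(tree, "neuron_tree"), inherits(regions, "fin_regions"))
  surface <- match.arg(surface)
  plane <- regions$plane
  pr <- .parent_rows(tree)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  lab <- tree$annotations
  octants <- expand.grid(region = c("DM", "DB", "VB", "VM"),
                         surface = c("medial", "lateral"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  octants$length_um <- 0; octants$length2d_um <- 0; octants$terminals <- 0L
  okey <- paste(octants$region, octants$surface)
  axial <- data.frame(length_um = 0, under_fin_um = 0,
                      terminals = 0L, terminals_under_fin = 0L)
  outside_len <- 0
  fin_edges <- which(!is.na(pr) & lab %in% fin_labels())
  if (length(fin_edges)) {
    A3 <- xyz[pr[fin_edges], , drop = FALSE]
    B3 <- xyz[fin_edges, , drop = FALSE]
    sub <- .split_edges(A3, B3, plane, regions)
    surf <- if (surface == "labels") {
      ifelse(lab[fin_edges] == "fin_medial", "medial", "lateral")[sub$edge]
    } else {
      mid3 <- (A3[sub$edge, , drop = FALSE] + B3[sub$edge, , drop = FALSE]) / 2
      ifelse(signed_distance(mid3, plane) >= 0, "medial", "lateral")
    }
    key <- paste(sub$region, surf)
    agg3 <- tapply(sub$len3, key, sum)
    agg2 <- tapply(sub$len2, key, sum)
    idx <- match(names(agg3), okey)
    octants$length_um[idx] <- octants$length_um[idx] + as.numeric(agg3)
    octants$length2d_um[idx] <- octants$length2d_um[idx] + as.numeric(agg2)
    outside_len <- sum(sub$len3[!sub$in_fp])
    fin_total <- sum(sub$len3)
    if (fin_total > 0 && outside_len / fin_total > outside_tol) {
      warning(sprintf("%.1f%% of fin-labeled length projects outside the fin footprint; assigned to nearest region",
                      100 * outside_len / fin_total))
    }
  }
  # terminals
  ch <- .children_rows(tree)
  leaves <- which(lengths(ch) == 0L)
  fin_leaves <- leaves[lab[leaves] %in% fin_labels()]
  if (length(fin_leaves)) {
    p2 <- project_points(xyz[fin_leaves, , drop = FALSE], plane)
    reg <- classify_region(p2, regions)
    surf_t <- if (surface == "labels") {
      ifelse(lab[fin_leaves] == "fin_medial", "medial", "lateral")
    } else {
      ifelse(signed_distance(xyz[fin_leaves, , drop = FALSE], plane) >= 0,
             "medial", "lateral")
    }
    cnt <- table(factor(paste(reg, surf_t), levels = okey))
    octants$terminals <- octants$terminals + as.integer(cnt)
  }
  # axial innervation
  ax_edges <- which(!is.na(pr) & lab == "axial")
  if (length(ax_edges)) {
    A3 <- xyz[pr[ax_edges], , drop = FALSE]
    B3 <- xyz[ax_edges, , drop = FALSE]
    sub <- .split_edges(A3, B3, plane, regions)
    axial$length_um <- sum(sub$len3)
    axial$under_fin_um <- sum(sub$len3[sub$in_fp])
  }
  ax_leaves <- leaves[lab[leaves] == "axial"]
  if (length(ax_leaves)) {
    p2 <- project_points(xyz[ax_leaves, , drop = FALSE], plane)
    axial$terminals <- length(ax_leaves)
    axial$terminals_under_fin <- sum(in_footprint(p2, regions))
  }
  structure(list(octants = octants, axial = axial, outside = outside_len),
            class = "region_innervation")
}

#' Construct a model fin
#'
#' A stereotyped 2D fin outline with a designated base edge; the base
#' midpoint and base angle define its registration frame. The base angle is
#' the angle (degrees) that the base segment (`fm_base_1 -> fm_base_2`)
#' makes with the in-plane body axis (the u axis).
#'
#' @param polygon n x 2 matrix (ring, not closed) with rownames including
#'   `fm_base_1` and `fm_base_2` marking the base edge endpoints.
#' @return Object of class `model_fin`.
#' @export
model_fin <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (is.null(rownames(polygon)) ||
      !all(c("fm_base_1", "fm_base_2") %in% rownames(polygon))) {
    stop("model fin polygon needs rownames with fm_base_1 and fm_base_2")
  }
  if (!.is_simple(polygon)) stop("model fin polygon is self-intersecting")
  b1 <- polygon["fm_base_1", ]; b2 <- polygon["fm_base_2", ]
  d <- b2 - b1
  structure(list(polygon = polygon,
                 base = rbind(b1, b2),
                 base_midpoint = (b1 + b2) / 2,
                 base_angle_deg = atan2(d[2], d[1]) * 180 / pi),
            class = "model_fin")
}

#' Build the cohort-mean model fin
#'
#' The default stereotyped fin outline: each fish's projected fin-membrane
#' footprint is expressed in its base frame (origin at the FM base midpoint,
#' first axis along the base, apex on the positive side) and the labelled
#' vertices are averaged across the cohort.
#'
#' @param landmark_sets List of [fin_landmarks()] sets.
#' @return A [model_fin()] with base midpoint (0, 0) and base angle 0.
#' @export
model_fin_from_cohort <- function(landmark_sets) {
  stopifnot(length(landmark_sets) >= 1L)
  ring_labs <- landmark_labels()[10:18]
  rings <- lapply(landmark_sets, function(lm) {
    pl <- fit_plane(lm)
    L2 <- project_points(unclass(lm), pl)
    rownames(L2) <- rownames(lm)
    fm <- L2[ring_labs, , drop = FALSE]
    o <- (fm["fm_base_1", ] + fm["fm_base_2", ]) / 2
    dx <- fm["fm_base_2", ] - fm["fm_base_1", ]
    dx <- dx / sqrt(sum(dx^2))
    dy <- c(-dx[2], dx[1])
    loc <- cbind((fm[, 1] - o[1]) * dx[1] + (fm[, 2] - o[2]) * dx[2],
                 (fm[, 1] - o[1]) * dy[1] + (fm[, 2] - o[2]) * dy[2])
    if (loc["fm_apex", 2] < 0) loc[, 2] <- -loc[, 2]
    rownames(loc) <- ring_labs
    loc
  })
  mean_ring <- Reduce(`+`, rings) / length(rings)
  model_fin(mean_ring)
}

#' Base frame of a fish's fin
#'
#' The registration targets for [register_model_fin()]: the projected FM
#' base midpoint and the base angle (degrees, relative to the in-plane body
#' axis) of one fish's fin.
#'
#' @param landmarks A [fin_landmarks()] set.
#' @param plane Its [fit_plane()].
#' @return List with `base_midpoint` (2D) and `base_angle_deg`.
#' @export
fin_base_frame <- function(landmarks, plane) {
  L2 <- project_points(unclass(landmarks), plane)
  rownames(L2) <- rownames(landmarks)
  d <- L2["fm_base_2", ] - L2["fm_base_1", ]
  list(base_midpoint = (L2["fm_base_1", ] + L2["fm_base_2", ]) / 2,
       base_angle_deg = atan2(d[2], d[1]) * 180 / pi)
}

#' Register the model fin onto a fish
#'
#' Rigid 2D transform (rotation + translation, no scaling) placing the
#' model's base midpoint on the fish's and matching the base angle.
#'
#' @param model A [model_fin()].
#' @param base_midpoint Target 2D point.
#' @param base_angle_deg Target base angle in degrees.
#' @return The placed polygon (n x 2 matrix, rownames preserved).
#' @export
register_model_fin <- function(model, base_midpoint, base_angle_deg) {
  stopifnot(inherits(model, "model_fin"))
  th <- (base_angle_deg - model$base_angle_deg) * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- sweep(model$polygon, 2, model$base_midpoint)
  out <- ctr %*% t(R)
  out <- sweep(out, 2, base_midpoint, `+`)
  rownames(out) <- rownames(model$polygon)
  out
}

#' Axial innervation overlapped by the (adducted) fin
#'
#' Projects the axial-labeled innervation onto the fin plane, clips it to
#' the placed fin polygon, and reports the 3D arc length of the clipped
#' parts together with the percentage of the total axial length they
#' represent — the skin innervation assumed to be contacted by the fin
#' during adduction.
#'
#' @param tree An annotated [neuron_tree()].
#' @param placed_fin 2D polygon (n x 2), e.g. from [register_model_fin()].
#' @param plane A [fit_plane()].
#' @return List with `length_within` (um) and `percent_of_axial` in
#'   [0, 100]; both 0 (with a warning) when the tree has no axial label.
#' @export
axial_overlap <- function(tree, placed_fin, plane) {
  stopifnot(inherits(tree, "neuron_tree"), inherits(plane, "fit_plane"))
  pr <- .parent_rows(tree)
  lab <- tree$annotations
  ax <- which(!is.na(pr) & lab == "axial")
  if (length(ax) == 0L) {
    warning("tree carries no axial-labeled innervation")
    return(list(length_within = 0, percent_of_axial = 0))
  }
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  A3 <- xyz[pr[ax], , drop = FALSE]; B3 <- xyz[ax, , drop = FALSE]
  A2 <- project_points(A3, plane); B2 <- project_points(B3, plane)
  len3 <- sqrt(rowSums((B3 - A3)^2))
  n <- nrow(placed_fin)
  tmat <- NULL
  for (i in seq_len(n)) {
    C <- placed_fin[i, ]; D <- placed_fin[if (i == n) 1L else i + 1L, ]
    tmat <- cbind(tmat, .edge_crossings(A2, B2, C, D))
  }
  splits <- lapply(seq_along(ax), function(i) {
    tv <- tmat[i, ]
    tv <- sort(tv[!is.na(tv)])
    if (length(tv) > 1L) tv <- tv[c(TRUE, diff(tv) > 1e-12)]
    tv
  })
  nseg <- lengths(splits) + 1L
  edge <- rep(seq_along(splits), nseg)
  t0 <- unlist(lapply(splits, function(s) c(0, s)), use.names = FALSE)
  t1 <- unlist(lapply(splits, function(s) c(s, 1)), use.names = FALSE)
  mid <- (t0 + t1) / 2
  mxy <- cbind(A2[edge, 1] + mid * (B2[edge, 1] - A2[edge, 1]),
               A2[edge, 2] + mid * (B2[edge, 2] - A2[edge, 2]))
  inside <- .in_poly(mxy, placed_fin, boundary = TRUE)
  within <- sum(len3[edge] * (t1 - t0) * inside)
  total <- sum(len3)
  list(length_within = within, percent_of_axial = 100 * within / total)
}
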
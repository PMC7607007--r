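# Tree builders and independent brute-force oracles. The oracles work
# directly on the node table with their own recursions and never call the
# package's traversal code.

make_tree <- function(id, parent, x, y, z = rep(0, length(id)), labels = NULL) {
  nodes <- data.frame(node_id = as.integer(id), structure = 2L,
                      x = x, y = y, z = z, radius = NA_real_,
                      parent_id = as.integer(parent))
  neuron_tree(nodes, labels)
}

path_tree <- function(n, step = 2) {
  make_tree(1:n, c(-1L, seq_len(n - 1)), x = step * (0:(n - 1)), y = rep(0, n))
}

# stem up +y then two straight daughters, `half_angle` degrees either side
# of the stem direction, each with `d_n` nodes
y_tree <- function(stem_n = 3, d_n = 12, half_angle = 45, step = 1) {
  sx <- rep(0, stem_n); sy <- step * (0:(stem_n - 1))
  a1 <- (90 - half_angle) * pi / 180
  a2 <- (90 + half_angle) * pi / 180
  bx <- sx[stem_n]; by <- sy[stem_n]
  d1x <- bx + step * (1:d_n) * cos(a1); d1y <- by + step * (1:d_n) * sin(a1)
  d2x <- bx + step * (1:d_n) * cos(a2); d2y <- by + step * (1:d_n) * sin(a2)
  n <- stem_n + 2 * d_n
  id <- 1:n
  parent <- c(-1L, seq_len(stem_n - 1),              # stem chain
              stem_n, stem_n + seq_len(d_n - 1),     # daughter 1
              stem_n, stem_n + d_n + seq_len(d_n - 1))  # daughter 2
  make_tree(id, parent, x = c(sx, d1x, d2x), y = c(sy, d1y, d2y))
}

# random binary topology with `ntips` terminals and random coordinates
random_bin_tree <- function(ntips, coord_sd = 20) {
  parent <- c(-1L, 1L)
  terminals <- 2L
  while (length(terminals) < ntips) {
    t <- terminals[sample.int(length(terminals), 1)]
    k <- length(parent)
    parent <- c(parent, t, t)
    terminals <- c(setdiff(terminals, t), k + 1L, k + 2L)
  }
  n <- length(parent)
  make_tree(1:n, parent,
            x = rnorm(n, 0, coord_sd), y = rnorm(n, 0, coord_sd),
            z = rnorm(n, 0, coord_sd))
}

bf_children <- function(tree) {
  pr <- match(tree$nodes$parent_id, tree$nodes$node_id)
  idx <- which(!is.na(pr))
  ch <- vector("list", nrow(tree$nodes))
  sp <- split(idx, pr[idx])
  ch[as.integer(names(sp))] <- sp
  ch
}

bf_tips_of <- function(ch, v) {
  if (length(ch[[v]]) == 0L) return(1L)
  sum(vapply(ch[[v]], function(k) bf_tips_of(ch, k), integer(1)))
}

bf_strahler <- function(tree) {
  ch <- bf_children(tree)
  rec <- function(v) {
    if (length(ch[[v]]) == 0L) return(1L)
    sv <- vapply(ch[[v]], rec, integer(1))
    m <- max(sv)
    if (length(sv) >= 2L && all(sv == m)) m + 1L else m
  }
  rec(which(tree$nodes$parent_id == -1L))
}

bf_mean_asymmetry <- function(tree) {
  ch <- bf_children(tree)
  vals <- numeric(0)
  for (v in which(lengths(ch) >= 2L)) {
    tv <- vapply(ch[[v]], function(k) bf_tips_of(ch, k), integer(1))
    prs <- utils::combn(seq_along(tv), 2)
    node_vals <- apply(prs, 2, function(p) {
      l <- tv[p[1]]; r <- tv[p[2]]
      if (l + r > 2L) abs(l - r) / (l + r - 2L) else NA_real_
    })
    if (any(!is.na(node_vals))) vals <- c(vals, mean(node_vals, na.rm = TRUE))
  }
  if (length(vals)) mean(vals) else NaN
}

bf_total_length <- function(tree) {
  pr <- match(tree$nodes$parent_id, tree$nodes$node_id)
  i <- which(!is.na(pr))
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  sum(sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[pr[i], , drop = FALSE])^2)))
}

bf_counts <- function(tree) {
  ch <- bf_children(tree)
  list(tips = sum(lengths(ch) == 0L),
       branch_points = sum(lengths(ch) >= 2L))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_tree <- function(tree, R, tvec) {
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% t(R)
  tree$nodes$x <- xyz[, 1] + tvec[1]
  tree$nodes$y <- xyz[, 2] + tvec[2]
  tree$nodes$z <- xyz[, 3] + tvec[3]
  tree
}

transform_landmarks <- function(lm, R, tvec) {
  m <- unclass(lm) %*% t(R)
  m <- sweep(m, 2, tvec, `+`)
  rownames(m) <- rownames(lm)
  fin_landmarks(m)
}

# noise-free, symmetric landmark fan (exactly coplanar)
clean_landmarks <- function(seed = 1) {
  cfg <- generator_config(seed = seed,
                          fin = list(r_fb = 80, band = 70,
                                     radial_noise = 0, z_noise = 0))
  set.seed(seed)
  generate_fin_landmarks(cfg)
}

# small cohort configuration for fast tests
small_config <- function(seed = 1, n = c(3, 2, 1), n_unbranched = 1, ...) {
  reg <- default_regimes()
  reg$arborized$n <- n[1]; reg$dense$n <- n[2]; reg$sparse$n <- n[3]
  generator_config(seed = seed, regimes = reg, n_unbranched = n_unbranched,
                   n_rb = min(2L, sum(n)), ...)
}

# tiny annotated tree whose fin edges are given explicitly as a matrix of 3D
# segments (each row: parent xyz then child xyz; the child carries `label`)
segment_tree <- function(p0, segs, labels) {
  xs <- p0[1]; ys <- p0[2]; zs <- p0[3]
  parent <- -1L
  lab <- "axial"
  for (i in seq_len(nrow(segs))) {
    xs <- c(xs, segs[i, 1], segs[i, 4]); ys <- c(ys, segs[i, 2], segs[i, 5])
    zs <- c(zs, segs[i, 3], segs[i, 6])
    parent <- c(parent, 1L, length(parent) + 1L)
    lab <- c(lab, "unlabeled", labels[i])
  }
  make_tree(seq_along(xs), parent, x = xs, y = ys, z = zs, labels = lab)
}

# feature table straight from in-memory cohort objects
cohort_features <- function(cohort) {
  do.call(rbind, lapply(names(cohort$trees), function(id) {
    feature_vector(cohort$trees[[id]],
                   cohort$metadata[cohort$metadata$neuron_id == id, ,
                                   drop = FALSE])
  }))
}
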
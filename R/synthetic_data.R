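# Synthetic cohorts with known ground truth. The generator emulates the
# study design: sparsely labeled fin sensory neurons whose soma sits on the
# body (hindbrain or Rohon-Beard spinal position, encoded as a signed
# anteroposterior coordinate), a long unbranched stem to the fin base, a
# bifurcating arbor over the near-planar fin surface (medial or lateral,
# offset +/- epsilon from the plane and labeled), an arbor over the adjacent
# axial body wall, and an 18-point fin edge landmark set (FB ring inside FM
# ring). Cohorts contain three branching-statistics regimes mirroring the
# three observed morphological clusters, plus one neuron that does not
# branch in the fin.
#
# Growth is a correlated random walk with segment-level bifurcation — a
# measurement test-bed, not a biophysical model. Ground-truth octant lengths
# are computed in the generator's own canonical frame by dense sub-sampling
# of every emitted edge, independent of the plane-fit/projection measurement
# path.

#' Default morphology regimes
#'
#' Three branching-statistics classes mimicking the observed clusters:
#' a moderately arborized majority class, a small densely branching class,
#' and a single sparsely branching cell. `n` per regime defaults to 14/5/1.
#'
#' @return Named list of regime parameter lists (`n`, `branch_prob` per
#'   node, `step_um`, `tortuosity` (sd of heading change per step, rad),
#'   `angle_mean`/`angle_sd` (daughter amplitude, degrees),
#'   `medial_fraction`, `max_branch_points`).
#' @export
default_regimes <- function() {
  list(
    arborized = list(n = 14L, branch_prob = 0.06, step_um = 4, tortuosity = 0.20,
                     angle_mean = 70, angle_sd = 12, medial_fraction = 0.7,
                     max_branch_points = 22L),
    dense = list(n = 5L, branch_prob = 0.14, step_um = 3, tortuosity = 0.45,
                 angle_mean = 105, angle_sd = 12, medial_fraction = 0.7,
                 max_branch_points = 55L),
    sparse = list(n = 1L, branch_prob = 0.025, step_um = 6, tortuosity = 0.08,
                  angle_mean = 40, angle_sd = 8, medial_fraction = 0.7,
                  max_branch_points = 4L)
  )
}

#' Generator configuration
#'
#' All tunables of the synthetic cohort, with defaults set to the study
#' conditions: 21 neurons (14/5/1 across three regimes plus one neuron that
#' does not branch in the fin), 4 Rohon-Beard cells at positive (spinal)
#' anteroposterior positions and 17 hindbrain cells at negative positions,
#' soma areas drawn within the observed 48.9-178.6 um^2 range, a fin of
#' ~150 um extent (FB radius + FM band), and a mild anterior-to-posterior
#' decline in arbor size (anterior neurons grow larger fin arbors).
#'
#' @param seed Integer seed; a fixed seed makes the cohort bit-identical.
#' @param regimes See [default_regimes()].
#' @param n_unbranched Neurons with an unbranched fin process (default 1).
#' @param n_rb Rohon-Beard neurons (positive ap positions); the unbranched
#'   neuron is always one of them.
#' @param fin Fin shape: `r_fb` (FB ring radius, um), `band` (FM band
#'   width, um), `radial_noise`, `z_noise` (out-of-plane sd, um).
#' @param surface_offset Out-of-plane offset of fin nodes (+ medial,
#'   - lateral, um).
#' @param surface_switch_prob Probability a daughter branch switches fin
#'   surface at a bifurcation.
#' @param ap_hb,ap_rb Uniform ranges (um) for hindbrain / RB soma positions.
#' @param soma_area_range Uniform range for soma areas (um^2).
#' @param ap_length_trend Fractional modulation of arbor size across the
#'   anteroposterior range (0 disables the trend).
#' @param axial Axial-arbor parameters: `branch_prob`, `step_um`,
#'   `tortuosity`, `base_branch_points` (added to half the neuron's fin
#'   branch-point budget), `extent` (x1, x2, y1, y2 rectangle, um), `z_um`.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             regimes = default_regimes(),
                             n_unbranched = 1L,
                             n_rb = 4L,
                             fin = list(r_fb = 80, band = 70,
                                        radial_noise = 3, z_noise = 2),
                             surface_offset = 3,
                             surface_switch_prob = 0.15,
                             ap_hb = c(-300, -50),
                             ap_rb = c(30, 150),
                             soma_area_range = c(48.9, 178.6),
                             ap_length_trend = 0.2,
                             axial = list(branch_prob = 0.05, step_um = 4,
                                          tortuosity = 0.25,
                                          base_branch_points = 5L,
                                          extent = c(-250, 250, -120, 60),
                                          z_um = 6)) {
  stopifnot(length(regimes) >= 1, n_unbranched >= 0)
  for (r in regimes) {
    stopifnot(r$branch_prob >= 0, r$branch_prob <= 1, r$step_um > 0,
              r$medial_fraction >= 0, r$medial_fraction <= 1)
  }
  structure(list(seed = as.integer(seed), regimes = regimes,
                 n_unbranched = as.integer(n_unbranched),
                 n_rb = as.integer(n_rb), fin = fin,
                 surface_offset = surface_offset,
                 surface_switch_prob = surface_switch_prob,
                 ap_hb = ap_hb, ap_rb = ap_rb,
                 soma_area_range = soma_area_range,
                 ap_length_trend = ap_length_trend, axial = axial),
            class = "generator_config")
}

#' Generate a fin landmark set
#'
#' 18 points on a noisy near-planar fan: the FB ring (radius `r_fb`) strictly
#' inside the FM ring (radius `r_fb + band`), base points exactly on the
#' body-axis line (y = 0), out-of-plane noise of sd `z_noise`. With
#' `z_noise = 0` all 18 points are exactly coplanar. Uses the current RNG
#' state (seed via [generate_cohort()] or `set.seed`).
#'
#' @param config A [generator_config()].
#' @return A [fin_landmarks()] set in the canonical frame (plane z = 0,
#'   base along x, fin at y > 0, medial side at z > 0).
#' @export
generate_fin_landmarks <- function(config) {
  f <- config$fin
  th <- seq(pi, 0, length.out = 9)
  fb_r <- pmax(f$r_fb + stats::rnorm(9, 0, f$radial_noise), f$r_fb / 2)
  fm_r <- pmax(f$r_fb + f$band + stats::rnorm(9, 0, f$radial_noise), fb_r + 2)
  ring <- function(r) {
    xy <- cbind(r * cos(th), r * sin(th))
    xy[c(1, 9), 2] <- 0  # base points exactly on the body axis
    xy
  }
  pts <- rbind(ring(fb_r), ring(fm_r))
  pts <- cbind(pts, stats::rnorm(18, 0, f$z_noise))
  rownames(pts) <- landmark_labels()
  fin_landmarks(pts)
}

# growable node store
.new_store <- function(cap = 1024L) {
  env <- new.env(parent = emptyenv())
  env$xyz <- matrix(NA_real_, cap, 3)
  env$parent <- integer(cap)
  env$label <- character(cap)
  env$n <- 0L
  env
}

.add_nodes <- function(env, xyz, parents, labels) {
  k <- nrow(xyz)
  while (env$n + k > nrow(env$xyz)) {
    env$xyz <- rbind(env$xyz, matrix(NA_real_, nrow(env$xyz), 3))
    env$parent <- c(env$parent, integer(length(env$parent)))
    env$label <- c(env$label, character(length(env$label)))
  }
  idx <- env$n + seq_len(k)
  env$xyz[idx, ] <- xyz
  env$parent[idx] <- parents
  env$label[idx] <- labels
  env$n <- env$n + k
  idx
}

# correlated random walk confined to a polygon; returns the kept points
.walk_segment <- function(pos, heading, m, step, tort, poly) {
  th <- heading + cumsum(stats::rnorm(m, 0, tort))
  xs <- pos[1] + cumsum(step * cos(th))
  ys <- pos[2] + cumsum(step * sin(th))
  inside <- pracma::inpolygon(xs, ys, poly[, 1], poly[, 2], boundary = FALSE)
  k <- if (all(inside)) m else which(!inside)[1] - 1L
  list(x = xs[seq_len(k)], y = ys[seq_len(k)],
       heading = if (k > 0L) th[k] else heading, exited = k < m)
}

# grow one bifurcating arbor inside `poly` starting at node `root_idx`
# (position pos0), planar at z via `zfun(surface)`; returns branch count.
# A tip whose segment hits the domain boundary turns back toward the domain
# centroid (with jitter) rather than dying, so the branch-point budget is
# actually consumed; tips terminate once the budget is exhausted (or after
# max_turns boundary hits, or at the global node cap).
.grow_arbor <- function(env, root_idx, pos0, heading0, surface0, params, poly,
                        zfun, labfun, switch_prob, max_bp,
                        max_turns = 50L, max_nodes = 20000L) {
  ctr <- colMeans(poly)
  bp <- 0L
  tips <- list(list(node = root_idx, pos = pos0, heading = heading0,
                    surface = surface0, turns = 0L))
  while (length(tips)) {
    i <- if (length(tips) == 1L) 1L else sample.int(length(tips), 1L)
    tip <- tips[[i]]
    tips[[i]] <- NULL
    m <- 1L + stats::rgeom(1, params$branch_prob)
    m <- min(max(m, 1L), 200L)
    w <- .walk_segment(tip$pos, tip$heading, m, params$step_um,
                       params$tortuosity, poly)
    k <- length(w$x)
    if (k > 0L) {
      idx <- .add_nodes(env,
                        cbind(w$x, w$y, zfun(tip$surface, k)),
                        c(tip$node, if (k > 1L) (env$n + 1L):(env$n + k - 1L)),
                        rep(labfun(tip$surface), k))
      end_node <- idx[k]
      end_pos <- c(w$x[k], w$y[k])
    } else {
      end_node <- tip$node
      end_pos <- tip$pos
    }
    if (env$n >= max_nodes) break
    if (w$exited) {
      if (tip$turns < max_turns) {
        back <- atan2(ctr[2] - end_pos[2], ctr[1] - end_pos[1])
        tips[[length(tips) + 1L]] <-
          list(node = end_node, pos = end_pos,
               heading = back + stats::rnorm(1, 0, 0.4),
               surface = tip$surface, turns = tip$turns + 1L)
      }
    } else if (bp < max_bp) {
      bp <- bp + 1L
      dth <- (params$angle_mean / 2 + stats::rnorm(2, 0, params$angle_sd)) * pi / 180
      mf <- if (is.null(params$medial_fraction)) 0.5 else params$medial_fraction
      for (sgn in c(1, -1)) {
        surf <- tip$surface
        # redraw from the configured fraction, so the stationary
        # medial/lateral split equals medial_fraction
        if (stats::runif(1) < switch_prob) {
          surf <- if (stats::runif(1) < mf) 1L else 2L
        }
        tips[[length(tips) + 1L]] <-
          list(node = end_node, pos = end_pos,
               heading = w$heading + sgn * dth[(3 - sgn) / 2],
               surface = surf, turns = tip$turns)
      }
    }
  }
  bp
}

#' Generate one synthetic neuron
#'
#' Soma on the body at the given anteroposterior position, an unbranched
#' axial-labeled stem to the fin base, a bifurcating fin arbor confined to
#' the landmark footprint (medial/lateral surfaces offset +/- epsilon and
#' labeled), and a bifurcating axial arbor on the adjacent body wall. Uses
#' the current RNG state.
#'
#' @param config A [generator_config()].
#' @param regime One regime parameter list (see [default_regimes()]).
#' @param landmarks The cohort's [generate_fin_landmarks()] set.
#' @param neuron_id Character id.
#' @param ap_position Anteroposterior soma position (um).
#' @param unbranched Grow a single unbranched fin process instead of an
#'   arbor (the "did not branch in the fin" case).
#' @param size_multiplier Scales the branch-point budgets (used for the
#'   anteroposterior size trend).
#' @return List with `tree` (annotated [neuron_tree()]) and `truth`
#'   (generator bookkeeping: regime sizes, per-label lengths, branch and
#'   terminal counts; octant truth is added by [cohort_truth()]).
#' @export
generate_neuron <- function(config, regime, landmarks, neuron_id,
                            ap_position, unbranched = FALSE,
                            size_multiplier = 1) {
  lm <- unclass(landmarks)
  footprint <- lm[landmark_labels()[10:18], 1:2]
  env <- .new_store()
  soma <- c(ap_position, -100, 0)
  .add_nodes(env, matrix(soma, 1), 0L, "axial")
  # unbranched stem: soma -> fin base entry
  entry <- c(stats::runif(1, -0.3, 0.3) * config$fin$r_fb, 0)
  v <- entry - soma[1:2]
  dist <- sqrt(sum(v^2))
  nstep <- max(2L, ceiling(dist / regime$step_um))
  tfrac <- seq_len(nstep) / nstep
  jig <- cbind(stats::rnorm(nstep, 0, 0.5), stats::rnorm(nstep, 0, 0.5))
  jig[nstep, ] <- 0
  stem_xy <- cbind(soma[1] + tfrac * v[1], soma[2] + tfrac * v[2]) + jig
  stem_idx <- .add_nodes(env, cbind(stem_xy, 0),
                         c(1L, if (nstep > 1L) 2L:(nstep)), # soma is node 1
                         rep("axial", nstep))
  stem_end <- stem_idx[nstep]
  stem_pts <- rbind(soma[1:2], stem_xy)
  stem_length <- sum(sqrt(rowSums(diff(stem_pts)^2)))
  # fin arbor
  surface0 <- if (stats::runif(1) < regime$medial_fraction) 1L else 2L
  zfun <- function(surface, k) rep(if (surface == 1L) config$surface_offset
                                   else -config$surface_offset, k)
  labfun <- function(surface) if (surface == 1L) "fin_medial" else "fin_lateral"
  heading0 <- pi / 2 + stats::rnorm(1, 0, 0.2)
  if (unbranched) {
    w <- .walk_segment(entry, heading0, 30L, regime$step_um,
                       regime$tortuosity, footprint)
    k <- length(w$x)
    if (k > 0L) {
      .add_nodes(env, cbind(w$x, w$y, zfun(surface0, k)),
                 c(stem_end, if (k > 1L) (env$n + 1L):(env$n + k - 1L)),
                 rep(labfun(surface0), k))
    }
    fin_bp <- 0L
  } else {
    max_bp <- max(1L, round(regime$max_branch_points * size_multiplier))
    fin_bp <- .grow_arbor(env, stem_end, entry, heading0, surface0, regime,
                          footprint, zfun, labfun,
                          config$surface_switch_prob, max_bp)
  }
  # axial arbor on the body wall, attached at the soma
  ax <- config$axial
  ext <- ax$extent
  rect <- cbind(ap_position + c(ext[1], ext[2], ext[2], ext[1]),
                c(ext[3], ext[3], ext[4], ext[4]))
  ax_params <- list(branch_prob = ax$branch_prob, step_um = ax$step_um,
                    tortuosity = ax$tortuosity, angle_mean = 80, angle_sd = 15)
  ax_bp_budget <- max(1L, round((ax$base_branch_points +
                                 0.5 * regime$max_branch_points) *
                                size_multiplier))
  ax_bp <- .grow_arbor(env, 1L, soma[1:2], stats::runif(1, 0, 2 * pi), 1L,
                       ax_params, rect,
                       function(surface, k) rep(ax$z_um, k),
                       function(surface) "axial",
                       0, ax_bp_budget)
  n <- env$n
  nodes <- data.frame(node_id = seq_len(n),
                      structure = c(1L, rep(2L, n - 1L)),
                      x = env$xyz[seq_len(n), 1],
                      y = env$xyz[seq_len(n), 2],
                      z = env$xyz[seq_len(n), 3],
                      radius = 1,
                      parent_id = ifelse(env$parent[seq_len(n)] == 0L, -1L,
                                         env$parent[seq_len(n)]))
  tree <- neuron_tree(nodes, env$label[seq_len(n)])
  truth <- .neuron_truth(tree, neuron_id, stem_length, unbranched)
  list(tree = tree, truth = truth)
}

# closed-form bookkeeping from the emitted node table (independent of the
# morphometry traversal: direct edge sums and a tip-count recursion)
.neuron_truth <- function(tree, neuron_id, stem_length, unbranched) {
  nd <- tree$nodes
  lab <- tree$annotations
  pr <- match(nd$parent_id, nd$node_id)
  nonroot <- which(nd$parent_id != -1L)
  step <- numeric(nrow(nd))
  step[nonroot] <- sqrt((nd$x[nonroot] - nd$x[pr[nonroot]])^2 +
                        (nd$y[nonroot] - nd$y[pr[nonroot]])^2 +
                        (nd$z[nonroot] - nd$z[pr[nonroot]])^2)
  by_label <- tapply(step[nonroot], lab[nonroot], sum)
  leaf <- !(seq_len(nrow(nd)) %in% pr[nonroot])
  fin_idx <- which(lab %in% fin_labels())
  # branch points of the fin restriction: nodes with >= 2 fin-labeled children
  fin_bp <- sum(table(pr[fin_idx]) >= 2L)
  fin_root <- if (length(fin_idx)) {
    roots <- setdiff(unique(pr[fin_idx]), fin_idx)
    roots[1]
  } else NA_integer_
  # Strahler of the fin subforest by a reverse index sweep (the generator
  # emits parents before children, so children always have larger indices)
  fin_children <- split(fin_idx, pr[fin_idx])
  fin_strahler <- NA_integer_
  if (!is.na(fin_root)) {
    str_arr <- rep(NA_integer_, nrow(nd))
    for (v in sort(c(fin_idx, fin_root), decreasing = TRUE)) {
      kids <- fin_children[[as.character(v)]]
      if (is.null(kids)) {
        str_arr[v] <- 1L
      } else {
        sv <- str_arr[kids]
        m <- max(sv)
        str_arr[v] <- if (length(sv) >= 2L && all(sv == m)) m + 1L else m
      }
    }
    fin_strahler <- str_arr[fin_root]
  }
  list(neuron_id = neuron_id,
       unbranched = unbranched,
       fin_branch_points = fin_bp,
       fin_strahler = fin_strahler,
       stem_length = stem_length,
       length_by_label = by_label,
       fin_length = sum(by_label[fin_labels()], na.rm = TRUE),
       axial_length = unname(by_label["axial"]),
       terminals_medial = sum(leaf & lab == "fin_medial"),
       terminals_lateral = sum(leaf & lab == "fin_lateral"),
       terminals_axial = sum(leaf & lab == "axial"))
}

#' Canonical-frame octant ground truth
#'
#' Computes the true per-octant fin lengths and the axial under-fin split in
#' the generator's canonical frame (plane z = 0) by densely sub-sampling
#' every emitted edge (`samples` points per edge) and classifying each
#' sample against the canonical landmark rings and dorsoventral line. This
#' path shares no code with the measurement pipeline (no plane fit, no
#' projection, no edge splitting), so it serves as an independent oracle.
#'
#' @param tree An annotated [neuron_tree()] in the canonical frame.
#' @param landmarks The canonical [generate_fin_landmarks()] set.
#' @param samples Sub-samples per edge (default 100).
#' @return List with `octants` (8-row data frame region x surface with
#'   `length_um`) and `axial` (`length_um`, `under_fin_um`,
#'   `terminals_under_fin`).
#' @export
cohort_truth <- function(tree, landmarks, samples = 100L) {
  lm <- unclass(landmarks)
  fb <- lm[landmark_labels()[1:9], 1:2]
  fm <- lm[landmark_labels()[10:18], 1:2]
  m_prox <- (fb["fb_base_1", ] + fb["fb_base_2", ]) / 2
  M <- (m_prox + fb["fb_apex", ]) / 2
  d <- fm["fm_apex", ] - M
  d <- d / sqrt(sum(d^2))
  s1 <- d[1] * (fb["fb_base_1", 2] - M[2]) - d[2] * (fb["fb_base_1", 1] - M[1])
  dsign <- sign(s1)
  classify <- function(x, y) {
    side <- dsign * (d[1] * (y - M[2]) - d[2] * (x - M[1]))
    inb <- pracma::inpolygon(x, y, fb[, 1], fb[, 2], boundary = FALSE)
    paste0(ifelse(side >= 0, "D", "V"), ifelse(inb, "B", "M"))
  }
  nd <- tree$nodes
  lab <- tree$annotations
  pr <- match(nd$parent_id, nd$node_id)
  sample_edges <- function(rows) {
    A <- cbind(nd$x[pr[rows]], nd$y[pr[rows]])
    B <- cbind(nd$x[rows], nd$y[rows])
    dz <- nd$z[rows] - nd$z[pr[rows]]
    len3 <- sqrt(rowSums((B - A)^2) + dz^2)
    tmid <- (seq_len(samples) - 0.5) / samples
    xs <- as.vector(outer(B[, 1] - A[, 1], tmid) + A[, 1])
    ys <- as.vector(outer(B[, 2] - A[, 2], tmid) + A[, 2])
    list(x = xs, y = ys, w = rep(len3 / samples, times = samples),
         edge_of = rep(seq_along(rows), times = samples))
  }
  octants <- expand.grid(region = c("DM", "DB", "VB", "VM"),
                         surface = c("medial", "lateral"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  octants$length_um <- 0
  fin_rows <- which(nd$parent_id != -1L & lab %in% fin_labels())
  if (length(fin_rows)) {
    sp <- sample_edges(fin_rows)
    reg <- classify(sp$x, sp$y)
    surf <- ifelse(lab[fin_rows] == "fin_medial", "medial",
                   "lateral")[sp$edge_of]
    agg <- tapply(sp$w, paste(reg, surf), sum)
    idx <- match(names(agg), paste(octants$region, octants$surface))
    octants$length_um[idx] <- as.numeric(agg)
  }
  ax_rows <- which(nd$parent_id != -1L & lab == "axial")
  axial <- list(length_um = 0, under_fin_um = 0, terminals_under_fin = 0L)
  if (length(ax_rows)) {
    sp <- sample_edges(ax_rows)
    infp <- pracma::inpolygon(sp$x, sp$y, fm[, 1], fm[, 2], boundary = TRUE)
    axial$length_um <- sum(sp$w)
    axial$under_fin_um <- sum(sp$w[infp])
    leaf <- !(seq_len(nrow(nd)) %in% pr[which(nd$parent_id != -1L)])
    ax_leaves <- which(leaf & lab == "axial")
    axial$terminals_under_fin <-
      sum(pracma::inpolygon(nd$x[ax_leaves], nd$y[ax_leaves],
                            fm[, 1], fm[, 2], boundary = TRUE))
  }
  list(octants = octants, axial = axial)
}

#' Generate a synthetic cohort
#'
#' Seeds the RNG from the config, generates the landmark set and all
#' neurons (regimes in order, then the unbranched neuron(s)), assigns
#' Rohon-Beard identities (positive ap positions; the unbranched neuron is
#' always an RB, mirroring the study's bookkeeping) and draws soma areas.
#' Identical seed and config give bit-identical output.
#'
#' @param config A [generator_config()].
#' @return List with `trees` (named list of annotated [neuron_tree()]s),
#'   `metadata` (data frame), `landmarks`, `truth` (named list of per-neuron
#'   bookkeeping), and `regime` (named character vector of true regime
#'   labels, `"unbranched"` for the non-branching neuron(s)).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  landmarks <- generate_fin_landmarks(config)
  regime_of <- unlist(lapply(names(config$regimes),
                             function(nm) rep(nm, config$regimes[[nm]]$n)))
  regime_of <- c(regime_of, rep("unbranched", config$n_unbranched))
  N <- length(regime_of)
  ids <- sprintf("n%02d", seq_len(N))
  # RB assignment: unbranched neuron(s) first, then random others
  is_rb <- logical(N)
  if (config$n_unbranched > 0 && config$n_rb > 0) {
    is_rb[regime_of == "unbranched"] <- TRUE
  }
  extra <- config$n_rb - sum(is_rb)
  if (extra > 0) {
    pool <- which(!is_rb)
    is_rb[sample(pool, min(extra, length(pool)))] <- TRUE
  }
  ap <- ifelse(is_rb,
               stats::runif(N, config$ap_rb[1], config$ap_rb[2]),
               stats::runif(N, config$ap_hb[1], config$ap_hb[2]))
  soma <- stats::runif(N, config$soma_area_range[1], config$soma_area_range[2])
  # anteroposterior size trend: anterior neurons get a larger budget
  ap_all <- c(config$ap_hb, config$ap_rb)
  ap_mid <- mean(range(ap_all)); ap_half <- diff(range(ap_all)) / 2
  mult <- 1 - config$ap_length_trend * (ap - ap_mid) / ap_half
  trees <- vector("list", N); truth <- vector("list", N)
  names(trees) <- ids; names(truth) <- ids
  for (i in seq_len(N)) {
    rg <- if (regime_of[i] == "unbranched") config$regimes[[1]]
          else config$regimes[[regime_of[i]]]
    g <- generate_neuron(config, rg, landmarks, ids[i], ap[i],
                         unbranched = regime_of[i] == "unbranched",
                         size_multiplier = mult[i])
    trees[[i]] <- g$tree
    truth[[i]] <- g$truth
  }
  metadata <- do.call(rbind, lapply(seq_len(N), function(i)
    neuron_metadata(ids[i], soma[i], ap[i], if (is_rb[i]) "RB" else "HB")))
  names(regime_of) <- ids
  list(trees = trees, metadata = metadata, landmarks = landmarks,
       truth = truth, regime = regime_of)
}

#' Generate a feature-space cohort with known regimes
#'
#' Draws feature rows directly from three (or more) Gaussian regimes in
#' standardized feature space: within-regime sd is 1 per feature and regime
#' means sit on mutually orthogonal directions scaled so that the distance
#' between any two regime centroids equals `separation` times the
#' within-regime RMS radius (`sqrt(p)`). `separation = 0` collapses all
#' regimes onto one blob.
#'
#' @param n_per_regime Integer vector of regime sizes.
#' @param separation Centroid distance in units of within-regime spread.
#' @param p Number of features (default 13).
#' @param seed Optional seed (otherwise the current RNG state is used).
#' @return List with `x` (matrix), `labels` (integer regime labels).
#' @export
generate_feature_cohort <- function(n_per_regime = c(10, 7, 3), separation = 4,
                                    p = 13L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(n_per_regime)
  stopifnot(K <= p)
  scale <- separation * sqrt(p) / sqrt(2)
  mu <- diag(K) * scale
  labels <- rep(seq_len(K), n_per_regime)
  x <- matrix(stats::rnorm(sum(n_per_regime) * p), ncol = p)
  x[, seq_len(K)] <- x[, seq_len(K)] + mu[labels, ]
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = labels)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the files the real pipeline consumes: one SWC and one
#' annotation TSV per neuron, a metadata CSV, a landmark CSV, and the
#' generator's truth tables (octant lengths and per-neuron summaries) for
#' auditing.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param truth_samples Sub-samples per edge for the octant truth.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth_samples = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$trees)) {
    write_swc(cohort$trees[[id]], file.path(dir, paste0(id, ".swc")))
    write_annotations(cohort$trees[[id]],
                      file.path(dir, paste0(id, "_annotations.tsv")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  write_landmarks(cohort$landmarks, file.path(dir, "landmarks.csv"))
  octs <- do.call(rbind, lapply(names(cohort$trees), function(id) {
    tr <- cohort_truth(cohort$trees[[id]], cohort$landmarks,
                       samples = truth_samples)
    data.frame(neuron_id = id, tr$octants,
               axial_um = tr$axial$length_um,
               axial_under_fin_um = tr$axial$under_fin_um)
  }))
  utils::write.csv(octs, file.path(dir, "truth_octants.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- do.call(rbind, lapply(cohort$truth, function(t)
    data.frame(neuron_id = t$neuron_id, regime = cohort$regime[t$neuron_id],
               unbranched = t$unbranched,
               fin_branch_points = t$fin_branch_points,
               fin_length_um = t$fin_length,
               axial_length_um = t$axial_length,
               terminals_medial = t$terminals_medial,
               terminals_lateral = t$terminals_lateral)))
  utils::write.csv(summ, file.path(dir, "truth_neurons.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
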
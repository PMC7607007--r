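# Interbranch re-segmentation and the 13-parameter morphological feature
# vector. All metrics are centerline-based (radii unused) and operate on a
# label restriction of the tree: an edge belongs to the restriction iff its
# child node carries one of the requested surface labels, so label classes
# partition the edge set exactly and restricted total lengths are additive.

# Resolve a restriction to the selected forest.
# Returns child rows (edges), restricted children lists, forest roots,
# and flags; errors when the selection is disconnected (multiple components).
.restrict <- function(tree, restriction = "all") {
  pr <- .parent_rows(tree)
  nonroot <- which(!is.na(pr))
  if (identical(restriction, "all")) {
    sel <- nonroot
  } else {
    if (!all(restriction %in% surface_labels())) {
      stop("unknown restriction label(s): ",
           paste(setdiff(restriction, surface_labels()), collapse = ", "))
    }
    sel <- nonroot[tree$annotations[nonroot] %in% restriction]
  }
  if (length(sel) == 0L) {
    stop("restriction selects an empty subtree (no edges carry the requested labels)")
  }
  n <- nrow(tree$nodes)
  in_sel <- logical(n); in_sel[sel] <- TRUE
  ch <- vector("list", n)
  sp <- split(sel, pr[sel])
  ch[as.integer(names(sp))] <- sp
  roots <- setdiff(unique(pr[sel]), sel)
  if (length(roots) > 1L) {
    stop("restriction selects a disconnected node set; orphan components rooted at node_id ",
         paste(tree$nodes$node_id[roots], collapse = ", "))
  }
  list(sel = sel, children = ch, root = roots, in_sel = in_sel, parent = pr)
}

.step_lengths <- function(tree) {
  pr <- .parent_rows(tree)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  d <- rep(NA_real_, nrow(xyz))
  nr <- which(!is.na(pr))
  d[nr] <- sqrt(rowSums((xyz[nr, , drop = FALSE] - xyz[pr[nr], , drop = FALSE])^2))
  d
}

#' Re-segment a tree into interbranch segments
#'
#' Splits the (restricted) arbor at its critical nodes — the segment origin
#' (forest root), branch points, and terminals — into interbranch segments:
#' maximal node paths whose interior nodes have exactly one child. For a
#' binary arbor hanging from a single stem, the number of segments equals the
#' number of terminals plus the number of branch points; a multifurcation of
#' arity a yields a child segments and counts once as a branch point.
#'
#' @param tree A [neuron_tree()].
#' @param restriction `"all"` or a character vector of surface labels; an
#'   edge is selected iff its child node carries one of the labels.
#' @return List of segments, each a list with `node_rows` (row indices,
#'   start critical node first), `arc_length`, `euclidean_length` (chord
#'   between endpoints, um) and `branch_order` (number of branch points on
#'   the path from the forest root up to and including the segment start).
#' @export
resegment <- function(tree, restriction = "all") {
  rs <- .restrict(tree, restriction)
  steps <- .step_lengths(tree)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  nch <- lengths(rs$children)
  is_branch <- nch >= 2L
  segments <- list()
  # queue of (critical start node, branch order at start)
  queue <- list(c(rs$root, as.integer(is_branch[rs$root])))
  while (length(queue)) {
    qe <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    s <- qe[1]; ord <- qe[2]
    for (c0 in rs$children[[s]]) {
      path <- c(s, c0)
      cur <- c0
      while (nch[cur] == 1L) {
        cur <- rs$children[[cur]][1]
        path <- c(path, cur)
      }
      arc <- sum(steps[path[-1]])
      eu <- sqrt(sum((xyz[cur, ] - xyz[s, ])^2))
      segments[[length(segments) + 1L]] <-
        list(node_rows = path, arc_length = arc, euclidean_length = eu,
             branch_order = ord)
      if (is_branch[cur]) queue[[length(queue) + 1L]] <- c(cur, ord + 1L)
    }
  }
  segments
}

#' Topological metrics of a (restricted) arbor
#'
#' Computes the branching metrics of the feature vector: the number of branch
#' points; the maximum branch order (number of branch points between the soma
#' and the terminal of the most-branched path, plus one); the Strahler number
#' (terminals are 1; a parent is n + 1 when all daughters carry n, otherwise
#' it takes the maximum daughter value); and the mean partition asymmetry
#' over branch points, `|l - r| / (l + r - 2)` for daughter terminal counts
#' (l, r), defined when l + r > 2 (a (1,1) bifurcation is excluded), with all
#' unordered daughter pairs averaged at a multifurcation.
#'
#' @inheritParams resegment
#' @return List with `n_branch_points`, `max_branch_order`, `strahler`,
#'   `mean_partition_asymmetry` (`NaN` when no branch point qualifies).
#' @export
topology_metrics <- function(tree, restriction = "all") {
  rs <- .restrict(tree, restriction)
  nch <- lengths(rs$children)
  # DFS order from the forest root (preallocated, iterative)
  n_forest <- length(rs$sel) + 1L
  order_ <- integer(n_forest)
  stack <- integer(n_forest); stack[1] <- rs$root; sp <- 1L; op <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    op <- op + 1L; order_[op] <- v
    kids <- rs$children[[v]]
    for (k in kids) { sp <- sp + 1L; stack[sp] <- k }
  }
  order_ <- order_[seq_len(op)]
  n <- nrow(tree$nodes)
  tips <- integer(n); strahler <- integer(n)
  for (v in rev(order_)) {
    kids <- rs$children[[v]]
    if (length(kids) == 0L) {
      tips[v] <- 1L; strahler[v] <- 1L
    } else {
      tips[v] <- sum(tips[kids])
      sv <- strahler[kids]
      m <- max(sv)
      strahler[v] <- if (length(sv) >= 2L && all(sv == m)) m + 1L else m
    }
  }
  branch_nodes <- order_[nch[order_] >= 2L]
  n_bp <- length(branch_nodes)
  # max branch order: branch points on each root-to-terminal path, + 1
  bp_on_path <- integer(n)
  for (v in order_) {
    here <- bp_on_path[v] + as.integer(nch[v] >= 2L)
    for (k in rs$children[[v]]) bp_on_path[k] <- here
  }
  terms <- order_[nch[order_] == 0L]
  max_order <- max(bp_on_path[terms]) + 1L
  # partition asymmetry
  asym <- rep(NA_real_, length(branch_nodes))
  i <- 0L
  for (v in branch_nodes) {
    i <- i + 1L
    tv <- tips[rs$children[[v]]]
    prs <- utils::combn(seq_along(tv), 2)
    vals <- apply(prs, 2, function(p) {
      l <- tv[p[1]]; r <- tv[p[2]]
      if (l + r > 2L) abs(l - r) / (l + r - 2L) else NA_real_
    })
    if (any(!is.na(vals))) asym[i] <- mean(vals, na.rm = TRUE)
  }
  mean_asym <- if (any(!is.na(asym))) mean(asym, na.rm = TRUE) else NaN
  list(n_branch_points = n_bp,
       max_branch_order = max_order,
       strahler = strahler[rs$root],
       mean_partition_asymmetry = mean_asym)
}

#' Geometric metrics of a (restricted) arbor
#'
#' Maximum path distance is the largest summed inter-node Euclidean step
#' length from the soma (the true tree root) to any selected terminal, so the
#' path leading up to a restricted arbor is always included, mirroring a
#' path measured "from the soma". Contraction is the per-segment chord/path
#' ratio, averaged over segments (1 = straight). Fractal dimension is the
#' per-segment slope of a log-log regression of cumulative path length on
#' cumulative chord length along the segment (exactly 1 for a straight
#' segment; segments with fewer than `min_fd_nodes` nodes are excluded).
#' Total length sums segment arc lengths; with `include_stem = TRUE` the arc
#' length of the path from the soma to the restricted arbor's origin is
#' added (the "processes leading up to the fin").
#'
#' @inheritParams resegment
#' @param include_stem Add the soma-to-arbor path length to `total_length`.
#' @param min_fd_nodes Minimum nodes per segment for the fractal-dimension
#'   regression (default 5).
#' @return List with `max_path_distance`, `mean_contraction`,
#'   `mean_fractal_dimension`, `total_length` (all um or dimensionless).
#' @export
geometry_metrics <- function(tree, restriction = "all", include_stem = FALSE,
                             min_fd_nodes = 5L) {
  rs <- .restrict(tree, restriction)
  segs <- resegment(tree, restriction)
  steps <- .step_lengths(tree)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  arcs <- vapply(segs, `[[`, numeric(1), "arc_length")
  total <- sum(arcs)
  if (include_stem) total <- total + .stem_length(tree, rs)
  zero_arc <- arcs <= 0
  if (any(zero_arc)) {
    warning(sum(zero_arc), " zero-arc-length segment(s) excluded from ratio averages")
  }
  contr <- vapply(segs, function(s) s$euclidean_length, numeric(1)) / arcs
  mean_contr <- if (any(!zero_arc)) mean(contr[!zero_arc]) else NaN
  # max path distance from the soma
  cum <- .cumdist_from_root(tree, steps)
  nch <- lengths(rs$children)
  terms <- which(rs$in_sel & nch == 0L)
  max_pd <- max(cum[terms])
  # fractal dimension per segment
  fd <- vapply(segs, function(s) {
    p <- s$node_rows
    if (length(p) < min_fd_nodes) return(NA_real_)
    pl <- cumsum(steps[p[-1]])
    chord <- sqrt(colSums((t(xyz[p[-1], , drop = FALSE]) - xyz[p[1], ])^2))
    ok <- chord > 0 & pl > 0
    if (sum(ok) < 2L) return(NA_real_)
    lc <- log(chord[ok]); ll <- log(pl[ok])
    if (stats::var(lc) == 0) return(NA_real_)
    stats::cov(lc, ll) / stats::var(lc)
  }, numeric(1))
  mean_fd <- if (any(!is.na(fd))) mean(fd, na.rm = TRUE) else NaN
  list(max_path_distance = max_pd,
       mean_contraction = mean_contr,
       mean_fractal_dimension = mean_fd,
       total_length = total)
}

# arc length of the path from the tree root to the restricted forest root
.stem_length <- function(tree, rs) {
  steps <- .step_lengths(tree)
  v <- rs$root
  len <- 0
  while (!is.na(rs$parent[v])) {
    len <- len + steps[v]
    v <- rs$parent[v]
  }
  len
}

.cumdist_from_root <- function(tree, steps = .step_lengths(tree)) {
  pr <- .parent_rows(tree)
  n <- nrow(tree$nodes)
  ch <- .children_rows(tree)
  cum <- numeric(n)
  root <- which(is.na(pr))
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (k in ch[[v]]) {
      cum[k] <- cum[v] + steps[k]
      stack <- c(stack, k)
    }
  }
  cum
}

#' Branch-angle metrics of a (restricted) arbor
#'
#' At each branch point three amplitude-style angles are measured between
#' the vectors from the branch point into its daughter segments, averaged
#' over all unordered daughter pairs at the node and then over branch points:
#' the branch angle and the remote angle both use the daughter segments'
#' endpoints (their next critical node) — they coincide under this package's
#' resolution of the branch-angle definition, see the methods vignette — and
#' the local angle uses the node `local_offset` raw trace nodes into each
#' daughter (clamped to the segment end for shorter daughters). All angles
#' are in degrees in [0, 180].
#'
#' @inheritParams resegment
#' @param local_offset Node-count offset for the local angle (default 10,
#'   counted on raw trace nodes without resampling).
#' @return List with `mean_branch_angle`, `mean_local_angle`,
#'   `mean_remote_angle` (degrees; `NaN` when the arbor has no branch point).
#' @export
angle_metrics <- function(tree, restriction = "all", local_offset = 10L) {
  rs <- .restrict(tree, restriction)
  segs <- resegment(tree, restriction)
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  starts <- vapply(segs, function(s) s$node_rows[1], integer(1))
  by_start <- split(seq_along(segs), starts)
  branch_at <- names(by_start)[vapply(by_start, length, integer(1)) >= 2L]
  if (length(branch_at) == 0L) {
    return(list(mean_branch_angle = NaN, mean_local_angle = NaN,
                mean_remote_angle = NaN))
  }
  ang <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
  }
  node_means <- function(point_of) {
    vapply(branch_at, function(bkey) {
      idx <- by_start[[bkey]]
      b <- as.integer(bkey)
      vecs <- lapply(idx, function(i) point_of(segs[[i]]) - xyz[b, ])
      prs <- utils::combn(length(vecs), 2)
      vals <- apply(prs, 2, function(p) ang(vecs[[p[1]]], vecs[[p[2]]]))
      if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_
    }, numeric(1))
  }
  endpoint_of <- function(s) xyz[s$node_rows[length(s$node_rows)], ]
  local_of <- function(s) {
    p <- s$node_rows
    xyz[p[min(1L + local_offset, length(p))], ]
  }
  remote <- node_means(endpoint_of)
  local <- node_means(local_of)
  safe_mean <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NaN
  list(mean_branch_angle = safe_mean(remote),
       mean_local_angle = safe_mean(local),
       mean_remote_angle = safe_mean(remote))
}

#' Names of the 13 feature columns
#'
#' @return Character vector of the 13 feature-vector column names, in order.
#' @export
feature_columns <- function() {
  c("n_branch_points", "max_branch_order", "strahler",
    "mean_partition_asymmetry", "max_path_distance", "mean_contraction",
    "mean_branch_angle", "mean_local_angle", "mean_remote_angle",
    "mean_fractal_dimension", "total_length", "soma_area", "ap_position")
}

#' Assemble the 13-parameter feature vector for one neuron
#'
#' Combines the 11 tree metrics (computed on the given restriction, by
#' default the fin-innervating arbor including the length of the processes
#' leading up to the fin) with the two soma parameters carried in the
#' metadata (soma area, um^2, and signed anteroposterior soma position, um).
#' An unbranched arbor yields 0 branch points, Strahler 1 and NaN sentinels
#' for the asymmetry and angle means.
#'
#' @param tree A [neuron_tree()].
#' @param meta One row of [neuron_metadata()] for this neuron.
#' @param restriction Label restriction, default [fin_labels()].
#' @param local_offset Offset for the local angle, see [angle_metrics()].
#' @return One-row data frame: `neuron_id` plus the 13 [feature_columns()].
#' @export
feature_vector <- function(tree, meta, restriction = fin_labels(),
                           local_offset = 10L) {
  if (is.null(meta) || nrow(meta) != 1L) {
    stop("missing metadata row for neuron")
  }
  topo <- topology_metrics(tree, restriction)
  geom <- geometry_metrics(tree, restriction, include_stem = !identical(restriction, "all"))
  angs <- angle_metrics(tree, restriction, local_offset = local_offset)
  out <- data.frame(
    neuron_id = meta$neuron_id,
    n_branch_points = topo$n_branch_points,
    max_branch_order = topo$max_branch_order,
    strahler = topo$strahler,
    mean_partition_asymmetry = topo$mean_partition_asymmetry,
    max_path_distance = geom$max_path_distance,
    mean_contraction = geom$mean_contraction,
    mean_branch_angle = angs$mean_branch_angle,
    mean_local_angle = angs$mean_local_angle,
    mean_remote_angle = angs$mean_remote_angle,
    mean_fractal_dimension = geom$mean_fractal_dimension,
    total_length = geom$total_length,
    soma_area = meta$soma_area_um2,
    ap_position = meta$ap_position_um,
    stringsAsFactors = FALSE
  )
  out
}
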
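# Reading, validating and writing traced neuron reconstructions (SWC) plus
# the sidecar tables (surface annotations, per-neuron metadata, fin landmarks)
# that the rest of the pipeline consumes.

#' Surface annotation labels
#'
#' The allowed per-node surface labels: `axial` (body-wall skin),
#' `fin_medial` / `fin_lateral` (the two surfaces of the pectoral fin) and
#' `unlabeled`.
#'
#' @return Character vector of the four allowed labels.
#' @export
surface_labels <- function() c("axial", "fin_medial", "fin_lateral", "unlabeled")

#' Labels denoting fin innervation
#'
#' @return Character vector `c("fin_medial", "fin_lateral")`.
#' @export
fin_labels <- function() c("fin_medial", "fin_lateral")

#' Construct a neuron tree
#'
#' A `neuron_tree` is a rooted tree of traced nodes in microns. Exactly one
#' node (the soma, by convention) has `parent_id = -1`; every other node's
#' parent must exist, the structure must be acyclic and connected, and all
#' coordinates finite. Node order in `nodes` is preserved as given.
#'
#' @param nodes Data frame with columns `node_id`, `structure`, `x`, `y`, `z`,
#'   `radius`, `parent_id`. Coordinates are interpreted as microns. `radius`
#'   may be `NA` (it is unused by all metrics).
#' @param annotations Optional character vector of surface labels, one per
#'   node row (see [surface_labels()]); defaults to all `"unlabeled"`.
#' @return An object of class `neuron_tree`: a list with elements `nodes`
#'   (the validated data frame), `root_id`, and `annotations`.
#' @export
neuron_tree <- function(nodes, annotations = NULL) {
  required <- c("node_id", "structure", "x", "y", "z", "radius", "parent_id")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("`nodes` must be a data frame with columns: ",
         paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  n <- nrow(nodes)
  if (n == 0L) stop("empty input: tree has zero nodes")
  if (anyDuplicated(nodes$node_id)) {
    stop("format error: duplicate node_id in tree (",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "), ")")
  }
  if (!all(is.finite(nodes$x) & is.finite(nodes$y) & is.finite(nodes$z))) {
    stop("non-finite coordinates in tree")
  }
  roots <- which(nodes$parent_id == -1L)
  if (length(roots) != 1L) {
    stop("structure error: tree must have exactly one root (parent_id = -1), found ",
         length(roots))
  }
  parent_row <- match(nodes$parent_id, nodes$node_id)
  bad <- which(is.na(parent_row) & nodes$parent_id != -1L)
  if (length(bad)) {
    stop("structure error: unresolvable parent_id ",
         paste(unique(nodes$parent_id[bad]), collapse = ", "))
  }
  # cycle / connectivity: every node must reach the root along parent links
  state <- integer(n)  # 0 unvisited, 1 on current walk, 2 confirmed
  state[roots] <- 2L
  for (i in seq_len(n)) {
    if (state[i] == 2L) next
    walk <- integer(0)
    j <- i
    while (state[j] == 0L) {
      state[j] <- 1L
      walk <- c(walk, j)
      j <- parent_row[j]
    }
    if (state[j] == 1L) {
      stop("structure error: cycle detected involving node_id ", nodes$node_id[j])
    }
    state[walk] <- 2L
  }
  if (is.null(annotations)) annotations <- rep("unlabeled", n)
  annotations <- as.character(annotations)
  if (length(annotations) != n) stop("annotations must have one label per node")
  if (!all(annotations %in% surface_labels())) {
    stop("validation error: unknown annotation label(s): ",
         paste(setdiff(unique(annotations), surface_labels()), collapse = ", "))
  }
  structure(
    list(nodes = nodes, root_id = nodes$node_id[roots], annotations = annotations),
    class = "neuron_tree"
  )
}

#' @export
print.neuron_tree <- function(x, ...) {
  lab <- table(factor(x$annotations, levels = surface_labels()))
  cat("<neuron_tree> ", nrow(x$nodes), " nodes, root ", x$root_id, "\n", sep = "")
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read an SWC reconstruction
#'
#' Parses a standard whitespace-delimited 7-column SWC file
#' (`id type x y z radius parent`; `#` comments allowed) and validates it.
#' Coordinates are taken as microns, no unit conversion is applied.
#'
#' @param path Path to an SWC file.
#' @return A [neuron_tree()] with all nodes `"unlabeled"`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty input: no data lines in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  ncols <- lengths(fields)
  if (any(ncols != 7L)) {
    stop("format error: line(s) without 7 columns in ", path,
         " (first offending line ", which(ncols != 7L)[1], ")")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("format error: non-numeric field in ", path)
  nodes <- data.frame(
    node_id   = as.integer(m[, 1]),
    structure = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5],
    radius    = m[, 6],
    parent_id = as.integer(m[, 7])
  )
  neuron_tree(nodes)
}

#' Write an SWC reconstruction
#'
#' Writes a standard 7-column SWC file. Missing radii are written as 1.0
#' (documented default; radii are unused by all metrics). Coordinates are
#' written with 6 decimal places, so `read_swc(write_swc(tree))` reproduces
#' topology exactly and coordinates to 1e-6 um, and a second write is
#' byte-identical to the first.
#'
#' @param tree A [neuron_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes
  r <- ifelse(is.na(nd$radius), 1.0, nd$radius)
  lines <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                   nd$node_id, nd$structure, nd$x, nd$y, nd$z, r, nd$parent_id)
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stop("I/O error: cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c("# SWC written by finmorph", lines), con)
  invisible(path)
}

#' Attach surface annotations from a sidecar table
#'
#' Reads a two-column TSV (`node_id`, `label`) and attaches the labels to the
#' tree. Nodes not listed stay `"unlabeled"`. Labels must be drawn from
#' [surface_labels()]; node ids must exist in the tree.
#'
#' @param path Path to a TSV file with a header line `node_id<TAB>label`.
#' @param tree A [neuron_tree()].
#' @return The tree with annotations attached.
#' @export
read_annotations <- function(path, tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character"),
                           col.names = c("node_id", "label"))
  set_annotations(tree, tab$node_id, tab$label)
}

#' Set surface annotations on a tree
#'
#' @param tree A [neuron_tree()].
#' @param node_ids Integer node ids to label.
#' @param labels Character labels from [surface_labels()], recycled if length 1.
#' @return The tree with annotations updated (unlisted nodes keep their label).
#' @export
set_annotations <- function(tree, node_ids, labels) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (length(labels) == 1L) labels <- rep(labels, length(node_ids))
  if (!all(labels %in% surface_labels())) {
    stop("validation error: unknown annotation label(s): ",
         paste(setdiff(unique(labels), surface_labels()), collapse = ", "))
  }
  rows <- match(node_ids, tree$nodes$node_id)
  if (anyNA(rows)) {
    stop("validation error: annotation refers to node_id not in tree: ",
         paste(node_ids[is.na(rows)], collapse = ", "))
  }
  tree$annotations[rows] <- labels
  tree
}

#' Write surface annotations to a sidecar TSV
#'
#' Only non-`unlabeled` nodes are written.
#'
#' @param tree A [neuron_tree()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  keep <- tree$annotations != "unlabeled"
  tab <- data.frame(node_id = tree$nodes$node_id[keep],
                    label = tree$annotations[keep])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-neuron metadata
#'
#' Constructs/validates the scalar metadata attached to each neuron: soma
#' area (um^2, from a single-micron z-slice of the original stack) and the
#' anteroposterior soma position (um, signed relative to the myomere 3/4
#' boundary; negative values indicate a hindbrain location, positive spinal
#' cord), plus an optional population label (`HB` hindbrain / `RB`
#' Rohon-Beard).
#'
#' @param neuron_id Character id.
#' @param soma_area Soma area in um^2, must be > 0.
#' @param ap_position Signed anteroposterior position in um.
#' @param population Optional `"HB"` or `"RB"` (or `NA`).
#' @return One-row data frame of class `neuron_metadata`.
#' @export
neuron_metadata <- function(neuron_id, soma_area, ap_position, population = NA_character_) {
  if (!is.finite(soma_area) || soma_area <= 0) {
    stop("soma_area must be a positive finite number for neuron ", neuron_id)
  }
  if (!is.finite(ap_position)) stop("ap_position must be finite for neuron ", neuron_id)
  if (!is.na(population) && !population %in% c("HB", "RB")) {
    stop("population must be HB, RB or NA")
  }
  out <- data.frame(neuron_id = as.character(neuron_id),
                    soma_area_um2 = soma_area,
                    ap_position_um = ap_position,
                    population = population,
                    stringsAsFactors = FALSE)
  class(out) <- c("neuron_metadata", class(out))
  out
}

#' Read per-neuron metadata CSV
#'
#' Expects columns `neuron_id`, `soma_area_um2`, `ap_position_um` and
#' optionally `population`.
#'
#' @param path CSV path.
#' @return Data frame with one validated row per neuron.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "soma_area_um2", "ap_position_um")
  if (!all(need %in% names(tab))) {
    stop("metadata CSV must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$population)) tab$population <- NA_character_
  rows <- lapply(seq_len(nrow(tab)), function(i)
    neuron_metadata(tab$neuron_id[i], tab$soma_area_um2[i],
                    tab$ap_position_um[i], tab$population[i]))
  do.call(rbind, rows)
}

#' Fin landmark labels
#'
#' The 18 labels of the fin edge landmark set: 9 on the fin-body (FB) outer
#' edge as demarked by the blood vessel and 9 on the fin-membrane (FM) edge.
#' Per ring: two base points (one on either side of the fin base), one apex
#' (maximum distance from the base) and three flank points per side.
#'
#' @return Character vector of 18 labels in ring order (base_1, flank_1..3,
#'   apex, flank_4..6, base_2; FB ring then FM ring).
#' @export
landmark_labels <- function() {
  ring <- function(p) paste0(p, c("_base_1", paste0("_flank_", 1:3), "_apex",
                                  paste0("_flank_", 4:6), "_base_2"))
  c(ring("fb"), ring("fm"))
}

#' Construct a fin landmark set
#'
#' @param points 18 x 3 numeric matrix of 3D coordinates (um) with rownames
#'   equal to [landmark_labels()] (any order; stored in ring order).
#' @return Object of class `fin_landmarks` (matrix with ordered rownames).
#' @export
fin_landmarks <- function(points) {
  points <- as.matrix(points)
  labs <- landmark_labels()
  if (nrow(points) != 18L || is.null(rownames(points)) ||
      !setequal(rownames(points), labs)) {
    stop("landmark set must contain exactly the 18 labels returned by landmark_labels()")
  }
  points <- points[labs, , drop = FALSE]
  if (!all(is.finite(points))) stop("non-finite landmark coordinates")
  if (anyDuplicated(points) > 0) stop("duplicate landmark coordinates")
  colnames(points) <- c("x_um", "y_um", "z_um")
  structure(points, class = c("fin_landmarks", "matrix"))
}

#' Read fin landmarks from CSV
#'
#' Expects columns `label`, `x_um`, `y_um`, `z_um` with 18 rows.
#'
#' @param path CSV path.
#' @return A [fin_landmarks()] object.
#' @export
read_landmarks <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tab))) {
    stop("landmark CSV must contain columns: ", paste(need, collapse = ", "))
  }
  m <- as.matrix(tab[, c("x_um", "y_um", "z_um")])
  rownames(m) <- tab$label
  fin_landmarks(m)
}

#' Write fin landmarks to CSV
#'
#' @param landmarks A [fin_landmarks()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "fin_landmarks"))
  tab <- data.frame(label = rownames(landmarks),
                    x_um = landmarks[, 1], y_um = landmarks[, 2],
                    z_um = landmarks[, 3])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# row index of each node's parent (NA for root)
.parent_rows <- function(tree) {
  pr <- match(tree$nodes$parent_id, tree$nodes$node_id)
  pr[tree$nodes$parent_id == -1L] <- NA_integer_
  pr
}

# list: children row indices per node row
.children_rows <- function(tree) {
  pr <- .parent_rows(tree)
  n <- nrow(tree$nodes)
  ch <- vector("list", n)
  idx <- which(!is.na(pr))
  sp <- split(idx, pr[idx])
  ch[as.integer(names(sp))] <- sp
  ch
}
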
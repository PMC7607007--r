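# Stage orchestration. Each stage reads and writes plain files (SWC,
# sidecar TSV, CSV, JSON, Newick) so partial re-runs are possible, and a
# full pipeline run under a fixed seed is byte-deterministic. The numbered
# scripts under analysis/ are thin drivers over these functions.

#' Compute the feature table for a directory of reconstructions
#'
#' Reads every `*.swc` in `swc_dir` (with its `<id>_annotations.tsv`
#' sidecar), assembles the 13-parameter feature vector per neuron, and flags
#' neurons as clusterable. A neuron that does not branch in the fin (no
#' fin-labeled branch point) is flagged `clusterable = FALSE` and is
#' excluded from clustering downstream, mirroring the study's exclusion of
#' the one non-branching cell. Unreadable inputs produce a per-file warning
#' and the run continues.
#'
#' @param swc_dir Directory of SWC files plus annotation sidecars.
#' @param metadata_csv Path to the metadata CSV (see [read_metadata()]).
#' @param out_csv Optional output CSV path.
#' @param restriction Label restriction for the tree metrics.
#' @param local_offset Local-angle node offset, see [angle_metrics()].
#' @return Data frame: `neuron_id`, the 13 [feature_columns()],
#'   `clusterable`.
#' @export
run_features <- function(swc_dir, metadata_csv, out_csv = NULL,
                         restriction = fin_labels(), local_offset = 10L) {
  files <- sort(list.files(swc_dir, pattern = "\\.swc$", full.names = TRUE))
  if (length(files) == 0L) stop("no SWC files found in ", swc_dir)
  meta <- read_metadata(metadata_csv)
  failed <- character(0)
  rows <- lapply(files, function(f) {
    id <- sub("\\.swc$", "", basename(f))
    tryCatch({
      tree <- read_swc(f)
      ann <- file.path(swc_dir, paste0(id, "_annotations.tsv"))
      if (file.exists(ann)) tree <- read_annotations(ann, tree)
      m <- meta[meta$neuron_id == id, , drop = FALSE]
      if (nrow(m) != 1L) stop("missing metadata for neuron ", id)
      fv <- feature_vector(tree, m, restriction, local_offset)
      fv$clusterable <- fv$n_branch_points > 0
      fv
    }, error = function(e) {
      failed <<- c(failed, paste0(id, ": ", conditionMessage(e)))
      NULL
    })
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(failed)) {
    warning("skipped ", length(failed), " neuron(s):\n  ",
            paste(failed, collapse = "\n  "))
  }
  if (length(rows) == 0L) stop("no neuron could be processed in ", swc_dir)
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Cluster the cohort and select k by silhouette
#'
#' Standardizes the 13 feature columns of the clusterable neurons, runs Ward
#' agglomerative clustering, selects k by mean silhouette width, and writes
#' (when `out_dir` is given) the labels CSV, the dendrogram as Newick and a
#' merge-table CSV, the silhouette-vs-k table, and the leave-one-feature-out
#' stability report.
#'
#' @param features Feature data frame from [run_features()] or a CSV path.
#' @param out_dir Optional output directory.
#' @param k_range Candidate k values, default `2:min(8, n - 1)`.
#' @param method Ward variant, see [ward_cluster()].
#' @return List with `assignment` (see [silhouette_select_k()]), `hclust`,
#'   `z` (standardized matrix), `labels` (data frame neuron_id, cluster) and
#'   `stability`.
#' @export
run_cluster <- function(features, out_dir = NULL, k_range = NULL,
                        method = "ward.D2") {
  if (is.character(features)) features <- utils::read.csv(features)
  keep <- if (!is.null(features$clusterable)) features$clusterable else TRUE
  feats <- features[keep, , drop = FALSE]
  if (nrow(feats) < 3L) stop("need at least 3 clusterable neurons")
  m <- as.matrix(feats[, feature_columns()])
  rownames(m) <- feats$neuron_id
  z <- standardize_features(m)
  hc <- ward_cluster(z, method)
  asg <- silhouette_select_k(z, hc, k_range)
  labels <- data.frame(neuron_id = feats$neuron_id, cluster = asg$labels)
  stability <- loo_feature_stability(z, asg$k, method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(labels, file.path(out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(asg$silhouette_by_k,
                     file.path(out_dir, "silhouette_by_k.csv"),
                     row.names = FALSE)
    utils::write.csv(stability, file.path(out_dir, "loo_stability.csv"),
                     row.names = FALSE)
    export_dendrogram(hc, file.path(out_dir, "dendrogram.nwk"),
                      file.path(out_dir, "dendrogram_merges.csv"))
  }
  list(assignment = asg, hclust = hc, z = z, labels = labels,
       stability = stability)
}

#' Quantify regional innervation for a directory of reconstructions
#'
#' Fits the fin plane from the landmark set, builds the quadrant partition,
#' and for every neuron computes the octant table, the under-fin axial
#' summary, and the model-fin adduction overlap (the model fin is the
#' cohort-mean footprint — here the cohort shares one landmark set —
#' registered to the fish's base frame). A conservation check (octant sum vs
#' the fin-restricted morphometry total) is executed per neuron and
#' reported.
#'
#' @param swc_dir Directory of SWC files plus annotation sidecars.
#' @param landmarks_csv Path to the landmark CSV (see [read_landmarks()]).
#' @param out_dir Optional output directory for `region_lengths.csv`,
#'   `axial_overlap.csv` and `conservation.csv`.
#' @return List with `regions` (the [build_regions()] partition),
#'   `octants` (long data frame over neurons), `overlap` (per-neuron axial
#'   summary) and `conservation` (per-neuron relative error).
#' @export
run_regions <- function(swc_dir, landmarks_csv, out_dir = NULL) {
  files <- sort(list.files(swc_dir, pattern = "\\.swc$", full.names = TRUE))
  if (length(files) == 0L) stop("no SWC files found in ", swc_dir)
  landmarks <- read_landmarks(landmarks_csv)
  plane <- fit_plane(landmarks)
  regions <- build_regions(landmarks, plane)
  model <- model_fin_from_cohort(list(landmarks))
  frame <- fin_base_frame(landmarks, plane)
  placed <- register_model_fin(model, frame$base_midpoint, frame$base_angle_deg)
  oct_rows <- list(); ov_rows <- list(); cons_rows <- list()
  for (f in files) {
    id <- sub("\\.swc$", "", basename(f))
    tree <- read_swc(f)
    ann <- file.path(swc_dir, paste0(id, "_annotations.tsv"))
    if (file.exists(ann)) tree <- read_annotations(ann, tree)
    ri <- assign_region_lengths(tree, regions)
    has_fin <- any(tree$annotations %in% fin_labels())
    fin_total <- if (has_fin) {
      geometry_metrics(tree, fin_labels(), include_stem = FALSE)$total_length
    } else 0
    oct_sum <- sum(ri$octants$length_um)
    rel_err <- if (fin_total > 0) abs(oct_sum - fin_total) / fin_total else 0
    ov <- if (any(tree$annotations == "axial")) {
      axial_overlap(tree, placed, plane)
    } else list(length_within = 0, percent_of_axial = 0)
    oct_rows[[id]] <- data.frame(neuron_id = id, ri$octants)
    ov_rows[[id]] <- data.frame(
      neuron_id = id,
      axial_um = ri$axial$length_um,
      under_fin_um = ri$axial$under_fin_um,
      axial_terminals = ri$axial$terminals,
      terminals_under_fin = ri$axial$terminals_under_fin,
      model_overlap_um = ov$length_within,
      model_overlap_percent = ov$percent_of_axial)
    cons_rows[[id]] <- data.frame(neuron_id = id, octant_sum_um = oct_sum,
                                  fin_total_um = fin_total,
                                  relative_error = rel_err)
  }
  octants <- do.call(rbind, oct_rows); rownames(octants) <- NULL
  overlap <- do.call(rbind, ov_rows); rownames(overlap) <- NULL
  conservation <- do.call(rbind, cons_rows); rownames(conservation) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(octants, file.path(out_dir, "region_lengths.csv"),
                     row.names = FALSE)
    utils::write.csv(overlap, file.path(out_dir, "axial_overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(conservation, file.path(out_dir, "conservation.csv"),
                     row.names = FALSE)
  }
  list(regions = regions, octants = octants, overlap = overlap,
       conservation = conservation)
}

#' Run the cohort-level statistical comparisons
#'
#' Computes (1) the Pearson correlation between medial-surface fin terminal
#' counts and terminal counts on the axial surface under the fin, (2) the
#' anteroposterior trend of total fin afferent length (regression ANOVA),
#' with and without the Rohon-Beard neurons, and (3) the axial-vs-fin total
#' length comparison (chi-square as printed, plus a paired Wilcoxon
#' alternative). Tests with insufficient n are skipped with a reason.
#'
#' @param octants Long octant table from [run_regions()] (or its CSV path).
#' @param overlap Overlap table from [run_regions()] (or its CSV path).
#' @param features Feature table from [run_features()] (or its CSV path).
#' @param metadata_csv Metadata CSV path (or a data frame).
#' @param out_json Optional JSON report path.
#' @return Nested list of test results.
#' @export
run_stats <- function(octants, overlap, features, metadata_csv,
                      out_json = NULL) {
  if (is.character(octants)) octants <- utils::read.csv(octants)
  if (is.character(overlap)) overlap <- utils::read.csv(overlap)
  if (is.character(features)) features <- utils::read.csv(features)
  meta <- if (is.character(metadata_csv)) read_metadata(metadata_csv) else metadata_csv
  med_term <- tapply(octants$terminals[octants$surface == "medial"],
                     octants$neuron_id[octants$surface == "medial"], sum)
  fin_len <- tapply(octants$length_um, octants$neuron_id, sum)
  ids <- names(med_term)
  ov <- overlap[match(ids, overlap$neuron_id), ]
  try_test <- function(expr) tryCatch(expr, error = function(e)
    list(skipped = TRUE, reason = conditionMessage(e)))
  pearson <- try_test(correlation_terminals(as.numeric(med_term),
                                            ov$terminals_under_fin))
  fids <- features$neuron_id
  mrow <- meta[match(fids, meta$neuron_id), ]
  trend_all <- try_test(trend_test(features$total_length,
                                   mrow$ap_position_um))
  trend_norb <- try_test(trend_test(features$total_length,
                                    mrow$ap_position_um,
                                    labels = mrow$population,
                                    exclude = "RB"))
  lcomp <- try_test(length_comparison(ov$axial_um,
                                      as.numeric(fin_len[ids])))
  res <- list(
    pearson_medial_vs_axial_under_fin = pearson,
    ap_trend_all = trend_all,
    ap_trend_without_rb = trend_norb,
    axial_vs_fin_length = lcomp
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(res, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, input-file hashes, per-stage
#' output paths and package version, so a run can be reproduced and outputs
#' can name the manifest that produced them.
#'
#' @param config The [generator_config()] (or any list) used.
#' @param input_files Character vector of input paths to hash.
#' @param outputs Named list of per-stage output paths.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, input_files, outputs, path) {
  manifest <- list(
    tool = "finmorph",
    version = as.character(utils::packageVersion("finmorph")),
    seed = config$seed,
    config = unclass(config),
    input_md5 = stats::setNames(as.list(unname(tools::md5sum(input_files))),
                                basename(input_files)),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML file path.
#' @return For `write_config`, `path` invisibly; for `read_config`, the
#'   reconstructed [generator_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(generator_config, yaml::read_yaml(path))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate -> features -> cluster -> regions -> stats, writing every stage
#' output under `out_dir` (`data/` for the simulated files, `results/` for
#' tables) plus a manifest. Deterministic: identical seed and config give
#' byte-identical outputs.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory.
#' @return Invisible list with each stage's in-memory result.
#' @export
run_pipeline <- function(config = generator_config(), out_dir) {
  data_dir <- file.path(out_dir, "data")
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  write_cohort(cohort, data_dir)
  write_config(config, file.path(out_dir, "config.yaml"))
  meta_csv <- file.path(data_dir, "metadata.csv")
  features <- run_features(data_dir, meta_csv,
                           out_csv = file.path(res_dir, "features.csv"))
  clu <- run_cluster(features, out_dir = res_dir)
  reg <- run_regions(data_dir, file.path(data_dir, "landmarks.csv"),
                     out_dir = res_dir)
  stats <- run_stats(reg$octants, reg$overlap, features, meta_csv,
                     out_json = file.path(res_dir, "statistics.json"))
  write_manifest(config,
                 input_files = sort(list.files(data_dir, full.names = TRUE)),
                 outputs = list(
                   features = "results/features.csv",
                   cluster_labels = "results/cluster_labels.csv",
                   dendrogram = "results/dendrogram.nwk",
                   region_lengths = "results/region_lengths.csv",
                   axial_overlap = "results/axial_overlap.csv",
                   conservation = "results/conservation.csv",
                   statistics = "results/statistics.json"),
                 path = file.path(out_dir, "manifest.json"))
  invisible(list(cohort = cohort, features = features, cluster = clu,
                 regions = reg, stats = stats))
}
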
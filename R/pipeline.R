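#' Pipeline run configuration
#'
#' All tunable parameters of the pocket-detection pipeline with their
#' defaults: 1 Angstrom grid spacing; 6 Angstrom solid-angle sphere; the
#' highest 20 percent of surface voxels as candidates; 20 Angstrom cluster
#' linkage distance with a `0.1 * 4pi` steradian solid-angle band; 10
#' Angstrom cavity-volume probe requiring 4 of 7 interior directions;
#' equal depth/volume weights; 4.5 Angstrom residue contact distance.
#'
#' @param spacing Grid spacing, Angstrom.
#' @param sa_radius Solid-angle virtual sphere radius, Angstrom.
#' @param surface_weight Boundary-layer weight of the solid-angle
#'   estimator (see [solid_angle_at()]).
#' @param candidate_fraction Fraction of surface voxels kept as concave
#'   candidates.
#' @param cluster_distance Single-linkage distance threshold, Angstrom.
#' @param sa_band Solid-angle similarity band for linkage, steradians.
#' @param volume_radius Cavity-volume probe sphere radius, Angstrom.
#' @param interior_direction_min Minimum interior directions (of 7) for a
#'   cavity-volume voxel.
#' @param w1,w2 Ranking weights for depth and volume (must sum to 1).
#' @param chains Optional chain selection.
#' @param match_distance Evaluation contact distance, Angstrom.
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   consumes no randomness).
#' @return Object of class `run_config`.
#' @export
run_config <- function(spacing = 1.0, sa_radius = 6, surface_weight = 0.5,
                       candidate_fraction = 0.20, cluster_distance = 20,
                       sa_band = 0.1 * 4 * pi, volume_radius = 10,
                       interior_direction_min = 4L, w1 = 0.5, w2 = 0.5,
                       chains = NULL, match_distance = 4.5, seed = 1L) {
  weights <- pocket_weights(w1, w2)
  stopifnot(spacing > 0, sa_radius > spacing, candidate_fraction > 0,
            candidate_fraction <= 1, cluster_distance > 0, sa_band >= 0,
            volume_radius >= 0, interior_direction_min >= 0,
            match_distance > 0)
  structure(list(spacing = spacing, sa_radius = sa_radius,
                 surface_weight = surface_weight,
                 candidate_fraction = candidate_fraction,
                 cluster_distance = cluster_distance, sa_band = sa_band,
                 volume_radius = volume_radius,
                 interior_direction_min = as.integer(interior_direction_min),
                 weights = weights, chains = chains,
                 match_distance = match_distance, seed = as.integer(seed)),
            class = "run_config")
}

#' Predict ranked binding regions for one structure
#'
#' Runs the full pipeline: parse -> voxelize -> solid angles -> candidate
#' selection -> clustering -> depth and volume features -> ranking.  When
#' no concave cavity is found (all cluster depths non-positive or all
#' volumes zero) the run completes cleanly with an empty region list and
#' `status = "no_rankable_region"`.
#'
#' @param pdb Path to a PDB file, a `pdb_structure`, or a `shape_fixture`.
#' @param config A [run_config()].
#' @return Object of class `pocket_prediction`: list with `structure`,
#'   `grid`, `sa_map`, `clusters`, `features`, `regions` (ranked), `table`
#'   (see [region_report()]), `status`, `config`, and `manifest`.
#' @export
pocket_predict <- function(pdb, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  checksum <- NA_character_
  if (inherits(pdb, "shape_fixture")) pdb <- pdb$structure
  if (is.character(pdb)) {
    checksum <- unname(tools::md5sum(pdb))
    pdb <- parse_pdb(pdb, chains = config$chains)
  } else if (!is.null(config$chains)) {
    pdb <- select_chains(pdb, config$chains)
  }
  stopifnot(inherits(pdb, "pdb_structure"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "voxpocket_no_region")) stop(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  padding <- max(10, config$sa_radius, config$volume_radius)
  grid <- stage("voxelization",
                build_grid(pdb, spacing = config$spacing,
                           padding = padding))
  sa_map <- stage("solid_angle",
                  solid_angle_all(grid, radius = config$sa_radius,
                                  surface_weight = config$surface_weight))
  cands <- stage("clustering",
                 select_candidates(sa_map, config$candidate_fraction))
  clusters <- stage("clustering",
                    cluster_voxels(cands,
                                   distance_threshold =
                                     config$cluster_distance,
                                   sa_band = config$sa_band))
  features <- stage("features", lapply(clusters, function(cl) {
    list(cluster = cl, depth = average_depth(cl),
         volume = cavity_volume(grid, cl$anchor,
                                probe_radius = config$volume_radius,
                                min_directions =
                                  config$interior_direction_min))
  }))
  status <- "ok"
  regions <- list()
  if (length(features) > 0L) {
    regions <- tryCatch(
      rank_regions(features, config$weights),
      voxpocket_no_region = function(e) {
        status <<- "no_rankable_region"
        list()
      })
  } else {
    status <- "no_rankable_region"
  }
  manifest <- list(
    package = "voxpocket",
    version = as.character(utils::packageVersion("voxpocket")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input = pdb$source_id, input_md5 = checksum,
    n_atoms = nrow(pdb$atoms), n_occupied_voxels = sum(grid$label > 0),
    n_surface_voxels = nrow(sa_map),
    config = config[setdiff(names(config), "weights")],
    w1 = config$weights$w1, w2 = config$weights$w2
  )
  structure(list(structure = pdb, grid = grid, sa_map = sa_map,
                 clusters = clusters, features = features,
                 regions = regions,
                 table = region_report(regions, pdb,
                                       config$match_distance),
                 status = status, config = config, manifest = manifest),
            class = "pocket_prediction")
}

#' Write predictions as TSV plus a JSON run manifest
#'
#' @param prediction A [pocket_predict()] result.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.manifest.json`.
#' @return Invisibly, the two file paths.
#' @export
write_predictions <- function(prediction, prefix) {
  stopifnot(inherits(prediction, "pocket_prediction"))
  tsv <- paste0(prefix, ".tsv")
  man <- paste0(prefix, ".manifest.json")
  utils::write.table(prediction$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(prediction$manifest,
                         list(status = prediction$status)),
                       man, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(tsv = tsv, manifest = man))
}

#' Evaluate a prediction against a truth table
#'
#' @param prediction A [pocket_predict()] result.
#' @param truth Data frame with columns `chain`, `resseq`, or a path to a
#'   [read_truth()] file, or `"ligand"` to derive the truth from the
#'   structure's own HETATM records.
#' @param k Integer vector of top-k cutoffs to evaluate (default 1:3).
#' @param path Optional JSON report output path.
#' @return Object of class `pocket_evaluation`: list with one entry per k
#'   (each holding `success`, `counts`, `metrics`, `matched_ranks`) plus
#'   `input`.
#' @export
pocket_evaluate <- function(prediction, truth, k = 1:3, path = NULL) {
  stopifnot(inherits(prediction, "pocket_prediction"))
  if (is.character(truth) && length(truth) == 1L) {
    truth <- if (identical(truth, "ligand")) {
      ligand_binding_residues(prediction$structure,
                              cutoff = prediction$config$match_distance)
    } else {
      read_truth(truth)
    }
  }
  per_k <- lapply(k, function(kk) {
    m <- match_regions(prediction$regions, truth, prediction$structure,
                       k = kk,
                       match_distance = prediction$config$match_distance)
    list(k = kk, success = m$success, matched_ranks = m$matched_ranks,
         counts = unclass(m$counts),
         metrics = {
           mt <- compute_metrics(m$counts)
           list(sensitivity = mt$sensitivity,
                specificity = mt$specificity, accuracy = mt$accuracy,
                ppv = mt$ppv, mcc = mt$mcc, flagged = mt$flagged)
         })
  })
  names(per_k) <- paste0("top", k)
  out <- structure(list(input = prediction$manifest$input,
                        n_truth_residues =
                          length(unique(paste(truth$chain, truth$resseq))),
                        results = per_k),
                   class = "pocket_evaluation")
  if (!is.null(path)) {
    jsonlite::write_json(unclass(out), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  out
}

#' Aggregate several evaluation reports
#'
#' @param paths Character vector of JSON files written by
#'   [pocket_evaluate()].
#' @return Data frame with one row per (input, k): success flag and the
#'   five metrics.
#' @export
summarize_evaluations <- function(paths) {
  rows <- list()
  for (p in paths) {
    rep <- jsonlite::read_json(p, simplifyVector = TRUE)
    for (nm in names(rep$results)) {
      r <- rep$results[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        input = rep$input, k = r$k, success = r$success,
        sensitivity = r$metrics$sensitivity,
        specificity = r$metrics$specificity,
        accuracy = r$metrics$accuracy, ppv = r$metrics$ppv,
        mcc = r$metrics$mcc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.pocket_prediction <- function(x, ...) {
  cat("<pocket_prediction> ", x$manifest$input, " [", x$status, "]\n",
      "  ", x$manifest$n_atoms, " atoms | ",
      x$manifest$n_occupied_voxels, " occupied voxels | ",
      x$manifest$n_surface_voxels, " surface voxels | ",
      length(x$regions), " ranked region(s)\n", sep = "")
  if (nrow(x$table)) {
    print(head(x$table[, c("rank", "rv", "size", "anchor_x", "anchor_y",
                           "anchor_z", "avg_depth", "volume_voxels")],
               5))
  }
  invisible(x)
}
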
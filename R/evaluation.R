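#' Confusion-matrix counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 tn = as.numeric(tn), fn = as.numeric(fn)),
            class = "confusion_counts")
}

#' Binding-site prediction metrics from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, positive predictive value `TP/(TP+FP)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator is zero is reported as 0 and named in the
#' `flagged` attribute.
#'
#' @param counts A [confusion_counts()].
#' @return Object of class `pocket_metrics`: list with `sensitivity`,
#'   `specificity`, `accuracy`, `ppv`, `mcc`, `counts`, and `flagged`
#'   (character vector of zero-denominator metrics).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  flagged <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flagged <<- c(flagged, name)
      0
    } else num / den
  }
  m <- list(
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    accuracy    = (tp + tn) / total,
    ppv         = safe(tp, tp + fp, "ppv"),
    mcc         = safe(tp * tn - fp * fn,
                       sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
                       "mcc"),
    counts = counts, flagged = flagged
  )
  structure(m, class = "pocket_metrics")
}

#' Binding residues derived from bound ligands
#'
#' Annotates as binding residues all protein residues with an atom within
#' `cutoff` of any `HETATM` atom (solvent excluded), the conventional
#' ligand-contact definition of a binding site.
#'
#' @param structure A `pdb_structure` whose `het` slot holds the ligand.
#' @param cutoff Contact distance in Angstrom (default 4.5).
#' @param exclude Hetero residue names ignored as ligands.
#' @return Data frame with columns `chain`, `resseq` (one row per binding
#'   residue), usable as the `truth` argument of [match_regions()].
#' @export
ligand_binding_residues <- function(structure, cutoff = 4.5,
                                    exclude = c("HOH", "WAT", "DOD")) {
  stopifnot(inherits(structure, "pdb_structure"))
  lig <- structure$het[!structure$het$resname %in% exclude, , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand HETATM records in structure")
  res <- residues_near(structure, as.matrix(lig[, c("x", "y", "z")]),
                       cutoff)
  res[, c("chain", "resseq"), drop = FALSE]
}

#' Read / write a two-column binding-site truth table
#'
#' Plain whitespace-separated text with a header line `chain resseq`.
#'
#' @param path File path.
#' @return Data frame with columns `chain`, `resseq`.
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer"))
  stopifnot(all(c("chain", "resseq") %in% names(df)))
  df[, c("chain", "resseq"), drop = FALSE]
}

#' @rdname read_truth
#' @param truth Data frame with columns `chain`, `resseq`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth[, c("chain", "resseq")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Match ranked regions against annotated binding residues
#'
#' A predicted region matches the truth iff any of its member voxel
#' centres lies within `match_distance` of any atom of an annotated
#' binding residue.  The prediction is a success when any of the top-`k`
#' regions matches.  Residue-level confusion counts are then accumulated
#' over all residues of the structure: a residue is predicted positive iff
#' it has an atom within `match_distance` of a matching top-`k` region's
#' member voxels.
#'
#' @param regions List of `ranked_region` (from [rank_regions()]); may be
#'   empty (no prediction: failure, all truth residues become FN).
#' @param truth Data frame with columns `chain`, `resseq` (non-empty).
#' @param structure The `pdb_structure` the predictions refer to.
#' @param k Number of top regions considered (default 3).
#' @param match_distance Contact distance in Angstrom (default 4.5).
#' @return Object of class `match_result`: list with `success`,
#'   `matched_ranks`, `counts` (a [confusion_counts()]), `k`,
#'   `match_distance`.
#' @export
match_regions <- function(regions, truth, structure, k = 3,
                          match_distance = 4.5) {
  stopifnot(inherits(structure, "pdb_structure"), k >= 1)
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("empty truth annotation")
  }
  atoms <- structure$atoms
  res_key <- paste(atoms$chain, atoms$resseq)
  all_res <- unique(res_key)
  truth_key <- unique(paste(truth$chain, truth$resseq))
  top <- top_k(regions, k)
  truth_pos <- as.matrix(atoms[res_key %in% truth_key,
                               c("x", "y", "z"), drop = FALSE])
  matched <- integer(0)
  pred_key <- character(0)
  for (rg in top) {
    mem <- as.matrix(rg$cluster$members[, c("x", "y", "z")])
    near <- residues_near(structure, mem, match_distance)
    is_match <- min_dist2(mem, truth_pos) <= match_distance^2
    if (is_match) {
      matched <- c(matched, rg$rank)
      pred_key <- union(pred_key, paste(near$chain, near$resseq))
    }
  }
  tp <- sum(truth_key %in% pred_key)
  fp <- sum(!pred_key %in% truth_key)
  fn <- sum(!truth_key %in% pred_key)
  tn <- length(all_res) - tp - fp - fn
  structure(list(success = length(matched) > 0L, matched_ranks = matched,
                 counts = confusion_counts(tp, fp, tn, fn),
                 k = k, match_distance = match_distance),
            class = "match_result")
}

# squared minimum distance between two point sets (n x 3, m x 3)
min_dist2 <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  best <- Inf
  for (m in seq_len(nrow(b))) {
    d2 <- (a[, 1] - b[m, 1])^2 + (a[, 2] - b[m, 2])^2 +
      (a[, 3] - b[m, 3])^2
    best <- min(best, min(d2))
  }
  best
}

#' @export
print.pocket_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.4f | specificity %.4f | accuracy %.4f | PPV %.4f | MCC %.4f\n",
    x$sensitivity, x$specificity, x$accuracy, x$ppv, x$mcc))
  if (length(x$flagged)) {
    cat("  zero-denominator (reported as 0):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
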
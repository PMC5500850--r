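# Turns normalized expression (log2 intensities) into one differential
# profile per treatment instance: corpus-level control-variance filtering,
# robust per-batch control references, log2 ratios, and
# strongest-instance selection per compound/system pair.

#' Retain low-variance genes by control variance
#'
#' Genes with the highest variance across control samples carry mostly
#' technical noise; the top `fraction` are removed corpus-wide.
#'
#' @param controls Expression matrix (genes x control samples), >= 2 columns.
#' @param fraction Proportion of genes to remove, in `[0, 1)`. Default 0.05.
#' @return Character vector of retained gene ids, in input order.
#' @export
drop_high_variance_genes <- function(controls, fraction = 0.05) {
  stopifnot(is.matrix(controls), fraction >= 0, fraction < 1)
  if (ncol(controls) < 2L)
    stop("variance filter needs >= 2 control samples")
  n <- nrow(controls)
  keep_n <- as.integer(ceiling((1 - fraction) * n))
  v <- apply(controls, 1L, var)
  # deterministic: sort by variance descending, gene id ascending at ties
  ord <- order(-v, rownames(controls))
  drop <- rownames(controls)[ord][seq_len(n - keep_n)]
  kept <- setdiff(rownames(controls), drop)
  ptgs_log("variance filter: dropped ", n - keep_n, "/", n, " genes")
  kept
}

#' Robust control reference for one batch
#'
#' With three or more control arrays, the one with the largest summed
#' Euclidean distance to the others is dropped as an outlier and the
#' remainder averaged; with exactly two, both are averaged.
#'
#' @param controls Expression matrix (genes x control samples), >= 2 columns.
#' @return Numeric vector: the reference profile.
#' @export
robust_control_reference <- function(controls) {
  stopifnot(is.matrix(controls))
  nc <- ncol(controls)
  if (nc < 2L) stop("control reference needs >= 2 control samples")
  if (nc == 2L) return(rowMeans(controls))
  d <- as.matrix(dist(t(controls)))
  sums <- rowSums(d)
  # drop the max-summed-distance control; break ties by sample id
  worst <- colnames(controls)[order(-sums, colnames(controls))][1]
  if (is.null(worst)) worst <- which.max(sums)
  keep <- setdiff(seq_len(nc), match(worst, colnames(controls)))
  if (anyNA(keep)) keep <- setdiff(seq_len(nc), which.max(sums))
  rowMeans(controls[, keep, drop = FALSE])
}

#' Differential profiles as log2 ratios to a control reference
#'
#' Inputs are already log2 scale, so the ratio is a subtraction.
#'
#' @param treatments Expression matrix (genes x treatment samples).
#' @param reference Numeric reference profile over the same genes.
#' @return Matrix of log2 ratios, genes x treatments.
#' @export
log_ratio_profiles <- function(treatments, reference) {
  stopifnot(is.matrix(treatments))
  if (nrow(treatments) != length(reference))
    stop("gene mismatch between treatments and reference")
  if (!is.null(names(reference)) && !is.null(rownames(treatments)) &&
      !identical(rownames(treatments), names(reference)))
    stop("gene order mismatch between treatments and reference")
  treatments - reference
}

#' Keep the strongest instance per compound/system pair
#'
#' Among replicate profiles of the same compound in the same system, the
#' one with the largest Euclidean norm (strongest overall response) is
#' kept; exact norm ties break by lexicographically smallest instance id.
#'
#' @param profiles Matrix of differential profiles, genes x instances.
#' @param instances Data frame with `instance_id`, `compound_id`,
#'   `system_id` covering the profile columns.
#' @return Matrix restricted to the selected instances.
#' @export
select_strongest_instances <- function(profiles, instances) {
  if (ncol(profiles) == 0L) return(profiles)
  stopifnot(all(colnames(profiles) %in% instances$instance_id))
  inst <- instances[match(colnames(profiles), instances$instance_id), ]
  norms <- sqrt(colSums(profiles^2))
  key <- paste(inst$compound_id, inst$system_id, sep = "\r")
  ord <- order(key, -norms, colnames(profiles))
  keep <- !duplicated(key[ord])
  chosen <- colnames(profiles)[ord][keep]
  ptgs_log("strongest-instance selection: ", length(chosen), " of ",
           ncol(profiles), " instances kept")
  profiles[, sort(chosen), drop = FALSE]
}

#' Full preprocessing pipeline for one corpus
#'
#' Applies the corpus-level control-variance filter, builds per-batch
#' robust control references, forms log2-ratio profiles, and keeps the
#' strongest instance per compound/system pair.
#'
#' @param expr Expression matrix (genes x samples, log2 scale) covering
#'   controls and treatments.
#' @param instances Instance table (see [read_instance_table()]).
#' @param variance_fraction Fraction of high-variance genes to drop.
#' @return List with `profiles` (genes x selected instances log2 ratios)
#'   and `genes` (retained gene ids).
#' @export
preprocess_corpus <- function(expr, instances, variance_fraction = 0.05) {
  stopifnot(all(instances$instance_id %in% colnames(expr)))
  ctrl_ids <- instances$instance_id[instances$is_control]
  trt <- instances[!instances$is_control, , drop = FALSE]
  if (length(ctrl_ids) < 2L) stop("corpus needs >= 2 control samples")
  genes <- drop_high_variance_genes(expr[, ctrl_ids, drop = FALSE],
                                    variance_fraction)
  expr <- expr[genes, , drop = FALSE]
  profiles <- matrix(NA_real_, length(genes), nrow(trt),
                     dimnames = list(genes, trt$instance_id))
  for (b in unique(trt$batch_id)) {
    bc <- instances$instance_id[instances$is_control & instances$batch_id == b]
    if (length(bc) < 2L)
      stop("batch ", b, " has fewer than 2 controls")
    ref <- robust_control_reference(expr[, bc, drop = FALSE])
    ids <- trt$instance_id[trt$batch_id == b]
    profiles[, ids] <- log_ratio_profiles(expr[, ids, drop = FALSE], ref)
  }
  profiles <- select_strongest_instances(profiles, instances)
  list(profiles = profiles, genes = genes)
}
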
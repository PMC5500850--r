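# Preranked gene-set enrichment of differential profiles and the
# quantization of enrichment FDR q-values into the non-negative integer
# activation counts that form the topic-model corpus. Each gene set
# contributes two signed features (SET+ and SET-), one per direction of
# activation.

#' Preranked gene-set enrichment for one profile
#'
#' Computes the weighted Kolmogorov-Smirnov running-sum enrichment score
#' of each set on the profile ranked by log2 ratio, with a permutation
#' null of random same-size gene sets. FDR q-values are
#' Benjamini-Hochberg adjusted permutation p-values, computed separately
#' for positively and negatively enriched sets.
#'
#' @param profile Named numeric vector of log2 ratios for one instance.
#' @param sets Gene-set collection (named list of gene id vectors).
#' @param n_perm Number of permutations (>= 100).
#' @param weight_p Weighting exponent for the running sum (1 = classic
#'   weighted GSEA).
#' @param min_overlap Sets overlapping the profile by fewer genes are
#'   skipped.
#' @return Data frame with one row per retained set: `set_name`,
#'   `direction` (`up`/`down`), `es`, `p`, `fdr_q`.
#' @export
preranked_enrichment <- function(profile, sets, n_perm = 1000, weight_p = 1,
                                 min_overlap = 5) {
  stopifnot(is.numeric(profile), !is.null(names(profile)), n_perm >= 100)
  n <- length(profile)
  ord <- order(-profile, names(profile))
  ranked <- profile[ord]
  gene_pos <- setNames(seq_len(n), names(ranked))
  w_abs <- abs(ranked)^weight_p

  all_tied <- length(unique(profile)) == 1L

  hit_list <- lapply(sets, function(g) unname(gene_pos[g[g %in% names(gene_pos)]]))
  sizes <- lengths(hit_list)
  keep <- sizes >= min_overlap & sizes < n
  if (any(!keep))
    ptgs_log("enrichment: skipped ", sum(!keep), " set(s) below overlap ",
             min_overlap)
  hit_list <- hit_list[keep]
  if (length(hit_list) == 0L)
    return(data.frame(set_name = character(), direction = character(),
                      es = numeric(), p = numeric(), fdr_q = numeric(),
                      stringsAsFactors = FALSE))

  es <- vapply(hit_list, function(h) .gsea_es_cpp(w_abs, as.integer(h)),
               numeric(1))

  # permutation null, shared across sets of the same size
  p_perm <- numeric(length(es))
  for (k in unique(lengths(hit_list))) {
    null_es <- .gsea_null_es_cpp(w_abs, as.integer(k), as.integer(n_perm))
    idx <- which(lengths(hit_list) == k)
    # p relative to the same-sign side of the null (classic GSEA
    # convention), so p is uniform under the null within each direction
    for (i in idx) {
      if (es[i] >= 0) {
        p_perm[i] <- (sum(null_es >= es[i]) + 1) / (sum(null_es >= 0) + 1)
      } else {
        p_perm[i] <- (sum(null_es <= es[i]) + 1) / (sum(null_es <= 0) + 1)
      }
    }
  }

  direction <- ifelse(es >= 0, "up", "down")
  q <- numeric(length(es))
  for (d in c("up", "down")) {
    i <- direction == d
    if (any(i)) q[i] <- p.adjust(p_perm[i], method = "BH")
  }
  if (all_tied) q[] <- 1  # degenerate all-tied ranking: no evidence
  data.frame(set_name = names(hit_list), direction = direction,
             es = unname(es), p = unname(p_perm), fdr_q = unname(q),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantize an enrichment FDR q-value into an activation count
#'
#' `count = max(round(-log2(q)) - 1, 0)`, with round-half-to-even.
#' Exact zeros (beyond permutation resolution) are floored at
#' `1/(n_perm + 1)` before the transform so counts stay bounded.
#'
#' @param fdr_q Numeric vector of q-values in `[0, 1]`.
#' @param n_perm Permutation count used to floor exact zeros.
#' @return Integer vector of non-negative activation counts.
#' @export
quantize_activation <- function(fdr_q, n_perm = 1000) {
  if (any(fdr_q < 0 | fdr_q > 1, na.rm = TRUE) || anyNA(fdr_q))
    stop("fdr_q values must lie in [0, 1]")
  q <- fdr_q
  q[q == 0] <- 1 / (n_perm + 1)
  as.integer(pmax(round(-log2(q)) - 1, 0))
}

#' Build the activation-count matrix for a profile corpus
#'
#' Runs preranked enrichment on every profile and quantizes the
#' direction-specific q-values into the instances x signed-features
#' count matrix consumed by [fit_components()].
#'
#' @param profiles Matrix of log2-ratio profiles, genes x instances.
#' @param sets Gene-set collection.
#' @param n_perm Permutations per profile.
#' @param weight_p Running-sum weighting exponent.
#' @param min_overlap Minimum profile overlap per set.
#' @return Integer matrix, instances x (2 x number of sets); feature
#'   columns are named `SET+` and `SET-`.
#' @export
activation_counts <- function(profiles, sets, n_perm = 1000, weight_p = 1,
                              min_overlap = 5) {
  stopifnot(is.matrix(profiles))
  features <- as.vector(rbind(paste0(names(sets), "+"), paste0(names(sets), "-")))
  counts <- matrix(0L, ncol(profiles), length(features),
                   dimnames = list(colnames(profiles), features))
  for (j in seq_len(ncol(profiles))) {
    enr <- preranked_enrichment(profiles[, j], sets, n_perm = n_perm,
                                weight_p = weight_p, min_overlap = min_overlap)
    if (nrow(enr) == 0L) next
    cnt <- quantize_activation(enr$fdr_q, n_perm = n_perm)
    feat <- paste0(enr$set_name, ifelse(enr$direction == "up", "+", "-"))
    counts[j, feat] <- cnt
  }
  ptgs_log("activation counts: ", nrow(counts), " instances x ",
           ncol(counts), " features, ", sum(counts > 0), " non-zero")
  counts
}
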
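# Deriving the gene-level representation of the selected component
# space: per-component gene lists from the most active instances and
# gene sets, the Bonferroni core set, and the biological-complexity
# proportions.

#' Top-mass subset of a discrete distribution
#'
#' Items sorted by descending probability; the smallest prefix whose
#' cumulative mass reaches `cum` is returned. Ties at the boundary break
#' by item id.
#'
#' @param distribution Named numeric vector summing to 1 (tolerance 1e-6).
#' @param cum Cumulative-mass threshold (default 0.2).
#' @return Character vector of selected item ids.
#' @export
top_mass_subset <- function(distribution, cum = 0.2) {
  if (length(distribution) == 0L) stop("empty distribution")
  if (abs(sum(distribution) - 1) > 1e-6)
    stop("distribution must sum to 1")
  ord <- order(-distribution, names(distribution))
  cs <- cumsum(distribution[ord])
  k <- which(cs >= cum - 1e-12)[1]
  if (is.na(k)) k <- length(distribution)
  names(distribution)[ord][seq_len(k)]
}

#' Derive the gene list characterizing one component
#'
#' The component's most active instances (top `p(i|z)` mass) and most
#' active gene sets (top `phi` mass) are taken at cumulative probability
#' `cum`. Every gene belonging to a top set is tested for differential
#' expression across the top instances with a two-sided one-sample
#' t-test of its log2 ratios against zero; genes with `p < alpha` are
#' kept, annotated with the direction of their mean shift, and ranked by
#' ascending p-value.
#'
#' @param profiles Log2-ratio profile matrix, genes x instances.
#' @param model A `ptgs_model`.
#' @param probs Output of [component_instance_probabilities()].
#' @param component Component id (e.g. `"C3"`).
#' @param sets The gene-set collection behind the signed features.
#' @param alpha Per-gene p-value cutoff (default 0.01).
#' @param cum Cumulative-mass threshold for top instances/sets.
#' @return Data frame `gene_id`, `direction`, `t_p_value`, `rank`, plus
#'   attributes `tests` (all tests, for core-set pooling) and
#'   `top_instances`.
#' @export
derive_component_genes <- function(profiles, model, probs, component, sets,
                                   alpha = 0.01, cum = 0.2) {
  stopifnot(component %in% rownames(model$phi))
  p_iz <- probs$p_i_given_z[component, ]
  top_inst <- top_mass_subset(p_iz, cum = cum)
  top_inst <- intersect(top_inst, colnames(profiles))
  if (length(top_inst) < 2L)
    stop("component ", component, " has fewer than 2 top instances")
  top_feat <- top_mass_subset(model$phi[component, ], cum = cum)
  set_names <- unique(sub("[+-]$", "", top_feat))
  candidates <- sort(unique(unlist(sets[set_names], use.names = FALSE)))
  candidates <- intersect(candidates, rownames(profiles))
  if (length(candidates) == 0L)
    stop("no candidate genes measured for component ", component)
  x <- profiles[candidates, top_inst, drop = FALSE]
  n <- ncol(x)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  tt <- mu / (s / sqrt(n))
  pv <- 2 * stats::pt(-abs(tt), df = n - 1)
  pv[!is.finite(pv)] <- 1  # zero-variance genes carry no evidence
  tests <- data.frame(gene_id = candidates, component = component,
                      mean_log2 = mu, t = tt, p = pv,
                      stringsAsFactors = FALSE, row.names = NULL)
  keep <- tests[tests$p < alpha, , drop = FALSE]
  keep <- keep[order(keep$p, keep$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = keep$gene_id,
                    direction = ifelse(keep$mean_log2 >= 0, "up", "down"),
                    t_p_value = keep$p,
                    rank = seq_len(nrow(keep)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "tests") <- tests
  attr(out, "top_instances") <- top_inst
  out
}

#' Derive the core gene set by pooled Bonferroni correction
#'
#' Pools every per-gene test over all components and keeps genes with
#' `p < alpha / m` where `m` is the total number of tests (or the
#' per-component test count with `per_component = TRUE`).
#'
#' @param tests Data frame of pooled tests (rows with `gene_id`,
#'   `component`, `p`).
#' @param alpha Nominal level before correction (default 0.01).
#' @param per_component Use the per-component test count as the
#'   Bonferroni denominator instead of the pooled count.
#' @return Character vector of core gene ids (de-duplicated, sorted).
#' @export
derive_core_set <- function(tests, alpha = 0.01, per_component = FALSE) {
  if (nrow(tests) == 0L) return(character())
  if (per_component) {
    m <- table(tests$component)[tests$component]
    keep <- tests$p < alpha / as.numeric(m)
  } else {
    keep <- tests$p < alpha / nrow(tests)
  }
  sort(unique(tests$gene_id[keep]))
}

#' Derive the full gene space of a selected component set
#'
#' Runs [derive_component_genes()] for every selected component and
#' pools the results into per-component lists (keyed by their letter
#' labels), the union list (`PTGS_ALL`), and the Bonferroni core
#' (`PTGS_CORE`).
#'
#' @inheritParams derive_component_genes
#' @param ptgs A `ptgs_definition`.
#' @return A `gene_space`: list with `components` (named list of gene
#'   list data frames), `all_genes`, `core_set`, `gene_sets` (exportable
#'   named list: per-component direction-suffixed sets plus PTGS_ALL and
#'   PTGS_CORE).
#' @export
derive_gene_space <- function(profiles, model, probs, ptgs, sets,
                              alpha = 0.01, cum = 0.2) {
  stopifnot(inherits(ptgs, "ptgs_definition"))
  comp_lists <- list()
  pooled <- list()
  for (i in seq_along(ptgs$selected_components)) {
    comp <- ptgs$selected_components[i]
    lab <- ptgs$labels[i]
    gl <- derive_component_genes(profiles, model, probs, comp, sets,
                                 alpha = alpha, cum = cum)
    comp_lists[[lab]] <- gl
    pooled[[lab]] <- attr(gl, "tests")
  }
  tests <- do.call(rbind, pooled)
  core <- derive_core_set(tests, alpha = alpha)
  all_genes <- sort(unique(unlist(lapply(comp_lists, `[[`, "gene_id"))))
  gmt <- list()
  for (lab in names(comp_lists)) {
    gl <- comp_lists[[lab]]
    for (d in c("up", "down")) {
      g <- gl$gene_id[gl$direction == d]
      if (length(g))
        gmt[[paste0("PTGS_", lab, "_", toupper(d))]] <- g
    }
    gmt[[paste0("PTGS_", lab)]] <- gl$gene_id
  }
  gmt[["PTGS_ALL"]] <- all_genes
  if (length(core)) gmt[["PTGS_CORE"]] <- core
  structure(list(components = comp_lists, all_genes = all_genes,
                 core_set = core, gene_sets = gmt, tests = tests),
            class = "gene_space")
}

#' Biological-complexity proportions
#'
#' The share of statistically significant analysis results attributable
#' to each component: `z_BC(i) = n_results(i) / sum(n_results)`.
#'
#' @param result_counts Non-negative counts of significant results per
#'   component.
#' @return Numeric vector of proportions summing to 1.
#' @export
biological_complexity <- function(result_counts) {
  if (any(result_counts < 0)) stop("counts must be non-negative")
  total <- sum(result_counts)
  if (total == 0) stop("all result counts are zero")
  result_counts / total
}

#' @export
print.gene_space <- function(x, ...) {
  cat("PTGS gene space:", length(x$all_genes), "genes over",
      length(x$components), "components;", length(x$core_set),
      "core genes\n")
  invisible(x)
}
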
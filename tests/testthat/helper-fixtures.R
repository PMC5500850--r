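# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests write themselves.

# A small GMT file with the given sets; returns its path.
write_gmt_fixture <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

# Activation counts drawn directly from the LDA generative process with
# planted phi: the oracle corpus for sampler-recovery tests.
lda_corpus_fixture <- function(n_inst = 60, K = 3, V = 30,
                               tokens_per_inst = 40, alpha = 0.2,
                               seed = 1) {
  set.seed(seed)
  phi <- matrix(0, K, V)
  block <- V %/% K
  for (k in seq_len(K)) {
    idx <- ((k - 1) * block + 1):(k * block)
    phi[k, idx] <- 1
  }
  phi <- phi / rowSums(phi)
  theta <- matrix(rgamma(n_inst * K, alpha), n_inst, K)
  theta <- theta / rowSums(theta)
  counts <- matrix(0L, n_inst, V,
                   dimnames = list(sprintf("i%03d", seq_len(n_inst)),
                                   sprintf("f%03d", seq_len(V))))
  for (i in seq_len(n_inst)) {
    z <- sample.int(K, tokens_per_inst, replace = TRUE, prob = theta[i, ])
    for (t in seq_len(tokens_per_inst)) {
      v <- sample.int(V, 1, prob = phi[z[t], ])
      counts[i, v] <- counts[i, v] + 1L
    }
  }
  list(counts = counts, phi = phi, theta = theta)
}

# Two-group expression fixture with an optional planted shift on a
# subset of genes.
expression_fixture <- function(n_genes = 50, n_treat = 3, n_ctrl = 3,
                               shifted_genes = character(), shift = 0,
                               noise_sd = 1, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  ctrl <- matrix(rnorm(n_genes * n_ctrl, 8, noise_sd), n_genes, n_ctrl,
                 dimnames = list(genes, paste0("c", seq_len(n_ctrl))))
  trt <- matrix(rnorm(n_genes * n_treat, 8, noise_sd), n_genes, n_treat,
                dimnames = list(genes, paste0("t", seq_len(n_treat))))
  trt[genes %in% shifted_genes, ] <- trt[genes %in% shifted_genes, ] + shift
  list(treatments = trt, controls = ctrl, genes = genes)
}

# Quadratic-time pair-counting AUC oracle (ties count one half).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
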
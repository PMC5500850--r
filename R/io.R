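# Readers and writers for the external formats consumed and produced by
# the pipeline: GMT gene-set collections, tab-separated expression
# matrices, CSV metadata tables, and JSON model documents.

MODEL_FORMAT_VERSION <- "ptgspace-model-1"
PTGS_FORMAT_VERSION <- "ptgspace-definition-1"

#' Read a gene-set collection from a GMT file
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Duplicate gene ids within a line are collapsed;
#' duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors of
#'   gene ids, with a `description` attribute per set.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descriptions <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    nms[i] <- fields[1]
    descriptions[i] <- fields[2]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("malformed GMT line ", i, ": set '", fields[1], "' is empty")
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  attr(sets, "description") <- setNames(descriptions, nms)
  class(sets) <- "gene_set_collection"
  ptgs_log("read ", length(sets), " gene sets from ", path)
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors (or `gene_set_collection`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects gene ids in the first column, sample ids in the header, and a
#' numeric body of log2-scale values. Duplicated gene or sample ids and
#' non-numeric cells are rejected.
#'
#' @param path Path to a tab-separated file.
#' @param transpose If `TRUE` the file is samples-in-rows and is
#'   transposed on read.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  stopifnot(file.exists(path))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("expression table needs an id column plus data")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric expression column(s): ",
         paste(colnames(body)[!num], collapse = ", "))
  m <- as.matrix(body)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in header")
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  if (transpose) m <- t(m)
  ptgs_log("read expression matrix ", nrow(m), " x ", ncol(m), " from ", path)
  m
}

#' Write an expression matrix to TSV
#'
#' @param m Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param id_column Name of the id column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  # %.17g guarantees bitwise round-trip of doubles through text
  chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  df <- data.frame(rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an instance (treatment) table from CSV
#'
#' Required columns: `instance_id`, `compound_id`, `system_id`,
#' `batch_id`, `is_control`. Optional: `concentration` (log10 molar by
#' default), `time`. Concentrations supplied in micromolar can be
#' converted with `units = "uM"`.
#'
#' @param path CSV path.
#' @param units `"log10M"` (default) or `"uM"`.
#' @return A data frame of instances.
#' @export
read_instance_table <- function(path, units = c("log10M", "uM")) {
  units <- match.arg(units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("instance_id", "compound_id", "system_id", "batch_id", "is_control")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("instance table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$instance_id)) stop("duplicate instance_id values")
  df$is_control <- as.logical(df$is_control)
  if (!is.null(df$concentration) && units == "uM")
    df$concentration <- log10(df$concentration * 1e-6)
  conc <- df$concentration[!df$is_control & !is.na(df$concentration)]
  if (length(conc) && !all(is.finite(conc)))
    stop("non-finite concentrations in instance table")
  # every non-control batch must resolve to at least one control
  ctrl_batches <- unique(df$batch_id[df$is_control])
  orphan <- setdiff(unique(df$batch_id[!df$is_control]), ctrl_batches)
  if (length(orphan))
    stop("batch(es) without controls: ", paste(orphan, collapse = ", "))
  df
}

#' Read a compound potency table from CSV
#'
#' Columns: `compound_id`, `system_id`, and any of `gi50`, `tgi`, `lc50`
#' in log10 molar units.
#'
#' @param path CSV path.
#' @return Data frame with potency columns in log10 molar.
#' @export
read_potency_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "system_id") %in% colnames(df)))
    stop("potency table needs compound_id and system_id columns")
  ok <- complete.cases(df[, intersect(c("gi50", "tgi", "lc50"), colnames(df))])
  if (all(c("gi50", "tgi", "lc50") %in% colnames(df))) {
    bad <- ok & !(df$gi50 <= df$tgi & df$tgi <= df$lc50)
    if (any(bad))
      stop("potency ordering gi50 <= tgi <= lc50 violated for: ",
           paste(df$compound_id[bad], collapse = ", "))
  }
  df
}

#' Read a pathology findings table from CSV
#'
#' Columns: `treatment_id`, `finding_type`, `grade` (one of present,
#' minimal, slight, moderate, severe) and `n_animals`.
#'
#' @param path CSV path.
#' @return Data frame of findings.
#' @export
read_pathology_findings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("treatment_id", "finding_type", "grade", "n_animals")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("findings table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- !df$grade %in% PATHOLOGY_GRADES
  if (any(bad))
    stop("unknown grade label(s) in record(s): ",
         paste(which(bad), collapse = ", "))
  if (any(df$n_animals < 1)) stop("n_animals must be >= 1")
  df
}

#' Read a DILI annotation table from CSV
#'
#' Columns: `compound_id`, `cmax` (log10 molar), `dili_class`
#' (`negative_control` or `dili_positive`); optional `severity_label`.
#'
#' @param path CSV path.
#' @return Data frame of annotations.
#' @export
read_dili_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "cmax", "dili_class")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(is.finite(df$cmax))) stop("non-finite cmax values")
  bad <- !df$dili_class %in% c("negative_control", "dili_positive")
  if (any(bad)) stop("unknown dili_class label(s)")
  df
}

#' Serialize a fitted component model to a JSON document
#'
#' The document is self-describing and carries a format-version field so
#' that incompatible files are rejected on read rather than silently
#' misread.
#'
#' @param model A `ptgs_model` from [fit_components()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_component_model <- function(model, path) {
  stopifnot(inherits(model, "ptgs_model"))
  doc <- list(
    format = MODEL_FORMAT_VERSION,
    K = model$K,
    feature_vocabulary = model$feature_vocabulary,
    instance_ids = model$instance_ids,
    theta = model$theta,
    phi = model$phi,
    alpha = model$alpha,
    beta = model$beta,
    hyper_shape = model$hyper_shape,
    hyper_rate = model$hyper_rate,
    seed = model$seed,
    n_sweeps = model$n_sweeps,
    burn_in = model$burn_in
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized component model
#'
#' @param path Path to a JSON document written by [write_component_model()].
#' @return A `ptgs_model`.
#' @export
read_component_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model document: ",
                                           conditionMessage(e)))
  if (is.null(doc$format) || !identical(doc$format, MODEL_FORMAT_VERSION))
    stop("model format version mismatch: expected ", MODEL_FORMAT_VERSION,
         ", found ", if (is.null(doc$format)) "<none>" else doc$format)
  theta <- as.matrix(doc$theta)
  phi <- as.matrix(doc$phi)
  comp_ids <- paste0("C", seq_len(doc$K))
  dimnames(theta) <- list(doc$instance_ids, comp_ids)
  dimnames(phi) <- list(comp_ids, doc$feature_vocabulary)
  model <- new_ptgs_model(
    theta = theta, phi = phi, alpha = doc$alpha, beta = doc$beta,
    feature_vocabulary = doc$feature_vocabulary,
    instance_ids = doc$instance_ids,
    hyper_shape = doc$hyper_shape, hyper_rate = doc$hyper_rate,
    seed = doc$seed, n_sweeps = doc$n_sweeps, burn_in = doc$burn_in
  )
  model
}

#' Serialize a PTGS definition (selected component space)
#'
#' @param ptgs A `ptgs_definition` from [cumulative_auc_selection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptgs_definition <- function(ptgs, path) {
  stopifnot(inherits(ptgs, "ptgs_definition"))
  doc <- c(list(format = PTGS_FORMAT_VERSION), unclass(ptgs))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized PTGS definition
#'
#' @param path Path to a JSON document written by [write_ptgs_definition()].
#' @return A `ptgs_definition`.
#' @export
read_ptgs_definition <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse definition document: ",
                                           conditionMessage(e)))
  if (is.null(doc$format) || !identical(doc$format, PTGS_FORMAT_VERSION))
    stop("definition format version mismatch")
  doc$format <- NULL
  structure(doc, class = "ptgs_definition")
}

#' @export
print.ptgs_model <- function(x, ...) {
  cat("PTGS component model: K =", x$K, "over", length(x$feature_vocabulary),
      "signed features,", length(x$instance_ids), "instances\n")
  cat("  alpha =", format(x$alpha, digits = 4),
      " beta =", format(x$beta, digits = 4), "\n")
  invisible(x)
}

#' @export
print.ptgs_definition <- function(x, ...) {
  cat("PTGS definition:", length(x$selected_components), "components (",
      paste(x$labels, collapse = ""), ") of", length(x$auc_curve), "\n")
  cat("  score threshold:", format(x$score_threshold, digits = 4), "\n")
  invisible(x)
}
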
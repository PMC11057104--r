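#' Construct a bulk experiment from an expression matrix and sample metadata
#'
#' A `bulk_experiment` couples a genes x samples expression matrix (raw counts
#' or normalized expression, all non-negative) with the sample-level design of
#' a repeated-measures study: which subject each sample belongs to, the repeat
#' index within subject, and the subject's binary group label (0 = control,
#' 1 = case).
#'
#' @param expression Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. Entries must be finite and non-negative.
#' @param metadata Data frame with columns `sample_id`, `subject_id`,
#'   `repeat_index` (integer >= 1) and `group` (0 or 1, constant within
#'   subject). One row per sample; every expression column must be described.
#'   Additional numeric columns are retained as extra covariates.
#' @return An object of class `bulk_experiment`: a list with elements
#'   `expression` (matrix, metadata-ordered columns) and `samples` (the
#'   validated metadata, rows aligned with the columns of `expression`).
#' @examples
#' y <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:4),
#'                  subject_id = rep(c("a", "b"), each = 2),
#'                  repeat_index = rep(1:2, 2),
#'                  group = rep(c(0, 1), each = 2))
#' be <- bulk_experiment(y, md)
#' be
#' @export
bulk_experiment <- function(expression, metadata) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression must have gene row names and sample column names")
  rownames(expression) <- trimws(rownames(expression))
  colnames(expression) <- trimws(colnames(expression))
  if (anyDuplicated(rownames(expression)))
    stop("duplicate gene ids in expression: ",
         paste(unique(rownames(expression)[duplicated(rownames(expression))]),
               collapse = ", "))
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample ids in expression: ",
         paste(unique(colnames(expression)[duplicated(colnames(expression))]),
               collapse = ", "))
  if (anyNA(expression) || any(!is.finite(expression)))
    stop("expression contains missing or non-finite values")
  if (any(expression < 0)) {
    bad <- which(expression < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(expression)[bad[1]], colnames(expression)[bad[2]]))
  }

  metadata <- as.data.frame(metadata)
  req <- c("sample_id", "subject_id", "repeat_index", "group")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  metadata$sample_id <- trimws(as.character(metadata$sample_id))
  metadata$subject_id <- trimws(as.character(metadata$subject_id))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  if (!all(metadata$repeat_index == as.integer(metadata$repeat_index)) ||
      any(metadata$repeat_index < 1))
    stop("repeat_index must be integers >= 1")
  metadata$repeat_index <- as.integer(metadata$repeat_index)
  key <- paste(metadata$subject_id, metadata$repeat_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, repeat_index) pair: ",
         key[duplicated(key)][1])
  if (!all(metadata$group %in% c(0, 1)))
    stop("group must be 0 or 1; offending sample(s): ",
         paste(metadata$sample_id[!metadata$group %in% c(0, 1)],
               collapse = ", "))
  grp_per_subj <- tapply(metadata$group, metadata$subject_id,
                         function(g) length(unique(g)))
  if (any(grp_per_subj > 1))
    stop("group label differs across repeats for subject(s): ",
         paste(names(grp_per_subj)[grp_per_subj > 1], collapse = ", "))

  absent <- setdiff(colnames(expression), metadata$sample_id)
  if (length(absent))
    stop("sample(s) in expression but missing from metadata: ",
         paste(absent, collapse = ", "))
  orphan <- setdiff(metadata$sample_id, colnames(expression))
  if (length(orphan))
    stop("sample(s) in metadata but missing from expression: ",
         paste(orphan, collapse = ", "))

  metadata <- metadata[match(colnames(expression), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(expression = expression, samples = metadata),
            class = "bulk_experiment")
}

#' @export
print.bulk_experiment <- function(x, ...) {
  tab <- table(x$samples$subject_id)
  cat(sprintf("bulk_experiment: %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  %d subjects (%d..%d repeats each); groups: %s\n",
              length(tab), min(tab), max(tab),
              paste(sprintf("%d x group=%s",
                            as.vector(table(x$samples$group[!duplicated(x$samples$subject_id)])),
                            names(table(x$samples$group[!duplicated(x$samples$subject_id)]))),
                    collapse = ", ")))
  invisible(x)
}

#' Subject-level group labels of a bulk experiment
#'
#' @param bulk A [bulk_experiment()].
#' @return Named numeric vector, one 0/1 entry per subject.
#' @export
subject_groups <- function(bulk) {
  stopifnot(inherits(bulk, "bulk_experiment"))
  md <- bulk$samples[!duplicated(bulk$samples$subject_id), ]
  setNames(md$group, md$subject_id)
}

#' Counts-per-million normalization
#'
#' Scales each sample (column) so its entries sum to one million. Columns with
#' zero total are left at zero with a warning.
#'
#' @param expression Non-negative genes x samples matrix.
#' @return Matrix of the same shape on the CPM scale.
#' @export
cpm <- function(expression) {
  tot <- colSums(expression)
  zero <- tot == 0
  if (any(zero)) {
    warning("sample(s) with zero total counts left unscaled: ",
            paste(colnames(expression)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(expression, 2, tot, "/") * 1e6
}

#' Read a bulk experiment from disk
#'
#' The expression matrix may be a delimited text file (TSV or CSV; first
#' column gene ids, header row sample ids) or a MatrixMarket `.mtx` file with
#' `genes.tsv` / `samples.tsv` sidecar files (one id per line) in the same
#' directory. Metadata is a TSV with columns `sample_id`, `subject_id`,
#' `repeat_index`, `group`.
#'
#' @param expression_path Path to the expression file.
#' @param metadata_path Path to the metadata TSV.
#' @return A validated [bulk_experiment()].
#' @export
read_bulk <- function(expression_path, metadata_path) {
  expr <- read_expression_matrix(expression_path)
  md <- read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  bulk_experiment(expr, md)
}

# internal: expression matrix from TSV/CSV or MatrixMarket + sidecars
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gf <- file.path(dir, "genes.tsv")
    sf <- file.path(dir, "samples.tsv")
    if (!file.exists(gf) || !file.exists(sf))
      stop("MatrixMarket input requires genes.tsv and samples.tsv next to ", path)
    rn <- trimws(readLines(gf))
    cn <- trimws(readLines(sf))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id counts do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  ids <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- trimws(colnames(m))
  m
}

#' Read a signature matrix
#'
#' A signature (reference) matrix holds the expected expression of marker
#' genes in purified cell types: rows are marker genes, columns are cell
#' types, entries are non-negative.
#'
#' @param path Path to a TSV (first column gene ids, header row cell types).
#' @return A validated numeric matrix of class `signature_matrix`.
#' @export
read_signature <- function(path) {
  m <- read_expression_matrix(path)
  signature_matrix(m)
}

#' Validate a signature matrix
#'
#' @param values Numeric marker-genes x cell-types matrix with dimnames.
#' @return The validated matrix with class `signature_matrix` prepended.
#' @export
signature_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2)
    stop("a signature matrix needs at least 2 cell types (columns)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("signature matrix must have gene row names and cell-type column names")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in signature: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-type names in signature")
  if (anyNA(values) || any(values < 0))
    stop("signature matrix entries must be non-negative and non-missing")
  if (nrow(values) < ncol(values))
    stop("signature matrix needs at least as many marker genes as cell types")
  zero_rows <- rowSums(values) == 0
  if (any(zero_rows))
    stop("all-zero signature row(s): ",
         paste(rownames(values)[zero_rows], collapse = ", "))
  class(values) <- c("signature_matrix", class(values))
  values
}

#' Construct a proportion set
#'
#' A samples x cell-types matrix of compositions: non-negative rows summing
#' to one. `origin` records which estimator produced it.
#'
#' @param values Numeric samples x cell-types matrix with dimnames.
#' @param origin One of `"stage1"`, `"stage3"`, `"truth"`.
#' @return The matrix with attribute `origin` and class `proportion_set`.
#' @export
proportion_set <- function(values, origin = c("stage1", "stage3", "truth")) {
  origin <- match.arg(origin)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("proportion set must have sample row names and cell-type column names")
  if (anyNA(values) || any(values < 0))
    stop("proportions must be non-negative and non-missing")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-8))
    stop("proportion rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  structure(values, origin = origin,
            class = c("proportion_set", "matrix", "array"))
}

#' @export
print.proportion_set <- function(x, ...) {
  cat(sprintf("proportion_set (origin: %s): %d samples x %d cell types\n",
              attr(x, "origin"), nrow(x), ncol(x)))
  print(utils::head(unclass(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write / read proportion sets
#'
#' `write_proportions()` writes a long-format TSV (`sample_id`, `cell_type`,
#' `proportion`) at `path` — the canonical on-disk form — plus a wide
#' genes-in-columns mirror at `<path minus extension>_wide.tsv`.
#' `read_proportions()` reads the long format back.
#'
#' @param p A [proportion_set()] (or samples x cell-types matrix).
#' @param path Output (input) TSV path.
#' @param origin Origin tag to attach on read.
#' @return `write_proportions()` returns `path` invisibly;
#'   `read_proportions()` returns a [proportion_set()].
#' @export
write_proportions <- function(p, path) {
  p <- as.matrix(p)
  if (nrow(p) == 0 || ncol(p) == 0)
    stop("cannot write an empty proportion set")
  long <- data.frame(
    sample_id = rep(rownames(p), times = ncol(p)),
    cell_type = rep(colnames(p), each = nrow(p)),
    proportion = as.vector(p)
  )
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wide_path <- paste0(tools::file_path_sans_ext(path), "_wide.tsv")
  wide <- data.frame(sample_id = rownames(p), p, check.names = FALSE)
  write.table(wide, wide_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path, origin = c("stage1", "stage3", "truth")) {
  origin <- match.arg(origin)
  long <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  samples <- unique(long$sample_id)
  types <- unique(long$cell_type)
  m <- matrix(NA_real_, length(samples), length(types),
              dimnames = list(samples, types))
  m[cbind(match(long$sample_id, samples), match(long$cell_type, types))] <-
    long$proportion
  if (anyNA(m)) stop("incomplete long-format proportion table: ", path)
  proportion_set(m, origin)
}

#' Write / read personalized panel sets
#'
#' Writes one genes x cell-types TSV per subject (`panel_<subject>.tsv`) and a
#' combined long-format coefficient table `coefficients.tsv` with columns
#' `gene`, `cell_type`, `m_hat`, `beta_hat`, and one `u_hat.<subject>` column
#' per subject.
#'
#' @param panels A `personalized_panel_set` from [run_stage2()].
#' @param dir Output directory (created if needed).
#' @param path Directory written by `write_panels()`.
#' @return `write_panels()` returns `dir` invisibly; `read_panels()` returns a
#'   `personalized_panel_set` (coefficient tables only; per-gene fit details
#'   such as variance components are not round-tripped).
#' @export
write_panels <- function(panels, dir) {
  stopifnot(inherits(panels, "personalized_panel_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(panels$panels)) {
    df <- data.frame(gene = panels$gene_ids, panels$panels[[s]],
                     check.names = FALSE)
    write.table(df, file.path(dir, paste0("panel_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  co <- panel_coefficients(panels)
  write.table(co, file.path(dir, "coefficients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_panels
#' @export
read_panels <- function(path) {
  files <- list.files(path, pattern = "^panel_.*\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no panel_<subject>.tsv files in ", path)
  subjects <- sub("^panel_(.*)\\.tsv$", "\\1", basename(files))
  panels <- lapply(files, function(f) {
    df <- read.delim(f, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene
    m
  })
  names(panels) <- subjects
  structure(list(panels = panels,
                 gene_ids = rownames(panels[[1]]),
                 cell_types = colnames(panels[[1]]),
                 fits = NULL),
            class = "personalized_panel_set")
}

# internal: long coefficient table (gene, cell_type, m_hat, beta_hat, u_hat.<subject>...)
panel_coefficients <- function(panels) {
  subjects <- names(panels$panels)
  rows <- lapply(panels$gene_ids, function(g) {
    fit <- panels$fits[[g]]
    df <- data.frame(gene = g, cell_type = panels$cell_types,
                     m_hat = fit$m_hat, beta_hat = fit$beta_hat)
    u <- t(fit$u_hat)  # cell_type x subject
    colnames(u) <- paste0("u_hat.", colnames(u))
    cbind(df, as.data.frame(u, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
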
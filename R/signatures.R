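# Correlation signatures of transitions and attractors in expression
# data: gene-gene and cell-cell Pearson correlations.

#' Construct an expression matrix object
#'
#' @param values cells x genes numeric matrix (`g[i, j]` = expression of
#'   gene `j` in cell `i`)
#' @param cell_ids,gene_ids optional identifiers
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 gene_ids = gene_ids),
            class = "expression_matrix")
}

#' Read / write an expression matrix (CSV/TSV, cells in rows)
#'
#' The first column holds cell ids; the header row holds gene ids.
#' @param path file path (`.tsv`/`.txt` read as tab-separated)
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE)
  expression_matrix(as.matrix(df))
}

#' @rdname read_expression
#' @param mat an `expression_matrix`
#' @export
write_expression <- function(mat, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- data.frame(cell = mat$cell_ids, mat$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gene-gene correlation signature
#'
#' Pearson correlation between every pair of genes across cells, with the
#' mean absolute off-diagonal value as a one-number summary. High
#' \eqn{|\gamma_{jj'}|} is the signature of a transition: cells squeezed
#' onto a 1D unstable manifold have (near-)collinear expression, making
#' all defined gene-gene correlations close to \eqn{\pm 1}. Genes with
#' zero variance have undefined correlations; they are flagged and
#' excluded from the summary, never imputed.
#'
#' @param mat an `expression_matrix` (or plain cells x genes matrix)
#' @return list with `corr` (gene x gene matrix, `NA` where undefined),
#'   `mean_abs` (mean |off-diagonal| over defined pairs),
#'   `constant_genes` (ids of flagged genes)
#' @export
gene_gene_corr <- function(mat) {
  V <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (nrow(V) < 2L || ncol(V) < 2L) {
    stop("need at least 2 cells and 2 genes", call. = FALSE)
  }
  sdv <- apply(V, 2L, stats::sd)
  const <- sdv == 0
  if (all(const)) {
    stop("all genes constant: no defined gene-gene correlations",
         call. = FALSE)
  }
  C <- matrix(NA_real_, ncol(V), ncol(V),
              dimnames = list(colnames(V), colnames(V)))
  ok <- which(!const)
  C[ok, ok] <- stats::cor(V[, ok, drop = FALSE])
  off <- C[upper.tri(C)]
  list(corr = C, mean_abs = mean(abs(off), na.rm = TRUE),
       constant_genes = colnames(V)[const])
}

#' Cell-cell correlation signature
#'
#' Pearson correlation between the expression vectors of every pair of
#' cells (across genes), averaged over all unordered pairs. Cells whose
#' expression vector is constant across genes have undefined correlations
#' and are excluded (and reported). Low cell-cell correlation combined
#' with high gene-gene correlation marks a population in transit along an
#' escape route.
#'
#' @inheritParams gene_gene_corr
#' @param standardize per-gene z-scoring before correlating (optional;
#'   changes what "collinear" means, see the methods vignette)
#' @return list with `mean_corr`, `n_pairs`, `excluded_cells`
#' @export
cell_cell_corr <- function(mat, standardize = FALSE) {
  V <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (nrow(V) < 2L || ncol(V) < 2L) {
    stop("need at least 2 cells and 2 genes", call. = FALSE)
  }
  if (standardize) {
    sdv <- apply(V, 2L, stats::sd)
    keep <- sdv > 0
    V <- scale(V[, keep, drop = FALSE])
  }
  sdc <- apply(V, 1L, stats::sd)
  excluded <- rownames(V)[sdc == 0]
  V <- V[sdc > 0, , drop = FALSE]
  if (nrow(V) < 2L) {
    stop("fewer than 2 cells with non-constant expression", call. = FALSE)
  }
  C <- stats::cor(t(V))
  off <- C[upper.tri(C)]
  list(mean_corr = mean(off), n_pairs = length(off),
       excluded_cells = excluded)
}

#' Per-group transition report
#'
#' Computes both correlation summaries for each group of cells (for
#' example, clusters or time points). During a transition the prediction
#' is low cell-cell correlation with high absolute gene-gene correlation;
#' at an attractor the pattern reverses. No thresholding is applied --
#' the report is descriptive.
#'
#' @inheritParams gene_gene_corr
#' @param cell_groups factor/character vector assigning each cell to a
#'   group (must partition the cells)
#' @return data frame with one row per usable group: `group`, `n_cells`,
#'   `mean_abs_gene_corr`, `mean_cell_corr`; skipped groups (fewer than
#'   2 cells) are listed in the `skipped` attribute
#' @export
transition_report <- function(mat, cell_groups) {
  V <- if (inherits(mat, "expression_matrix")) mat$values else as.matrix(mat)
  if (length(cell_groups) != nrow(V)) {
    stop("cell_groups must have one entry per cell", call. = FALSE)
  }
  groups <- unique(as.character(cell_groups))
  rows <- list(); skipped <- character(0)
  for (g in groups) {
    idx <- which(as.character(cell_groups) == g)
    if (length(idx) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    sub <- V[idx, , drop = FALSE]
    gg <- tryCatch(gene_gene_corr(sub), error = function(e) NULL)
    cc <- tryCatch(cell_cell_corr(sub), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n_cells = length(idx),
      mean_abs_gene_corr = if (is.null(gg)) NA_real_ else gg$mean_abs,
      mean_cell_corr = if (is.null(cc)) NA_real_ else cc$mean_corr)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(0), n_cells = integer(0),
               mean_abs_gene_corr = numeric(0),
               mean_cell_corr = numeric(0))
  }
  attr(out, "skipped") <- skipped
  out
}
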
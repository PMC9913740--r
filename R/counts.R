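#' Construct a single-cell UMI count matrix container
#'
#' Bundles a cells x genes matrix of UMI counts with per-gene biotype
#' annotation and an optional per-cell label (e.g. "Cancer Epithelial" from an
#' external annotation step). Cells are rows, genes are columns throughout the
#' package.
#'
#' @param counts integer matrix, cells x genes. A base matrix or a
#'   \code{\link[Matrix]{sparseMatrix}}; must carry unique row (cell) and
#'   column (gene) names.
#' @param gene_biotype character vector of biotypes (e.g. "protein_coding"),
#'   one per gene, recycled from a scalar. Defaults to "protein_coding".
#' @param cell_label optional character vector of per-cell annotation labels.
#' @return An object of class \code{tsp_counts}: a list with elements
#'   \code{counts}, \code{gene_biotype} (named by gene) and \code{cell_label}
#'   (named by cell, or NULL).
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' tsp_counts(m)
#' @export
tsp_counts <- function(counts, gene_biotype = "protein_coding",
                       cell_label = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate gene identifiers")
  cx <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (any(cx < 0) || any(cx != floor(cx)))
    stop("counts must be non-negative integers")
  gene_biotype <- rep_len(as.character(gene_biotype), ncol(counts))
  names(gene_biotype) <- colnames(counts)
  if (!is.null(cell_label)) {
    cell_label <- rep_len(as.character(cell_label), nrow(counts))
    names(cell_label) <- rownames(counts)
  }
  structure(list(counts = counts, gene_biotype = gene_biotype,
                 cell_label = cell_label),
            class = "tsp_counts")
}

#' @export
print.tsp_counts <- function(x, ...) {
  cat(sprintf("tsp_counts: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  bt <- table(x$gene_biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "),
      "\n")
  if (!is.null(x$cell_label)) {
    lb <- table(x$cell_label)
    cat("  cell labels:",
        paste(sprintf("%s=%d", names(lb), lb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.tsp_counts <- function(x) dim(x$counts)

subset_tsp_counts <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- rownames(m$counts)
  if (is.null(genes)) genes <- colnames(m$counts)
  tsp_counts(m$counts[cells, genes, drop = FALSE],
             gene_biotype = m$gene_biotype[genes],
             cell_label = if (is.null(m$cell_label)) NULL
                          else m$cell_label[cells])
}

#' Filter genes by biotype, symbol prefix and detection rate
#'
#' Retains genes whose biotype is in \code{keep_biotypes}, whose identifier
#' does not start with any of \code{exclude_prefixes} (used to drop
#' mitochondrial "MT-" and ribosomal "RPL"/"RPS" genes), and which are
#' detected (count > 0) in at least \code{min_cells} cells. The cell set is
#' unchanged.
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @param keep_biotypes character vector of biotypes to keep.
#' @param exclude_prefixes character vector of gene-symbol prefixes to drop.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return A filtered \code{tsp_counts}.
#' @export
filter_genes <- function(m, keep_biotypes = "protein_coding",
                         exclude_prefixes = c("MT-", "RPL", "RPS"),
                         min_cells = 3) {
  stopifnot(inherits(m, "tsp_counts"), min_cells >= 0)
  ids <- colnames(m$counts)
  keep <- m$gene_biotype %in% keep_biotypes
  for (p in exclude_prefixes)
    keep <- keep & !startsWith(ids, p)
  detected <- Matrix::colSums(m$counts > 0)
  keep <- keep & detected >= min_cells
  if (!any(keep)) stop("no genes pass filters")
  subset_tsp_counts(m, genes = ids[keep])
}

#' Filter cells by detected-gene count and annotation label
#'
#' Retains cells with at least \code{min_genes} genes detected (count > 0)
#' and, when \code{keep_label} is given, whose annotation equals it. The gene
#' set is unchanged.
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @param min_genes minimum detected genes per cell.
#' @param keep_label optional cell annotation to keep (e.g.
#'   "Cancer Epithelial"); requires \code{m$cell_label}.
#' @return A filtered \code{tsp_counts}.
#' @export
filter_cells <- function(m, min_genes = 200, keep_label = NULL) {
  stopifnot(inherits(m, "tsp_counts"), min_genes >= 0)
  keep <- Matrix::rowSums(m$counts > 0) >= min_genes
  if (!is.null(keep_label)) {
    if (is.null(m$cell_label))
      stop("`keep_label` given but the matrix carries no cell labels")
    keep <- keep & m$cell_label == keep_label
  }
  if (!any(keep)) stop("no cells pass filters")
  subset_tsp_counts(m, cells = rownames(m$counts)[keep])
}

#' Read a 10x-style count directory
#'
#' Expects \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (gene id, gene symbol, biotype as tab-separated columns; additional columns
#' ignored). The MTX file stores genes x cells as 10x does; the returned
#' object is cells x genes.
#'
#' @param dir directory containing the three files.
#' @param annotation optional path to a two-column CSV (cell_id, label).
#' @return A \code{\link{tsp_counts}} object.
#' @export
read_counts_10x <- function(dir, annotation = NULL) {
  mtx <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- utils::read.delim(file.path(dir, "features.tsv"),
                             header = FALSE, stringsAsFactors = FALSE)
  counts <- Matrix::t(mtx)
  dimnames(counts) <- list(barcodes, feats[[1]])
  biotype <- if (ncol(feats) >= 3) feats[[3]] else "protein_coding"
  label <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.csv(annotation, stringsAsFactors = FALSE)
    label <- ann[[2]][match(barcodes, ann[[1]])]
  }
  tsp_counts(as(counts, "CsparseMatrix"), gene_biotype = biotype,
             cell_label = label)
}

#' Write a count matrix as a 10x-style directory
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_counts_10x <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- as(Matrix::t(Matrix::Matrix(m$counts, sparse = TRUE)), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "barcodes.tsv"))
  feats <- data.frame(id = colnames(m$counts), symbol = colnames(m$counts),
                      biotype = m$gene_biotype)
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
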
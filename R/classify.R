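#' Assign units to TNBCtype-4 subtypes by centroid correlation
#'
#' Correlates every unit's expression vector (a cell, bulk sample or cell
#' line) with each subtype centroid over the genes shared between the
#' expression matrix and the centroid matrix, and assigns the subtype with
#' the highest positive correlation. Units whose best correlation is not
#' positive, or whose shared-gene vector has zero variance, are labelled
#' \code{"unassigned"}. Exact ties are broken by centroid column order, with
#' a warning.
#'
#' @param expr numeric matrix, units x genes (log scale expected for the
#'   default Pearson method).
#' @param centroids numeric matrix, genes x subtypes, with gene row names and
#'   subtype column names (default order BL1, BL2, LAR, M).
#' @param method correlation kind, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param min_shared_genes minimum number of genes shared between \code{expr}
#'   and \code{centroids}.
#' @return A data.frame with one row per unit: \code{unit_id}, \code{label},
#'   \code{best_corr}, one \code{corr_<subtype>} column per subtype, and
#'   \code{undefined_corr} flagging zero-variance units.
#' @export
classify_subtypes <- function(expr, centroids,
                              method = c("pearson", "spearman"),
                              min_shared_genes = 20) {
  method <- match.arg(method)
  shared <- intersect(colnames(expr), rownames(centroids))
  if (length(shared) < min_shared_genes)
    stop(sprintf("only %d genes shared between expression and centroids (need %d)",
                 length(shared), min_shared_genes))
  cen <- as.matrix(centroids)[shared, , drop = FALSE]
  if (ncol(cen) < 2) stop("need at least 2 subtype centroids")
  sds <- apply(cen, 2, stats::sd)
  if (any(sds == 0))
    stop("constant centroid column(s) on shared genes: ",
         paste(colnames(cen)[sds == 0], collapse = ", "))
  ex <- as.matrix(expr)[, shared, drop = FALSE]
  subtypes <- colnames(cen)

  unit_sd <- apply(ex, 1, stats::sd)
  cors <- matrix(NA_real_, nrow(ex), ncol(cen),
                 dimnames = list(rownames(ex), subtypes))
  ok <- unit_sd > 0
  if (any(ok))
    cors[ok, ] <- stats::cor(t(ex[ok, , drop = FALSE]), cen, method = method)

  label <- rep("unassigned", nrow(ex))
  best <- rep(NA_real_, nrow(ex))
  tie_units <- character(0)
  for (u in which(ok)) {
    cv <- cors[u, ]
    mx <- max(cv)
    best[u] <- mx
    if (mx > 0) {
      hits <- which(cv == mx)
      if (length(hits) > 1) tie_units <- c(tie_units, rownames(ex)[u])
      label[u] <- subtypes[hits[1]]
    }
  }
  if (length(tie_units) > 0)
    warning(sprintf("%d unit(s) with tied best correlation assigned to the first subtype in order: %s",
                    length(tie_units),
                    paste(utils::head(tie_units, 5), collapse = ", ")))
  out <- data.frame(unit_id = rownames(ex), label = label, best_corr = best,
                    undefined_corr = !ok, stringsAsFactors = FALSE)
  cor_df <- as.data.frame(cors)
  names(cor_df) <- paste0("corr_", subtypes)
  rownames(out) <- NULL
  cbind(out, cor_df, row.names = NULL)
}
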
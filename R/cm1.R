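#' CM1 scores for one subtype
#'
#' Supervised univariate class-separation statistic. For every gene, with
#' in-subtype cell values x and out-of-subtype values y,
#' \deqn{CM1 = (\bar x - \bar y) / (1 + (\max y - \min y))}
#' Large positive scores mark genes up-regulated in the subtype relative to
#' all other subtypes, large negative scores down-regulated ones; the
#' out-class range in the denominator penalises genes that are merely
#' heterogeneous outside the subtype.
#'
#' Cells labelled \code{"unassigned"} are excluded from both groups. The
#' out-class range is taken over individual out-of-subtype cells by default;
#' \code{range_over = "subtype_means"} instead takes it over the per-subtype
#' mean expressions (both readings of the statistic occur in practice).
#'
#' @param expr numeric matrix, cells x genes (log2 normalized).
#' @param labels a data.frame with columns \code{unit_id} and \code{label}
#'   (as returned by \code{\link{classify_subtypes}}), or a character vector
#'   named by cell id.
#' @param subtype the subtype whose markers are scored.
#' @param range_over take max/min of the out-class values over
#'   \code{"cells"} (default) or over \code{"subtype_means"}.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{subtype}, \code{cm1}, \code{x_bar}, \code{y_bar}, \code{y_max},
#'   \code{y_min}.
#' @export
cm1_scores <- function(expr, labels, subtype,
                       range_over = c("cells", "subtype_means")) {
  range_over <- match.arg(range_over)
  lab <- if (is.data.frame(labels))
    stats::setNames(labels$label, labels$unit_id) else labels
  lab <- lab[rownames(expr)]
  if (anyNA(lab)) stop("labels do not cover all cells of `expr`")
  assigned <- lab != "unassigned"
  in_grp <- assigned & lab == subtype
  out_grp <- assigned & lab != subtype
  if (sum(in_grp) < 2) stop(sprintf("subtype '%s' has fewer than 2 cells", subtype))
  if (sum(out_grp) < 2) stop("fewer than 2 cells outside the subtype")

  x_bar <- colMeans(expr[in_grp, , drop = FALSE])
  yv <- expr[out_grp, , drop = FALSE]
  y_bar <- colMeans(yv)
  if (range_over == "cells") {
    y_max <- apply(yv, 2, max)
    y_min <- apply(yv, 2, min)
  } else {
    other <- setdiff(unique(lab[out_grp]), "unassigned")
    means <- vapply(other, function(s)
      colMeans(expr[assigned & lab == s, , drop = FALSE]),
      numeric(ncol(expr)))
    y_max <- apply(means, 1, max)
    y_min <- apply(means, 1, min)
  }
  data.frame(gene_id = colnames(expr), subtype = subtype,
             cm1 = (x_bar - y_bar) / (1 + (y_max - y_min)),
             x_bar = x_bar, y_bar = y_bar, y_max = y_max, y_min = y_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select top and bottom CM1-ranked candidate genes
#'
#' Sorts genes by CM1 score in descending order and returns the first k as
#' up-regulated and the last k as down-regulated candidates. Ties at a rank
#' boundary are broken by lexicographic gene id. A selected "up" gene must
#' have cm1 > 0 and a "down" gene cm1 < 0; violating genes are dropped with a
#' warning, so the result may hold fewer than 2k genes.
#'
#' @param t a CM1 table from \code{\link{cm1_scores}}.
#' @param k number of genes per direction (default 4).
#' @return A data.frame \code{gene_id}, \code{direction} ("up"/"down"),
#'   \code{cm1}, ordered strongest first within each direction.
#' @export
select_candidates <- function(t, k = 4) {
  stopifnot(k >= 1)
  if (nrow(t) < 2 * k)
    stop(sprintf("need at least %d genes, got %d", 2 * k, nrow(t)))
  ord <- order(-t$cm1, t$gene_id)
  up <- t[ord[seq_len(k)], ]
  dn <- t[rev(ord)[seq_len(k)], ]        # strongest (most negative) first
  dn <- dn[order(dn$cm1, dn$gene_id), ]
  bad_up <- up$cm1 <= 0
  bad_dn <- dn$cm1 >= 0
  if (any(bad_up) || any(bad_dn))
    warning(sprintf("dropped %d candidate(s) whose CM1 sign contradicts the direction",
                    sum(bad_up) + sum(bad_dn)))
  rbind(
    data.frame(gene_id = up$gene_id[!bad_up],
               direction = rep("up", sum(!bad_up)),
               cm1 = up$cm1[!bad_up], stringsAsFactors = FALSE),
    data.frame(gene_id = dn$gene_id[!bad_dn],
               direction = rep("down", sum(!bad_dn)),
               cm1 = dn$cm1[!bad_dn], stringsAsFactors = FALSE)
  )
}

#' Remove cross-subtype overlaps from candidate lists
#'
#' Any gene appearing in two or more per-subtype candidate lists is removed
#' from all of them, yielding pairwise-disjoint subtype-specific signatures.
#' Within-list order is preserved.
#'
#' @param candidates named list of per-subtype candidate data.frames from
#'   \code{\link{select_candidates}}.
#' @return A named list of the same shape, class \code{tsp_signatures};
#'   pairwise disjoint gene lists. Empty lists are allowed (warned).
#' @export
remove_overlaps <- function(candidates) {
  if (length(candidates) < 2) stop("need candidate lists for at least 2 subtypes")
  genes <- unlist(lapply(candidates, `[[`, "gene_id"), use.names = FALSE)
  dup <- unique(genes[duplicated(genes)])
  out <- lapply(candidates, function(df) {
    df[!df$gene_id %in% dup, , drop = FALSE]
  })
  empty <- names(out)[vapply(out, nrow, 0L) == 0]
  if (length(empty) > 0)
    warning("overlap removal emptied the signature for: ",
            paste(empty, collapse = ", "))
  structure(out, removed = dup, class = "tsp_signatures")
}

#' @export
print.tsp_signatures <- function(x, ...) {
  cat("TSPSig signature set\n")
  for (s in names(x))
    cat(sprintf("  %s: %d genes (%d up, %d down)\n", s, nrow(x[[s]]),
                sum(x[[s]]$direction == "up"),
                sum(x[[s]]$direction == "down")))
  rem <- attr(x, "removed")
  if (length(rem) > 0)
    cat("  removed as cross-subtype overlaps:", paste(rem, collapse = ", "), "\n")
  invisible(x)
}

#' Discover subtype-specific signatures from labelled expression
#'
#' Convenience wrapper running \code{\link{cm1_scores}} and
#' \code{\link{select_candidates}} for every subtype present, then
#' \code{\link{remove_overlaps}}.
#'
#' @inheritParams cm1_scores
#' @param subtypes subtype names to process; defaults to all assigned labels.
#' @param k genes per direction per subtype before overlap removal.
#' @return A \code{tsp_signatures} list with the per-subtype CM1 tables in
#'   \code{attr(, "cm1_tables")}.
#' @export
discover_signatures <- function(expr, labels, subtypes = NULL, k = 4,
                                range_over = c("cells", "subtype_means")) {
  range_over <- match.arg(range_over)
  lab <- if (is.data.frame(labels))
    stats::setNames(labels$label, labels$unit_id) else labels
  if (is.null(subtypes))
    subtypes <- setdiff(sort(unique(lab)), "unassigned")
  tables <- lapply(subtypes, function(s)
    cm1_scores(expr, labels, s, range_over = range_over))
  names(tables) <- subtypes
  cand <- lapply(tables, select_candidates, k = k)
  sig <- remove_overlaps(cand)
  attr(sig, "cm1_tables") <- tables
  sig
}

#' Write a signature set as JSON
#'
#' @param sig a \code{tsp_signatures} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_signatures_json <- function(sig, path) {
  jsonlite::write_json(lapply(unclass(sig), function(df)
    df[, c("gene_id", "direction", "cm1")]), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature set from JSON
#'
#' @param path file written by \code{\link{write_signatures_json}}.
#' @return A \code{tsp_signatures} list.
#' @export
read_signatures_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, as.data.frame), class = "tsp_signatures")
}
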
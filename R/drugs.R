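#' Median split of cell lines by signature expression
#'
#' High group = strictly above the median; low = at or below. With an even
#' count of distinct values the split is balanced; ties at the median go to
#' the low group (deterministic).
#'
#' @param sig_expr named numeric vector, signature score or expression per
#'   cell line.
#' @return A list with character vectors \code{high} and \code{low} of line
#'   ids (indices when unnamed).
#' @export
median_split <- function(sig_expr) {
  stopifnot(length(sig_expr) >= 2)
  if (length(unique(sig_expr)) == 1) stop("all values identical; no split possible")
  med <- stats::median(sig_expr)
  ids <- if (is.null(names(sig_expr))) seq_along(sig_expr) else names(sig_expr)
  list(high = ids[sig_expr > med], low = ids[sig_expr <= med])
}

#' Compare IC50 between high- and low-expression groups for one drug
#'
#' Two-sided Mann-Whitney test of ln(IC50) values between the groups, with
#' exact enumeration for total n <= 12 (no ties) and the tie-corrected normal
#' approximation otherwise. Direction is the sign of
#' median(high) - median(low): negative means the high-expression group is
#' more sensitive (lower IC50), positive more resistant.
#'
#' @param groups a \code{\link{median_split}} result.
#' @param ic50 numeric matrix, lines x drugs (ln IC50; NAs allowed), or a
#'   named vector for a single drug.
#' @param drug drug (column) name when \code{ic50} is a matrix.
#' @return A list: \code{drug}, \code{statistic}, \code{p}, \code{direction}
#'   (-1/0/1), \code{n_high}, \code{n_low}; or, when a group has fewer than 2
#'   non-missing lines, a list with \code{skipped = TRUE} and a
#'   \code{reason}.
#' @export
compare_ic50 <- function(groups, ic50, drug = NULL) {
  vals <- if (is.matrix(ic50) || is.data.frame(ic50)) {
    if (is.null(drug)) stop("`drug` required when ic50 is a matrix")
    stats::setNames(as.numeric(ic50[, drug]), rownames(ic50))
  } else ic50
  hi <- vals[groups$high]; lo <- vals[groups$low]
  hi <- hi[!is.na(hi)]; lo <- lo[!is.na(lo)]
  if (length(hi) < 2 || length(lo) < 2)
    return(list(drug = drug, skipped = TRUE,
                reason = sprintf("fewer than 2 non-missing lines per group (%d high, %d low)",
                                 length(hi), length(lo))))
  if (length(unique(c(hi, lo))) == 1)
    return(list(drug = drug, statistic = length(hi) * length(lo) / 2, p = 1,
                direction = 0, n_high = length(hi), n_low = length(lo)))
  exact <- (length(hi) + length(lo)) <= 12 && !anyDuplicated(c(hi, lo))
  wt <- suppressWarnings(stats::wilcox.test(hi, lo, exact = exact,
                                            correct = !exact))
  list(drug = drug, statistic = unname(wt$statistic),
       p = min(wt$p.value, 1),
       direction = sign(stats::median(hi) - stats::median(lo)),
       n_high = length(hi), n_low = length(lo))
}

#' Spearman correlation between signature expression and drug response
#'
#' Spearman rho with average ranks for ties; two-sided p via the t
#' approximation. Positive rho: higher signature expression associates with
#' higher IC50, i.e. resistance; negative rho: sensitivity.
#'
#' @param sig_expr numeric vector per cell line.
#' @param ic50 numeric vector of ln IC50 per cell line (NAs dropped
#'   pairwise).
#' @return A list: \code{rho}, \code{p}, \code{n}.
#' @export
spearman_drug_corr <- function(sig_expr, ic50) {
  ok <- !is.na(sig_expr) & !is.na(ic50)
  x <- sig_expr[ok]; y <- ic50[ok]
  if (length(x) < 4) stop("need at least 4 paired non-missing values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input vector; Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = min(ct$p.value, 1), n = length(x))
}

#' Per-subtype drug-sensitivity screen
#'
#' For each subtype: restricts to that subtype's cell lines, scores them with
#' the subtype signature, median-splits, compares every drug's IC50 between
#' groups, and correlates the signature score with every drug's IC50.
#'
#' @param expr numeric matrix, cell lines x genes.
#' @param ic50 numeric matrix, cell lines x drugs (ln IC50, NAs allowed).
#' @param sig a \code{tsp_signatures} list.
#' @param line_subtype named character vector, subtype per cell line.
#' @param mode score aggregation mode.
#' @return data.frame with one row per (subtype, drug): test statistic, p,
#'   direction, Spearman rho and p, group sizes; skipped drugs carry NA
#'   statistics and the skip reason.
#' @export
drug_sensitivity_screen <- function(expr, ic50, sig, line_subtype,
                                    mode = "signed_mean") {
  stopifnot(!is.null(rownames(expr)), !is.null(rownames(ic50)))
  rows <- list()
  for (s in names(sig)) {
    lines <- names(line_subtype)[line_subtype == s]
    lines <- intersect(lines, intersect(rownames(expr), rownames(ic50)))
    if (length(lines) < 4) next
    score <- signature_score(expr[lines, , drop = FALSE], sig[[s]],
                             mode = mode)
    grp <- median_split(score)
    for (d in colnames(ic50)) {
      cmp <- compare_ic50(grp, ic50[lines, , drop = FALSE], d)
      rho <- tryCatch(
        spearman_drug_corr(score, ic50[lines, d]),
        error = function(e) list(rho = NA_real_, p = NA_real_, n = NA_integer_))
      rows[[length(rows) + 1]] <- data.frame(
        subtype = s, drug = d,
        statistic = if (isTRUE(cmp$skipped)) NA_real_ else cmp$statistic,
        p_split = if (isTRUE(cmp$skipped)) NA_real_ else cmp$p,
        direction = if (isTRUE(cmp$skipped)) NA_real_ else cmp$direction,
        rho = rho$rho, p_rho = rho$p,
        n_lines = length(lines),
        skipped = isTRUE(cmp$skipped),
        reason = if (isTRUE(cmp$skipped)) cmp$reason else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
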
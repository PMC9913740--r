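#' Shannon entropy of an expression vector, in bits
#'
#' Plug-in (maximum-likelihood) entropy over a histogram of
#' \code{n_bins} equal-width bins spanning the observed range. A constant
#' vector occupies a single bin and has entropy 0.
#'
#' @param values numeric vector (finite).
#' @param n_bins number of equal-width bins (>= 2).
#' @return Entropy in bits, between 0 and log2(n_bins).
#' @examples
#' gene_entropy(rep(1, 10), 10)          # 0
#' gene_entropy(seq(0, 1, length = 100), 10)  # ~ log2(10)
#' @export
gene_entropy <- function(values, n_bins = 10) {
  stopifnot(length(values) >= 1, n_bins >= 2)
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  # right-closed bins, lowest bin left-closed, matching cut(include.lowest)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(cut(values, breaks, include.lowest = TRUE, labels = FALSE),
                  nbins = n_bins)
  p <- cnt[cnt > 0] / length(values)
  -sum(p * log2(p))
}

#' Per-gene mean absolute inter-gene correlation
#'
#' For every gene in \code{gene_set}, the mean of |correlation| with every
#' other gene in the set, across cells. When the number of gene pairs exceeds
#' \code{max_pairs}, a seeded uniform subsample of pairs is used and each
#' gene's mean is taken over its sampled pairs. Genes constant across cells
#' have undefined correlations and are excluded with a warning.
#'
#' @param expr numeric matrix, cells x genes.
#' @param gene_set character vector of at least 2 gene ids.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param max_pairs cap on the number of gene pairs evaluated.
#' @param seed RNG seed for the pair subsample.
#' @return Named numeric vector, mean |corr| per (non-constant) gene.
#' @export
intergene_correlation <- function(expr, gene_set,
                                  method = c("spearman", "pearson"),
                                  max_pairs = Inf, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(gene_set) >= 2)
  missing <- setdiff(gene_set, colnames(expr))
  if (length(missing) > 0)
    stop("genes absent from expression matrix: ", paste(missing, collapse = ", "))
  sub <- expr[, gene_set, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s): ",
            paste(gene_set[sds == 0], collapse = ", "))
    sub <- sub[, sds > 0, drop = FALSE]
    if (ncol(sub) < 2) stop("fewer than 2 non-constant genes remain")
  }
  g <- ncol(sub)
  pairs <- utils::combn(g, 2)
  if (ncol(pairs) > max_pairs) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  cm <- abs(stats::cor(sub, method = method))
  sums <- numeric(g)
  cnts <- integer(g)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sums[i] <- sums[i] + cm[i, j]; cnts[i] <- cnts[i] + 1L
    sums[j] <- sums[j] + cm[i, j]; cnts[j] <- cnts[j] + 1L
  }
  keep <- cnts > 0
  stats::setNames(sums[keep] / cnts[keep], colnames(sub)[keep])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Compare signature genes to background genes on a per-gene metric
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of signature-gene metric
#' values against background-gene values. Exact enumeration is used when both
#' groups have at most 20 values and there are no ties; otherwise the normal
#' approximation with tie correction. If every value in both groups is
#' identical the p-value is 1 by convention.
#'
#' @param sig numeric vector of metric values for signature genes.
#' @param bg numeric vector of metric values for background genes.
#' @param metric_name label carried into the result.
#' @return A list with \code{metric_name}, \code{signature_values},
#'   \code{background_values}, \code{statistic} (Mann-Whitney U of the
#'   signature group) and \code{p_value}.
#' @export
compare_to_background <- function(sig, bg, metric_name = "metric") {
  stopifnot(length(sig) > 0, length(bg) > 0)
  if (length(unique(c(sig, bg))) == 1) {
    return(list(metric_name = metric_name, signature_values = sig,
                background_values = bg,
                statistic = length(sig) * length(bg) / 2, p_value = 1))
  }
  exact <- length(sig) <= 20 && length(bg) <= 20 &&
    !anyDuplicated(c(sig, bg))
  wt <- suppressWarnings(stats::wilcox.test(sig, bg, exact = exact,
                                            correct = !exact))
  list(metric_name = metric_name, signature_values = sig,
       background_values = bg,
       statistic = unname(wt$statistic), p_value = min(wt$p.value, 1))
}

#' Representativeness of a signature against background genes
#'
#' Computes three per-gene metrics on a log-normalized expression matrix --
#' mean expression, histogram entropy in bits, and mean absolute inter-gene
#' correlation -- for the pooled signature genes and for the background (all
#' other genes), and tests each metric with a two-sided rank-sum test.
#' Inter-gene correlation of the background is evaluated on random background
#' gene sets of the same size as the signature (seeded), since all-pairs
#' background correlation is both unpayable and structurally incomparable.
#'
#' @param expr numeric matrix, cells x genes.
#' @param sig a \code{tsp_signatures} list (gene lists pooled across
#'   subtypes).
#' @param n_bins histogram bins for the entropy metric.
#' @param n_background_sets number of random background gene sets for the
#'   correlation metric.
#' @param seed RNG seed for background sampling.
#' @param method correlation kind for the inter-gene metric.
#' @return A list of three \code{\link{compare_to_background}} results,
#'   named \code{mean_expression}, \code{entropy_bits},
#'   \code{intergene_corr}.
#' @export
representativeness <- function(expr, sig, n_bins = 10,
                               n_background_sets = 20, seed = 7,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  sig_genes <- unique(unlist(lapply(sig, `[[`, "gene_id"), use.names = FALSE))
  sig_genes <- intersect(sig_genes, colnames(expr))
  if (length(sig_genes) < 2) stop("fewer than 2 signature genes in `expr`")
  bg_genes <- setdiff(colnames(expr), sig_genes)
  if (length(bg_genes) < length(sig_genes))
    stop("background smaller than signature")

  mean_sig <- colMeans(expr[, sig_genes, drop = FALSE])
  mean_bg <- colMeans(expr[, bg_genes, drop = FALSE])
  ent_sig <- vapply(sig_genes, function(g) gene_entropy(expr[, g], n_bins), 0)
  ent_bg <- vapply(bg_genes, function(g) gene_entropy(expr[, g], n_bins), 0)

  cor_sig <- suppressWarnings(
    intergene_correlation(expr, sig_genes, method = method))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cor_bg <- unlist(lapply(seq_len(n_background_sets), function(i) {
    gs <- sample(bg_genes, length(sig_genes))
    suppressWarnings(intergene_correlation(expr, gs, method = method))
  }))

  list(
    mean_expression = compare_to_background(mean_sig, mean_bg,
                                            "mean_expression"),
    entropy_bits = compare_to_background(ent_sig, ent_bg, "entropy_bits"),
    intergene_corr = compare_to_background(cor_sig, cor_bg, "intergene_corr")
  )
}
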
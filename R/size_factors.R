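#' Pooling-deconvolution size factors
#'
#' Estimates one positive scaling factor per cell by summing cells into
#' overlapping pools and deconvolving the pooled estimates. Cells are placed
#' on a ring ordered by library size; for every pool size each window of
#' consecutive cells forms a pseudo-cell whose summed profile is compared,
#' gene by gene, against the average profile of all cells. The median of the
#' per-gene ratios estimates the sum of the member cells' factors, giving one
#' linear equation per pool. The overdetermined system is solved by least
#' squares and the solution rescaled to mean one. Pooling makes the per-pool
#' estimates robust to the zero inflation that breaks per-cell
#' median-of-ratios estimators on UMI data.
#'
#' If any solved factor is non-positive the function falls back to
#' library-size factors for all cells, with a warning; the result then carries
#' \code{attr(, "fallback") == TRUE}.
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @param pool_sizes integer vector of pool sizes, each at least 2; sizes
#'   exceeding the cell count are capped to it.
#' @param min_mean genes with average count below this are ignored when
#'   scaling pools against the average profile.
#' @return Named numeric vector of per-cell factors (mean 1), with attribute
#'   \code{fallback} (logical).
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(200 * 50, 5), 200, 50,
#'             dimnames = list(paste0("c", 1:200), paste0("g", 1:50)))
#' f <- compute_size_factors(tsp_counts(m), pool_sizes = c(11, 21))
#' stopifnot(abs(mean(f) - 1) < 1e-9)
#' @export
compute_size_factors <- function(m, pool_sizes = c(21, 41, 61, 81, 101),
                                 min_mean = 0.1) {
  stopifnot(inherits(m, "tsp_counts"), length(pool_sizes) >= 1)
  counts <- as.matrix(m$counts)
  n <- nrow(counts)
  pool_sizes <- sort(unique(pmin(as.integer(pool_sizes), n)))
  if (any(pool_sizes < 2)) stop("every pool size must be at least 2")
  if (n < min(pool_sizes)) stop("fewer cells than the smallest pool size")

  lib <- rowSums(counts)
  # ring ordered by library size; ties broken by cell id so the estimate is
  # invariant to the input ordering of the cells
  ord <- order(lib, rownames(counts))
  ref <- colMeans(counts)                # average profile of all cells
  use <- ref >= min_mean & ref > 0
  if (!any(use)) stop("no genes usable as reference for deconvolution")
  sub <- counts[ord, use, drop = FALSE]
  refu <- ref[use]

  # cumulative sums along the doubled ring give O(1) window sums
  cs <- rbind(0, apply(rbind(sub, sub[seq_len(max(pool_sizes) - 1), ,
                                      drop = FALSE]), 2, cumsum))
  rows <- vector("list", length(pool_sizes))
  rhs <- vector("list", length(pool_sizes))
  for (k in seq_along(pool_sizes)) {
    ps <- pool_sizes[k]
    pool_sums <- cs[seq_len(n) + ps, , drop = FALSE] -
      cs[seq_len(n), , drop = FALSE]
    ratios <- sweep(pool_sums, 2, refu, "/")
    rhs[[k]] <- apply(ratios, 1, stats::median)
    idx <- outer(seq_len(n) - 1L, seq_len(ps) - 1L, "+") %% n + 1L
    rows[[k]] <- idx                     # members (ring positions) per pool
  }
  n_eq <- length(pool_sizes) * n
  i <- rep(seq_len(n_eq), times = rep(pool_sizes, each = n))
  j <- unlist(lapply(rows, function(ix) as.integer(t(ix))))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n_eq, n))
  b <- unlist(rhs)

  ata <- as.matrix(Matrix::crossprod(A))
  atb <- as.numeric(Matrix::crossprod(A, b))
  sol <- tryCatch(solve(ata + diag(1e-8, n), atb), error = function(e) NULL)

  fallback <- is.null(sol) || any(!is.finite(sol)) || any(sol <= 0)
  if (fallback) {
    warning("deconvolution produced non-positive factors; ",
            "falling back to library-size factors")
    f <- lib / mean(lib)
  } else {
    f <- numeric(n)
    f[ord] <- sol
    f <- f / mean(f)
  }
  names(f) <- rownames(counts)
  attr(f, "fallback") <- fallback
  f
}

#' Library-size factors
#'
#' Per-cell total count divided by the mean total count.
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @return Named numeric vector of factors with mean 1.
#' @export
library_size_factors <- function(m) {
  lib <- Matrix::rowSums(m$counts)
  f <- as.numeric(lib) / mean(lib)
  names(f) <- rownames(m$counts)
  attr(f, "fallback") <- FALSE
  f
}

#' Normalize counts by size factors
#'
#' Divides each cell's counts by its size factor and applies log2(x + 1).
#' All downstream modules consume this scale.
#'
#' @param m a \code{\link{tsp_counts}} object.
#' @param f numeric vector of positive size factors, one per cell (any order,
#'   matched by name when named).
#' @return A dense numeric matrix, cells x genes, of log2 normalized
#'   expression.
#' @export
normalize_counts <- function(m, f) {
  stopifnot(inherits(m, "tsp_counts"))
  if (length(f) != nrow(m$counts))
    stop("need one size factor per cell")
  if (!is.null(names(f))) {
    if (!setequal(names(f), rownames(m$counts)))
      stop("size factor names do not match cell ids")
    f <- f[rownames(m$counts)]
  }
  if (any(!is.finite(f)) || any(f <= 0))
    stop("size factors must be positive and finite")
  expr <- log2(sweep(as.matrix(m$counts), 1, as.numeric(f), "/") + 1)
  dimnames(expr) <- dimnames(m$counts)
  expr
}
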
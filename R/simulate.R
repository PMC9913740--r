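#' Simulate a single-cell UMI count matrix with planted subtype markers
#'
#' Negative-binomial UMI counts for cells split across TNBCtype-4 subtypes.
#' Gene baseline means are log-normal (UMI-like mean-abundance spread), each
#' cell has a log-normal size factor, and every subtype gets disjoint sets of
#' planted up- and down-regulated marker genes whose means are shifted by
#' +/- \code{log_fc} (log2 units) in that subtype's cells:
#' counts ~ NB(mean = sf * baseline * 2^(+/- log_fc), dispersion), with
#' Var = mu + dispersion * mu^2. Centroids are the true per-subtype mean
#' log2 expression. A handful of non-protein-coding and
#' mitochondrial/ribosomal-named genes (never markers) exercise the QC
#' filters.
#'
#' The generator is a pure function of its arguments: the same (config, seed)
#' reproduces the output bit for bit, and the caller's RNG state is left
#' untouched.
#'
#' @param n_cells_per_subtype named integer vector, cells per subtype
#'   (default 4 subtypes BL1, BL2, LAR, M).
#' @param n_genes total genes.
#' @param n_markers_up,n_markers_down planted markers per direction per
#'   subtype (disjoint across subtypes).
#' @param log_fc marker shift in log2 units (0 gives a null matrix).
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param size_factor_sd sd of log true size factors.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of gene
#'   baseline means.
#' @param marker_min_baseline markers are planted on genes whose baseline
#'   mean is at least this many counts (left-truncated log-normal draw), so
#'   a planted fold change is detectable at UMI depth; matches the empirical
#'   fact that class-separation statistics select well-expressed genes.
#' @param n_other_biotype,n_excluded_prefix counts of decoy genes for the QC
#'   filters.
#' @param seed RNG seed.
#' @return A list: \code{counts} (a \code{\link{tsp_counts}}),
#'   \code{centroids} (genes x subtypes true mean log2 expression), and
#'   \code{truth} (markers per subtype with direction, true size factors,
#'   true labels, config and seed).
#' @export
simulate_counts <- function(n_cells_per_subtype = c(BL1 = 100, BL2 = 100,
                                                    LAR = 100, M = 100),
                            n_genes = 1000, n_markers_up = 4,
                            n_markers_down = 4, log_fc = 2,
                            dispersion = 0.5, size_factor_sd = 0.25,
                            baseline_meanlog = 0, baseline_sdlog = 1,
                            marker_min_baseline = 1,
                            n_other_biotype = 10, n_excluded_prefix = 6,
                            seed = 1) {
  stopifnot(log_fc >= 0, dispersion > 0, size_factor_sd >= 0)
  subtypes <- names(n_cells_per_subtype)
  if (is.null(subtypes)) stop("n_cells_per_subtype must be named by subtype")
  n_marker_total <- length(subtypes) * (n_markers_up + n_markers_down)
  if (n_marker_total + n_other_biotype + n_excluded_prefix > n_genes)
    stop("marker and decoy gene demand exceeds n_genes")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_cells <- sum(n_cells_per_subtype)
  labels <- rep(subtypes, n_cells_per_subtype)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  # decoy genes occupy the tail, markers the head: never overlapping
  biotype <- rep("protein_coding", n_genes)
  if (n_other_biotype > 0)
    biotype[seq(n_genes - n_other_biotype + 1, n_genes)] <- "lincRNA"
  if (n_excluded_prefix > 0) {
    pre <- rep(c("MT-", "RPL", "RPS"), length.out = n_excluded_prefix)
    idx <- seq(n_genes - n_other_biotype - n_excluded_prefix + 1,
               n_genes - n_other_biotype)
    gene_ids[idx] <- paste0(pre, seq_along(idx))
  }

  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  if (n_marker_total > 0 && marker_min_baseline > 0) {
    # inverse-CDF left truncation keeps the marker draw log-normal above the
    # detectability floor
    p0 <- stats::plnorm(marker_min_baseline, baseline_meanlog, baseline_sdlog)
    u <- stats::runif(n_marker_total, p0, 1)
    baseline[seq_len(n_marker_total)] <-
      stats::qlnorm(u, baseline_meanlog, baseline_sdlog)
  }
  sf <- stats::rlnorm(n_cells, 0, size_factor_sd)
  sf <- sf / mean(sf)

  markers <- list()
  ptr <- 1
  for (s in subtypes) {
    up <- gene_ids[seq_len(n_markers_up) + ptr - 1]; ptr <- ptr + n_markers_up
    dn <- gene_ids[seq_len(n_markers_down) + ptr - 1]; ptr <- ptr + n_markers_down
    markers[[s]] <- data.frame(
      gene_id = c(up, dn),
      direction = rep(c("up", "down"), c(n_markers_up, n_markers_down)),
      log_fc = rep(c(log_fc, -log_fc), c(n_markers_up, n_markers_down)),
      stringsAsFactors = FALSE)
  }

  # per-subtype mean profile (before size factors)
  mean_by_subtype <- matrix(rep(baseline, length(subtypes)), ncol = length(subtypes),
                            dimnames = list(gene_ids, subtypes))
  for (s in subtypes) {
    mk <- markers[[s]]
    mean_by_subtype[mk$gene_id, s] <-
      mean_by_subtype[mk$gene_id, s] * 2^mk$log_fc
  }

  mu <- t(mean_by_subtype[, labels, drop = FALSE]) * sf
  counts <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                  size = 1 / dispersion),
                   nrow = n_cells, ncol = n_genes,
                   dimnames = list(cell_ids, gene_ids))

  centroids <- log2(mean_by_subtype + 1)
  truth <- list(markers = markers, size_factors = stats::setNames(sf, cell_ids),
                labels = stats::setNames(labels, cell_ids),
                mean_by_subtype = mean_by_subtype,
                config = list(n_cells_per_subtype = n_cells_per_subtype,
                              n_genes = n_genes, n_markers_up = n_markers_up,
                              n_markers_down = n_markers_down, log_fc = log_fc,
                              dispersion = dispersion,
                              size_factor_sd = size_factor_sd),
                seed = seed)
  list(counts = tsp_counts(counts, gene_biotype = biotype,
                           cell_label = "Cancer Epithelial"),
       centroids = centroids, truth = truth)
}

#' Simulate a right-censored survival cohort from a proportional-hazards model
#'
#' Clinical covariates (age, tumor size, stage III vs I/II, chemotherapy,
#' hormone therapy) and a standard-normal signature score are drawn, event
#' times follow a Weibull-baseline proportional-hazards model by inverse
#' transform, and independent uniform censoring is tuned numerically to the
#' requested censoring rate. Optionally, samples x genes expression is
#' generated for a supplied signature with each gene loading on the true
#' score (direction-signed), so the cohort can be pushed through the scoring
#' and stratification pipeline.
#'
#' @param n cohort size.
#' @param betas named log-hazard-ratio vector over any of \code{score},
#'   \code{age}, \code{tumor_size}, \code{stage}, \code{chemotherapy},
#'   \code{hormone_therapy} (age and tumor_size effects are per unit of the
#'   standardized covariate used internally).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (time in months).
#' @param censoring_target fraction of censored samples in [0, 0.9].
#' @param sig_entry optional signature data.frame (gene_id, direction) for
#'   which expression is generated.
#' @param sig_noise_sd per-gene noise sd around the loaded score.
#' @param seed RNG seed.
#' @return A list: \code{cohort} (data.frame sample_id, time, event, score,
#'   age, tumor_size, stage, chemotherapy, hormone_therapy), \code{expr}
#'   (NULL or samples x genes matrix), \code{truth} (betas, achieved
#'   censoring, config, seed).
#' @export
simulate_survival <- function(n, betas = c(score = 0.7),
                              baseline_shape = 1.2, baseline_scale = 60,
                              censoring_target = 0.3, sig_entry = NULL,
                              sig_noise_sd = 0.5, seed = 1) {
  stopifnot(censoring_target >= 0, censoring_target <= 0.9)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  covs <- data.frame(
    score = stats::rnorm(n),
    age = stats::rnorm(n),               # standardized age
    tumor_size = stats::rnorm(n),        # standardized tumor size
    stage = stats::rbinom(n, 1, 0.3),    # 1 = stage III, 0 = I/II
    chemotherapy = stats::rbinom(n, 1, 0.5),
    hormone_therapy = stats::rbinom(n, 1, 0.4))
  unknown <- setdiff(names(betas), names(covs))
  if (length(unknown) > 0)
    stop("unknown covariates in betas: ", paste(unknown, collapse = ", "))
  lp <- as.numeric(as.matrix(covs[, names(betas), drop = FALSE]) %*% betas)

  # inverse transform for Weibull baseline: S0(t) = exp(-(t/scale)^shape)
  u <- stats::runif(n)
  t_event <- baseline_scale * (-log(u) / exp(lp))^(1 / baseline_shape)

  if (censoring_target == 0) {
    time <- t_event; event <- rep(1L, n); achieved <- 0
  } else {
    uc <- stats::runif(n)
    cens_rate <- function(cmax) mean(uc * cmax < t_event)
    # rate decreases from 1 to ~0 as cmax grows
    upper <- max(t_event) * 2
    while (cens_rate(upper) > censoring_target && upper < 1e9) upper <- upper * 2
    if (cens_rate(upper) > censoring_target) {
      warning(sprintf("censoring target %.2f unattainable; achieved %.2f",
                      censoring_target, cens_rate(upper)))
      cmax <- upper
    } else {
      cmax <- stats::uniroot(function(cm) cens_rate(cm) - censoring_target,
                             c(1e-8, upper))$root
    }
    cens <- uc * cmax
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    achieved <- mean(event == 0)
  }
  time <- pmax(time, 1e-8)

  cohort <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                       time = time, event = event, covs,
                       stringsAsFactors = FALSE)
  expr <- NULL
  if (!is.null(sig_entry)) {
    dirs <- ifelse(sig_entry$direction == "down", -1, 1)
    expr <- sapply(seq_len(nrow(sig_entry)), function(j)
      dirs[j] * covs$score + stats::rnorm(n, 0, sig_noise_sd))
    dimnames(expr) <- list(cohort$sample_id, sig_entry$gene_id)
  }
  list(cohort = cohort, expr = expr,
       truth = list(betas = betas, achieved_censoring = achieved,
                    config = list(n = n, baseline_shape = baseline_shape,
                                  baseline_scale = baseline_scale,
                                  censoring_target = censoring_target),
                    seed = seed))
}

#' Simulate cell lines with planted signature-drug associations
#'
#' A latent standard-normal signature level per cell line and one ln(IC50)
#' vector per drug are drawn from a Gaussian copula calibrated so the
#' population Spearman correlation between signature and each drug equals
#' the planted value (rho_pearson = 2 sin(pi * rho_s / 6)). With
#' |planted_rho| = 1 the pair is exactly co/antimonotone. Signature gene
#' expression is the direction-signed latent level plus optional noise.
#'
#' @param n_lines number of cell lines (default 26, split 6/8/4/6 across
#'   BL1/BL2/LAR/M plus 2 unassigned, as a GDSC-like TNBC panel).
#' @param planted_rho named numeric vector, target Spearman rho per drug, in
#'   [-1, 1].
#' @param sig_entry signature data.frame (gene_id, direction) used to emit
#'   an expression matrix.
#' @param subtype_split named integer vector summing to \code{n_lines}.
#' @param noise_sd per-gene expression noise sd (0 keeps the signed z-mean
#'   score exactly monotone in the latent level).
#' @param seed RNG seed.
#' @return A list: \code{expr} (lines x genes), \code{sig_level} (latent
#'   signature level per line), \code{ic50} (lines x drugs), \code{subtype}
#'   (named vector), \code{truth}.
#' @export
simulate_cell_lines <- function(n_lines = 26,
                                planted_rho = c(drugA = -0.6, drugB = 0.6,
                                                drugC = 0),
                                sig_entry = data.frame(
                                  gene_id = paste0("SG", 1:6),
                                  direction = rep(c("up", "down"), 3)),
                                subtype_split = c(BL1 = 6, BL2 = 8, LAR = 4,
                                                  M = 6, unassigned = 2),
                                noise_sd = 0, seed = 1) {
  stopifnot(all(abs(planted_rho) <= 1), sum(subtype_split) == n_lines)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  line_ids <- sprintf("line%02d", seq_len(n_lines))
  subtype <- stats::setNames(rep(names(subtype_split), subtype_split),
                             line_ids)
  z0 <- stats::rnorm(n_lines)
  r <- 2 * sin(pi * planted_rho / 6)     # Pearson latent giving Spearman rho
  ic50 <- sapply(seq_along(planted_rho), function(d) {
    if (abs(planted_rho[d]) == 1) sign(planted_rho[d]) * z0
    else r[d] * z0 + sqrt(1 - r[d]^2) * stats::rnorm(n_lines)
  })
  dimnames(ic50) <- list(line_ids, names(planted_rho))

  dirs <- ifelse(sig_entry$direction == "down", -1, 1)
  expr <- sapply(seq_len(nrow(sig_entry)), function(j)
    dirs[j] * z0 + if (noise_sd > 0) stats::rnorm(n_lines, 0, noise_sd) else 0)
  dimnames(expr) <- list(line_ids, sig_entry$gene_id)

  list(expr = expr, sig_level = stats::setNames(z0, line_ids), ic50 = ic50,
       subtype = subtype,
       truth = list(planted_rho = planted_rho, subtype_split = subtype_split,
                    config = list(n_lines = n_lines, noise_sd = noise_sd),
                    seed = seed))
}
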
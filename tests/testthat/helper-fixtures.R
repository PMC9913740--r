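# Small deterministic fixtures shared across test files.

# random count matrix with named dims
rand_counts <- function(n_cells, n_genes, lambda = 3, seed = 1,
                        biotype = "protein_coding") {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  tsp_counts(m, gene_biotype = biotype)
}

# four-subtype centroid matrix with orthogonal-ish block patterns
toy_centroids <- function(n_genes = 40, seed = 2) {
  set.seed(seed)
  cen <- matrix(rnorm(n_genes * 4, mean = 2, sd = 1), n_genes, 4,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                c("BL1", "BL2", "LAR", "M")))
  blk <- split(seq_len(n_genes), rep(1:4, length.out = n_genes))
  for (k in 1:4) cen[blk[[k]], k] <- cen[blk[[k]], k] + 3
  cen
}

# independent product-limit estimator: explicit per-event-time loop
km_by_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    n_at <- sum(time >= ut[i])
    s <- s * (1 - d / n_at)
    out$surv[i] <- s
  }
  out
}

# independent two-group log-rank O/E/V: explicit loop over event times
logrank_by_hand <- function(time, event, grp1) {
  ut <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V, chisq = (O1 - E1)^2 / V)
}

# Efron partial log-likelihood for a single covariate, explicit loops
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sr <- sum(exp(beta * x[R]))
    sd_ <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sr - (l / d) * sd_)
  }
  ll
}
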
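make_labelled_expr <- function(n_in = 5, n_out = 6, genes = 3, seed = 1) {
  set.seed(seed)
  expr <- matrix(rnorm((n_in + n_out) * genes), n_in + n_out, genes,
                 dimnames = list(sprintf("c%02d", seq_len(n_in + n_out)),
                                 sprintf("g%02d", seq_len(genes))))
  labels <- setNames(rep(c("A", "B"), c(n_in, n_out)), rownames(expr))
  list(expr = expr, labels = labels)
}

test_that("CM1 matches its closed form on flat groups", {
  d <- make_labelled_expr()
  d$expr[, 1] <- rep(c(3, 1), c(5, 6))           # out-class range 0
  d$expr[, 2] <- rep(2, 11)                      # identical distributions
  tab <- cm1_scores(d$expr, d$labels, "A")
  expect_equal(tab$cm1[1], (3 - 1) / (1 + 0))
  expect_equal(tab$cm1[2], 0)
  expect_equal(tab$y_max[1], 1)
  expect_equal(tab$y_min[1], 1)
})

test_that("CM1 table equals a per-gene scalar-loop oracle", {
  set.seed(23)
  expr <- matrix(rnorm(200 * 50, 2), 200, 50,
                 dimnames = list(sprintf("c%03d", 1:200),
                                 sprintf("g%03d", 1:50)))
  labels <- setNames(sample(c("BL1", "BL2", "LAR", "M", "unassigned"), 200,
                            replace = TRUE), rownames(expr))
  tab <- cm1_scores(expr, labels, "BL2")
  for (j in seq_len(50)) {
    x <- expr[labels == "BL2", j]
    y <- expr[labels %in% c("BL1", "LAR", "M"), j]
    expect_equal(tab$cm1[j],
                 (mean(x) - mean(y)) / (1 + (max(y) - min(y))),
                 tolerance = 1e-10)
  }
  # invariant of the table itself
  expect_equal(tab$cm1, (tab$x_bar - tab$y_bar) / (1 + (tab$y_max - tab$y_min)),
               tolerance = 1e-12)
})

test_that("unassigned cells are excluded from both CM1 groups", {
  d <- make_labelled_expr(4, 4, 2)
  lab2 <- d$labels
  lab2[5:6] <- "unassigned"
  tab <- cm1_scores(d$expr, lab2, "A")
  x <- d$expr[1:4, 1]; y <- d$expr[7:8, 1]
  expect_equal(tab$cm1[1], (mean(x) - mean(y)) / (1 + max(y) - min(y)))
})

test_that("CM1 is invariant to adding a constant and mirrors under swap", {
  d <- make_labelled_expr(6, 6, 8, seed = 4)
  t1 <- cm1_scores(d$expr, d$labels, "A")
  t2 <- cm1_scores(d$expr + 5.5, d$labels, "A")
  expect_equal(t1$cm1, t2$cm1, tolerance = 1e-12)

  # equal-range mirror: group B = group A shifted per gene, so the in- and
  # out-class ranges coincide and swapping roles flips the sign exactly
  set.seed(4)
  base <- matrix(rnorm(6 * 8), 6, 8)
  delta <- rnorm(8, 0, 2)
  expr <- rbind(base, sweep(base, 2, delta, "+"))
  dimnames(expr) <- list(sprintf("c%02d", 1:12), sprintf("g%02d", 1:8))
  labels <- setNames(rep(c("A", "B"), each = 6), rownames(expr))
  tA <- cm1_scores(expr, labels, "A")
  tB <- cm1_scores(expr, labels, "B")
  expect_equal(tB$cm1, -tA$cm1, tolerance = 1e-12)
})

test_that("the subtype-means denominator variant is selectable and differs", {
  set.seed(31)
  expr <- matrix(rnorm(120 * 10, 2), 120, 10,
                 dimnames = list(sprintf("c%03d", 1:120),
                                 sprintf("g%02d", 1:10)))
  labels <- setNames(rep(c("BL1", "BL2", "LAR", "M"), each = 30),
                     rownames(expr))
  t_cells <- cm1_scores(expr, labels, "BL1", range_over = "cells")
  t_means <- cm1_scores(expr, labels, "BL1", range_over = "subtype_means")
  # per-cell ranges dominate per-subtype-mean ranges
  expect_true(all(t_cells$y_max - t_cells$y_min >=
                    t_means$y_max - t_means$y_min))
  om <- sapply(c("BL2", "LAR", "M"), function(s)
    colMeans(expr[labels == s, ]))
  expect_equal(t_means$y_max, unname(apply(om, 1, max)), tolerance = 1e-12)
})

test_that("candidate selection applies rank and sign rules literally", {
  # all-nonnegative scores: the top k become "up" genes, but every "down"
  # candidate fails the cm1 < 0 sign guard and is dropped
  tab <- data.frame(gene_id = paste0("g", 0:9), subtype = "A",
                    cm1 = 9:0, x_bar = 0, y_bar = 0, y_max = 0, y_min = 0,
                    stringsAsFactors = FALSE)
  expect_warning(sel <- select_candidates(tab, k = 4), "sign")
  expect_equal(sel$gene_id[sel$direction == "up"], paste0("g", 0:3))
  expect_equal(sum(sel$direction == "down"), 0)
})

test_that("down candidates with negative scores survive; zero is dropped", {
  tab <- data.frame(gene_id = sprintf("g%02d", 1:9), subtype = "A",
                    cm1 = c(5, 4, 3, 2, 1, 0, -1, -2, -3),
                    x_bar = 0, y_bar = 0, y_max = 0, y_min = 0,
                    stringsAsFactors = FALSE)
  expect_warning(sel <- select_candidates(tab, k = 4), "sign")
  expect_equal(sel$gene_id[sel$direction == "up"],
               c("g01", "g02", "g03", "g04"))
  # bottom four are {0, -1, -2, -3}; the zero fails the down sign guard
  expect_equal(sel$gene_id[sel$direction == "down"],
               c("g09", "g08", "g07"))
  expect_equal(nrow(sel), 7)
})

test_that("rank ties at the boundary resolve lexicographically", {
  tab <- data.frame(gene_id = c("gB", "gA", "gC", "gD", "gE"), subtype = "A",
                    cm1 = c(3, 3, 3, -1, -2),
                    x_bar = 0, y_bar = 0, y_max = 0, y_min = 0,
                    stringsAsFactors = FALSE)
  sel <- select_candidates(tab, k = 2)
  expect_equal(sel$gene_id[sel$direction == "up"], c("gA", "gB"))
  expect_error(select_candidates(tab[1:3, ], k = 2), "at least")
})

test_that("overlap removal yields disjoint lists and preserves order", {
  mk <- function(g) data.frame(gene_id = g,
                               direction = rep(c("up", "down"),
                                               length.out = length(g)),
                               cm1 = seq(2, -2, length.out = length(g)),
                               stringsAsFactors = FALSE)
  disjoint <- list(A = mk(paste0("a", 1:8)), B = mk(paste0("b", 1:8)),
                   C = mk(paste0("c", 1:8)), D = mk(paste0("d", 1:8)))
  out <- remove_overlaps(disjoint)
  expect_equal(lapply(unclass(out), `[[`, "gene_id"),
               lapply(disjoint, `[[`, "gene_id"))

  shared <- list(A = mk(c("G", "a1", "a2")), B = mk(c("b1", "G", "b2")))
  out2 <- remove_overlaps(shared)
  expect_false("G" %in% unlist(lapply(out2, `[[`, "gene_id")))
  expect_equal(nrow(out2$A), 2)
  expect_equal(nrow(out2$B), 2)
})

test_that("engineered overlaps reproduce the 4/6/6/6 size pattern", {
  # list 1 shares 4 genes (2 with list 2, 1 with list 3, 1 with list 4);
  # lists 3 and 4 additionally share 1 gene, so lists 2-4 lose 2 genes each.
  mk <- function(g) data.frame(gene_id = g,
                               direction = "up", cm1 = 1,
                               stringsAsFactors = FALSE)
  l1 <- c("s12a", "s12b", "s13", "s14", "u11", "u12", "u13", "u14")
  l2 <- c("s12a", "s12b", "u21", "u22", "u23", "u24", "u25", "u26")
  l3 <- c("s13", "s34", "u31", "u32", "u33", "u34", "u35", "u36")
  l4 <- c("s14", "s34", "u41", "u42", "u43", "u44", "u45", "u46")
  cand <- list(BL1 = mk(l1), BL2 = mk(l2), LAR = mk(l3), M = mk(l4))
  out <- remove_overlaps(cand)
  sizes <- vapply(out, nrow, 0L)
  # independent set-arithmetic oracle
  all_g <- c(l1, l2, l3, l4)
  dup <- unique(all_g[duplicated(all_g)])
  oracle <- vapply(list(l1, l2, l3, l4),
                   function(g) sum(!g %in% dup), 0L)
  expect_equal(unname(sizes), oracle)
  expect_equal(unname(sizes), c(4L, 6L, 6L, 6L))
})

test_that("overlap removal is independent of subtype order", {
  mk <- function(g) data.frame(gene_id = g, direction = "up", cm1 = 1,
                               stringsAsFactors = FALSE)
  cand <- list(A = mk(c("x", "a")), B = mk(c("x", "b")), C = mk(c("c", "a")))
  # list A loses both genes: the emptied-signature warning is expected
  expect_warning(o1 <- remove_overlaps(cand), "emptied")
  expect_warning(o2 <- remove_overlaps(rev(cand)), "emptied")

  for (s in names(o1))
    expect_equal(o1[[s]]$gene_id, o2[[s]]$gene_id)
})

test_that("planted markers top their own subtype's ranking on clean data", {
  sim <- simulate_counts(n_cells_per_subtype = c(BL1 = 60, BL2 = 60,
                                                 LAR = 60, M = 60),
                         n_genes = 300, log_fc = 3, dispersion = 0.1,
                         size_factor_sd = 0, seed = 19)
  ex <- normalize_counts(sim$counts, library_size_factors(sim$counts))
  labels <- sim$truth$labels
  for (s in names(sim$truth$markers)) {
    tab <- cm1_scores(ex, labels, s)
    up <- sim$truth$markers[[s]]
    up <- up$gene_id[up$direction == "up"]
    top <- tab$gene_id[order(-tab$cm1)][seq_along(up)]
    expect_setequal(top, up)
  }
})
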
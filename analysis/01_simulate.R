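#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a single-cell UMI cohort with planted
# subtype markers, a bulk validation cohort with survival outcomes tied to a
# signature score, and a GDSC-like cell-line panel with planted drug
# associations. Everything downstream reads from results/.

library(tspsig)

seed <- 20260924
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("single-cell cohort: 4 subtypes x 300 cells, 2000 genes, ",
        "4 up + 4 down markers per subtype at log-FC 2")
sc <- simulate_counts(
  n_cells_per_subtype = c(BL1 = 300, BL2 = 300, LAR = 300, M = 300),
  n_genes = 2000, n_markers_up = 4, n_markers_down = 4,
  log_fc = 2, dispersion = 0.5, size_factor_sd = 0.25, seed = seed)
write_counts_10x(sc$counts, "results/data/sc_counts")
write.csv(data.frame(gene_id = rownames(sc$centroids), sc$centroids),
          "results/data/centroids.csv", row.names = FALSE)
jsonlite::write_json(
  list(markers = sc$truth$markers, seed = sc$truth$seed),
  "results/data/sc_truth.json", auto_unbox = TRUE, digits = NA)

message("bulk validation cohort: n = 400, planted score log-HR 1.1, ",
        "stage/age/chemotherapy effects, 30% censoring")
sig_template <- data.frame(gene_id = paste0("SG", 1:6),
                           direction = rep(c("up", "down"), 3))
sv <- simulate_survival(
  400, betas = c(score = 1.1, age = 0.3, stage = 0.5, chemotherapy = -0.2),
  censoring_target = 0.3, sig_entry = sig_template, seed = seed + 1)
write.csv(sv$cohort, "results/data/clinical.csv", row.names = FALSE)
write.csv(data.frame(sample_id = rownames(sv$expr), sv$expr),
          "results/data/bulk_expr.csv", row.names = FALSE)

message("cell-line panel: 26 lines (6/8/4/6 + 2 unassigned), ",
        "7 drugs with planted Spearman structure")
cl <- simulate_cell_lines(
  n_lines = 26,
  planted_rho = c(PF4708671 = -0.6, Linifanib = -0.5, SN38 = 0.6,
                  PARP_0108 = 0.5, Avagacestat = -0.4, AZD7762 = -0.6,
                  Pictilisib = 0.5),
  noise_sd = 0.2, seed = seed + 2)
write.csv(data.frame(line_id = rownames(cl$expr), cl$expr),
          "results/data/line_expr.csv", row.names = FALSE)
write.csv(data.frame(line_id = rownames(cl$ic50), cl$ic50),
          "results/data/ic50.csv", row.names = FALSE)
write.csv(data.frame(line_id = names(cl$subtype), subtype = cl$subtype),
          "results/data/line_subtypes.csv", row.names = FALSE)

message("wrote results/data/: sc_counts/ (10x-style), centroids.csv, ",
        "clinical.csv, bulk_expr.csv, line_expr.csv, ic50.csv, ",
        "line_subtypes.csv")
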
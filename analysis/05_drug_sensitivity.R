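#!/usr/bin/env Rscript
# Associate signature expression with drug response on the cell-line panel:
# per-subtype median split + rank-sum comparison of ln(IC50), and Spearman
# correlation between signature score and each drug's ln(IC50).

library(tspsig)

le <- read.csv("results/data/line_expr.csv")
expr <- as.matrix(le[, -1])
rownames(expr) <- le[[1]]
ic <- read.csv("results/data/ic50.csv")
ic50 <- as.matrix(ic[, -1])
rownames(ic50) <- ic[[1]]
subs <- read.csv("results/data/line_subtypes.csv")
line_subtype <- setNames(subs$subtype, subs$line_id)

sig_entry <- data.frame(gene_id = paste0("SG", 1:6),
                        direction = rep(c("up", "down"), 3))
sigs <- structure(
  setNames(rep(list(sig_entry), 4), c("BL1", "BL2", "LAR", "M")),
  class = "tsp_signatures")

res <- drug_sensitivity_screen(expr, ic50, sigs, line_subtype)
res$significant <- !res$skipped & res$p_rho < 0.05
print(res[, c("subtype", "drug", "p_split", "direction", "rho", "p_rho",
              "significant")], digits = 3, row.names = FALSE)
n_sig <- sum(res$significant, na.rm = TRUE)
message(sprintf(
  "%d / %d subtype-drug pairs significantly correlated (p < 0.05); %s",
  n_sig, nrow(res),
  "negative rho = sensitivity, positive = resistance"))
write.csv(res, "results/drug_sensitivity.csv", row.names = FALSE)
message("wrote results/drug_sensitivity.csv")
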
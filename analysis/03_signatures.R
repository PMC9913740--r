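#!/usr/bin/env Rscript
# Score every gene per subtype with the CM1 statistic, select top/bottom
# candidates, remove cross-subtype overlaps to obtain the TSPSigs, check the
# result against the planted truth, and run the representativeness
# comparison against background genes.

library(tspsig)

ed <- read.csv("results/normalized_expr.csv", check.names = FALSE)
expr <- as.matrix(ed[, -1])
rownames(expr) <- ed[[1]]
assign <- read.csv("results/subtype_assignments.csv")

sig <- discover_signatures(expr, assign, k = 4)
print(sig)

cm1_tabs <- attr(sig, "cm1_tables")
write.csv(do.call(rbind, cm1_tabs), "results/cm1_scores.csv",
          row.names = FALSE)
write_signatures_json(sig, "results/signatures.json")

truth <- jsonlite::read_json("results/data/sc_truth.json",
                             simplifyVector = TRUE)
for (s in names(sig)) {
  planted <- truth$markers[[s]]$gene_id
  got <- sig[[s]]$gene_id
  message(sprintf("%s: %d/%d selected genes are planted markers", s,
                  sum(got %in% planted), length(got)))
}

rep_res <- representativeness(expr, sig, n_bins = 10, seed = 7)
summ <- data.frame(
  metric = names(rep_res),
  signature_mean = sapply(rep_res, function(r) mean(r$signature_values)),
  background_mean = sapply(rep_res, function(r) mean(r$background_values)),
  statistic = sapply(rep_res, `[[`, "statistic"),
  p_value = sapply(rep_res, `[[`, "p_value"))
print(summ, digits = 3, row.names = FALSE)
write.csv(summ, "results/representativeness.csv", row.names = FALSE)
message("wrote results/cm1_scores.csv, signatures.json, ",
        "representativeness.csv")
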
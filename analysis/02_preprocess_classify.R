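#!/usr/bin/env Rscript
# QC-filter the single-cell counts, estimate deconvolution size factors,
# normalize, and assign every cell to a TNBCtype-4 subtype by centroid
# correlation.

library(tspsig)

counts <- read_counts_10x("results/data/sc_counts")
message(sprintf("loaded %d cells x %d genes", nrow(counts$counts),
                ncol(counts$counts)))

counts <- filter_genes(counts, keep_biotypes = "protein_coding",
                       exclude_prefixes = c("MT-", "RPL", "RPS"),
                       min_cells = 3)
counts <- filter_cells(counts, min_genes = 50)
message(sprintf("after QC: %d cells x %d genes", nrow(counts$counts),
                ncol(counts$counts)))

f <- compute_size_factors(counts)
message(sprintf("size factors: range %.2f-%.2f, deconvolution %s",
                min(f), max(f),
                if (attr(f, "fallback")) "fell back to library size"
                else "solved"))
write.csv(data.frame(cell_id = names(f), factor = as.numeric(f)),
          "results/size_factors.csv", row.names = FALSE)

expr <- normalize_counts(counts, f)

cen_df <- read.csv("results/data/centroids.csv")
cen <- as.matrix(cen_df[, -1])
rownames(cen) <- cen_df$gene_id

assign <- classify_subtypes(expr, cen, method = "pearson")
tabulated <- table(assign$label)
message("subtype assignment: ",
        paste(sprintf("%s=%d", names(tabulated), tabulated), collapse = ", "))
write.csv(assign, "results/subtype_assignments.csv", row.names = FALSE)

# pass the normalized matrix along as plain CSV for the signature step
write.csv(data.frame(cell_id = rownames(expr), expr, check.names = FALSE),
          "results/normalized_expr.csv", row.names = FALSE)
message("wrote results/size_factors.csv, subtype_assignments.csv, ",
        "normalized_expr.csv")
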
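#!/usr/bin/env Rscript
# Step 2 — balance the simulated maps, compare conditions, and quantify
# the range of cis contacts along the chromosome.
#
# SCN-balances the WT-like and matP-null-like maps from step 1, writes
# their log2 ratio (Gaussian sigma 1 bin), computes the per-bin range of
# cis contacts (robust threshold, >=30-point components, diamond-5
# closing, perpendicular width x 5 kb / 2), and summarizes the range
# inside vs outside the insulated Ter interval.

suppressMessages(library(terscope))

wt <- scn_normalize(read_matrix_tsv("results/map_wt_raw.tsv"))
mut <- scn_normalize(read_matrix_tsv("results/map_matP_raw.tsv"))

ratio <- log_ratio_map(mut, wt, sigma = 1)
utils::write.table(round(ratio$matrix, 4), "results/ratio_matP_over_wt.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

range_of <- function(nm, label) {
  wp <- diagonal_width_profile(significance_mask(nm))
  write_bedgraph(data.frame(start = (seq_along(wp$range_kb) - 1) * 5000,
                            end = seq_along(wp$range_kb) * 5000,
                            value = wp$range_kb),
                 sprintf("results/range_%s.bedgraph", label))
  wp
}
wp_wt <- range_of(wt, "wt")
wp_mut <- range_of(mut, "matP")

ter <- c(160, 240); outside <- c(270, 130)
rows <- rbind(
  data.frame(map = "WT-like", region = "Ter",
             summarize_range(wp_wt, ter)[c("q25", "median", "q75",
                                           "n_bins")]),
  data.frame(map = "WT-like", region = "outside",
             summarize_range(wp_wt, outside)[c("q25", "median", "q75",
                                               "n_bins")]),
  data.frame(map = "matP-null-like", region = "Ter",
             summarize_range(wp_mut, ter)[c("q25", "median", "q75",
                                            "n_bins")]),
  data.frame(map = "matP-null-like", region = "outside",
             summarize_range(wp_mut, outside)[c("q25", "median", "q75",
                                                "n_bins")]))
utils::write.table(rows, "results/range_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("range of cis contacts (kb):\n")
print(rows, row.names = FALSE)
cat("\nIn the WT-like map the insulated Ter shows a markedly smaller\n",
    "median range than the rest of the chromosome; the matP-null-like\n",
    "map shows no such contrast, and its ratio map is enriched (red)\n",
    "over Ter. Summary written to results/range_summary.tsv\n", sep = "")
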
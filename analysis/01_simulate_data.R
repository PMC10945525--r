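#!/usr/bin/env Rscript
# Step 1 — simulate the study's data types.
#
# Two Hi-C-like contact maps of a 2-Mb circular chromosome at 5-kb bins:
# a "WT-like" map in which a 500-kb Ter interval has a 4x reduced contact
# range (lambda 50 kb vs 200 kb elsewhere, emulating MatP/matS inhibition
# of MukBEF-driven long-range contacts) plus two CID boundaries, and a
# "matP-null-like" map with uniform lambda and the same CID structure.
# Also: a ChIP experiment with 3x replication-following enrichment
# excluded from Ter, and a genome with a matS cluster around dif.

suppressMessages(library(terscope))
dir.create("results", showWarnings = FALSE)

L <- 2e6; bin <- 5000; N <- L / bin          # 400 bins
ter_bins <- c(150, 250)                       # 500 kb Ter interval

lam <- rep(2e5, N)
wt <- gen_contact_map(chrom_length = L, bin_size = bin, lambda = 2e5,
                      ter_interval = ter_bins, ter_lambda_factor = 0.25,
                      cid_boundaries = c(60, 330), insulation = 0.5,
                      depth = 400, seed = 101)
mut <- gen_contact_map(chrom_length = L, bin_size = bin, lambda = 2e5,
                       cid_boundaries = c(60, 330), insulation = 0.5,
                       depth = 400, seed = 102)

write_matrix_tsv(wt, "results/map_wt_raw.tsv")
write_matrix_tsv(mut, "results/map_matP_raw.tsv")
cat(sprintf("wrote raw maps: %d x %d bins, %.0f / %.0f total contacts\n",
            N, N, sum(wt$matrix) / 2, sum(mut$matrix) / 2))

chip <- gen_chip_experiment(chrom_length = L,
                            replicated_interval = c(0, 1e6),
                            enrichment_fold = 3,
                            ter_excluded_interval = c(75e4, 125e4),
                            peaks = data.frame(
                              center = c(8e5, 9e5, 12e5),
                              fold = c(15, 20, 25),
                              width = c(40, 50, 60)),
                            depth = 100, seed = 103)
saveRDS_like <- function(tr, path) {       # plain-text per-bp dump, binned
  write_bedgraph(bin_track(tr, 1000), path)
}
saveRDS_like(chip$ip, "results/chip_ip_1kb.bedgraph")
saveRDS_like(chip$input, "results/chip_input_1kb.bedgraph")
cat("wrote ChIP IP/input coverage (1-kb binned bedGraph)\n")

# genome with 20 matS in an 800-kb Ter region centered on dif at 1 Mb
sites <- sort(round(seq(6.2e5, 1.38e6, length.out = 20) / 10) * 10)
gen <- gen_genome(L, planted_sites = sites, dif = 1e6, seed = 104)
write_fasta(c(synthetic_chromosome = gen$sequence),
            "results/genome_synthetic.fa")
write_bed(data.frame(start = sites, end = sites + 13,
                     name = sprintf("matS_%02d", seq_along(sites))),
          "results/matS_planted.bed")
cat(sprintf("wrote synthetic genome (%d bp) with %d planted matS\n",
            nchar(gen$sequence), length(sites)))

# per-bp ChIP tracks are regenerated by later steps from the same seeds;
# only binned summaries are kept on disk to stay plain-text and small
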
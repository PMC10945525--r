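#!/usr/bin/env Rscript
# Step 4 — ChIP enrichment, smoothing and peak calling.
#
# Regenerates the step-1 ChIP experiment at per-bp resolution (same
# seed), normalizes IP against input by total counts, smooths with a
# 50-kb sliding window for the regional picture, and calls peaks with
# the 10x-background / 30-bp rule on the unsmoothed enrichment. Peak
# sequences (center +/- 50 bp) are extracted for external motif tools.

suppressMessages(library(terscope))

L <- 2e6
chip <- gen_chip_experiment(chrom_length = L,
                            replicated_interval = c(0, 1e6),
                            enrichment_fold = 3,
                            ter_excluded_interval = c(75e4, 125e4),
                            peaks = data.frame(
                              center = c(8e5, 9e5, 12e5),
                              fold = c(15, 20, 25),
                              width = c(40, 50, 60)),
                            depth = 100, seed = 103)

enr <- normalize_tracks(chip$ip, chip$input)
sm <- smooth_track(enr, 5e4)
write_bedgraph(bin_track(sm, 5000), "results/chip_enrichment_50kb.bedgraph")

peaks <- call_peaks(enr)
write_bed(data.frame(start = peaks$start, end = peaks$end,
                     name = sprintf("peak_%d", seq_len(nrow(peaks))),
                     score = round(peaks$max_fold, 1)),
          "results/chip_peaks.bed")

genome <- read_fasta("results/genome_synthetic.fa")[[1]]
write_fasta(peak_sequences(peaks, genome, flank = 50),
            "results/chip_peak_sequences.fa")

med_repl <- median(sm$values[1:5e5], na.rm = TRUE)
med_ter <- median(sm$values[9e5:11e5], na.rm = TRUE)
med_unrepl <- median(sm$values[13e5:2e6], na.rm = TRUE)
cat(sprintf("smoothed enrichment medians: replicated %.2f, Ter %.2f, unreplicated %.2f\n",
            med_repl, med_ter, med_unrepl))
cat(sprintf("%d peaks called (planted narrow sites at 800, 900 and 1200 kb):\n",
            nrow(peaks)))
print(peaks, row.names = FALSE)
cat("\nThe replicated half shows ~3x the enrichment of the\n",
    "unreplicated half, and the Ter-excluded window sits at baseline,\n",
    "reproducing the replication-following / Ter-excluded pattern.\n",
    sep = "")
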
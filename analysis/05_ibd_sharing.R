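#!/usr/bin/env Rscript
# Step 5: IBD segment post-processing.
#
# Consensus of the ten synthetic fastIBD runs (majority coverage), genetic-map
# interpolation, removal of tracts under 1 cM, 7 cM long-tract labeling,
# per-pair and cross-population sharing summaries, IBD occurrence in 10 cM
# windows, and the permutation test for overlap of the top-5% windows with the
# selected-region intervals (a hotspot was planted inside one of them at
# simulation time).

library(maizedemog)

dir.create("results/ibd", showWarnings = FALSE, recursive = TRUE)
inp <- "results/synthetic"
map <- read_genetic_map(file.path(inp, "map.tsv"))
pops <- read_pops(file.path(inp, "pops.tsv"))
runs <- lapply(sprintf("%s/ibd_run%02d.tsv", inp, 1:10), read_ibd)
cat(sprintf("loaded 10 runs, %.0f segments each on average\n",
            mean(vapply(runs, nrow, 0))))

cons <- consensus_ibd(runs)
cat(sprintf("majority (>5/10) consensus: %d segments\n", nrow(cons)))
seg <- ibd_add_cM(cons, map)
seg <- filter_short(seg, min_cM = 1.0)
seg <- classify_long(seg, thr_cM = 7.0)
cat(sprintf("after 1 cM filter: %d segments, %d long (> 7 cM)\n",
            nrow(seg), sum(seg$long)))
utils::write.table(seg, "results/ibd/consensus_segments.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

sh <- pair_sharing(seg, pops)
utils::write.table(sh$per_pair, "results/ibd/pair_sharing.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sh$pop_means, "results/ibd/pop_means.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("mean per-pair sharing (cM, zero-sharing pairs included):\n")
print(sh$pop_means)

n_ts <- sum(pops == "TS"); n_nss <- sum(pops == "NSS")
cross <- seg[pops[seg$sampleA] != pops[seg$sampleB], , drop = FALSE]
track <- hotspot_occurrence(cross, map, pairs = n_ts * n_nss, window_cM = 10)
utils::write.table(track, "results/ibd/hotspot_track.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
top <- track[order(-track$occurrence), ][1:3, ]
cat("top cross-population windows:\n")
print(top[, c("chrom", "start_cM", "end_cM", "occurrence")])

regions <- read_bed(file.path(inp, "selected_regions.bed"))
ovl <- overlap_permutation_test(track, regions, map, top_q = 0.95,
                                n_perm = 999, seed = 55)
cat(sprintf("top-5%% windows overlapping selected regions: %.1f%% (P = %.3f)\n",
            100 * ovl$overlap_fraction, ovl$p_value))
writeLines(c(sprintf("overlap_fraction %.6f", ovl$overlap_fraction),
             sprintf("p_value %.6f", ovl$p_value),
             sprintf("n_top %d", ovl$n_top)),
           "results/ibd/overlap_test.txt")
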
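#!/usr/bin/env Rscript
# Step 4: population characterization.
#
# Windowed Weir-Cockerham Fst between the tropical and temperate panels and
# population-specific SNP counts come from the SFS panel (its sites are
# unlinked by construction); the LD statistics (r2 of adjacent SNPs, decay
# distance at the r2 = 0.1 cutoff, greedy pruning) run on a separate
# haplotype-block panel that carries planted linkage; the kinship filter is
# demonstrated on the same panel with a spiked-in duplicate line.

library(maizedemog)

dir.create("results/popstats", showWarnings = FALSE, recursive = TRUE)
v <- load_variants("results/synthetic/panel.vcf")
pops <- read_pops("results/synthetic/pops.tsv")

fst <- wc_fst_windows(v, pops, "TS", "NSS",
                      window_bp = 1e6, step_bp = 2e5, min_seg = 30)
utils::write.table(fst, "results/popstats/fst_windows.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Fst: %d windows, %d defined, median %.4f (global %.4f)\n",
            nrow(fst), sum(!is.na(fst$fst)),
            stats::median(fst$fst, na.rm = TRUE),
            wc_fst_global(v, pops, "TS", "NSS")))

spec <- pop_specific_snps(v, pops, sample_n = 50, reps = 10, seed = 27)
utils::write.table(spec$summary, "results/popstats/pop_specific.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("population-specific SNPs: %.1f%% of sites; per-population means:\n",
            100 * spec$mean_frac_specific))
print(spec$summary)

ld_panel <- simulate_ld_panel(n_samples = 100, n_snps = 400, n_founders = 4,
                              block_len = 5, noise_rate = 0.05,
                              spacing_bp = 100, seed = 33)
pairs <- ld_r2_adjacent(ld_panel, k = 10)
decay <- ld_decay_distance(pairs, r2_cut = 0.1, dist_bin_bp = 100)
utils::write.table(pairs, "results/popstats/ld_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(decay$r2_bins, "results/popstats/ld_r2_bins.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("LD decay distance (r2 <= 0.1): %s bp%s\n",
            format(round(decay$decay_bp)),
            if (decay$censored) " (right-censored)" else ""))
pruned <- ld_prune(ld_panel, r2_thresh = 0.2, window_bp = 5e5)
cat(sprintf("LD pruning: %d -> %d SNPs\n", length(ld_panel$pos),
            length(pruned$pos)))

dup <- ld_panel
dup$geno <- cbind(dup$geno, dup$geno[, 1])
dup$samples <- c(dup$samples, "dup_of_s1")
colnames(dup$geno) <- dup$samples
kept <- kinship_filter(dup, threshold = 0.5, seed = 41)
cat(sprintf("kinship filter (> 0.5): removed %s\n",
            paste(attr(kept, "removed"), collapse = ", ")))
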
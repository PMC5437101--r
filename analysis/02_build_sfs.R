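#!/usr/bin/env Rscript
# Step 2: build the observed joint SFS from the synthetic VCF.
#
# Mirrors the study's data processing: keep synonymous SNPs, drop sites in
# regions under selection, thin to >= 2 kb spacing in ten random replicates,
# and project the allele counts to the analysis sample sizes. The spectrum of
# the first thinning replicate drives the model fits; retention across
# replicates is reported alongside.

library(maizedemog)

inp <- "results/synthetic"
dir.create("results/sfs", showWarnings = FALSE, recursive = TRUE)

v <- load_variants(file.path(inp, "panel.vcf"))
pops <- read_pops(file.path(inp, "pops.tsv"))
cat(sprintf("loaded %d SNPs x %d lines\n", length(v$pos), ncol(v$geno)))

v_syn <- filter_synonymous(v)
cat(sprintf("synonymous: %d (%.1f%%)\n", length(v_syn$pos),
            100 * length(v_syn$pos) / length(v$pos)))

v_clean <- exclude_regions(v_syn, read_bed(file.path(inp, "selected_regions.bed")))
cat(sprintf("outside selected regions: %d\n", length(v_clean$pos)))

thins <- thin_variants(v_clean, min_bp = 2000, reps = 10, seed = 91)
ret <- vapply(thins, function(t) length(t$pos), 0L)
cat(sprintf("thinning (2 kb, 10 replicates): retained %.1f%% +- %.2f%%\n",
            mean(ret) / length(v_clean$pos) * 100,
            stats::sd(ret) / length(v_clean$pos) * 100))

proj <- c(20, 20)
sfs <- joint_sfs_from_genotypes(thins[[1]], pops, pop_pair = c("TS", "NSS"),
                                proj = proj, polarization = "unfolded")
write_sfs(sfs, "results/sfs/observed.sfs")
cat(sprintf("joint SFS %dx%d: %.0f sites of unmasked mass (%d dropped) -> %s\n",
            proj[1], proj[2], sfs_total(sfs), attr(sfs, "dropped_sites"),
            "results/sfs/observed.sfs"))
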
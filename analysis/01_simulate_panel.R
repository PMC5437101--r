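#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Emits a desk-scale stand-in for the maize inbred-line panel: a VCF of
# unlinked biallelic SNPs drawn from the two-bottleneck split model at its
# reference parameters (80 tropical + 80 temperate lines) on ten 125 Mb
# chromosomes (~100 cM each at the 0.8 cM/Mb baseline), a BED of
# "selected-region" intervals, a jittered genetic map, and ten noisy
# detector runs over one IBD truth set. Hotspots are planted inside the
# first selected region of chr3 and chr8 (echoing the bins where selection
# signals cluster) plus chr1, so the downstream overlap test has signal.

library(maizedemog)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20170518

cfg <- sim_config(params = split5_reference_fit()$scaled,
                  n_snps = 20000, n1 = 80, n2 = 80,
                  chrom_lengths = setNames(rep(125e6, 10), paste0("chr", 1:10)),
                  sel_region_frac = 0.02,
                  ibd_rate = 2, ibd_mean_cM = 3,
                  hotspot_enrichment = 10,
                  mc_replicates = 20000, seed = seed)

cat("simulating genotype panel under the reference split model...\n")
sim <- simulate_genotypes(cfg, out_dir = out)
cat(sprintf("  %d SNPs x %d lines -> %s\n", nrow(sim$truth),
            length(sim$pops), sim$vcf_path))
cat(sprintf("  %d selected-region intervals -> %s\n", nrow(sim$regions),
            sim$bed_path))

map <- simulate_map(cfg, out_path = file.path(out, "map.tsv"))
cat(sprintf("  genetic map: %d anchors, %.0f cM total\n", nrow(map),
            sum(tapply(map$pos_cM, map$chrom, max))))

# plant IBD hotspots over the selected region of five chromosomes, aligned
# to the 10 cM analysis windows so the enrichment lands where the region is
hot <- do.call(rbind, lapply(c("chr1", "chr3", "chr5", "chr8", "chr9"),
               function(ch) {
  r <- sim$regions[sim$regions$chrom == ch, ][1, ]
  mid <- as.numeric(interpolate_cM(map, ch, (r$start + r$end) / 2))
  w0 <- floor(mid / 10) * 10
  data.frame(chrom = ch, start_cM = w0, end_cM = w0 + 10)
}))
cfg$hotspots <- hot

ibd <- simulate_ibd_runs(cfg, names(sim$pops), map, n_runs = 10,
                         out_paths = file.path(out, sprintf("ibd_run%02d.tsv",
                                                            1:10)))
cat(sprintf("  IBD: %d truth segments, 10 noisy detector runs\n",
            nrow(ibd$truth)))
cat(sprintf("  hotspots planted at: %s\n",
            paste(sprintf("%s:%.0f-%.0f cM", hot$chrom, hot$start_cM,
                          hot$end_cM), collapse = ", ")))
cat("done; inputs under", out, "\n")
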
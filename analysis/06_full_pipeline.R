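#!/usr/bin/env Rscript
# Step 6: the same analysis as steps 2-5 through the single orchestrated
# entry point, exercising the stage sequencing, logging and summary output.

library(maizedemog)

inp <- "results/synthetic"
rc <- run_config(vcf = file.path(inp, "panel.vcf"),
                 pops_file = file.path(inp, "pops.tsv"),
                 regions_bed = file.path(inp, "selected_regions.bed"),
                 map_file = file.path(inp, "map.tsv"),
                 ibd_files = sprintf("%s/ibd_run%02d.tsv", inp, 1:10),
                 models = "split1",
                 mu = 2.230e-8, L = 3.8e6,
                 projection = c(20, 20), polarization = "unfolded",
                 engine_replicates = 10000, seed = 2718,
                 out_dir = "results/full_run")
res <- run_full(rc)
cat(readLines("results/full_run/summary.txt"), sep = "\n")
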
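#!/usr/bin/env Rscript
# Step 3: fit demographic models to the observed joint SFS and compare them.
#
# Fits the simple split (split1), the split with an ancestral size change
# (split2) and the full two-bottleneck linear-decline model (split5, started
# from the reference parameter set), profiles theta analytically at every
# evaluation, and reports log-likelihoods, AIC ranking and the declared
# nested likelihood-ratio tests. Scaled estimates of the best model are
# converted to physical units via theta = 4*Na*mu*L.

library(maizedemog)

dir.create("results/fits", showWarnings = FALSE, recursive = TRUE)
mu <- 2.230e-8
L <- 3.8e6
sfs <- read_sfs("results/sfs/observed.sfs")
cat(sprintf("observed SFS mass: %.0f\n", sfs_total(sfs)))

cfg <- coalescent_config(10000, seed = 314)
fits <- list()

cat("fitting split1 (instantaneous sizes, symmetric gene flow)...\n")
fits$split1 <- fit_model("split1", sfs, engine = "mc", cfg = cfg,
                         max_eval = 200)

cat("fitting split2 (adds an ancestral size change)...\n")
fits$split2 <- fit_model("split2", sfs, engine = "mc", cfg = cfg,
                         max_eval = 200)

cat("fitting split5 (double bottleneck + linear decline), from the reference start...\n")
ref <- split5_reference_fit()$scaled$params
fits$split5 <- fit_model("split5", sfs, engine = "mc", cfg = cfg,
                         starts = list(ref, ref * 2), max_eval = 200)

cmp <- compare_models(fits)
print(cmp$table)
utils::write.table(cmp$table, "results/fits/model_comparison.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(cmp$lrt)) {
  print(cmp$lrt)
  utils::write.table(cmp$lrt, "results/fits/model_lrt.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

best <- fits[[cmp$table$model[1]]]
cat(sprintf("best model by AIC: %s (loglik %.2f)\n", best$model_id, best$loglik))
write_params(best$params, "results/fits/best_scaled.params")
phys <- to_physical(best$params, mu, L)
write_params(phys, "results/fits/best_physical.params")
cat(sprintf("implied ancestral size Na = %.0f individuals\n", phys$Na))
cat("parameter files under results/fits/\n")
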
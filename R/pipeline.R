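#' Declared nesting graph among the demographic models
#'
#' Likelihood-ratio tests are computed only for these (null, alternative)
#' pairs; degrees of freedom are the difference in free parameter counts.
#'
#' @return data.frame (null, alt, df)
#' @export
nested_model_pairs <- function() {
  pairs <- rbind(
    c("neutral", "two_epoch"), c("neutral", "three_epoch"),
    c("two_epoch", "three_epoch"),
    c("split1", "split2"), c("split1", "split3"), c("split1", "split4"),
    c("split2", "split5"), c("split3", "split5"))
  data.frame(null = pairs[, 1], alt = pairs[, 2],
             df = vapply(seq_len(nrow(pairs)), function(i)
               length(model_param_names(pairs[i, 2])) -
                 length(model_param_names(pairs[i, 1])), 0L))
}

#' Model comparison table
#'
#' @param fits named list of [fit_model()] results
#' @return list: \code{table} (model, k, loglik, AIC, dAIC; increasing
#'   AIC), \code{lrt} (nested pairs present among the fits, with statistic
#'   and p-value)
#' @export
compare_models <- function(fits) {
  tab <- data.frame(model = vapply(fits, `[[`, "", "model_id"),
                    k = vapply(fits, `[[`, 0L, "k"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    AIC = vapply(fits, `[[`, 0, "aic"))
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  np <- nested_model_pairs()
  have <- np$null %in% tab$model & np$alt %in% tab$model
  lr <- NULL
  if (any(have)) {
    np <- np[have, , drop = FALSE]
    ids <- vapply(fits, `[[`, "", "model_id")
    lr <- do.call(rbind, lapply(seq_len(nrow(np)), function(i) {
      f0 <- fits[[which(ids == np$null[i])[1]]]
      f1 <- fits[[which(ids == np$alt[i])[1]]]
      stat <- max(0, 2 * (f1$loglik - f0$loglik))
      data.frame(null = np$null[i], alt = np$alt[i], df = np$df[i],
                 statistic = stat,
                 p_value = tryCatch(lrt(f0$loglik, f1$loglik, np$df[i]),
                                    error = function(e) NA_real_))
    }))
  }
  list(table = tab, lrt = lr)
}

log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(...)))
}

#' Run configuration for the full pipeline
#'
#' @param vcf path to the SNP VCF
#' @param pops_file two-column sample/population TSV
#' @param mu substitution rate per bp per generation
#' @param L effective sequence length, bp
#' @param regions_bed optional BED of regions to exclude (and to test
#'   hotspot overlap against)
#' @param map_file optional genetic-map TSV (required for IBD analyses)
#' @param ibd_files optional character vector of IBD run TSVs
#' @param models model ids to fit
#' @param pop_pair the two population labels, (pop1, pop2)
#' @param projection projected haplotype counts
#' @param polarization \code{"folded"} or \code{"unfolded"}
#' @param thin_min_bp,thin_reps distance thinning settings
#' @param engine_replicates Monte Carlo replicates per spectrum evaluation
#' @param seed master seed; every stage derives its own stream from it
#' @param out_dir output directory
#' @return validated config list, class \code{run_config}
#' @export
run_config <- function(vcf, pops_file, mu, L, regions_bed = NULL,
                       map_file = NULL, ibd_files = NULL,
                       models = c("split1", "split5"),
                       pop_pair = c("TS", "NSS"), projection = c(20, 20),
                       polarization = "folded",
                       thin_min_bp = 2000, thin_reps = 10,
                       engine_replicates = 20000, seed, out_dir) {
  if (missing(mu) || is.null(mu)) stop("config field missing: mu")
  if (missing(L) || is.null(L)) stop("config field missing: L")
  if (missing(seed) || is.null(seed)) stop("config field missing: seed")
  for (f in c(vcf, pops_file, regions_bed, map_file, ibd_files))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  models <- vapply(models, match.arg, "", choices = model_ids())
  structure(list(vcf = vcf, pops_file = pops_file, mu = mu, L = L,
                 regions_bed = regions_bed, map_file = map_file,
                 ibd_files = ibd_files, models = unname(models),
                 pop_pair = pop_pair, projection = projection,
                 polarization = polarization,
                 thin_min_bp = thin_min_bp, thin_reps = thin_reps,
                 engine_replicates = engine_replicates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: build the observed joint SFS (synonymous filter, selected-region
#' exclusion, distance thinning, projection) -> fit the requested models by
#' Poisson composite likelihood -> model comparison (AIC order, nested
#' LRTs) -> population characterization (windowed Fst, population-specific
#' SNPs, LD decay) -> IBD analyses (consensus, length filter, sharing,
#' hotspots, overlap permutation test). Every table is written to
#' \code{out_dir} together with a flat key-value summary; a stage failure
#' aborts with the stage name while earlier outputs remain on disk.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with the per-stage results
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    log_msg("stage %s: start", name)
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_msg("stage %s: done", name)
    out
  }
  summary_kv <- c(sprintf("seed %d", config$seed))

  res$sfs <- stage("build-sfs", {
    v <- load_variants(config$vcf)
    pops <- read_pops(config$pops_file)
    v <- filter_synonymous(v)
    n_syn <- n_variants(v)
    if (!is.null(config$regions_bed))
      v <- exclude_regions(v, read_bed(config$regions_bed))
    thins <- thin_variants(v, min_bp = config$thin_min_bp,
                           reps = config$thin_reps, seed = config$seed)
    retention <- mean(vapply(thins, n_variants, 0L)) / n_variants(v)
    sfs <- joint_sfs_from_genotypes(thins[[1]], pops,
                                    pop_pair = config$pop_pair,
                                    proj = config$projection,
                                    polarization = config$polarization)
    write_sfs(sfs, file.path(config$out_dir, "observed.sfs"))
    summary_kv <<- c(summary_kv,
                     sprintf("n_synonymous %d", n_syn),
                     sprintf("n_after_exclusion %d", n_variants(v)),
                     sprintf("thin_retention %.4f", retention),
                     sprintf("sfs_mass %.4f", sfs_total(sfs)))
    list(sfs = sfs, variants = v, thins = thins, pops = pops)
  })

  res$fits <- stage("fit", {
    fits <- list()
    for (m in config$models) {
      cfg <- coalescent_config(config$engine_replicates,
                               seed = config$seed + 17L)
      fits[[m]] <- fit_model(m, res$sfs$sfs, engine = "auto", cfg = cfg)
      write_params(fits[[m]]$params,
                   file.path(config$out_dir, sprintf("fit_%s.params", m)))
      summary_kv <<- c(summary_kv,
                       sprintf("loglik_%s %.6f", m, fits[[m]]$loglik))
    }
    fits
  })

  res$comparison <- stage("compare", {
    cmp <- compare_models(res$fits)
    utils::write.table(cmp$table,
                       file.path(config$out_dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cmp$lrt))
      utils::write.table(cmp$lrt, file.path(config$out_dir, "model_lrt.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    best <- res$fits[[cmp$table$model[1]]]
    phys <- tryCatch({
      bp <- best$params; to_physical(bp, config$mu, config$L)
    }, error = function(e) NULL)
    if (!is.null(phys))
      write_params(phys, file.path(config$out_dir, "best_physical.params"))
    summary_kv <<- c(summary_kv, sprintf("best_model %s", cmp$table$model[1]))
    cmp
  })

  res$popstats <- stage("popstats", {
    v <- res$sfs$variants
    pops <- res$sfs$pops
    fst <- wc_fst_windows(v, pops, config$pop_pair[1], config$pop_pair[2])
    utils::write.table(fst, file.path(config$out_dir, "fst_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ld <- ld_r2_adjacent(v)
    decay <- if (nrow(ld)) ld_decay_distance(ld) else NULL
    if (nrow(ld))
      utils::write.table(ld, file.path(config$out_dir, "ld_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    sizes <- table(unname(pops[names(pops) %in% v$samples]))
    sn <- min(50, sizes)
    spec <- pop_specific_snps(v, pops, sample_n = sn,
                              seed = config$seed + 23L)
    utils::write.table(spec$summary,
                       file.path(config$out_dir, "pop_specific_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(decay) && !is.na(decay$decay_bp))
      summary_kv <<- c(summary_kv, sprintf("ld_decay_bp %.1f", decay$decay_bp))
    summary_kv <<- c(summary_kv,
                     sprintf("frac_pop_specific %.4f", spec$mean_frac_specific))
    list(fst = fst, ld = ld, decay = decay, specific = spec)
  })

  if (!is.null(config$ibd_files) && !is.null(config$map_file)) {
    res$ibd <- stage("ibd", {
      map <- read_genetic_map(config$map_file)
      runs <- lapply(config$ibd_files, read_ibd)
      seg <- if (length(runs) > 1L) consensus_ibd(runs) else runs[[1]]
      seg <- ibd_add_cM(seg, map)
      seg <- filter_short(seg, 1.0)
      seg <- classify_long(seg, 7.0)
      utils::write.table(seg, file.path(config$out_dir, "ibd_segments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      pops <- res$sfs$pops
      sharing <- pair_sharing(seg, pops)
      utils::write.table(sharing$per_pair,
                         file.path(config$out_dir, "ibd_pair_sharing.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      n1 <- sum(pops == config$pop_pair[1])
      n2 <- sum(pops == config$pop_pair[2])
      cross <- seg[pops[seg$sampleA] != pops[seg$sampleB], , drop = FALSE]
      track <- hotspot_occurrence(cross, map, pairs = n1 * n2)
      utils::write.table(track, file.path(config$out_dir, "ibd_hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ovl <- NULL
      if (!is.null(config$regions_bed)) {
        ovl <- overlap_permutation_test(track, read_bed(config$regions_bed),
                                        map, seed = config$seed + 31L)
        summary_kv <<- c(summary_kv,
                         sprintf("ibd_overlap_fraction %.4f", ovl$overlap_fraction),
                         sprintf("ibd_overlap_p %.4f", ovl$p_value))
      }
      list(segments = seg, sharing = sharing, track = track, overlap = ovl)
    })
  }

  writeLines(summary_kv, file.path(config$out_dir, "summary.txt"))
  log_msg("pipeline complete: %s", config$out_dir)
  invisible(res)
}
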
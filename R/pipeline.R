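# End-to-end orchestration. Stages communicate only through plain files in
# the output directory, so any stage can be re-run or inspected in
# isolation; a manifest records the configuration, seeds and output hashes.

#' Pipeline configuration
#'
#' Collects the constants the pipeline stages share. Defaults follow the
#' analysis they implement: `B = 250` bootstrap replicates per condition,
#' `k_top_genes = 50` for the heme response score, `kmeans_k = 2`
#' pseudocytometry clusters, and `epsilon_tbars = 156` mM^-1 cm^-1.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param B Bootstrap replicates per condition.
#' @param k_top_genes Heme response score set size.
#' @param kmeans_k Pseudocytometry cluster count (fixed at 2).
#' @param epsilon_tbars Molar absorptivity for the TBARS conversion.
#' @param n_images Synthetic images generated for the pseudocytometry
#'   stage.
#' @param cells_per_image,apoptotic_fraction Image-generator settings.
#' @param n_genes,samples_per_condition Count-generator settings.
#' @param presets Preset table; default [default_presets()].
#' @param out_dir Output directory.
#' @param config_file Optional YAML file of flat key-value overrides,
#'   applied over the defaults before the explicit arguments.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, B = 250L, k_top_genes = 50L,
                            kmeans_k = 2L, epsilon_tbars = 156,
                            n_images = 4L, cells_per_image = 80L,
                            apoptotic_fraction = 0.5,
                            n_genes = 3000L, samples_per_condition = 8L,
                            presets = default_presets(),
                            out_dir = tempfile("hemoscape_run_"),
                            config_file = NULL) {
  cfg <- list(seed = seed, B = B, k_top_genes = k_top_genes,
              kmeans_k = kmeans_k, epsilon_tbars = epsilon_tbars,
              n_images = n_images, cells_per_image = cells_per_image,
              apoptotic_fraction = apoptotic_fraction,
              n_genes = n_genes,
              samples_per_condition = samples_per_condition,
              presets = presets, out_dir = out_dir)
  if (!is.null(config_file)) {
    overrides <- yaml::read_yaml(config_file)
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0L)
      stop("unknown configuration keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    supplied <- names(match.call())[-1]
    for (nm in setdiff(names(overrides), supplied))
      cfg[[nm]] <- overrides[[nm]]
  }
  num <- c("seed", "B", "k_top_genes", "kmeans_k", "epsilon_tbars",
           "n_images", "cells_per_image", "n_genes",
           "samples_per_condition")
  for (nm in num)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("'", nm, "' must be a positive number", call. = FALSE)
  if (cfg$kmeans_k != 2L)
    stop("'kmeans_k' is fixed at 2 for the two-population classifier",
         call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

.stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order — synthetic-data generation,
#' pseudocytometry, biochemical conversion, gene-set scoring, bootstrap
#' PCA — writing every stage output as plain files under
#' `config$out_dir`, and finishes with a manifest (configuration echo,
#' derived stage seeds, file MD5 hashes). An identical configuration
#' reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.yml`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                sprintf(fmt, ...)))
  }
  files <- character(0)
  keep <- function(f) { files <<- c(files, f); f }

  # --- synthetic_data: readout pools -------------------------------------
  t0 <- proc.time()[["elapsed"]]
  pools <- tryCatch({
    utils::write.csv(config$presets, keep(out("presets.csv")),
                     row.names = FALSE)
    pl <- pools_from_presets(config$presets, seed = derive_seed(config$seed, 1))
    long <- do.call(rbind, lapply(names(pl$pools), function(cond)
      do.call(rbind, lapply(names(pl$pools[[cond]]), function(r)
        data.frame(condition = cond, readout = r,
                   value = pl$pools[[cond]][[r]],
                   stringsAsFactors = FALSE)))))
    utils::write.csv(long, keep(out("pools.csv")), row.names = FALSE)
    pl
  }, error = function(e) .stage_fail("synthetic_data", e))
  say("synthetic_data: %d pool values", sum(config$presets$n))

  # --- pseudocytometry ---------------------------------------------------
  cyto <- tryCatch({
    results <- lapply(seq_len(config$n_images), function(i) {
      spec <- synthetic_image_spec(
        n_cells = config$cells_per_image,
        apoptotic_fraction = config$apoptotic_fraction,
        seed = derive_seed(config$seed, 100 + i))
      img <- generate_image(spec)
      for (ch in c("nuclei", "neun", "casp3"))
        write_channel_tiff(img[[ch]],
                           keep(out(sprintf("image%02d_%s.tif", i, ch))))
      cells <- segment_cells(img$nuclei, img$neun, img$casp3)
      classify_cells(cells, seed = derive_seed(config$seed, 200 + i))
    })
    all_cells <- do.call(rbind, lapply(seq_along(results), function(i)
      cbind(image = sprintf("image%02d", i), results[[i]]$cells)))
    utils::write.csv(all_cells, keep(out("cells.csv")), row.names = FALSE)
    frac <- apoptotic_fraction_by_image(results)
    utils::write.csv(frac, keep(out("apoptotic_fractions.csv")),
                     row.names = FALSE)
    frac
  }, error = function(e) .stage_fail("pseudocytometry", e))
  say("pseudocytometry: %d images, mean apoptotic fraction %.3f",
      nrow(cyto), attr(cyto, "pooled")[["mean"]])

  # --- biochem -----------------------------------------------------------
  tbars <- tryCatch({
    ab <- with_seed(derive_seed(config$seed, 300), {
      data.frame(sample_id = sprintf("s%02d", 1:12),
                 a532 = stats::runif(12, 0.02, 0.30),
                 a600 = stats::runif(12, 0.005, 0.02),
                 protein_g = stats::runif(12, 5e-4, 2e-3))
    })
    m <- tbars_measurement(ab$a532, ab$a600, epsilon = config$epsilon_tbars)
    ab$mda_um <- mda_concentration(m)
    ab$mda_um_per_g <- normalize_to_protein(ab$mda_um, ab$protein_g)
    utils::write.csv(ab, keep(out("tbars.csv")), row.names = FALSE)
    ab
  }, error = function(e) .stage_fail("biochem", e))
  say("biochem: %d TBARS conversions", nrow(tbars))

  # --- genescores --------------------------------------------------------
  scores <- tryCatch({
    design <- synthetic_count_design(
      n_genes = config$n_genes,
      samples_per_condition = config$samples_per_condition,
      seed = derive_seed(config$seed, 400))
    sim <- generate_counts(design)
    utils::write.table(sim$counts, keep(out("counts.tsv")), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.csv(sim$samples, keep(out("samples.csv")),
                     row.names = FALSE)
    v <- vst_counts(sim$counts)
    contrast <- sim$samples$condition %in% c("Ctrl", "HemeAlb")
    de <- rank_de(v[, contrast], sim$samples$condition[contrast],
                  treatment = "HemeAlb", control = "Ctrl")
    utils::write.csv(de, keep(out("de_heme_albumin.csv")),
                     row.names = FALSE)
    stress_set <- build_score_set(de, k = config$k_top_genes)
    # curated stand-in sets: halves of the simulated programs
    hs <- sim$truth$gene[sim$truth$program == "heme_stress"]
    hm <- sim$truth$gene[sim$truth$program == "heme_metab"]
    curated <- list(nrf2 = hs[seq_len(length(hs) %/% 2)],
                    heme_metab = hm[seq_len(length(hm) %/% 2)],
                    iron_transport = hm[(length(hm) %/% 2 + 1):length(hm)])
    write_gmt(c(list(heme_stress = stress_set), curated),
              keep(out("gene_sets.gmt")))
    sets <- read_gmt(out("gene_sets.gmt"))
    tabs <- lapply(names(sets), function(nm) {
      s <- score_samples(v, sets[[nm]], set_name = nm)
      data.frame(sample = names(s$score),
                 condition = sim$samples$condition,
                 set_name = nm, score = unname(s$score),
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, tabs), keep(out("scores.csv")),
                     row.names = FALSE)
    r2 <- score_correlation(score_samples(v, sets$heme_stress, "heme_stress"),
                            score_samples(v, sets$nrf2, "nrf2"))
    list(sets = sets, r2_stress_nrf2 = r2)
  }, error = function(e) .stage_fail("genescores", e))
  say("genescores: heme response set of %d genes, stress~nrf2 r^2 = %.3f",
      length(scores$sets$heme_stress), scores$r2_stress_nrf2)

  # --- bootpca -----------------------------------------------------------
  fit <- tryCatch({
    f <- boot_pca(pools, B = config$B, seed = derive_seed(config$seed, 500))
    utils::write.csv(cbind(condition = f$pca$condition_labels,
                           as.data.frame(f$pseudoslices$values)),
                     keep(out("pseudoslices.csv")), row.names = FALSE)
    utils::write.csv(as.data.frame(coef(f)), keep(out("loadings.csv")))
    utils::write.csv(data.frame(component = colnames(coef(f)),
                                explained_fraction = f$pca$explained_fraction),
                     keep(out("explained_variance.csv")), row.names = FALSE)
    utils::write.csv(merge(f$centroids, f$states, by = "condition",
                           sort = FALSE),
                     keep(out("centroids.csv")), row.names = FALSE)
    f
  }, error = function(e) .stage_fail("bootpca", e))
  say("bootpca: %d pseudoslices, PC1 %.1f%%, PC2 %.1f%%",
      nrow(fit$pca$scores), 100 * fit$pca$explained_fraction[1],
      100 * fit$pca$explained_fraction[2])

  manifest <- list(
    package_version = as.character(utils::packageVersion("hemoscape")),
    seed = config$seed,
    stage_seeds = list(pools = derive_seed(config$seed, 1),
                       images = derive_seed(config$seed, 101),
                       tbars = derive_seed(config$seed, 300),
                       counts = derive_seed(config$seed, 400),
                       bootpca = derive_seed(config$seed, 500)),
    config = config[setdiff(names(config), c("presets", "out_dir"))],
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
    outputs = as.list(tools::md5sum(sort(files)))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest[setdiff(names(manifest), "elapsed_s")],
                   out("manifest.yml"))
  say("pipeline complete: %d files in %s", length(files) + 1, config$out_dir)
  invisible(manifest)
}
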
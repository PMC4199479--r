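#' Run the full discovery-and-validation pipeline on a synthetic study
#'
#' End-to-end driver: simulates (or reads) a three-cohort study, runs
#' variant QC on the discovery cohort, codes genotypes under the
#' additive, dominant and rare-collapsed schemes, performs per-cohort
#' covariate-adjusted single-variant regression for every common variant
#' under the four model tags (`unt`/`log` x `add`/`dom`), combines the
#' cohorts by Liptak meta-analysis and by pooled mega-analysis, and runs
#' the hotspot-tiled stepwise regression (additive + collapsed coding)
#' on the pre-adjusted discovery trait. Outputs are written as TSVs
#' shaped like the study's association and tiled-selection tables.
#'
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param out_dir output directory; inputs land in `out_dir/inputs`,
#'   results in `out_dir/results`.
#' @param trait name of the trait column (default `"CALM"`).
#' @return list with `qc` (the [run_variant_qc()] result), `assoc`
#'   (wide per-variant association table: per-cohort beta/se/p, meta p,
#'   mega beta/se/p per model), `tiled` (list of [tiled_regression()]
#'   models, untransformed and log trait), `tiled_table` (tiled-selection
#'   summary), and `paths`.
#' @export
nf1_pipeline <- function(config = sim_config(), out_dir = tempfile("nf1_"),
                         trait = "CALM") {
  sim <- simulate_study(config, out_dir = file.path(out_dir, "inputs"))
  # read the written files back: the pipeline consumes files, not the
  # in-memory simulation objects
  pheno <- read_phenotype_table(sim$paths$pheno)
  gm <- read_genotypes(sim$paths$geno_tsv, "tsv", samples = pheno$sample_id)
  tiles <- read_hotspots(sim$paths$hotspots,
                         stats::setNames(config$chrom_length, config$chrom))

  cohort_names <- config$cohorts$name
  disc <- cohort_names[1]
  disc_ids <- pheno$sample_id[pheno$cohort == disc]
  qc <- run_variant_qc(subset_genotypes(gm, samples = disc_ids),
                       pheno[pheno$cohort == disc, ])
  kept <- colnames(qc$genotypes$calls)
  common <- qc$report$maf$variant_id[qc$report$maf$rarity_class == "common"]

  # per-cohort QC'd genotypes restricted to the DISC-retained variants
  gm_all <- mask_low_quality_calls(subset_genotypes(gm, variants = kept))
  models <- c("unt_add", "log_add", "unt_dom", "log_dom")
  rows <- list()
  for (v in common) {
    for (m in models) {
      code_fun <- if (endsWith(m, "dom")) code_dominant else code_additive
      per_cohort <- lapply(cohort_names, function(co) {
        idx <- pheno$cohort == co
        single_variant_regression(pheno[[trait]][idx], pheno[idx, ],
                                  code_fun(gm_all$calls[idx, v]),
                                  model = m, target_id = v)
      })
      pc <- do.call(rbind, per_cohort)
      row <- data.frame(target_id = v, model = m)
      for (i in seq_along(cohort_names)) {
        row[[paste0("beta_", cohort_names[i])]] <- pc$beta[i]
        row[[paste0("se_", cohort_names[i])]] <- pc$se[i]
        row[[paste0("p_", cohort_names[i])]] <- pc$p_value[i]
      }
      row$meta_p <- if (all(!is.na(pc$p_value)))
        liptak_meta(pc$p_value, pc$n_used, target_id = v,
                    model = m)$combined_p else NA_real_
      mega <- mega_analysis(pheno[[trait]], pheno,
                            code_fun(gm_all$calls[, v]),
                            model = m, target_id = v)
      row$beta_mega <- mega$beta
      row$se_mega <- mega$se
      row$p_mega <- mega$p_value
      rows[[paste0(v, "_", m)]] <- row
    }
  }
  assoc <- do.call(rbind, rows)
  rownames(assoc) <- NULL

  # tiled regression on the pre-adjusted discovery trait, additive +
  # collapsed-rare coding
  disc_idx <- match(disc_ids, rownames(qc$genotypes$calls))
  disc_idx <- disc_idx[!is.na(disc_idx)]
  coded <- code_genotypes(qc$genotypes, "add_collapsed", tiles,
                          maf = qc$report$maf)
  ph_disc <- pheno[match(rownames(qc$genotypes$calls), pheno$sample_id), ]
  tiled <- lapply(c(unt = "unt", log = "log"), function(tf) {
    y <- residualize_trait(ph_disc[[trait]], ph_disc, transform = tf)
    tiled_regression(y, coded, tiles)
  })
  tiled_table <- do.call(rbind, lapply(names(tiled), function(tf) {
    s <- tiled[[tf]]$selected
    if (nrow(s) == 0) return(NULL)
    cbind(trait_transform = tf, s)
  }))
  if (is.null(tiled_table))
    tiled_table <- data.frame(trait_transform = character(),
                              column_id = character(), beta = numeric(),
                              se = numeric(), p_value = numeric())

  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(association = file.path(res_dir, "association_table.tsv"),
                tiled = file.path(res_dir, "tiled_selection.tsv"),
                qc = file.path(res_dir, "qc_report.json"))
  write.table(assoc, paths$association, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tiled_table, paths$tiled, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(retained_dimensions = as.list(qc$report$retained_dimensions),
         masked_calls = qc$report$masked_calls,
         excluded_samples = qc$report$excluded_samples,
         excluded_variants = qc$report$excluded_variants,
         hwe_flags = qc$report$hwe[qc$report$hwe$flagged, ]),
    paths$qc, auto_unbox = TRUE, digits = NA)

  list(qc = qc, assoc = assoc, tiled = tiled, tiled_table = tiled_table,
       sim = sim, paths = c(sim$paths, paths))
}
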
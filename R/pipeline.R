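#' Default pipeline configuration
#'
#' All simulation parameters and every analysis threshold surface as named
#' keys with their standard defaults: specificity AUC > 0.5 at FDR < 0.05,
#' bulk DE FDR < 0.05 with |log2FC| > 0.25 for the signature, pseudobulk
#' detection fraction 5%, meta-cells of 30 nuclei with at most 10 shared,
#' 50 background peak sets, driver-TF FDR < 0.01, signed network power 9,
#' minimum module size 50, merge cut height 0.25, enhancer-atlas overlap
#' threshold 25%.
#'
#' @param seed Integer seed driving the whole run.
#' @return Nested list with components `sim` (see [sim_config()]) and
#'   `params`.
#' @export
default_config <- function(seed = 1L) {
  list(
    sim = list(seed = as.integer(seed)),
    params = list(
      min_frac = 0.05, de_fdr = 0.05, conc_fdr = 0.05, assign_fdr = 0.05,
      auc_min = 0.5, spec_fdr = 0.05, sig_de_fdr = 0.05, sig_lfc_min = 0.25,
      n_bins = 24, n_ctrl = 100,
      n_components = 10, k = 30, max_shared = 10,
      bias_bins = 10, n_bg = 50,
      driver_fdr = 0.01,
      power = 9, min_module_size = 50, merge_cut_height = 0.25,
      cut_height = 0.6, coexpr_base_mean = 1, coexpr_lfc = 0.05,
      coexpr_p = 0.05,
      atlas_threshold = 0.25,
      exclude_metacells = character()
    )
  )
}

pipeline_stages <- c("simulate", "specificity", "pseudobulk", "de",
                     "concordance", "assign-celltypes", "strand-check",
                     "signature", "metacell", "motif-dev", "footprint",
                     "associate", "coexpress")

stage_deps <- list(
  "specificity" = "simulate", "pseudobulk" = "simulate", "de" = "simulate",
  "concordance" = "de", "assign-celltypes" = c("concordance", "pseudobulk"),
  "strand-check" = "de", "signature" = c("specificity", "de"),
  "metacell" = "simulate", "motif-dev" = "simulate",
  "footprint" = "simulate",
  "associate" = c("specificity", "signature", "metacell", "motif-dev"),
  "coexpress" = "de")

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in canonical order on a fresh synthetic
#' dataset, writing each stage's tables under `out_dir/<stage>/` plus a
#' `manifest.yaml` recording configuration, seed and package version.
#' Rerunning with the same configuration and seed reproduces every output
#' byte for byte.
#'
#' @param config A list as from [default_config()], or the path to a YAML
#'   file with the same structure. `config$sim` is passed to
#'   [sim_config()]; `config$params` holds the analysis thresholds.
#' @param out_dir Output directory (created if needed).
#' @param stages Ordered subset of
#'   `r paste(pipeline_stages, collapse = ", ")` (default: all).
#' @param seed Overrides `config$sim$seed` when given.
#' @param write Write stage artifacts to `out_dir` (default TRUE); with
#'   `FALSE` the pipeline runs fully in memory and `out_dir` may be
#'   omitted.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         stages = pipeline_stages, seed = NULL,
                         write = TRUE) {
  if (write && is.null(out_dir))
    stopf("out_dir is required when write = TRUE")
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  defaults <- default_config(config$sim$seed)
  params <- utils::modifyList(defaults$params, config$params %||% list())
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  for (s in stages) {
    need <- setdiff(stage_deps[[s]], stages)
    if (length(need))
      stopf("stage '%s' requires stage '%s' to run first", s, need[[1L]])
  }
  if (write) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(sim_config, config$sim)
  st <- new.env(parent = emptyenv())
  put <- function(stage, name, table) {
    if (!write) return(invisible(NULL))
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    write_table(table, file.path(d, paste0(name, ".tsv")))
  }

  for (stage in stages) {
    message("stage: ", stage)
    switch(stage,
      "simulate" = {
        st$mo <- generate_multiome(cfg)
        st$bulk <- generate_bulk_cohorts(cfg)
        sites <- st$mo$peaks[st$mo$peaks$label %in% st$mo$truth$driver_peaks,
                             , drop = FALSE]
        st$fragments <- generate_fragments(cfg, sites, st$mo$nuclei)
        st$norm <- log_normalize(st$mo$rna)
        if (write) {
          d <- file.path(out_dir, "simulate")
          dir.create(d, showWarnings = FALSE)
          write_matrix_triple(st$mo$rna, file.path(d, "rna"))
          write_matrix_triple(st$mo$atac, file.path(d, "atac"))
          put("simulate", "nuclei", st$mo$nuclei)
          write_bed(st$mo$peaks, file.path(d, "peaks.bed"))
          write_fragments(st$fragments, file.path(d, "fragments.tsv"))
        }
      },
      "specificity" = {
        st$spec_auc <- rank_auc_all(st$norm, st$mo$nuclei$cell_type)
        put("specificity", "gene_auc", st$spec_auc)
      },
      "pseudobulk" = {
        st$pb <- pseudobulk_aggregate(st$mo$rna, st$mo$nuclei,
                                      min_frac = params$min_frac)
      },
      "de" = {
        st$de1 <- nb_glm_de(st$bulk$cohort1$counts, st$bulk$cohort1$samples,
                            covariates = "sex")
        st$de2 <- nb_glm_de(st$bulk$cohort2$counts, st$bulk$cohort2$samples,
                            covariates = "sex")
        st$de2_unstranded <- nb_glm_de(st$bulk$cohort2_unstranded,
                                       st$bulk$cohort2$samples,
                                       covariates = "sex")
        put("de", "cohort1", st$de1)
        put("de", "cohort2", st$de2)
        put("de", "cohort2_unstranded", st$de2_unstranded)
      },
      "concordance" = {
        st$concordant <- concordant_degs(st$de1, st$de2,
                                         fdr = params$conc_fdr)
        put("concordance", "concordant_degs", st$concordant)
      },
      "assign-celltypes" = {
        st$ct_de <- lapply(st$pb[vapply(st$pb, `[[`, TRUE, "testable")],
                           function(x) nb_glm_de(x$counts, x$samples))
        asn <- assign_degs_to_celltypes(st$concordant, st$ct_de,
                                        fdr = params$assign_fdr)
        st$assigned <- asn
        flat <- asn
        flat$cell_types <- vapply(asn$cell_types, paste, "", collapse = ",")
        put("assign-celltypes", "deg_celltypes", flat)
      },
      "strand-check" = {
        pairs <- data.frame(
          gene_plus = st$bulk$truth$antisense_pair[["gene_plus"]],
          gene_minus = st$bulk$truth$antisense_pair[["gene_minus"]],
          stringsAsFactors = FALSE)
        st$strand <- strand_artifact_check(st$de2, st$de2_unstranded, pairs)
        put("strand-check", "flagged", st$strand)
      },
      "signature" = {
        cm_auc <- st$spec_auc[st$spec_auc$group == "CM", , drop = FALSE]
        st$signature <- build_af_signature(
          cm_auc, st$de1, st$de2, auc_min = params$auc_min,
          spec_fdr = params$spec_fdr, de_fdr = params$sig_de_fdr,
          lfc_min = params$sig_lfc_min)
        put("signature", "signature", data.frame(
          gene = c(st$signature$up_genes, st$signature$down_genes),
          direction = rep(c("up", "down"),
                          c(length(st$signature$up_genes),
                            length(st$signature$down_genes))),
          stringsAsFactors = FALSE))
      },
      "metacell" = {
        emb <- pca_embed(st$norm, n_components = params$n_components)
        st$metacells <- make_metacells(emb, st$mo$nuclei, k = params$k,
                                       max_shared = params$max_shared,
                                       seed = cfg$seed + 11L)
        st$mc_rna <- aggregate_matrix(st$mo$rna, st$metacells)
        st$mc_atac <- aggregate_matrix(st$mo$atac, st$metacells)
        put("metacell", "assignment",
            st$metacells[, c("metacell_id", "nucleus_id")])
      },
      "motif-dev" = {
        bias <- peak_bias(st$mo$atac, st$mo$peaks$gc,
                          n_bins = params$bias_bins)
        bg <- sample_background_peaks(bias, n_bg = params$n_bg,
                                      seed = cfg$seed + 12L)
        st$motif_dev <- motif_deviations(st$mo$atac, st$mo$motifs, bg)
        st$bias <- bias
        st$bg <- bg
      },
      "footprint" = {
        sites <- st$mo$peaks[st$mo$peaks$label %in% st$mo$truth$driver_peaks,
                             , drop = FALSE]
        nuc <- st$mo$nuclei
        groups <- list(
          CM_AF = nuc$nucleus_id[nuc$cell_type == "CM" &
                                   nuc$condition == "AF"],
          CM_SR = nuc$nucleus_id[nuc$cell_type == "CM" &
                                   nuc$condition == "SR"],
          other = nuc$nucleus_id[nuc$cell_type != "CM"])
        st$footprint <- footprint_profile(st$fragments, sites, groups)
        prof <- do.call(cbind, lapply(st$footprint, `[[`, "profile"))
        put("footprint", "profiles",
            data.frame(position = as.integer(rownames(prof)), prof,
                       row.names = NULL))
      },
      "associate" = {
        mc_norm <- log_normalize(as_sparse(st$mc_rna))
        cm_ids <- metacell_info(st$metacells)
        cm_ids <- cm_ids$metacell_id[cm_ids$cell_type == "CM"]
        cm_ids <- setdiff(cm_ids, params$exclude_metacells)
        up_score <- module_score(mc_norm, st$signature$up_genes,
                                 n_bins = params$n_bins,
                                 n_ctrl = params$n_ctrl,
                                 seed = cfg$seed + 13L)[cm_ids]
        mc_z <- rowsum(st$motif_dev$z[st$metacells$nucleus_id, ,
                                      drop = FALSE],
                       group = st$metacells$metacell_id) /
          as.vector(table(st$metacells$metacell_id)[
            sort(unique(st$metacells$metacell_id))])
        tf_expr <- mc_norm[cm_ids, st$mo$truth$tf_genes, drop = FALSE]
        colnames(tf_expr) <- names(st$mo$truth$tf_genes)
        st$corr_motif <- correlate_with_signature(
          up_score, mc_z[cm_ids, , drop = FALSE])
        st$corr_expr <- correlate_with_signature(up_score,
                                                 as.matrix(tf_expr))
        st$drivers <- select_driver_tfs(st$corr_motif, st$corr_expr,
                                        fdr_max = params$driver_fdr)
        st$up_score <- up_score
        # product-of-AUC TF ranking within CM (expression x motif activity)
        cm_gene_auc <- st$spec_auc[st$spec_auc$group == "CM", , drop = FALSE]
        motif_auc <- rank_auc_test(st$motif_dev$z, st$mo$nuclei$cell_type,
                                   "CM")
        st$tf_rank <- suppressMessages(rank_tfs_by_specificity(
          cm_gene_auc, motif_auc, tf_motif_map = st$mo$truth$tf_genes))
        put("associate", "driver_tfs", st$drivers)
        put("associate", "tf_rank", st$tf_rank)
      },
      "coexpress" = {
        merged <- rbind(st$bulk$cohort1$counts, st$bulk$cohort2$counts)
        samples <- rbind(st$bulk$cohort1$samples, st$bulk$cohort2$samples)
        samples$cohort <- rep(c(0L, 1L), c(nrow(st$bulk$cohort1$samples),
                                           nrow(st$bulk$cohort2$samples)))
        de_m <- nb_glm_de(merged, samples, covariates = c("sex", "cohort"))
        genes <- prefilter_genes(de_m, base_mean_min = params$coexpr_base_mean,
                                 lfc_min = params$coexpr_lfc,
                                 p_max = params$coexpr_p)
        st$coexpr_genes <- genes
        if (length(genes) >= 3) {
          expr <- log1p(merged[, genes, drop = FALSE] /
                          size_factors(merged))
          expr <- residualize_covariates(expr,
                                         samples[, c("sex", "cohort")])
          keep <- apply(expr, 2L, stats::sd) > 0
          adj <- signed_adjacency(expr[, keep, drop = FALSE],
                                  power = params$power)
          tom <- topological_overlap(adj)
          st$modules <- detect_modules(
            tom, expr[, keep, drop = FALSE],
            min_module_size = params$min_module_size,
            cut_height = params$cut_height,
            merge_cut_height = params$merge_cut_height)
          put("coexpress", "modules", data.frame(
            gene = names(st$modules$labels),
            module = unname(st$modules$labels), stringsAsFactors = FALSE))
        }
      }
    )
  }
  if (write) {
    manifest <- list(package = "afcellsig",
                     version = as.character(utils::packageVersion("afcellsig")),
                     seed = cfg$seed, stages = stages, params = params,
                     sim = config$sim)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(as.list(st))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
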
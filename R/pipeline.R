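#' Pipeline configuration
#'
#' All thresholds of the four stages with their standard defaults, plus a
#' master seed from which every stochastic operation derives a child seed.
#'
#' @param p_thr,fc_thr stage-1 KS p-value and absolute fold-change
#'   thresholds.
#' @param n_boot_ks KS bootstrap resamples.
#' @param run_fdr_grid run the stage-1 permutation FDR grid (diagnostic).
#' @param n_perm_fdr permutations for the FDR grid.
#' @param fdr_p_grid,fdr_fc_grid stage-1 FDR grid.
#' @param enrichment_thresholds `"auto"` (randomized-set FDR selection) or a
#'   named list per classifier of `list(p_threshold=, oe_threshold=)`.
#' @param enrich_p_grid,enrich_oe_grid,n_iter_enrich stage-2 threshold grid
#'   and random iterations.
#' @param mi_p MI significance level for network edges.
#' @param n_null_mi pooled permutation-null size for the MI threshold.
#' @param n_boot_regulon bootstrap networks per regulon.
#' @param consensus_p bootstrap-consensus binomial p threshold.
#' @param sd_min s.d. filter of the network preprocessing.
#' @param mra_percentile null-model coverage defining the MRA threshold.
#' @param mra_fallback MRA threshold when the null model is empty.
#' @param null_spec a [null_model_spec()].
#' @param slr_percentile pooled percentile for the attribution fraction
#'   threshold.
#' @param fdr_max,delta_percentile,use_delta core-sample selection
#'   parameters; `use_delta = FALSE` gives the binary-phenotype mode with
#'   trivial cores.
#' @param seed master seed.
#' @return an `mmra_config` list.
#' @export
mmra_config <- function(p_thr = 0.001, fc_thr = 2, n_boot_ks = 1000,
                        run_fdr_grid = FALSE, n_perm_fdr = 1000,
                        fdr_p_grid = c(0.001, 0.01), fdr_fc_grid = c(1.5, 2, 2.5),
                        enrichment_thresholds = "auto",
                        enrich_p_grid = c(0.001, 0.01, 0.05),
                        enrich_oe_grid = c(1.5, 2, 2.5), n_iter_enrich = 1000,
                        mi_p = 1e-7, n_null_mi = 1e5, n_boot_regulon = 100,
                        consensus_p = 1e-12, sd_min = 1.2, mra_percentile = 95,
                        mra_fallback = 1e-4, null_spec = null_model_spec(),
                        slr_percentile = 90, fdr_max = 0.05,
                        delta_percentile = 95, use_delta = TRUE, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "mmra_config"
  cfg
}

#' Run the full four-stage pipeline
#'
#' Executes differential expression, target enrichment, regulon/MRA and
#' stepwise-regression attribution in sequence, recording a candidate
#' funnel and a manifest of thresholds and seeds. A stage with zero
#' survivors stops the pipeline with a clear report rather than an error.
#'
#' @param mrna,mirna paired expression matrices (log2, identical ordered
#'   samples).
#' @param classification classification data frame.
#' @param signatures long signature data frame.
#' @param target_map predicted-target map.
#' @param config an [mmra_config()].
#' @param out_dir optional directory; when given, every intermediate table
#'   and the manifest are written there.
#' @return list `candidates`, `funnel`, `manifest`, `status` plus all
#'   intermediate results (`de`, `enrichment`, `regulons`, `mra`,
#'   `attributions`, ...).
#' @export
run_mmra <- function(mrna, mirna, classification, signatures, target_map,
                     config = mmra_config(), out_dir = NULL) {
  stopifnot(identical(colnames(mrna), colnames(mirna)))
  classification <- validate_classification(classification)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  cfg_plain$null_spec <- unclass(cfg_plain$null_spec)
  manifest <- list(config = cfg_plain, seeds = list(), thresholds = list())
  funnel <- list(n_mirnas = nrow(mirna))
  persist <- function(obj, name) {
    if (!is.null(out_dir) && is.data.frame(obj))
      utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  finish <- function(status, ...) {
    extras <- list(...)
    manifest$funnel <- funnel
    out <- c(list(candidates = extras$candidates %||% empty_candidates(),
                  funnel = funnel, manifest = manifest, status = status),
             extras[setdiff(names(extras), "candidates")])
    if (!is.null(out_dir))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  }

  ## ---- stage 1: differential expression on subtype cores ----
  classifiers <- sort(unique(classification$classifier))
  cores_list <- lapply(classifiers, function(cl)
    select_core_samples(classification, cl, fdr_max = config$fdr_max,
                        delta_percentile = config$delta_percentile,
                        use_delta = config$use_delta))
  names(cores_list) <- classifiers
  manifest$thresholds$delta <- lapply(cores_list, `[[`, "delta_threshold")

  s1 <- child_seed(config$seed, 1)
  manifest$seeds$diffexp <- s1
  set.seed(s1)
  de <- do.call(rbind, lapply(cores_list, function(cores)
    differential_micrornas(mirna, cores, p_thr = config$p_thr,
                           fc_thr = config$fc_thr, n_boot = config$n_boot_ks)))
  rownames(de) <- NULL
  persist(de, "step1_diffexp")

  if (isTRUE(config$run_fdr_grid)) {
    set.seed(child_seed(config$seed, 11))
    manifest$seeds$fdr_grid <- child_seed(config$seed, 11)
    fdr_grids <- lapply(cores_list, function(cores)
      permutation_fdr_grid(mirna, cores, p_grid = config$fdr_p_grid,
                           fc_grid = config$fdr_fc_grid,
                           n_perm = config$n_perm_fdr,
                           n_boot = config$n_boot_ks))
    for (cl in names(fdr_grids)) persist(fdr_grids[[cl]], paste0("step1_fdr_", cl))
  } else fdr_grids <- NULL

  funnel$step1_differential <- length(unique(de$mirna[de$pass]))
  if (funnel$step1_differential == 0)
    return(finish("no differential microRNAs at step 1", de = de,
                  fdr_grids = fdr_grids))

  ## ---- stage 2: target enrichment ----
  universe <- intersect(rownames(mrna), unique(target_map$gene))
  manifest$thresholds$enrichment_universe <- length(universe)
  s2 <- child_seed(config$seed, 2)
  manifest$seeds$enrichment <- s2
  set.seed(s2)
  thresholds <- if (identical(config$enrichment_thresholds, "auto"))
    select_enrichment_thresholds(de, target_map, signatures, universe,
                                 p_grid = config$enrich_p_grid,
                                 oe_grid = config$enrich_oe_grid,
                                 n_iter = config$n_iter_enrich)
  else config$enrichment_thresholds
  manifest$thresholds$enrichment <- lapply(thresholds, function(t)
    t[c("p_threshold", "oe_threshold")])
  enrichment <- filter_by_enrichment(de, thresholds, target_map, signatures,
                                     universe)
  persist(enrichment, "step2_enrichment")
  step2_mirnas <- unique(enrichment$mirna[enrichment$pass])
  funnel$step2_enriched <- length(step2_mirnas)
  if (funnel$step2_enriched == 0)
    return(finish("no target-enriched microRNAs at step 2", de = de,
                  enrichment = enrichment, fdr_grids = fdr_grids))

  ## ---- stage 3: regulons + MRA ----
  s3 <- child_seed(config$seed, 3)
  manifest$seeds$regulon <- s3
  set.seed(s3)
  mi_thr <- mi_significance_threshold(ncol(mrna), p_target = config$mi_p,
                                      n_null = config$n_null_mi)
  manifest$thresholds$mi <- mi_thr$threshold
  regulons <- list()
  for (m in step2_mirnas) {
    prep <- preprocess_for_network(mrna, mirna[m, , drop = FALSE],
                                   sd_min = config$sd_min)
    regulons[[m]] <- build_regulon(prep, mi_thr$threshold,
                                   n_boot = config$n_boot_regulon,
                                   consensus_p = config$consensus_p)
  }
  persist(data.frame(
    mirna = rep(names(regulons), vapply(regulons, function(r) nrow(r$edges), 1L)),
    do.call(rbind, lapply(regulons, `[[`, "edges"))), "step3_regulons")

  set.seed(child_seed(config$seed, 31))
  manifest$seeds$null_model <- child_seed(config$seed, 31)
  nullm <- build_null_model(mirna, mrna, cores_list, regulons,
                            spec = config$null_spec,
                            mi_threshold = mi_thr$threshold,
                            n_boot = config$n_boot_regulon,
                            consensus_p = config$consensus_p,
                            sd_min = config$sd_min)
  sig_keys <- unique(signatures[, c("classifier", "subtype", "direction")])
  null_p <- unlist(lapply(nullm$regulons, function(r)
    vapply(seq_len(nrow(sig_keys)), function(i) {
      sig <- signature_genes(signatures, sig_keys$classifier[i],
                             sig_keys$subtype[i], sig_keys$direction[i])
      mra_test(r, sig, rownames(mrna))$p
    }, 1)))
  mra_thr <- mra_threshold_from_null(null_p, percentile = config$mra_percentile,
                                     fallback = config$mra_fallback)
  manifest$thresholds$mra <- mra_thr$threshold
  manifest$thresholds$n_null_mirnas <- length(nullm$mirnas)

  en_assoc <- enrichment[enrichment$pass, ]
  mra <- do.call(rbind, lapply(seq_len(nrow(en_assoc)), function(i) {
    a <- en_assoc[i, ]
    sig <- signature_genes(signatures, a$classifier, a$subtype, a$sig_direction)
    res <- mra_test(regulons[[a$mirna]], sig, rownames(mrna))
    data.frame(classifier = a$classifier, subtype = a$subtype, mirna = a$mirna,
               sig_direction = a$sig_direction, overlap = res$overlap,
               p = res$p, pass = res$p <= mra_thr$threshold,
               stringsAsFactors = FALSE)
  }))
  persist(mra, "step3_mra")
  funnel$step3_mra <- length(unique(mra$mirna[mra$pass]))
  if (funnel$step3_mra == 0)
    return(finish("no microRNAs surviving MRA at step 3", de = de,
                  enrichment = enrichment, regulons = regulons, mra = mra,
                  null_model = nullm, fdr_grids = fdr_grids))

  ## ---- stage 4: stepwise regression attribution ----
  surv_regs <- regulons[unique(mra$mirna[mra$pass])]
  sig_genes_all <- intersect(unique(signatures$gene), rownames(mrna))
  gene_fits <- list()
  for (g in sig_genes_all) {
    cand <- names(surv_regs)[vapply(surv_regs, function(r)
      g %in% r$edges$gene, TRUE)]
    if (length(cand) == 0) next
    gene_fits[[g]] <- fit_stepwise(mrna[g, ], t(mirna[cand, , drop = FALSE]))
  }
  attributions <- aggregate_fractions(gene_fits, signatures, rownames(mrna))
  persist(attributions, "step4_attributions")
  if (is.null(attributions) || nrow(attributions) == 0)
    return(finish("no signature genes carried a regression model at step 4",
                  de = de, enrichment = enrichment, regulons = regulons,
                  mra = mra, null_model = nullm, fdr_grids = fdr_grids))
  frac_thr <- fraction_threshold(attributions, percentile = config$slr_percentile)
  manifest$thresholds$slr_fraction <- frac_thr

  candidates <- final_candidates(attributions, frac_thr, de, enrichment, mra)
  persist(candidates, "step4_candidates")
  funnel$step4_candidates <- length(unique(candidates$mirna))

  finish(if (funnel$step4_candidates > 0) "ok" else
           "no candidates above the attribution threshold",
         candidates = candidates, de = de, enrichment = enrichment,
         regulons = regulons, mra = mra, null_model = nullm,
         attributions = attributions, gene_fits = gene_fits,
         fdr_grids = fdr_grids)
}
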
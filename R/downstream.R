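#' Null-model fold-change threshold for cell-line consolidation
#'
#' Draws `n_random` random microRNA sets of size `set_size`, computes for
#' every member the folded fold change (max(FC, 1/FC)) between samples of
#' the target subtype and the rest, and returns the chosen percentile of the
#' pooled null FC distribution. Uses R's RNG stream.
#'
#' @param mirna microRNA expression matrix (log2, cell lines as columns).
#' @param labels character vector of subtype labels per column.
#' @param target_subtype subtype whose contrast defines the FC.
#' @param set_size size of each random microRNA set.
#' @param n_random number of random sets (default 1000).
#' @param percentile percentile of the pooled distribution (default 90).
#' @return list `threshold`, `null_fc` (pooled folded FC values).
#' @export
nullmodel_fc_threshold <- function(mirna, labels, target_subtype, set_size,
                                   n_random = 1000, percentile = 90) {
  stopifnot(length(labels) == ncol(mirna))
  in_s <- labels == target_subtype
  if (!any(in_s) || all(in_s)) stop("target subtype must split the samples")
  fc_all <- 2^abs(rowMeans(mirna[, in_s, drop = FALSE]) -
                  rowMeans(mirna[, !in_s, drop = FALSE]))
  pool <- rownames(mirna)
  set_size <- min(set_size, length(pool))
  null_fc <- unlist(lapply(seq_len(n_random), function(i)
    fc_all[sample(pool, set_size)]))
  list(threshold = pctl(null_fc, percentile), null_fc = unname(null_fc))
}

#' Fraction of signature genes correlated with a microRNA across subtypes
#'
#' Computes subtype-level mean expression for the microRNA and each
#' signature gene, their Spearman correlation across subtypes, and the
#' fraction of genes with |r| above `r_threshold`. Genes with constant
#' subtype means (undefined correlation) are excluded and logged. Refused
#' for fewer than four subtypes, where rank correlations over subtype means
#' are unreliable.
#'
#' @param gene_expr expression matrix of signature genes (genes x samples).
#' @param mirna_expr numeric microRNA profile over the same samples.
#' @param labels character vector of subtype labels per sample.
#' @param r_threshold absolute Spearman correlation threshold.
#' @return list `fraction`, `r` (named per-gene correlations), `n_used`,
#'   `n_excluded`.
#' @export
correlation_fraction <- function(gene_expr, mirna_expr, labels, r_threshold) {
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 4) {
    warning("fewer than 4 subtypes: correlation fraction not computed")
    return(list(fraction = NA_real_, r = NULL, n_used = 0L, n_excluded = 0L))
  }
  m_means <- vapply(subtypes, function(s) mean(mirna_expr[labels == s]), 1)
  g_means <- vapply(subtypes, function(s)
    rowMeans(gene_expr[, labels == s, drop = FALSE]), numeric(nrow(gene_expr)))
  if (!is.matrix(g_means))  # single-gene input collapses to a vector
    g_means <- matrix(g_means, nrow = 1,
                      dimnames = list(rownames(gene_expr), subtypes))
  const <- apply(g_means, 1, function(v) stats::sd(v) == 0)
  if (any(const))
    mmra_log(sprintf("%d gene(s) with constant subtype means excluded", sum(const)))
  g_means <- g_means[!const, , drop = FALSE]
  if (nrow(g_means) == 0)
    return(list(fraction = NA_real_, r = NULL, n_used = 0L,
                n_excluded = sum(const)))
  r <- apply(g_means, 1, function(v) stats::cor(v, m_means, method = "spearman"))
  list(fraction = mean(abs(r) > r_threshold), r = r,
       n_used = length(r), n_excluded = sum(const))
}

#' Consolidate a microRNA-subtype association in cell lines
#'
#' Combines the two consolidation criteria: (i) differential expression
#' between cell lines of the target subtype and the rest exceeding a
#' null-model FC threshold, in the direction found in the tumour analysis;
#' (ii) the fraction of subtype signature genes correlated with the microRNA
#' across subtypes exceeding a significance cut. The association is
#' validated when both pass (the correlation criterion is waived where it
#' cannot be computed).
#'
#' @param mirna_expr microRNA profile across cell lines (log2).
#' @param labels subtype labels per cell line.
#' @param target_subtype the associated subtype.
#' @param expr_direction `"UP"` or `"DOWN"`, tumour-side direction.
#' @param fc_threshold from [nullmodel_fc_threshold()].
#' @param gene_expr signature-gene expression matrix (or `NULL` to skip the
#'   correlation criterion).
#' @param r_threshold,min_corr_fraction correlation criterion parameters.
#' @return list `fc`, `fc_pass`, `correlation_fraction`, `corr_pass`,
#'   `validated`.
#' @export
consolidate_association <- function(mirna_expr, labels, target_subtype,
                                    expr_direction, fc_threshold,
                                    gene_expr = NULL, r_threshold = 0.9,
                                    min_corr_fraction = 0.1) {
  in_s <- labels == target_subtype
  lfc <- mean(mirna_expr[in_s]) - mean(mirna_expr[!in_s])
  fc <- 2^lfc
  dir_ok <- (expr_direction == "UP" && lfc > 0) ||
            (expr_direction == "DOWN" && lfc < 0)
  fc_pass <- dir_ok && max(fc, 1 / fc) > fc_threshold
  corr <- if (is.null(gene_expr)) list(fraction = NA_real_)
          else correlation_fraction(gene_expr, mirna_expr, labels, r_threshold)
  corr_pass <- if (is.na(corr$fraction)) NA else corr$fraction > min_corr_fraction
  list(fc = fc, fc_pass = fc_pass, correlation_fraction = corr$fraction,
       corr_pass = corr_pass, validated = fc_pass && !isFALSE(corr_pass))
}

#' Differential expression in microRNA-silencing experiments
#'
#' Genes responding to microRNA silencing: absolute fold change above
#' `fc_thr` and Welch t-test p below `p_thr` between transduced and
#' scramble-control replicates, minus genes satisfying the same
#' direction-specific criteria between wild-type and scramble (unspecific
#' transduction response).
#'
#' @param transduced,scramble,wildtype expression matrices (genes x
#'   replicates, log2), identical gene order; >= 2 replicates each.
#' @param fc_thr absolute FC threshold (default 1.5).
#' @param p_thr t-test p threshold (default 0.05).
#' @return list `up`, `down` (gene ids), `table` (per-gene statistics).
#' @export
silencing_de <- function(transduced, scramble, wildtype, fc_thr = 1.5,
                         p_thr = 0.05) {
  for (m in list(transduced, scramble, wildtype))
    if (ncol(m) < 2) stop("need >= 2 replicates per condition for the t-test")
  stopifnot(identical(rownames(transduced), rownames(scramble)),
            identical(rownames(transduced), rownames(wildtype)))
  de_flags <- function(a, b) {
    lfc <- rowMeans(a) - rowMeans(b)
    p <- vapply(seq_len(nrow(a)), function(i)
      stats::t.test(a[i, ], b[i, ])$p.value, 1)
    list(lfc = lfc, p = p,
         up = lfc > log2(fc_thr) & p < p_thr,
         down = lfc < -log2(fc_thr) & p < p_thr)
  }
  ts <- de_flags(transduced, scramble)
  ws <- de_flags(wildtype, scramble)
  up <- rownames(transduced)[ts$up & !ws$up]
  down <- rownames(transduced)[ts$down & !ws$down]
  tab <- data.frame(gene = rownames(transduced), log2fc = ts$lfc, p = ts$p,
                    wt_log2fc = ws$lfc, wt_p = ws$p,
                    up = rownames(transduced) %in% up,
                    down = rownames(transduced) %in% down,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(up = up, down = down, table = tab)
}

#' Enrichment of silencing-response genes in pooled subtype signatures
#'
#' Hypergeometric upper-tail tests of upregulated genes against the pooled
#' UP signature and downregulated genes against the pooled DOWN signature,
#' with fold enrichment (O/E).
#'
#' @param up,down silencing-response gene lists ([silencing_de()]).
#' @param sig_up,sig_down pooled signature gene sets.
#' @param universe gene universe.
#' @param p_thr significance threshold (default 0.05).
#' @return data frame with one row per test (`set`, `k`, `p`, `fold`,
#'   `pass`).
#' @export
signature_shift_test <- function(up, down, sig_up, sig_down, universe,
                                 p_thr = 0.05) {
  one <- function(genes, sig, label) {
    h <- hypergeom_enrichment(genes, intersect(sig, universe), universe, 1)
    data.frame(set = label, n_genes = h$n_targets, k = h$k, p = h$p,
               fold = h$oe_ratio, pass = h$p < p_thr, stringsAsFactors = FALSE)
  }
  rbind(one(up, sig_up, "up_vs_sigUP"), one(down, sig_down, "down_vs_sigDOWN"))
}

#' Identify core microRNA targets
#'
#' For every gene upregulated in vitro by silencing of any validated
#' microRNA, the gene's tumour expression is regressed (stepwise, AIC) on
#' the validated microRNA set; the gene is a core target of microRNA M when
#' it was selected with a negative coefficient for M. Edges are labelled
#' `"solid"` when the gene was upregulated in M's own silencing experiment
#' (in vitro + in vivo) and `"dashed"` otherwise (in vivo only).
#'
#' @param up_lists named list (microRNA -> upregulated gene ids in its
#'   silencing experiment).
#' @param mrna tumour mRNA expression matrix (log2).
#' @param mirna tumour microRNA expression matrix (log2), containing the
#'   validated microRNAs.
#' @param validated_mirnas character vector of validated microRNA ids.
#' @return data frame `gene`, `mirna`, `coefficient`, `in_vitro`, `edge`.
#' @export
identify_core_targets <- function(up_lists, mrna, mirna, validated_mirnas) {
  stopifnot(all(validated_mirnas %in% rownames(mirna)))
  genes <- intersect(unique(unlist(up_lists)), rownames(mrna))
  X <- t(mirna[validated_mirnas, , drop = FALSE])
  rows <- list()
  for (g in genes) {
    fit <- fit_stepwise(mrna[g, ], X)
    neg <- fit$selected[fit$selected < 0]
    for (m in names(neg)) {
      in_vitro <- !is.null(up_lists[[m]]) && g %in% up_lists[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, mirna = m, coefficient = unname(neg[[m]]),
        in_vitro = in_vitro, edge = if (in_vitro) "solid" else "dashed",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(), mirna = character(),
                         coefficient = numeric(), in_vitro = logical(),
                         edge = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export a core-target network as an edge-list TSV
#'
#' @param core_targets output of [identify_core_targets()].
#' @param path output file.
#' @export
write_core_target_network <- function(core_targets, path) {
  utils::write.table(core_targets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
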
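#' Hypergeometric target enrichment with O/E ratio
#'
#' Upper-tail hypergeometric test of the overlap between a microRNA's
#' predicted targets and a signature gene set within a gene universe, plus
#' the observed/expected overlap ratio. Targets are intersected with the
#' universe before testing; the p-value is Bonferroni-adjusted by `n_tests`.
#'
#' @param targets character vector of target genes.
#' @param signature character vector of signature genes (subset of universe).
#' @param universe character vector of universe genes.
#' @param n_tests Bonferroni family size (>= 1).
#' @return list `k` (overlap), `p` (raw), `p_adj`, `oe_ratio`, `n_targets`,
#'   `n_signature`, `n_universe`.
#' @export
hypergeom_enrichment <- function(targets, signature, universe, n_tests = 1) {
  if (length(universe) == 0) stop("empty universe")
  if (length(signature) == 0) stop("empty signature")
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (!all(signature %in% universe)) stop("signature must be a subset of the universe")
  targets <- intersect(targets, universe)
  k <- length(intersect(targets, signature))
  Tn <- length(targets); S <- length(signature); U <- length(universe)
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, S, U - S, Tn, lower.tail = FALSE)
  expected <- Tn * S / U
  oe <- if (expected > 0) k / expected else 0
  list(k = k, p = p, p_adj = min(1, p * n_tests), oe_ratio = oe,
       n_targets = Tn, n_signature = S, n_universe = U)
}

# enrichment table for one set of (mirna, subtype) pairs within a classifier;
# both UP and DOWN signatures are tested for every pair
enrich_table <- function(pairs, classifier, target_map, signatures, universe) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    m <- pairs$mirna[i]; s <- pairs$subtype[i]
    tg <- targets_of(target_map, m)
    for (dir in c("UP", "DOWN")) {
      sig <- intersect(signature_genes(signatures, classifier, s, dir), universe)
      if (length(sig) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        classifier = classifier, subtype = s, mirna = m, sig_direction = dir,
        n_targets_mapped = length(tg), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(NULL)
  n_tests <- nrow(tab)  # Bonferroni family: all tests within the classifier
  stats <- lapply(seq_len(nrow(tab)), function(i) {
    tg <- targets_of(target_map, tab$mirna[i])
    sig <- intersect(signature_genes(signatures, classifier, tab$subtype[i],
                                     tab$sig_direction[i]), universe)
    if (length(tg) == 0)
      return(list(k = 0L, p = 1, p_adj = 1, oe_ratio = 0))
    hypergeom_enrichment(tg, sig, universe, n_tests)
  })
  tab$k <- vapply(stats, function(x) as.integer(x$k), 1L)
  tab$p <- vapply(stats, function(x) x$p, 1)
  tab$p_adj <- vapply(stats, function(x) x$p_adj, 1)
  tab$oe_ratio <- vapply(stats, function(x) x$oe_ratio, 1)
  tab
}

count_enriched <- function(tab, p_thr, oe_thr) {
  if (is.null(tab) || nrow(tab) == 0) return(0L)
  sig <- tab$p_adj < p_thr & tab$oe_ratio > oe_thr
  # a microRNA counts once per subtype even if both directions pass
  length(unique(paste(tab$mirna, tab$subtype)[sig]))
}

#' Select enrichment thresholds by randomized-set FDR
#'
#' For each classifier and each (p, O/E) grid cell: FDR = mean number of
#' significant microRNAs across `n_iter` random microRNA sets (same size as
#' the observed subtype-specific set, drawn from all microRNAs with mapped
#' targets) divided by the observed significant count. The minimizing cell
#' is chosen per classifier (ties broken toward the more stringent pair).
#'
#' @param de differential-expression table ([differential_micrornas()]),
#'   `pass` rows are used.
#' @param target_map predicted-target map.
#' @param signatures signature table.
#' @param universe gene universe for the hypergeometric test.
#' @param p_grid,oe_grid threshold grids.
#' @param n_iter random iterations (default 1000).
#' @return list per classifier: `p_threshold`, `oe_threshold`, `fdr_table`.
#' @export
select_enrichment_thresholds <- function(de, target_map, signatures, universe,
                                         p_grid = c(0.001, 0.01, 0.05),
                                         oe_grid = c(1.5, 2, 2.5),
                                         n_iter = 1000) {
  pool <- unique(target_map$mirna)
  out <- list()
  for (cl in unique(de$classifier)) {
    hits <- de[de$classifier == cl & de$pass, c("mirna", "subtype")]
    if (nrow(hits) == 0) next
    obs_tab <- enrich_table(hits, cl, target_map, signatures, universe)
    grid <- expand.grid(p_thr = p_grid, oe_thr = oe_grid)
    grid$n_observed <- vapply(seq_len(nrow(grid)), function(i)
      count_enriched(obs_tab, grid$p_thr[i], grid$oe_thr[i]), 1L)
    rand_sum <- numeric(nrow(grid))
    sizes <- table(hits$subtype)
    for (it in seq_len(n_iter)) {
      rnd <- do.call(rbind, lapply(names(sizes), function(s)
        data.frame(mirna = sample(pool, sizes[[s]]), subtype = s,
                   stringsAsFactors = FALSE)))
      rtab <- enrich_table(rnd, cl, target_map, signatures, universe)
      rand_sum <- rand_sum + vapply(seq_len(nrow(grid)), function(i)
        count_enriched(rtab, grid$p_thr[i], grid$oe_thr[i]), 1L)
    }
    grid$mean_n_random <- rand_sum / n_iter
    grid$fdr <- ifelse(grid$n_observed > 0,
                       grid$mean_n_random / grid$n_observed, NA_real_)
    ok <- which(!is.na(grid$fdr))
    best <- if (length(ok)) {
      o <- ok[order(grid$fdr[ok], grid$p_thr[ok], -grid$oe_thr[ok])]
      o[1]
    } else NA_integer_
    out[[cl]] <- list(
      p_threshold = if (is.na(best)) min(p_grid) else grid$p_thr[best],
      oe_threshold = if (is.na(best)) max(oe_grid) else grid$oe_thr[best],
      fdr_table = grid)
  }
  out
}

#' Filter differential microRNAs by target enrichment
#'
#' A (microRNA, subtype) association passes when the microRNA's predicted
#' targets are enriched in that subtype's UP or DOWN signature at the
#' classifier's thresholds. MicroRNAs absent from the target map are logged
#' and fail automatically. Both direction results are emitted with a `pass`
#' flag.
#'
#' @param de differential-expression table (`pass` rows are used).
#' @param thresholds output of [select_enrichment_thresholds()], or a list of
#'   per-classifier `list(p_threshold=, oe_threshold=)`.
#' @param target_map,signatures,universe as in
#'   [select_enrichment_thresholds()].
#' @return enrichment results data frame with logical `pass`.
#' @export
filter_by_enrichment <- function(de, thresholds, target_map, signatures, universe) {
  out <- list()
  for (cl in unique(de$classifier)) {
    hits <- de[de$classifier == cl & de$pass, c("mirna", "subtype")]
    if (nrow(hits) == 0) next
    unmapped <- setdiff(unique(hits$mirna), unique(target_map$mirna))
    if (length(unmapped))
      mmra_log(sprintf("%s: %d differential microRNA(s) have no mapped targets: %s",
                       cl, length(unmapped), paste(unmapped, collapse = ", ")))
    tab <- enrich_table(hits, cl, target_map, signatures, universe)
    if (is.null(tab)) next
    th <- thresholds[[cl]]
    tab$pass <- tab$p_adj < th$p_threshold & tab$oe_ratio > th$oe_threshold
    out[[cl]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
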
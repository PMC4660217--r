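#' Preprocess a stacked matrix for network inference
#'
#' Row-wise stacks the mRNA matrix and one microRNA profile, undoes the log2
#' transform (`Y = 2^X`), quantile-normalizes across samples (mean-of-sorted
#' reference), re-applies log2, and drops genes whose standard deviation on
#' the processed scale falls below `sd_min`. The hub row is exempt from the
#' filter.
#'
#' @param mrna mRNA expression matrix (log2).
#' @param mirna_row named single-row numeric vector (log2 microRNA profile),
#'   or a 1-row matrix; name must not clash with a gene id.
#' @param sd_min s.d. filter threshold (default 1.2).
#' @return list `matrix` (filtered, hub last row), `hub` (hub id),
#'   `removed` (dropped gene ids).
#' @export
preprocess_for_network <- function(mrna, mirna_row, sd_min = 1.2) {
  if (is.matrix(mirna_row)) {
    hub <- rownames(mirna_row)[1]
    mirna_row <- mirna_row[1, ]
  } else {
    hub <- attr(mirna_row, "hub") %||% names(mirna_row)[1]
  }
  if (is.null(hub) || is.na(hub)) stop("hub row must be named")
  if (stats::sd(mirna_row) == 0) stop("hub profile is constant")
  if (!identical(length(mirna_row), ncol(mrna)))
    stop("hub profile and mRNA matrix must share the sample set")
  x <- rbind(mrna, mirna_row)
  rownames(x)[nrow(x)] <- hub
  y <- 2^x
  yn <- limma::normalizeQuantiles(y)
  z <- log2(yn)
  sds <- apply(z, 1, stats::sd)
  keep <- sds >= sd_min
  keep[nrow(z)] <- TRUE  # hub always retained
  removed <- rownames(z)[!keep]
  list(matrix = z[keep, , drop = FALSE], hub = hub, removed = removed)
}

# bandwidth of the Gaussian-kernel MI estimator on the copula scale:
# Silverman-type 2-D rule, sd(uniform) * n^(-1/6)
mi_bandwidth <- function(n) n^(-1 / 6) / sqrt(12)

#' Mutual information (Gaussian kernel, copula transform)
#'
#' Kernel-density MI estimate on rank-transformed (copula) data with a
#' sample-size-dependent bandwidth; symmetric, clamped at zero, invariant
#' under strictly monotone transforms of either argument. For bivariate
#' Gaussian data with correlation rho the estimate tracks the closed form
#' `-0.5 * log(1 - rho^2)`.
#'
#' @param x,y numeric vectors of equal length >= 10.
#' @return nonnegative MI estimate (nats).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("need at least 10 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  cpp_mutual_information(as.numeric(x), as.numeric(y), mi_bandwidth(length(x)))
}

#' MI significance threshold from a permutation null
#'
#' Pools `n_null` MI values computed between independently permuted rank
#' vectors of length `n_samples`, fits a linear model of `log(p)` versus MI
#' on the null tail (empirical survival probabilities of the largest
#' `tail_frac` values) and extrapolates to `p_target`. Uses R's RNG stream.
#'
#' @param n_samples sample size of the expression matrix.
#' @param p_target target significance level (default 1e-7).
#' @param n_null pooled permutation-null size (default 1e5).
#' @param tail_frac fraction of the null used for the tail fit (default 0.05).
#' @return list `threshold`, `fit` (slope/intercept), `null_quantile99`.
#' @export
mi_significance_threshold <- function(n_samples, p_target = 1e-7,
                                      n_null = 1e5, tail_frac = 0.05) {
  if (p_target >= 1) return(list(threshold = 0, fit = NULL, null_quantile99 = NA))
  null_mi <- sort(cpp_null_mi(as.integer(n_samples), as.integer(n_null),
                              mi_bandwidth(n_samples)), decreasing = TRUE)
  k <- max(50L, ceiling(tail_frac * n_null))
  if (k > n_null) stop("null sample too small for the tail fit")
  mi_tail <- null_mi[seq_len(k)]
  p_tail <- seq_len(k) / n_null  # empirical survival probability
  if (stats::sd(mi_tail) == 0) stop("degenerate null tail (constant MI)")
  fit <- stats::lm(log(p_tail) ~ mi_tail)
  b <- coef(fit)
  if (b[2] >= 0) stop("degenerate null-tail fit (non-negative slope)")
  thr <- unname((log(p_target) - b[1]) / b[2])
  list(threshold = thr, fit = c(intercept = unname(b[1]), slope = unname(b[2])),
       null_quantile99 = pctl(null_mi, 99))
}

#' Build a single-hub bootstrap-consensus regulon
#'
#' For each of `n_boot` bootstraps (samples resampled with replacement), the
#' hub-gene MI is computed for every retained gene and edges above
#' `mi_threshold` are kept. Edge support counts are then tested against a
#' binomial null with success rate = total kept edges / (n_boot * n_genes)
#' (random edge placement); edges with support p below `consensus_p` form
#' the regulon. Uses R's RNG stream.
#'
#' @param prep output of [preprocess_for_network()].
#' @param mi_threshold MI significance threshold
#'   ([mi_significance_threshold()]).
#' @param n_boot bootstrap networks (default 100).
#' @param consensus_p binomial support p-value threshold (default 1e-12).
#' @return object of class `mmra_regulon`: list `hub`, `edges` (data frame
#'   `gene`, `mi`, `support`, `support_p`), `n_boot`, `mi_threshold`.
#' @export
build_regulon <- function(prep, mi_threshold, n_boot = 100, consensus_p = 1e-12) {
  m <- prep$matrix
  hub_i <- which(rownames(m) == prep$hub)
  genes <- rownames(m)[-hub_i]
  gm <- m[-hub_i, , drop = FALSE]
  n <- ncol(m)
  h <- mi_bandwidth(n)
  support <- integer(length(genes))
  mi_sum <- numeric(length(genes))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    mi <- cpp_mi_hub(m[hub_i, idx], gm[, idx, drop = FALSE], h)
    kept <- mi > mi_threshold
    support[kept] <- support[kept] + 1L
    mi_sum[kept] <- mi_sum[kept] + mi[kept]
  }
  total_kept <- sum(support)
  rate <- total_kept / (n_boot * length(genes))
  support_p <- stats::pbinom(support - 1L, n_boot, rate, lower.tail = FALSE)
  keep <- support > 0 & support_p < consensus_p
  edges <- data.frame(gene = genes[keep],
                      mi = ifelse(support[keep] > 0,
                                  mi_sum[keep] / support[keep], 0),
                      support = support[keep], support_p = support_p[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$mi), ]
  rownames(edges) <- NULL
  if (nrow(edges) == 0)
    mmra_log(sprintf("empty regulon for hub %s", prep$hub))
  structure(list(hub = prep$hub, edges = edges, n_boot = n_boot,
                 mi_threshold = mi_threshold, edge_rate = rate),
            class = "mmra_regulon")
}

#' @export
print.mmra_regulon <- function(x, ...) {
  cat(sprintf("<mmra_regulon> hub %s: %d edge(s), %d bootstraps, MI threshold %.4g\n",
              x$hub, nrow(x$edges), x$n_boot, x$mi_threshold))
  invisible(x)
}

#' Master regulator analysis test
#'
#' Upper-tail Fisher's exact test of the overlap between a regulon and a
#' signature gene set over a gene universe.
#'
#' @param regulon `mmra_regulon` object or character vector of regulon genes.
#' @param signature character vector of signature genes.
#' @param universe character vector of universe genes.
#' @return list `overlap`, `p`.
#' @export
mra_test <- function(regulon, signature, universe) {
  genes <- if (inherits(regulon, "mmra_regulon")) regulon$edges$gene else regulon
  genes <- intersect(genes, universe)
  signature <- intersect(signature, universe)
  if (length(genes) == 0) return(list(overlap = 0L, p = 1))
  k <- length(intersect(genes, signature))
  tab <- matrix(c(k, length(genes) - k, length(signature) - k,
                  length(universe) - length(genes) - length(signature) + k), 2)
  list(overlap = k, p = stats::fisher.test(tab, alternative = "greater")$p.value)
}

#' Null-model specification for the MRA threshold
#'
#' @param min_expressed_frac minimum fraction of samples in which a null
#'   microRNA must be detected (default 0.1, i.e. > 45 of 450).
#' @param detect_thr log2 detection threshold (default 0).
#' @param snr_bound signal-to-noise bound; SNR = difference of group means
#'   divided by the sum of within-group s.d. A null microRNA needs
#'   |SNR| < `snr_bound` in every subtype contrast (default 0.05). Set
#'   `literal_sign = TRUE` for the one-sided reading SNR < -`snr_bound`.
#' @param max_regulon_overlap maximum overlap (shared / smaller regulon size)
#'   with any candidate regulon (default 0.70).
#' @param literal_sign use the one-sided SNR filter.
#' @return a `null_model_spec` list.
#' @export
null_model_spec <- function(min_expressed_frac = 0.1, detect_thr = 0,
                            snr_bound = 0.05, max_regulon_overlap = 0.70,
                            literal_sign = FALSE) {
  structure(list(min_expressed_frac = min_expressed_frac,
                 detect_thr = detect_thr, snr_bound = snr_bound,
                 max_regulon_overlap = max_regulon_overlap,
                 literal_sign = literal_sign), class = "null_model_spec")
}

snr_stat <- function(x, y) {
  (mean(x) - mean(y)) / (stats::sd(x) + stats::sd(y))
}

#' Select null-model microRNAs and build their regulons
#'
#' Null microRNAs are expressed (detected above `detect_thr` in more than
#' `min_expressed_frac` of samples) but not differential (SNR within bound
#' in every subtype contrast of every supplied core set), and their regulons
#' must overlap every candidate regulon by less than `max_regulon_overlap`
#' (shared genes / smaller regulon).
#'
#' @param mirna microRNA expression matrix.
#' @param mrna mRNA expression matrix (for per-hub preprocessing).
#' @param cores_list list of core-sample sets (one per classifier).
#' @param candidate_regulons list of `mmra_regulon` for the candidates.
#' @param spec a [null_model_spec()].
#' @param mi_threshold,n_boot,consensus_p,sd_min regulon-building parameters.
#' @param max_null cap on the number of null regulons built (cost control).
#' @return list `mirnas` (selected ids), `regulons` (list of `mmra_regulon`).
#' @export
build_null_model <- function(mirna, mrna, cores_list, candidate_regulons,
                             spec = null_model_spec(), mi_threshold,
                             n_boot = 100, consensus_p = 1e-12, sd_min = 1.2,
                             max_null = 20) {
  n <- ncol(mirna)
  detected <- rowMeans(mirna > spec$detect_thr) > spec$min_expressed_frac
  cand_hubs <- vapply(candidate_regulons, function(r) r$hub, "")
  ok <- detected & !(rownames(mirna) %in% cand_hubs)
  for (cores in cores_list) {
    for (s in names(cores$cores)) {
      core <- intersect(cores$cores[[s]], colnames(mirna))
      if (length(core) < 2) next
      rest <- setdiff(colnames(mirna), intersect(cores$members[[s]], colnames(mirna)))
      snr <- apply(mirna, 1, function(v) snr_stat(v[core], v[rest]))
      pass <- if (spec$literal_sign) snr < -spec$snr_bound
              else abs(snr) < spec$snr_bound
      ok <- ok & pass
    }
  }
  sel <- rownames(mirna)[ok]
  if (length(sel) > max_null) sel <- sel[seq_len(max_null)]
  regs <- list()
  for (m in sel) {
    prep <- preprocess_for_network(mrna, mirna[m, , drop = FALSE], sd_min = sd_min)
    reg <- build_regulon(prep, mi_threshold, n_boot, consensus_p)
    overlap_ok <- all(vapply(candidate_regulons, function(cr) {
      a <- reg$edges$gene; b <- cr$edges$gene
      if (length(a) == 0 || length(b) == 0) return(TRUE)
      length(intersect(a, b)) / min(length(a), length(b)) < spec$max_regulon_overlap
    }, TRUE))
    if (overlap_ok) regs[[m]] <- reg
  }
  if (length(regs) == 0)
    warning("no microRNAs qualified for the null model; ",
            "MRA threshold will fall back to its default")
  list(mirnas = names(regs), regulons = regs)
}

#' MRA p-value threshold from the null model
#'
#' The threshold is the lower-tail percentile of the null MRA p-value
#' distribution such that `percentile`% of null p-values lie above it.
#' Candidates with MRA p above the threshold are filtered out.
#'
#' @param null_p numeric vector of null-model MRA p-values (may be empty).
#' @param percentile coverage of the null above the threshold (default 95).
#' @param fallback threshold used when the null model is empty
#'   (default 1e-4).
#' @return list `threshold`, `n_null`, `fallback_used`, `permissive`.
#' @export
mra_threshold_from_null <- function(null_p, percentile = 95, fallback = 1e-4) {
  if (length(null_p) == 0)
    return(list(threshold = fallback, n_null = 0L, fallback_used = TRUE,
                permissive = FALSE))
  thr <- pctl(null_p, 100 - percentile)
  permissive <- thr > 0.05
  if (permissive)
    mmra_log(sprintf(
      "null MRA p-values are large (threshold %.3g); gate is permissive", thr))
  list(threshold = thr, n_null = length(null_p), fallback_used = FALSE,
       permissive = permissive)
}

#' Preranked enrichment of a signature along MI-ranked regulon genes
#'
#' Regulon genes are ranked by decreasing MI; a weighted running-sum
#' enrichment score (weight = MI for signature hits, uniform penalty for
#' misses) is normalized against gene-label permutations. Uses R's RNG
#' stream.
#'
#' @param regulon `mmra_regulon` object.
#' @param signature character vector of signature genes.
#' @param n_perm label permutations (default 1000).
#' @return list `es`, `nes`, `perm_p`, `leading_edge`.
#' @export
mi_rank_enrichment <- function(regulon, signature, n_perm = 1000) {
  edges <- regulon$edges[order(-regulon$edges$mi), ]
  genes <- edges$gene
  w <- edges$mi
  hit <- genes %in% signature
  if (!any(hit)) stop("no signature genes in the regulon")
  es_of <- function(hit) {
    inc <- ifelse(hit, w / sum(w[hit]), 0)
    dec <- ifelse(hit, 0, 1 / max(1L, sum(!hit)))
    run <- cumsum(inc - dec)
    run[which.max(abs(run))]
  }
  es <- es_of(hit)
  perm <- vapply(seq_len(n_perm), function(i) es_of(sample(hit)), 1)
  same <- perm[sign(perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  perm_p <- (1 + sum(abs(perm) >= abs(es) & sign(perm) == sign(es))) / (1 + n_perm)
  peak <- which.max(abs(cumsum(ifelse(hit, w / sum(w[hit]), 0) -
                               ifelse(hit, 0, 1 / sum(!hit)))))
  leading <- if (es > 0) genes[seq_len(peak)][hit[seq_len(peak)]]
             else genes[seq(peak, length(genes))][hit[seq(peak, length(genes))]]
  list(es = es, nes = nes, perm_p = perm_p, leading_edge = leading)
}
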
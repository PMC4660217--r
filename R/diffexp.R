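#' Select subtype core samples
#'
#' Core membership for one classifier: classification FDR below `fdr_max`
#' and distance to the nearest template strictly below the
#' `delta_percentile` of the pooled delta distribution across all samples of
#' that classifier (linear-interpolation percentile).
#'
#' @param records classification data frame.
#' @param classifier classifier to process.
#' @param fdr_max NTP FDR ceiling (default 0.05).
#' @param delta_percentile percentile of the pooled delta distribution
#'   defining the distance threshold (default 95).
#' @param use_delta set `FALSE` for binary designs without meaningful
#'   template distances; cores then use the FDR rule only.
#' @return list with `classifier`, `delta_threshold`, `cores` (named list of
#'   core sample ids per subtype) and `members` (full subtype membership).
#' @export
select_core_samples <- function(records, classifier, fdr_max = 0.05,
                                delta_percentile = 95, use_delta = TRUE) {
  r <- records[records$classifier == classifier, ]
  if (nrow(r) == 0) stop("no records for classifier ", classifier)
  thr <- if (use_delta) pctl(r$delta, delta_percentile) else Inf
  subtypes <- sort(unique(r$subtype))
  cores <- lapply(subtypes, function(s) {
    ok <- r$subtype == s & r$ntp_fdr < fdr_max & r$delta < thr
    r$sample[ok]
  })
  names(cores) <- subtypes
  empty <- vapply(cores, length, 1L) == 0
  if (any(empty)) {
    warning("empty core for subtype(s): ", paste(subtypes[empty], collapse = ", "),
            "; skipped downstream")
  }
  members <- split(r$sample, r$subtype)
  list(classifier = classifier, delta_threshold = thr,
       cores = cores, members = members)
}

#' Bootstrap Kolmogorov-Smirnov test
#'
#' Two-sample KS statistic with a bootstrap null: `n_boot` resamples with
#' replacement from the pooled sample into groups of the original sizes;
#' `p = (1 + #\{D_boot >= D\}) / (1 + n_boot)`. Uses R's RNG stream.
#'
#' @param x,y numeric samples (nonempty).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @return list `statistic` (D), `p.value`, `n_boot`.
#' @export
ks_boot <- function(x, y, n_boot = 1000) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  if (n_boot < 1) stop("n_boot must be >= 1")
  r <- cpp_ks_boot(as.numeric(x), as.numeric(y), as.integer(n_boot), 0L)
  list(statistic = r$statistic,
       p.value = (1 + r$exceed) / (1 + n_boot), n_boot = n_boot)
}

# early-exit variant used inside permutation grids: returns TRUE when the
# bootstrap p is provably < p_thr, FALSE as soon as it is provably >= p_thr
ks_boot_passes <- function(x, y, p_thr, n_boot) {
  max_exceed <- ceiling(p_thr * (1 + n_boot))  # exceed >= this => p >= p_thr
  r <- cpp_ks_boot(as.numeric(x), as.numeric(y), as.integer(n_boot),
                   as.integer(max_exceed))
  (1 + r$exceed) / (1 + n_boot) < p_thr
}

#' Fold change between two log2 groups
#'
#' `FC = 2^(mean(x) - mean(y))` (geometric mean ratio on the linear scale).
#' The absolute criterion "FC > t" is met when `FC > t` or `FC < 1/t`.
#'
#' @param x_log2,y_log2 numeric log2 expression values.
#' @return positive fold change.
#' @export
fold_change <- function(x_log2, y_log2) 2^(mean(x_log2) - mean(y_log2))

fc_passes <- function(fc, fc_thr) fc > fc_thr | fc < 1 / fc_thr

#' Subtype-specific differential microRNA expression
#'
#' For each (subtype, microRNA): contrast subtype core samples against all
#' other samples, excluding non-core members of the test subtype from both
#' groups (low-confidence members contribute to neither side). A microRNA is
#' retained when the bootstrap KS p-value is below `p_thr` and the absolute
#' fold change exceeds `fc_thr`. The KS test is only run where the
#' fold-change criterion holds (retention requires both); other rows carry
#' `ks_p = NA`.
#'
#' @param mirna microRNA expression matrix (log2).
#' @param cores output of [select_core_samples()].
#' @param p_thr KS p-value threshold (default 0.001).
#' @param fc_thr absolute fold-change threshold (default 2).
#' @param n_boot bootstrap resamples per test (default 1000).
#' @return data frame `classifier`, `subtype`, `mirna`, `fold_change`,
#'   `ks_p`, `direction`, `pass`.
#' @export
differential_micrornas <- function(mirna, cores, p_thr = 0.001, fc_thr = 2,
                                   n_boot = 1000) {
  samples <- colnames(mirna)
  out <- list()
  for (s in names(cores$cores)) {
    core <- intersect(cores$cores[[s]], samples)
    if (length(core) == 0) next
    rest <- setdiff(samples, intersect(cores$members[[s]], samples))
    fc <- 2^(rowMeans(mirna[, core, drop = FALSE]) -
             rowMeans(mirna[, rest, drop = FALSE]))
    ks_p <- rep(NA_real_, nrow(mirna))
    cand <- which(fc_passes(fc, fc_thr))
    for (i in cand)
      ks_p[i] <- ks_boot(mirna[i, core], mirna[i, rest], n_boot)$p.value
    out[[s]] <- data.frame(
      classifier = cores$classifier, subtype = s, mirna = rownames(mirna),
      fold_change = unname(fc), ks_p = ks_p,
      direction = ifelse(fc > 1, "UP", "DOWN"),
      pass = !is.na(ks_p) & ks_p < p_thr, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# count of (subtype, microRNA) passes on a grid of (p, fc) thresholds, given
# one assignment of samples; shared by observed and permuted runs
de_grid_counts <- function(mirna, cores, p_grid, fc_grid, n_boot) {
  fc_min <- min(fc_grid)
  p_max <- max(p_grid)
  counts <- matrix(0L, length(p_grid), length(fc_grid),
                   dimnames = list(paste0("p", p_grid), paste0("fc", fc_grid)))
  samples <- colnames(mirna)
  for (s in names(cores$cores)) {
    core <- intersect(cores$cores[[s]], samples)
    if (length(core) == 0) next
    rest <- setdiff(samples, intersect(cores$members[[s]], samples))
    fc <- 2^(rowMeans(mirna[, core, drop = FALSE]) -
             rowMeans(mirna[, rest, drop = FALSE]))
    cand <- which(fc_passes(fc, fc_min))
    for (i in cand) {
      r <- cpp_ks_boot(mirna[i, core], mirna[i, rest], as.integer(n_boot),
                       as.integer(ceiling(p_max * (1 + n_boot))))
      p <- (1 + r$exceed) / (1 + n_boot)
      for (a in seq_along(p_grid))
        for (b in seq_along(fc_grid))
          if (p < p_grid[a] && fc_passes(fc[i], fc_grid[b]))
            counts[a, b] <- counts[a, b] + 1L
    }
  }
  counts
}

#' Permutation-based FDR grid for the differential thresholds
#'
#' For each (p, FC) threshold pair, the FDR is the mean number of significant
#' (subtype, microRNA) calls over `n_perm` sample-reshuffled datasets divided
#' by the observed significant count (`NA` when the observed count is zero).
#' The recommended pair minimizes FDR; when several pairs are comparable the
#' intermediate (sufficiently selective but not over-stringent) choice is the
#' sensible default, as the attached note records.
#'
#' @param mirna microRNA expression matrix.
#' @param cores output of [select_core_samples()].
#' @param p_grid,fc_grid threshold grids.
#' @param n_perm number of sample reshuffles (default 1000).
#' @param n_boot KS bootstrap resamples per test.
#' @return data frame (`p_thr`, `fc_thr`, `n_observed`, `mean_n_permuted`,
#'   `fdr`) with attributes `recommended` (row index) and `note`.
#' @export
permutation_fdr_grid <- function(mirna, cores, p_grid = c(0.001, 0.01),
                                 fc_grid = c(1.5, 2, 2.5), n_perm = 1000,
                                 n_boot = 1000) {
  obs <- de_grid_counts(mirna, cores, p_grid, fc_grid, n_boot)
  perm_sum <- matrix(0, length(p_grid), length(fc_grid))
  samples <- colnames(mirna)
  for (k in seq_len(n_perm)) {
    shuf <- mirna
    colnames(shuf) <- sample(samples)  # reshuffle sample identities
    shuf <- shuf[, samples, drop = FALSE]
    perm_sum <- perm_sum + de_grid_counts(shuf, cores, p_grid, fc_grid, n_boot)
  }
  perm_mean <- perm_sum / n_perm
  g <- expand.grid(p_thr = p_grid, fc_thr = fc_grid)
  g$n_observed <- as.vector(obs)
  g$mean_n_permuted <- as.vector(perm_mean)
  g$fdr <- ifelse(g$n_observed > 0, g$mean_n_permuted / g$n_observed, NA_real_)
  ok <- which(!is.na(g$fdr))
  attr(g, "recommended") <- if (length(ok)) ok[which.min(g$fdr[ok])] else NA_integer_
  attr(g, "note") <- paste(
    "When several threshold pairs reach comparably low FDR, prefer the",
    "intermediate pair: the first pipeline stage should be selective but",
    "not so stringent that true candidates are lost.")
  g
}
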
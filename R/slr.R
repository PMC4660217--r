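#' Bidirectional stepwise linear regression with AIC stopping
#'
#' Starting from the full model (gene expression regressed on all candidate
#' microRNAs), single-variable drops and adds are evaluated and the
#' AIC-minimizing move taken until no move lowers AIC by more than `tol`.
#' Exact ties (within `tol`) are broken toward the smaller model, then by
#' variable name, making the search invariant to candidate input order. A
#' near-perfect fit is guarded by flooring the residual sum of squares.
#'
#' @param y numeric response (log2 gene expression across samples).
#' @param X numeric matrix of candidate explanatory variables
#'   (samples x microRNAs, named columns).
#' @param tol AIC comparison tolerance (default 1e-8).
#' @return list `selected` (named coefficient vector, intercept excluded,
#'   possibly empty), `aic`, `n_candidates`.
#' @export
fit_stepwise <- function(y, X, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("candidate columns must be named")
  n <- length(y)
  p <- ncol(X)
  if (p < 1) stop("need at least one candidate")
  if (n <= p + 1) stop("need more samples than candidates + 1")
  X <- X[, order(colnames(X)), drop = FALSE]

  rss_floor <- n * 1e-12
  aic_of <- function(vars) {
    if (length(vars) == 0) {
      rss <- sum((y - mean(y))^2)
      k <- 1
    } else {
      f <- stats::lm.fit(cbind(1, X[, vars, drop = FALSE]), y)
      rss <- sum(f$residuals^2)
      k <- length(vars) + 1
    }
    rss <- max(rss, rss_floor)
    n * log(rss / n) + 2 * (k + 1)  # Gaussian AIC up to an additive constant
  }

  current <- colnames(X)            # start from the full model
  cur_aic <- aic_of(current)
  repeat {
    moves <- list()
    for (v in current)              # drops first: ties favour smaller models
      moves[[paste0("-", v)]] <- aic_of(setdiff(current, v))
    for (v in setdiff(colnames(X), current))
      moves[[paste0("+", v)]] <- aic_of(c(current, v))
    if (length(moves) == 0) break
    aics <- unlist(moves)
    best <- min(aics)
    if (best >= cur_aic - tol) break
    # among moves tied within tol of the best, the first (drop, name order) wins
    pick <- names(aics)[which(aics <= best + tol)[1]]
    v <- substring(pick, 2)
    current <- if (substring(pick, 1, 1) == "-") setdiff(current, v)
               else sort(c(current, v))
    cur_aic <- aics[[pick]]
  }

  if (length(current) == 0)
    return(list(selected = stats::setNames(numeric(0), character(0)),
                aic = cur_aic, n_candidates = p))
  f <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, current, drop = FALSE]), y)
  co <- f$coefficients[-1]
  names(co) <- current
  list(selected = co, aic = cur_aic, n_candidates = p)
}

#' Aggregate stepwise selections to microRNA-level fractions
#'
#' For each microRNA and each signature: the fraction of that signature's
#' genes (restricted to `universe`, the genes eligible for fitting) whose
#' selected explanatory set includes the microRNA, split by coefficient
#' sign.
#'
#' @param gene_fits named list (gene id -> [fit_stepwise()] result); genes
#'   without a model are simply absent.
#' @param signatures long signature data frame.
#' @param universe character vector of genes the fits were run over (the
#'   expression matrix gene space); signature sizes are computed within it.
#' @return data frame `mirna`, `classifier`, `subtype`, `direction`,
#'   `n_signature`, `n_selected_neg`, `n_selected_pos`, `frac_neg`,
#'   `frac_pos`.
#' @export
aggregate_fractions <- function(gene_fits, signatures, universe) {
  sel <- lapply(gene_fits, `[[`, "selected")
  mirnas <- sort(unique(unlist(lapply(sel, names))))
  keys <- unique(signatures[, c("classifier", "subtype", "direction")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sig <- intersect(signature_genes(signatures, keys$classifier[i],
                                     keys$subtype[i], keys$direction[i]),
                     universe)
    if (length(sig) == 0) next
    in_sig <- intersect(sig, names(sel))
    for (m in mirnas) {
      co <- vapply(sel[in_sig], function(s) if (m %in% names(s)) s[[m]] else NA_real_, 1)
      n_neg <- sum(!is.na(co) & co < 0)
      n_pos <- sum(!is.na(co) & co > 0)
      rows[[length(rows) + 1]] <- data.frame(
        mirna = m, classifier = keys$classifier[i], subtype = keys$subtype[i],
        direction = keys$direction[i], n_signature = length(sig),
        n_selected_neg = n_neg, n_selected_pos = n_pos,
        frac_neg = n_neg / length(sig), frac_pos = n_pos / length(sig),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Percentile threshold over pooled attribution fractions
#'
#' @param attributions output of [aggregate_fractions()] (or a numeric
#'   vector of fractions).
#' @param percentile pooled percentile (default 90).
#' @return the threshold (fractions must strictly exceed it downstream).
#' @export
fraction_threshold <- function(attributions, percentile = 90) {
  fr <- if (is.numeric(attributions)) attributions
        else c(attributions$frac_neg, attributions$frac_pos)
  if (length(fr) == 0) stop("no fractions to pool")
  thr <- pctl(fr, percentile)
  if (all(fr == fr[1]))
    mmra_log("all pooled fractions are equal; strict threshold passes none")
  thr
}

#' Assemble the final candidate table
#'
#' A candidate record is emitted for each (microRNA, classifier, subtype,
#' signature direction) association that survived differential expression,
#' target enrichment and MRA, and whose attribution fraction strictly
#' exceeds the threshold. The dominant coefficient sign, the concordance of
#' microRNA expression direction with the signature direction, and any other
#' same-classifier signatures passing the fraction threshold via regression
#' alone are recorded.
#'
#' @param attributions output of [aggregate_fractions()].
#' @param threshold output of [fraction_threshold()].
#' @param de differential-expression table.
#' @param enrichment enrichment table ([filter_by_enrichment()]).
#' @param mra data frame `mirna`, `classifier`, `subtype`, `sig_direction`,
#'   `p`, `pass` of MRA results.
#' @return data frame of candidate records (possibly empty).
#' @export
final_candidates <- function(attributions, threshold, de, enrichment, mra) {
  de_pass <- de[de$pass, c("classifier", "subtype", "mirna", "direction")]
  names(de_pass)[4] <- "expr_direction"
  en_pass <- enrichment[enrichment$pass,
                        c("classifier", "subtype", "mirna", "sig_direction")]
  mra_pass <- mra[mra$pass, c("classifier", "subtype", "mirna", "sig_direction")]
  assoc <- merge(merge(de_pass, en_pass), mra_pass)
  if (nrow(assoc) == 0) return(empty_candidates())
  rows <- list()
  for (i in seq_len(nrow(assoc))) {
    a <- assoc[i, ]
    fr <- attributions[attributions$mirna == a$mirna &
                       attributions$classifier == a$classifier &
                       attributions$subtype == a$subtype &
                       attributions$direction == a$sig_direction, ]
    if (nrow(fr) == 0) next
    frac <- max(fr$frac_neg, fr$frac_pos)
    if (!(frac > threshold)) {
      if (frac == threshold)
        mmra_log(sprintf("boundary fraction for %s / %s %s-%s: %.3f == threshold",
                         a$mirna, a$classifier, a$subtype, a$sig_direction, frac))
      next
    }
    sign <- if (fr$frac_neg >= fr$frac_pos) "negative" else "positive"
    others <- attributions[attributions$mirna == a$mirna &
                           attributions$classifier == a$classifier &
                           !(attributions$subtype == a$subtype &
                             attributions$direction == a$sig_direction) &
                           pmax(attributions$frac_neg, attributions$frac_pos) >
                             threshold, ]
    rows[[length(rows) + 1]] <- data.frame(
      mirna = a$mirna, classifier = a$classifier, subtype = a$subtype,
      expr_direction = a$expr_direction, sig_direction = a$sig_direction,
      slr_fraction = frac, slr_sign = sign,
      opposite_direction = a$expr_direction != a$sig_direction,
      other_signatures = paste(paste0(others$subtype, "-", others$direction),
                               collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(mirna = character(), classifier = character(), subtype = character(),
             expr_direction = character(), sig_direction = character(),
             slr_fraction = numeric(), slr_sign = character(),
             opposite_direction = logical(), other_signatures = character(),
             stringsAsFactors = FALSE)
}
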
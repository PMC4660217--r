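#' Validate an expression matrix
#'
#' Expression matrices are plain numeric matrices with unique feature row
#' names and unique sample column names, on log2 scale unless flagged
#' otherwise via the `"scale"` attribute (`"log2"` or `"linear"`).
#'
#' @param x numeric matrix, features x samples.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param na_policy `"error"` (default) or `"drop"`: drop features containing
#'   non-finite values instead of failing.
#' @return the validated matrix with a `"scale"` attribute.
#' @export
as_expression_matrix <- function(x, scale = c("log2", "linear"),
                                 na_policy = c("error", "drop")) {
  scale <- match.arg(scale)
  na_policy <- match.arg(na_policy)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs feature row names and sample column names")
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  bad <- !is.finite(x)
  if (any(bad)) {
    if (na_policy == "error")
      stop("non-finite expression values (set na_policy = 'drop' to remove features)")
    keep <- rowSums(bad) == 0
    mmra_log(sprintf("dropping %d feature(s) with non-finite values", sum(!keep)))
    x <- x[keep, , drop = FALSE]
  }
  attr(x, "scale") <- scale
  x
}

#' Read / write a TSV expression matrix
#'
#' The on-disk format is tab-separated with a header row of sample ids and
#' feature ids in the first column.
#'
#' @param path file path.
#' @param ... passed to [as_expression_matrix()].
#' @return for the reader, a validated expression matrix.
#' @export
read_expression_matrix <- function(path, ...) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  as_expression_matrix(m, ...)
}

#' @rdname read_expression_matrix
#' @param x expression matrix.
#' @export
write_expression_matrix <- function(x, path) {
  d <- data.frame(feature = rownames(x), x, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample classification table
#'
#' Columns: `sample`, `classifier`, `subtype`, `ntp_fdr` (nearest-template
#' classification FDR in \[0,1\]) and `delta` (distance to the nearest
#' template, finite, >= 0). One record per (sample, classifier).
#'
#' @param path file path.
#' @return a data frame with the five columns above.
#' @export
read_classification <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_classification(d)
}

#' @rdname read_classification
#' @param records classification data frame.
#' @export
write_classification <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_classification <- function(d) {
  need <- c("sample", "classifier", "subtype", "ntp_fdr", "delta")
  if (!all(need %in% names(d)))
    stop("classification table needs columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  d$sample <- as.character(d$sample)
  d$classifier <- as.character(d$classifier)
  d$subtype <- as.character(d$subtype)
  if (anyDuplicated(d[, c("sample", "classifier")]))
    stop("duplicate (sample, classifier) records")
  if (any(!is.finite(d$delta)) || any(d$delta < 0)) stop("delta must be finite and >= 0")
  if (any(d$ntp_fdr < 0 | d$ntp_fdr > 1)) stop("ntp_fdr must lie in [0, 1]")
  d
}

#' Load and align a paired mRNA/microRNA dataset
#'
#' Reads the two expression matrices and the classification table, intersects
#' their sample sets and returns all three with an identical ordered sample
#' list. Dropped samples are logged.
#'
#' @param mrna_path,mirna_path TSV expression matrices (genes x samples,
#'   microRNAs x samples), log2 scale.
#' @param classification_path classification TSV (see [read_classification()]).
#' @return list with `mrna`, `mirna`, `classification`, `samples`, `dropped`.
#' @export
load_paired_dataset <- function(mrna_path, mirna_path, classification_path) {
  mrna <- read_expression_matrix(mrna_path)
  mirna <- read_expression_matrix(mirna_path)
  cls <- read_classification(classification_path)
  align_paired_dataset(mrna, mirna, cls)
}

#' @rdname load_paired_dataset
#' @param mrna,mirna expression matrices.
#' @param classification classification data frame.
#' @export
align_paired_dataset <- function(mrna, mirna, classification) {
  classification <- validate_classification(classification)
  common <- intersect(intersect(colnames(mrna), colnames(mirna)),
                      unique(classification$sample))
  if (length(common) == 0) stop("no samples shared by the three inputs")
  all_ids <- unique(c(colnames(mrna), colnames(mirna), classification$sample))
  dropped <- setdiff(all_ids, common)
  if (length(dropped))
    mmra_log(sprintf("dropping %d unpaired sample(s): %s", length(dropped),
                     paste(utils::head(dropped, 5), collapse = ", ")))
  common <- sort(common)
  list(mrna = mrna[, common, drop = FALSE],
       mirna = mirna[, common, drop = FALSE],
       classification = classification[classification$sample %in% common, ],
       samples = common, dropped = dropped)
}

#' Build subtype signatures from score tables or GMT
#'
#' Signatures are stored long: one row per (classifier, subtype, direction,
#' gene), `direction` being `"UP"` or `"DOWN"`.
#'
#' Two score-table styles are supported, mirroring how published CRC
#' classifiers distribute their gene lists:
#' * `"pam"` (CRCA/CCS style): columns `subtype`, `gene`, `score`; UP = score
#'   > 0, DOWN = score < 0.
#' * `"fc"` (CCMS style): columns `subtype`, `gene`, `log2fc`, `adj_p`; UP =
#'   log2fc > 0.5 and adj_p < 0.05, DOWN = log2fc < -0.5 and adj_p < 0.05.
#'
#' GMT input encodes classifier/subtype/direction in the set name as
#' `CLASSIFIER.SUBTYPE.UP` / `...DOWN`.
#'
#' @param path TSV score table or GMT file.
#' @param style `"pam"`, `"fc"` or `"gmt"`.
#' @param classifier classifier label attached to score-table signatures.
#' @return data frame `classifier`, `subtype`, `direction`, `gene`.
#' @export
load_signatures <- function(path, style = c("gmt", "pam", "fc"), classifier = NULL) {
  style <- match.arg(style)
  if (style == "gmt") {
    lines <- readLines(path)
    out <- lapply(lines[nzchar(lines)], function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      key <- strsplit(f[1], ".", fixed = TRUE)[[1]]
      if (length(key) != 3 || !key[3] %in% c("UP", "DOWN"))
        stop("GMT set name must be CLASSIFIER.SUBTYPE.UP|DOWN, got: ", f[1])
      genes <- unique(f[-(1:2)])
      genes <- genes[nzchar(genes)]
      data.frame(classifier = key[1], subtype = key[2], direction = key[3],
                 gene = genes, stringsAsFactors = FALSE)
    })
    sig <- do.call(rbind, out)
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(classifier)) stop("classifier label required for score tables")
    if (style == "pam") {
      stopifnot(all(c("subtype", "gene", "score") %in% names(d)))
      up <- d[d$score > 0, ]
      dn <- d[d$score < 0, ]
    } else {
      stopifnot(all(c("subtype", "gene", "log2fc", "adj_p") %in% names(d)))
      up <- d[d$log2fc > 0.5 & d$adj_p < 0.05, ]
      dn <- d[d$log2fc < -0.5 & d$adj_p < 0.05, ]
    }
    mk <- function(dd, dir)
      if (nrow(dd)) data.frame(classifier = classifier, subtype = dd$subtype,
                               direction = dir, gene = dd$gene,
                               stringsAsFactors = FALSE)
    sig <- rbind(mk(up, "UP"), mk(dn, "DOWN"))
  }
  sig$gene <- toupper(sig$gene)
  sig <- unique(sig)
  validate_signatures(sig)
}

validate_signatures <- function(sig) {
  key <- paste(sig$classifier, sig$subtype, sig$gene)
  both <- tapply(sig$direction, key, function(d) length(unique(d)) > 1)
  if (any(both))
    stop("gene(s) listed both UP and DOWN for one subtype: ",
         paste(utils::head(names(both)[both], 3), collapse = ", "))
  rownames(sig) <- NULL
  sig
}

#' Extract one signature gene set
#'
#' @param signatures long signature data frame from [load_signatures()].
#' @param classifier,subtype,direction selection keys.
#' @return character vector of gene ids (possibly empty).
#' @export
signature_genes <- function(signatures, classifier, subtype, direction) {
  unique(signatures$gene[signatures$classifier == classifier &
                         signatures$subtype == subtype &
                         signatures$direction == direction])
}

#' Write signatures to GMT
#'
#' @param signatures long signature data frame.
#' @param path output file.
#' @export
write_signatures_gmt <- function(signatures, path) {
  keys <- unique(signatures[, c("classifier", "subtype", "direction")])
  keys <- keys[order(keys$classifier, keys$subtype, keys$direction), ]
  lines <- apply(keys, 1, function(k) {
    g <- sort(signature_genes(signatures, k[1], k[2], k[3]))
    paste(c(paste(k, collapse = "."), "mmra", g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Combine per-database target predictions into a target map
#'
#' A (microRNA, gene) pair is retained when at least two prediction databases
#' agree on it; experimentally validated pairs are added unconditionally.
#' Identifiers are upper-cased before matching; input table order is
#' irrelevant.
#'
#' @param prediction_tables list of two-column data frames (`mirna`, `gene`),
#'   one per prediction database.
#' @param validated_table optional two-column data frame of validated pairs.
#' @return data frame `mirna`, `gene`, `n_databases`, `validated` (the target
#'   map), canonically ordered.
#' @export
combine_target_predictions <- function(prediction_tables, validated_table = NULL) {
  if (length(prediction_tables) < 2 && is.null(validated_table))
    stop("need at least two prediction databases (or a validated table)")
  canon <- function(d) {
    d <- d[, 1:2]
    names(d) <- c("mirna", "gene")
    d$mirna <- toupper(as.character(d$mirna))
    d$gene <- toupper(as.character(d$gene))
    unique(d)
  }
  preds <- lapply(prediction_tables, canon)
  all_pairs <- do.call(rbind, preds)
  if (is.null(all_pairs)) all_pairs <- data.frame(mirna = character(), gene = character())
  key <- paste(all_pairs$mirna, all_pairs$gene, sep = "\r")
  counts <- table(key)
  keep <- names(counts)[counts >= 2]
  map <- if (length(keep)) {
    parts <- strsplit(keep, "\r", fixed = TRUE)
    data.frame(mirna = vapply(parts, `[`, "", 1), gene = vapply(parts, `[`, "", 2),
               n_databases = as.integer(counts[keep]), validated = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(), gene = character(),
               n_databases = integer(), validated = logical())
  }
  if (!is.null(validated_table)) {
    v <- canon(validated_table)
    vkey <- paste(v$mirna, v$gene, sep = "\r")
    map$validated <- paste(map$mirna, map$gene, sep = "\r") %in% vkey
    extra <- v[!vkey %in% paste(map$mirna, map$gene, sep = "\r"), , drop = FALSE]
    if (nrow(extra)) {
      nd <- counts[paste(extra$mirna, extra$gene, sep = "\r")]
      extra$n_databases <- ifelse(is.na(nd), 0L, as.integer(nd))
      extra$validated <- TRUE
      map <- rbind(map, extra)
    }
  }
  map <- map[order(map$mirna, map$gene), ]
  rownames(map) <- NULL
  map
}

#' Read / write a prebuilt target map
#'
#' @param path TSV with columns `mirna`, `gene` and optionally `n_databases`,
#'   `validated`.
#' @return target-map data frame.
#' @export
read_target_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna", "gene") %in% names(d)))
  d$mirna <- toupper(d$mirna)
  d$gene <- toupper(d$gene)
  if (is.null(d$n_databases)) d$n_databases <- 2L
  if (is.null(d$validated)) d$validated <- FALSE
  bad <- d$n_databases < 2 & !d$validated
  if (any(bad)) stop("target map contains pairs with < 2 databases and not validated")
  d <- d[order(d$mirna, d$gene), c("mirna", "gene", "n_databases", "validated")]
  rownames(d) <- NULL
  d
}

#' @rdname read_target_map
#' @param map target-map data frame.
#' @export
write_target_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Targets of one microRNA
#'
#' @param map target map.
#' @param mirna microRNA id.
#' @return character vector of target gene ids.
#' @export
targets_of <- function(map, mirna) {
  unique(map$gene[map$mirna == toupper(mirna)])
}
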
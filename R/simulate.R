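#' Simulation configuration
#'
#' Defines the paired-dataset generator's study conditions. Defaults describe
#' three balanced subtypes with two planted driver microRNAs: each driver is
#' downregulated (log2 shift `driver_shift`) in its assigned subtype, and its
#' target genes follow `baseline + slope * microRNA + noise` with negative
#' `slope`, making them upregulated members of that subtype's UP signature.
#'
#' Signature composition per subtype: planted driver targets (drivered
#' subtypes only), `n_shifted_up` subtype-upregulated non-target genes, and
#' `n_stale` genes carried as UP labels without a planted programme (published
#' signatures routinely contain genes that do not co-vary in a new cohort).
#' DOWN signatures consist of `n_stale` label-only genes.
#'
#' @param n_subtypes number of subtypes.
#' @param n_per_subtype samples per subtype.
#' @param n_genes number of mRNAs.
#' @param n_mirnas number of microRNAs.
#' @param n_drivers planted driver microRNAs (one subtype each).
#' @param driver_shift log2 mean shift of a driver in its subtype (negative =
#'   downregulated).
#' @param slope regression slope linking a target gene to its driver
#'   (negative = anti-correlated).
#' @param noise_sd Gaussian noise s.d. on the log2 scale.
#' @param n_targets planted target genes per driver.
#' @param n_decoy_targets additional random predicted targets per driver.
#' @param n_shifted_up subtype-shifted non-target UP genes per subtype.
#' @param shift_up log2 up-shift of those genes in their subtype.
#' @param n_stale label-only genes per signature direction.
#' @param frac_lowconf fraction of samples given a low-confidence
#'   classification (ntp_fdr >= 0.05).
#' @param seed RNG seed, recorded in the truth manifest.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subtypes = 3, n_per_subtype = 60, n_genes = 500,
                       n_mirnas = 60, n_drivers = 2, driver_shift = -1.5,
                       slope = -0.8, noise_sd = 0.5, n_targets = 40,
                       n_decoy_targets = 20, n_shifted_up = 20, shift_up = 1.0,
                       n_stale = 40, frac_lowconf = 0.05, seed = 7) {
  cfg <- list(n_subtypes = n_subtypes, n_per_subtype = n_per_subtype,
              n_genes = n_genes, n_mirnas = n_mirnas, n_drivers = n_drivers,
              driver_shift = driver_shift, slope = slope, noise_sd = noise_sd,
              n_targets = n_targets, n_decoy_targets = n_decoy_targets,
              n_shifted_up = n_shifted_up, shift_up = shift_up,
              n_stale = n_stale, frac_lowconf = frac_lowconf, seed = seed)
  counts <- unlist(cfg[c("n_subtypes", "n_per_subtype", "n_genes", "n_mirnas",
                         "n_drivers", "n_targets")])
  if (any(counts <= 0)) stop("all counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_drivers > n_subtypes) stop("at most one driver per subtype")
  needed <- n_subtypes * (n_targets + n_shifted_up + 2 * n_stale)
  if (needed > n_genes)
    stop("not enough genes for the requested signatures (need ", needed, ")")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a paired mRNA-microRNA dataset with planted drivers
#'
#' Generates the full input set of the pipeline — paired expression matrices,
#' classification records, subtype signatures, a predicted-target map — plus
#' a truth manifest listing the planted drivers and their targets.
#'
#' Classification records carry `ntp_fdr` drawn low (U(0, 0.04)) for
#' confidently assigned samples (a `frac_lowconf` share instead gets
#' U(0.05, 0.3)), and `delta` from a Beta(2, 5) so that the pooled
#' 95th-percentile core rule removes roughly 5% of samples.
#'
#' @param config a [sim_config()].
#' @return list `mrna`, `mirna`, `classification`, `signatures`,
#'   `target_map`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_subtypes; np <- config$n_per_subtype
  n <- ns * np
  subtype <- rep(paste0("S", seq_len(ns)), each = np)
  samples <- sprintf("SAMP%03d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  mirnas <- sprintf("MIR%03d", seq_len(config$n_mirnas))

  # ---- gene role assignment (disjoint blocks) ----
  pool <- genes
  take <- function(k) { g <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; g }
  roles <- list()
  for (s in seq_len(ns)) {
    st <- paste0("S", s)
    roles[[st]] <- list(
      targets = if (s <= config$n_drivers) take(config$n_targets) else character(),
      shifted = take(config$n_shifted_up),
      stale_up = take(config$n_stale),
      stale_dn = take(config$n_stale))
  }

  # ---- microRNA matrix ----
  mirna_base <- rnorm(config$n_mirnas, mean = 5, sd = 1.5)
  M <- matrix(rnorm(config$n_mirnas * n, sd = config$noise_sd),
              nrow = config$n_mirnas, dimnames = list(mirnas, samples))
  M <- M + mirna_base
  drivers <- mirnas[seq_len(config$n_drivers)]
  driver_subtype <- paste0("S", seq_len(config$n_drivers))
  for (d in seq_len(config$n_drivers))
    M[drivers[d], subtype == driver_subtype[d]] <-
      M[drivers[d], subtype == driver_subtype[d]] + config$driver_shift

  # ---- mRNA matrix ----
  gene_base <- stats::setNames(rnorm(config$n_genes, mean = 7, sd = 1.5), genes)
  G <- matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
              nrow = config$n_genes, dimnames = list(genes, samples))
  G <- G + gene_base
  for (s in seq_len(ns)) {
    st <- paste0("S", s)
    in_s <- subtype == st
    sh <- roles[[st]]$shifted
    G[sh, in_s] <- G[sh, in_s] + config$shift_up
    if (s <= config$n_drivers) {
      # targets track their driver: baseline + slope * centered microRNA + noise
      m_c <- M[drivers[s], ] - mean(M[drivers[s], ])
      tg <- roles[[st]]$targets
      G[tg, ] <- G[tg, ] + matrix(rep(config$slope * m_c, each = length(tg)),
                                  nrow = length(tg))
    }
  }

  # ---- classification ----
  lowconf <- runif(n) < config$frac_lowconf
  cls <- data.frame(
    sample = samples, classifier = "SIM", subtype = subtype,
    ntp_fdr = ifelse(lowconf, runif(n, 0.05, 0.3), runif(n, 0, 0.04)),
    delta = rbeta(n, 2, 5), stringsAsFactors = FALSE)

  # ---- signatures ----
  sig <- do.call(rbind, lapply(names(roles), function(st) {
    r <- roles[[st]]
    rbind(
      data.frame(classifier = "SIM", subtype = st, direction = "UP",
                 gene = c(r$targets, r$shifted, r$stale_up)),
      data.frame(classifier = "SIM", subtype = st, direction = "DOWN",
                 gene = r$stale_dn))
  }))
  sig <- validate_signatures(sig)

  # ---- predicted-target map ----
  map_rows <- list()
  for (d in seq_len(config$n_drivers)) {
    st <- driver_subtype[d]
    non_t <- setdiff(genes, roles[[st]]$targets)
    tg <- c(roles[[st]]$targets, sample(non_t, config$n_decoy_targets))
    map_rows[[d]] <- data.frame(mirna = drivers[d], gene = tg,
                                n_databases = sample(2:4, length(tg), TRUE),
                                validated = FALSE)
  }
  for (m in setdiff(mirnas, drivers)) {
    tg <- sample(genes, config$n_targets + config$n_decoy_targets)
    map_rows[[length(map_rows) + 1]] <-
      data.frame(mirna = m, gene = tg,
                 n_databases = sample(2:4, length(tg), TRUE), validated = FALSE)
  }
  map <- do.call(rbind, map_rows)
  map <- map[order(map$mirna, map$gene), ]
  rownames(map) <- NULL

  truth <- list(drivers = drivers, driver_subtype = driver_subtype,
                targets = stats::setNames(
                  lapply(seq_len(config$n_drivers),
                         function(d) roles[[driver_subtype[d]]]$targets),
                  drivers),
                config = unclass(config), seed = config$seed)

  list(mrna = as_expression_matrix(G), mirna = as_expression_matrix(M),
       classification = cls, signatures = sig, target_map = map, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Emits the same TSV/GMT dialects the readers consume, plus a JSON truth
#' manifest.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$mrna, file.path(dir, "mrna.tsv"))
  write_expression_matrix(sim$mirna, file.path(dir, "mirna.tsv"))
  write_classification(sim$classification, file.path(dir, "classification.tsv"))
  write_signatures_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  write_target_map(sim$target_map, file.path(dir, "target_map.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
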
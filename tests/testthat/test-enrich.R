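test_that("hypergeometric enrichment matches its analytic anchors", {
  # expectation case: E = 100 * 50 / 1000 = 5, observed 5 -> O/E = 1
  u <- sprintf("g%04d", 1:1000)
  tg <- c(u[1:5], u[101:195])       # 100 targets, 5 in the signature
  sig <- u[1:50]
  h <- hypergeom_enrichment(tg, sig, u)
  expect_equal(h$oe_ratio, 1)
  # zero overlap
  h0 <- hypergeom_enrichment(u[301:400], sig, u)
  expect_equal(h0$oe_ratio, 0)
  expect_equal(h0$p_adj, 1)
  # exact enumeration on a small universe
  u20 <- letters[1:20]
  tg20 <- u20[1:5]; sig20 <- u20[c(1, 2, 3, 10)]
  h20 <- hypergeom_enrichment(tg20, sig20, u20)
  expect_equal(h20$p, enum_hyper_upper(3, 4, 20, 5), tolerance = 1e-12)
  expect_error(hypergeom_enrichment(tg20, character(), u20), "empty signature")
})

test_that("implementation equals exact tail enumeration for all small universes", {
  set.seed(5)
  for (rep in 1:200) {
    U <- sample(5:25, 1)
    u <- sprintf("g%d", 1:U)
    Tn <- sample(1:U, 1); S <- sample(1:U, 1)
    tg <- sample(u, Tn); sig <- sample(u, S)
    h <- hypergeom_enrichment(tg, sig, u)
    if (h$k == 0) next
    expect_equal(h$p, enum_hyper_upper(h$k, S, U, Tn), tolerance = 1e-10)
  }
})

test_that("universe membership outside targets and signature acts only through its size", {
  u <- sprintf("g%03d", 1:200)
  tg <- u[1:20]; sig <- u[11:40]
  h1 <- hypergeom_enrichment(tg, sig, u)
  u2 <- c(u[1:40], sprintf("x%03d", 1:160))  # swap unrelated universe genes
  h2 <- hypergeom_enrichment(tg, sig, u2)
  expect_equal(h1$p, h2$p)
  expect_equal(h1$oe_ratio, h2$oe_ratio)
})

test_that("a planted driver passes enrichment while decoys set the FDR floor", {
  sim <- default_sim
  universe <- intersect(rownames(sim$mrna), unique(sim$target_map$gene))
  d <- sim$truth$drivers[1]
  sig <- intersect(signature_genes(sim$signatures, "SIM",
                                   sim$truth$driver_subtype[1], "UP"), universe)
  tg <- targets_of(sim$target_map, d)
  h <- hypergeom_enrichment(tg, sig, universe, n_tests = 100)
  expect_lt(h$p_adj, 1e-10)
  expect_gt(h$oe_ratio, 1.5)
})

test_that("randomized-set FDR table equals an RNG-replayed independent recount", {
  sim <- tiny_sim
  cores <- select_core_samples(sim$classification, "SIM")
  set.seed(2)
  de <- differential_micrornas(sim$mirna, cores, n_boot = 1000)
  universe <- intersect(rownames(sim$mrna), unique(sim$target_map$gene))
  p_grid <- c(0.01, 0.05); oe_grid <- 1.5
  set.seed(31)
  th <- select_enrichment_thresholds(de, sim$target_map, sim$signatures,
                                     universe, p_grid, oe_grid, n_iter = 20)
  grid <- th$SIM$fdr_table
  # independent recount: same draw order, enrichment arithmetic from scratch
  hits <- de[de$pass, c("mirna", "subtype")]
  recount <- function(pairs) {
    n_sig <- 0L
    rows <- list()
    for (i in seq_len(nrow(pairs))) {
      for (dir in c("UP", "DOWN")) {
        s <- intersect(signature_genes(sim$signatures, "SIM", pairs$subtype[i], dir),
                       universe)
        if (!length(s)) next
        tg <- intersect(targets_of(sim$target_map, pairs$mirna[i]), universe)
        k <- length(intersect(tg, s))
        rows[[length(rows) + 1]] <- data.frame(
          mirna = pairs$mirna[i], subtype = pairs$subtype[i],
          p = if (k == 0) 1 else phyper(k - 1, length(s),
                                        length(universe) - length(s),
                                        length(tg), lower.tail = FALSE),
          oe = if (length(tg)) k / (length(tg) * length(s) / length(universe)) else 0)
      }
    }
    tab <- do.call(rbind, rows)
    tab$p_adj <- pmin(1, tab$p * nrow(tab))
    tab
  }
  count_at <- function(tab, p_thr, oe_thr)
    length(unique(paste(tab$mirna, tab$subtype)[tab$p_adj < p_thr & tab$oe > oe_thr]))
  obs_tab <- recount(hits)
  for (i in seq_len(nrow(grid)))
    expect_identical(grid$n_observed[i],
                     count_at(obs_tab, grid$p_thr[i], grid$oe_thr[i]))
  set.seed(31)
  pool <- unique(sim$target_map$mirna)
  sizes <- table(hits$subtype)
  rand_sum <- numeric(nrow(grid))
  for (it in 1:20) {
    rnd <- do.call(rbind, lapply(names(sizes), function(s)
      data.frame(mirna = sample(pool, sizes[[s]]), subtype = s)))
    rtab <- recount(rnd)
    rand_sum <- rand_sum + vapply(seq_len(nrow(grid)), function(i)
      count_at(rtab, grid$p_thr[i], grid$oe_thr[i]), 1L)
  }
  expect_equal(grid$mean_n_random, rand_sum / 20)
})

test_that("a uniformly random target map gives high randomized-set FDR", {
  sim <- tiny_sim
  cores <- select_core_samples(sim$classification, "SIM")
  set.seed(6)
  de <- differential_micrornas(sim$mirna, cores, n_boot = 1000)
  # scramble the map: every microRNA gets uniform random targets
  set.seed(61)
  rmap <- sim$target_map
  rmap$gene <- sample(rownames(sim$mrna), nrow(rmap), replace = TRUE)
  rmap <- unique(rmap[order(rmap$mirna, rmap$gene), ])
  universe <- rownames(sim$mrna)
  th <- select_enrichment_thresholds(de, rmap, sim$signatures, universe,
                                     p_grid = 0.5, oe_grid = 1, n_iter = 50)
  fdr <- th$SIM$fdr_table$fdr
  expect_true(all(is.na(fdr) | fdr >= 0.5))
})

test_that("enrichment filtering gates on both thresholds and logs unmapped microRNAs", {
  sim <- default_sim
  cores <- select_core_samples(sim$classification, "SIM")
  set.seed(8)
  de <- differential_micrornas(sim$mirna, cores)
  universe <- intersect(rownames(sim$mrna), unique(sim$target_map$gene))
  th <- list(SIM = list(p_threshold = 0.001, oe_threshold = 1.5))
  en <- filter_by_enrichment(de, th, sim$target_map, sim$signatures, universe)
  expect_setequal(unique(en$mirna[en$pass]), sim$truth$drivers)
  expect_true(all(en$sig_direction[en$pass] == "UP"))
  # a microRNA with no mapped targets auto-fails and is logged
  map2 <- sim$target_map[!sim$target_map$mirna %in% sim$truth$drivers[1], ]
  expect_message(en2 <- filter_by_enrichment(de, th, map2, sim$signatures, universe),
                 "no mapped targets")
  expect_false(any(en2$pass & en2$mirna == sim$truth$drivers[1]))
})
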
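test_that("network preprocessing linearizes, quantile-normalizes and applies the s.d. filter", {
  sim <- tiny_sim
  hub <- sim$mirna[1, , drop = FALSE]
  prep <- preprocess_for_network(sim$mrna, hub, sd_min = 0.7)
  # brute-force recount of the s.d. rule on the processed matrix
  stacked <- rbind(sim$mrna, hub)
  z <- log2(limma::normalizeQuantiles(2^stacked))
  sds <- apply(z, 1, sd)
  expect_setequal(prep$removed, rownames(sim$mrna)[sds[seq_len(nrow(sim$mrna))] < 0.7])
  expect_true(rownames(hub) %in% rownames(prep$matrix))  # hub exempt
  # constant gene is always removed
  m2 <- sim$mrna
  m2[3, ] <- 5
  prep2 <- preprocess_for_network(m2, hub, sd_min = 0.7)
  expect_true(rownames(m2)[3] %in% prep2$removed)
  # constant hub is a hard error
  hub0 <- hub; hub0[1, ] <- 1
  expect_error(preprocess_for_network(sim$mrna, hub0), "constant")
})

test_that("quantile normalization makes permuted-sample columns identical when sorted", {
  x <- matrix(c(rnorm(50), sample(rnorm(50))), ncol = 2,
              dimnames = list(sprintf("g%d", 1:50), c("a", "b")))
  x[, 2] <- sample(x[, 1])
  qn <- limma::normalizeQuantiles(2^x)
  expect_equal(unname(sort(qn[, 1])), unname(sort(qn[, 2])), tolerance = 1e-12)
})

test_that("mutual information is symmetric, transform-invariant and tracks the Gaussian closed form", {
  set.seed(10)
  x <- rnorm(300); y <- rnorm(300)
  expect_identical(mutual_information(x, y), mutual_information(y, x))
  # strictly monotone transforms leave the rank-based estimate unchanged
  expect_identical(mutual_information(x, y), mutual_information(exp(x), y^3))
  # closed form -0.5 log(1 - rho^2) across correlation levels
  for (rho in c(0.2, 0.5, 0.8)) {
    set.seed(100 + round(100 * rho))
    n <- 2000
    a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
    expect_lt(abs(mutual_information(a, b) + 0.5 * log(1 - rho^2)), 0.1)
  }
  expect_error(mutual_information(rep(1, 20), rnorm(20)), "zero-variance")
})

test_that("MI significance threshold extrapolates the permutation null tail", {
  expect_equal(mi_significance_threshold(100, p_target = 1)$threshold, 0)
  set.seed(12)
  t3 <- mi_significance_threshold(200, p_target = 1e-3, n_null = 20000)$threshold
  set.seed(12)
  t7 <- mi_significance_threshold(200, p_target = 1e-7, n_null = 20000)$threshold
  expect_gt(t7, t3)
  # extrapolated threshold at p = 1e-3 close to the direct empirical
  # 99.9th percentile of a large permutation null
  set.seed(13)
  direct <- quantile(mmra:::cpp_null_mi(200L, 100000L, mmra:::mi_bandwidth(200)),
                     0.999, type = 7, names = FALSE)
  expect_lt(abs(t3 - direct) / direct, 0.10)
})

test_that("regulon building recovers planted targets and stays empty for noise hubs", {
  sim <- default_sim
  d <- sim$truth$drivers[2]
  prep <- preprocess_for_network(sim$mrna, sim$mirna[d, , drop = FALSE],
                                 sd_min = 0.7)
  set.seed(14)
  thr <- mi_significance_threshold(ncol(sim$mrna), n_null = 20000)$threshold
  set.seed(15)
  reg <- build_regulon(prep, thr, n_boot = 50, consensus_p = 1e-6)
  tg <- intersect(sim$truth$targets[[d]], rownames(prep$matrix))
  found <- intersect(reg$edges$gene, tg)
  expect_gt(length(found) / length(tg), 0.95)
  expect_gt(min(reg$edges$support[reg$edges$gene %in% tg]), 45)
  # a noise microRNA yields an empty or near-empty regulon
  noise <- setdiff(rownames(sim$mirna), sim$truth$drivers)[1]
  prep0 <- preprocess_for_network(sim$mrna, sim$mirna[noise, , drop = FALSE],
                                  sd_min = 0.7)
  set.seed(16)
  expect_message(reg0 <- build_regulon(prep0, thr, n_boot = 50,
                                       consensus_p = 1e-6), "empty regulon")
  expect_equal(nrow(reg0$edges), 0)
})

test_that("edge support counts shrink as the MI threshold rises (fixed bootstrap seed)", {
  # support monotonicity is the invariant here: the consensus binomial null
  # renormalizes by the total edge rate, so the *final* edge set of a
  # stricter threshold need not nest inside the looser one
  sim <- tiny_sim
  d <- sim$truth$drivers[1]
  prep <- preprocess_for_network(sim$mrna, sim$mirna[d, , drop = FALSE],
                                 sd_min = 0.7)
  support_of <- function(thr) {
    set.seed(18)
    reg <- build_regulon(prep, thr, n_boot = 30, consensus_p = 1 - 1e-12)
    setNames(reg$edges$support, reg$edges$gene)
  }
  lo <- support_of(0.10)
  hi <- support_of(0.25)
  expect_true(all(names(hi) %in% names(lo)))
  expect_true(all(hi <= lo[names(hi)]))
})

test_that("the MRA Fisher test matches exact hypergeometric enumeration", {
  u <- sprintf("g%04d", 1:1000)
  sig <- u[1:50]
  expect_lt(mra_test(sig, sig, u)$p, 1e-40)         # regulon = signature
  expect_gt(mra_test(u[51:100], sig, u)$p, 0.9)     # disjoint sets
  expect_equal(mra_test(character(), sig, u)$p, 1)  # empty regulon
  # 2x2 table (10, 40; 15, 935): regulon 50, signature 25, overlap 10
  reg <- c(u[1:10], u[26:65]); sg <- u[1:25]
  got <- mra_test(reg, sg, u)$p
  exact <- enum_hyper_upper(10, 25, 1000, 50)
  expect_equal(got, exact, tolerance = 1e-10)
})

test_that("the MRA threshold is the order statistic leaving 95% of the null above", {
  set.seed(19)
  null_p <- runif(20)
  got <- mra_threshold_from_null(null_p, percentile = 95)
  expect_equal(got$threshold, quantile(null_p, 0.05, type = 7, names = FALSE))
  fb <- mra_threshold_from_null(numeric(0))
  expect_true(fb$fallback_used)
  expect_equal(fb$threshold, 1e-4)
  expect_message(mra_threshold_from_null(rep(0.99, 20)), "permissive")
})

test_that("null-model selection excludes drivers and low-expression microRNAs", {
  sim <- default_sim
  cores <- select_core_samples(sim$classification, "SIM")
  # plant a barely-detected microRNA
  mirna <- sim$mirna
  low <- "MIRLOW"
  mirna <- rbind(mirna, setNames(rep(-5, ncol(mirna)), colnames(mirna)))
  rownames(mirna)[nrow(mirna)] <- low
  mirna[low, 1:10] <- 1  # detected in only 10 of 180 samples
  set.seed(20)
  thr <- 0.2
  nm <- build_null_model(mirna, sim$mrna[1:80, ], list(cores),
                         candidate_regulons = list(), mi_threshold = thr,
                         n_boot = 5, consensus_p = 1e-3, sd_min = 0.7,
                         max_null = 5)
  expect_false(any(sim$truth$drivers %in% nm$mirnas))
  expect_false(low %in% nm$mirnas)
})

test_that("MI-ranked enrichment matches a hand-computed running sum", {
  # 20-gene regulon, 5 signature genes at known positions, equal weights
  edges <- data.frame(gene = sprintf("g%02d", 1:20), mi = rep(1, 20),
                      support = 10, support_p = 0)
  reg <- structure(list(hub = "m", edges = edges, n_boot = 10, mi_threshold = 0),
                   class = "mmra_regulon")
  sig <- c("g01", "g02", "g05", "g11", "g18")
  set.seed(22)
  res <- mi_rank_enrichment(reg, sig, n_perm = 200)
  # hand computation: +1/5 per hit, -1/15 per miss; peak after g05
  run <- cumsum(ifelse(edges$gene %in% sig, 1 / 5, -1 / 15))
  expect_equal(res$es, run[which.max(abs(run))])
  expect_setequal(res$leading_edge, c("g01", "g02", "g05"))
  # signature on top -> maximal ES and small p; uniform placement -> large p
  sig_top <- sprintf("g%02d", 1:5)
  set.seed(23)
  top <- mi_rank_enrichment(reg, sig_top, n_perm = 200)
  expect_equal(top$es, 1)
  expect_lt(top$perm_p, 0.05)
  sig_unif <- sprintf("g%02d", c(2, 6, 10, 14, 18))
  set.seed(24)
  unif <- mi_rank_enrichment(reg, sig_unif, n_perm = 200)
  expect_gt(unif$perm_p, 0.3)
})
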
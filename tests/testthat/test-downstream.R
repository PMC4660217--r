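test_that("null-model FC threshold reduces to the full-distribution percentile", {
  set.seed(40)
  m <- matrix(rnorm(30 * 12, 5), 30, 12,
              dimnames = list(sprintf("m%02d", 1:30), sprintf("c%02d", 1:12)))
  labels <- rep(c("SSM", "other"), each = 6)
  fc_all <- 2^abs(rowMeans(m[, 1:6]) - rowMeans(m[, 7:12]))
  got <- nullmodel_fc_threshold(m, labels, "SSM", set_size = 30, n_random = 50)
  expect_equal(got$threshold, quantile(fc_all, 0.9, type = 7, names = FALSE))
  # Monte-Carlo reproducibility across seeds of the same size
  set.seed(41); a <- nullmodel_fc_threshold(m, labels, "SSM", 10, n_random = 400)
  set.seed(42); b <- nullmodel_fc_threshold(m, labels, "SSM", 10, n_random = 400)
  expect_lt(abs(a$threshold - b$threshold), 0.1)
})

test_that("correlation fraction counts perfect anti-correlation and drops degenerate genes", {
  labels <- rep(paste0("S", 1:6), each = 3)
  mir <- rep(c(6, 5, 4, 3, 2, 1), each = 3)
  g_anti <- -mir + rnorm(18, sd = 1e-6)
  g_const <- rep(3, 18)
  ge <- rbind(anti = g_anti, konst = g_const)
  colnames(ge) <- paste0("c", 1:18)
  expect_message(res <- correlation_fraction(ge, mir, labels, r_threshold = 0.9),
                 "constant subtype means")
  expect_equal(res$fraction, 1)       # the informative gene counts, |r| = 1
  expect_equal(res$n_excluded, 1L)
  expect_equal(unname(abs(res$r["anti"])), 1)
  # refused for three-subtype designs
  expect_warning(r3 <- correlation_fraction(ge, mir, rep(paste0("S", 1:3), 6), 0.9),
                 "fewer than 4")
  expect_true(is.na(r3$fraction))
})

test_that("correlation fraction matches a hand computation on fixed means", {
  labels <- rep(paste0("S", 1:6), each = 2)
  mir <- rep(c(1, 4, 2, 6, 3, 5), each = 2)
  ge <- matrix(rep(c(10, 8, 9, 5, 7, 6), each = 2), nrow = 1,
               dimnames = list("g1", paste0("c", 1:12)))
  res <- correlation_fraction(ge, mir, labels, r_threshold = 0.8)
  hand <- cor(c(10, 8, 9, 5, 7, 6), c(1, 4, 2, 6, 3, 5), method = "spearman")
  expect_equal(unname(res$r["g1"]), hand)
  expect_equal(res$fraction, as.numeric(abs(hand) > 0.8))
})

test_that("silencing response subtracts the unspecific wild-type signal", {
  genes <- sprintf("g%02d", 1:30)
  base <- matrix(5, 30, 2, dimnames = list(genes, c("r1", "r2")))
  noise <- function() matrix(rnorm(60, sd = 0.05), 30, 2)
  scr <- base + noise()
  tr <- base + noise(); wt <- base + noise()
  tr["g01", ] <- tr["g01", ] + 1      # specific up (2x)
  tr["g02", ] <- tr["g02", ] + 1      # shifted in both -> excluded
  wt["g02", ] <- wt["g02", ] + 1
  tr["g03", ] <- tr["g03", ] - 1      # specific down
  de <- silencing_de(tr, scr, wt)
  expect_true("g01" %in% de$up)
  expect_false("g02" %in% de$up)
  expect_true("g03" %in% de$down)
  # replicate order must not matter
  de2 <- silencing_de(tr[, 2:1], scr[, 2:1], wt, fc_thr = 1.5)
  expect_identical(de$up, de2$up)
  expect_identical(de$down, de2$down)
  expect_error(silencing_de(tr[, 1, drop = FALSE], scr, wt), "replicates")
})

test_that("signature shift test flags directed enrichment and matches enumeration", {
  u <- sprintf("g%03d", 1:200)
  sig_up <- u[1:40]; sig_dn <- u[41:60]
  res <- signature_shift_test(up = u[1:15], down = u[150:160],
                              sig_up = sig_up, sig_down = sig_dn, universe = u)
  expect_true(res$pass[res$set == "up_vs_sigUP"])
  expect_gt(res$fold[res$set == "up_vs_sigUP"], 1)
  expect_false(res$pass[res$set == "down_vs_sigDOWN"])
  # toy 2x2: 3 of 5 selected genes inside a 4-gene signature, universe 20
  toy <- signature_shift_test(up = letters[1:5], down = character(0)[0],
                              sig_up = letters[c(1:3, 10)], sig_down = letters[4],
                              universe = letters[1:20])
  expect_equal(toy$p[1], enum_hyper_upper(3, 4, 20, 5), tolerance = 1e-10)
})

test_that("core targets require a negative coefficient and label edge provenance", {
  set.seed(44)
  n <- 200
  mir <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(paste0("miR", 1:4), paste0("s", 1:n)))
  # a gene anti-correlated with three of the four microRNAs
  g_multi <- -0.6 * mir[1, ] - 0.5 * mir[2, ] - 0.7 * mir[3, ] + rnorm(n, sd = 0.3)
  g_pos <- 0.8 * mir[4, ] + rnorm(n, sd = 0.3)
  mrna <- rbind(GMULTI = g_multi, GPOS = g_pos)
  colnames(mrna) <- colnames(mir)
  up_lists <- list(miR1 = c("GMULTI"), miR4 = c("GPOS"))
  ct <- identify_core_targets(up_lists, mrna, mir, paste0("miR", 1:4))
  got <- ct[ct$gene == "GMULTI", ]
  expect_setequal(got$mirna, c("miR1", "miR2", "miR3"))
  expect_true(all(got$coefficient < 0))
  expect_identical(got$edge[got$mirna == "miR1"], "solid")    # in vitro + in vivo
  expect_true(all(got$edge[got$mirna != "miR1"] == "dashed")) # in vivo only
  # positive-coefficient association is never a core target
  expect_false(any(ct$gene == "GPOS" & ct$mirna == "miR4"))
})

test_that("consolidation combines the FC and correlation criteria", {
  # microRNA lowest in S1 with graded subtype means; genes mirror it inversely,
  # so subtype-mean Spearman correlations are near -1
  set.seed(45)
  labels <- rep(paste0("S", 1:6), each = 3)
  lev <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4, S5 = 5, S6 = 6)
  mir <- lev[labels] + rnorm(18, sd = 0.05)
  ge <- matrix(rep(8 - lev[labels], 10), 10, byrow = TRUE,
               dimnames = list(paste0("g", 1:10), paste0("c", 1:18)))
  ge <- ge + rnorm(180, sd = 0.05)
  res <- consolidate_association(mir, labels, "S1", "DOWN", fc_threshold = 1.5,
                                 gene_expr = ge, r_threshold = 0.8,
                                 min_corr_fraction = 0.1)
  expect_true(res$fc_pass)
  expect_true(res$corr_pass)
  expect_true(res$validated)
  # wrong direction fails the FC criterion outright
  res2 <- consolidate_association(mir, labels, "S1", "UP", fc_threshold = 1.5)
  expect_false(res2$fc_pass)
  expect_false(res2$validated)
})
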
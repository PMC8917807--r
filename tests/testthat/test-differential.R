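test_that("de_table matches hand-computed Welch statistics on a 3v3 toy", {
  a <- c(5.0, 5.2, 4.8); b <- c(6.1, 6.4, 5.9)
  m <- mat_from_rows(list(g1 = c(a, b), g2 = rep(5, 6)))
  ds <- make_dataset(m, conditions = rep(c("c0", "c1"), each = 3),
                     replicates = rep(paste0("r", 1:3), 2),
                     layer = "protein")
  de <- de_table(ds, "c0", "c1")
  expect_equal(de$log2_fc[de$gene == "g1"], mean(b) - mean(a))
  # Welch t by the direct formula
  t_hand <- (mean(b) - mean(a)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(de$t[de$gene == "g1"], t_hand, tolerance = 1e-12)
  # identical means, zero variance: no statistic, fold change 0
  expect_equal(de$log2_fc[de$gene == "g2"], 0)
  expect_false(de$significant[de$gene == "g2"])
  expect_error(de_table(ds, "c0", "nope"), "Unknown")
})

test_that("de_table log2 fold change is antisymmetric in the conditions", {
  set.seed(3)
  m <- matrix(rnorm(20 * 6, 10), 20, 6,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:6)))
  ds <- make_dataset(m, conditions = rep(c("c0", "c1"), each = 3),
                     replicates = rep(paste0("r", 1:3), 2),
                     layer = "protein")
  fwd <- de_table(ds, "c0", "c1")
  rev <- de_table(ds, "c1", "c0")
  expect_equal(fwd$log2_fc, -rev$log2_fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
})

test_that("the fold-change threshold is strict: |fc| at the boundary is not significant", {
  # plant a gene whose log2 FC lands exactly on the threshold used
  a <- c(5, 5 + 1e-6, 5 - 1e-6); b <- a + 0.58
  m <- mat_from_rows(list(edge = c(a, b), strong = c(a, a + 2)))
  ds <- make_dataset(m, conditions = rep(c("c0", "c1"), each = 3),
                     replicates = rep(paste0("r", 1:3), 2),
                     layer = "protein")
  fc_edge <- mean(b) - mean(a)
  de <- de_table(ds, "c0", "c1", fc_threshold = fc_edge)
  expect_equal(de$log2_fc[de$gene == "edge"], 0.58, tolerance = 1e-9)
  expect_lt(de$adj_p[de$gene == "edge"], 0.05)
  expect_false(de$significant[de$gene == "edge"])  # strict ">" excludes it
  expect_true(de$significant[de$gene == "strong"])
})

test_that("pair concordance classifies signs and excludes zero fold changes", {
  de <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                       log2_fc = c(1.2, 0.7, -0.7, 0, 2),
                       significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  pairs <- tibble::tibble(gene_a = c("a", "a", "a", "a"),
                          gene_b = c("b", "c", "d", "e"),
                          identity_ab = 50, identity_ba = 50)
  expect_warning(out <- pair_concordance(de, pairs), "zero fold change")
  expect_equal(nrow(out), 2)  # (a,e) dropped: e not significant; (a,d) zero
  expect_equal(out$class[out$gene_b == "b"], "concordant")
  expect_equal(out$class[out$gene_b == "c"], "opposite")
})

test_that("a planted opposite fraction among DE pairs is recovered", {
  set.seed(41)
  n <- 800
  opp <- runif(n) < 0.2
  fc_a <- sample(c(-1, 1), n, TRUE) * runif(n, 0.6, 2)
  fc_b <- ifelse(opp, -sign(fc_a), sign(fc_a)) * runif(n, 0.6, 2)
  de <- tibble::tibble(gene = c(sprintf("a%04d", 1:n), sprintf("b%04d", 1:n)),
                       log2_fc = c(fc_a, fc_b), significant = TRUE)
  pairs <- tibble::tibble(gene_a = sprintf("a%04d", 1:n),
                          gene_b = sprintf("b%04d", 1:n),
                          identity_ab = 50, identity_ba = 50)
  out <- pair_concordance(de, pairs)
  expect_equal(nrow(out), n)  # concordant + opposite = pairs with both DE
  expect_lt(abs(mean(out$class == "opposite") - mean(opp)), 0.03)
})

test_that("degradation-class Fisher p equals the hypergeometric oracle", {
  # perfectly separated 2x2: (10,0 / 0,10)
  classes <- setNames(rep(c("NED", "ED"), each = 10),
                      sprintf("g%02d", 1:20))
  deltas <- tibble::tibble(gene_a = character(), gene_b = character(),
                           delta = numeric())
  res <- degradation_class_analysis(deltas, classes,
                                    complex_members = sprintf("g%02d", 1:10))
  # two-sided Fisher p for the extreme table: 2 * P(X >= 10), X hypergeom
  oracle <- 2 * hyper_upper_oracle(10, 10, 20, 10)
  expect_equal(res$enrichment$p, oracle, tolerance = 1e-9)
  expect_equal(res$enrichment$ned_in_complex, 10)
  expect_true(is.na(res$delta_comparison$p))  # no pairs: untestable
})

test_that("identical delta distributions give a large rank-sum p, planted shifts a small one", {
  set.seed(43)
  classes <- setNames(rep(c("NED", "ED"), each = 200),
                      c(sprintf("n%03d", 1:200), sprintf("e%03d", 1:200)))
  base <- rnorm(200, 0, 0.2)
  deltas_same <- tibble::tibble(
    gene_a = names(classes)[1:200][1:100] |> c(names(classes)[201:400][1:100]),
    gene_b = names(classes)[1:200][101:200] |> c(names(classes)[201:400][101:200]),
    delta = c(base[1:100], base[1:100]))
  res_same <- degradation_class_analysis(deltas_same, classes, character(0))
  expect_gt(res_same$delta_comparison$p, 0.5)
  deltas_shift <- deltas_same
  deltas_shift$delta[1:100] <- deltas_shift$delta[1:100] - 0.3
  res_shift <- degradation_class_analysis(deltas_shift, classes, character(0))
  expect_lt(res_shift$delta_comparison$p, 0.01)
  expect_lt(res_shift$delta_comparison$median_delta_ned,
            res_shift$delta_comparison$median_delta_ed)
})

test_that("PSM filtering retains exactly the clean PSMs of the planted fixture", {
  sim <- simulate_psm_table(n_psms = 20,
                            violation_rates = list(reverse = 0.1,
                                                   contaminant = 0,
                                                   low_score = 0.15,
                                                   low_intensity = 0.05),
                            seed = 8)
  expect_equal(sim$truth$expected_survivors, 14)
  kept <- psm_filter(sim$psms)
  expect_equal(nrow(kept), 14)
  expect_true(all(!kept$is_reverse & !kept$is_contaminant))
  expect_true(all(kept$score >= 15))
  # the single-peptide protein survives filtering but not summarization
  expect_true("Psingle" %in% kept$protein)
  q <- psm_summarize(sim$psms)
  expect_false("Psingle" %in% rownames(q))
  expect_true(all(c("P01", "P02", "P03", "P04") %in% rownames(q)))
  # all PSMs flagged reverse -> nothing survives
  allrev <- sim$psms; allrev$is_reverse <- TRUE
  expect_equal(nrow(psm_summarize(allrev)), 0)
  # no violations -> everything retained
  clean <- simulate_psm_table(n_psms = 20,
                              violation_rates = list(reverse = 0,
                                                     contaminant = 0,
                                                     low_score = 0,
                                                     low_intensity = 0),
                              seed = 8)
  expect_equal(nrow(psm_filter(clean$psms)), 20)
})

test_that("psm_summarize is invariant to row order and to equal intensities", {
  sim <- simulate_psm_table(seed = 10)
  q1 <- psm_summarize(sim$psms)
  set.seed(1)
  shuffled <- sim$psms[sample(nrow(sim$psms)), ]
  q2 <- psm_summarize(shuffled)
  expect_equal(q1, q2[rownames(q1), ])
  # constant intensities: all normalized quantities identical (zero)
  flat <- sim$psms
  flat[grep("^channel_", names(flat))] <- 5e4
  qf <- psm_summarize(flat)
  expect_true(all(qf == 0))
})

test_that("ranked fold-change KS matches the exhaustive ECDF oracle", {
  fc <- setNames(c(2.0, 1.5, 1.2, 0.8, -0.3, -0.9, 0.1, -1.2, 0.5, -0.6),
                 sprintf("g%02d", 1:10))
  gene_set <- sprintf("g%02d", c(1, 2, 3, 9))   # 6 vs 4 split
  out <- ranked_fc_ks(fc, gene_set)
  x <- fc[gene_set]; y <- fc[setdiff(names(fc), gene_set)]
  expect_equal(out$D, ks_D_oracle(x, y), tolerance = 1e-12)
  expect_equal(out$p, ks_p_oracle(x, y), tolerance = 1e-9)
  # complete separation: D = 1
  top <- names(sort(fc, decreasing = TRUE))[1:4]
  expect_equal(ranked_fc_ks(fc, top)$D, 1)
  # uniformly interleaved set: small D, large p
  fc2 <- setNames(seq_len(20), sprintf("h%02d", 1:20))
  inter <- sprintf("h%02d", seq(1, 20, by = 2))
  out2 <- ranked_fc_ks(fc2, inter)
  expect_lte(out2$D, 0.1)
  expect_gt(out2$p, 0.9)
  expect_error(ranked_fc_ks(fc, character(0)), "Empty")
  expect_error(ranked_fc_ks(fc, "nope"), "subset")
})
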
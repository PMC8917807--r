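test_that("ratio profiles subtract log2 quantities where both genes exist", {
  m <- mat_from_rows(list(a1 = c(8, 7, 6, 5, 4, 3), b1 = c(5, 5, 5, 5, 5, NA)))
  ds <- make_dataset(m, conditions = rep(c("t0", "t1"), each = 3),
                     replicates = rep(paste0("r", 1:3), 2),
                     layer = "protein")
  pairs <- tibble::tibble(gene_a = "a1", gene_b = "b1",
                          identity_ab = 80, identity_ba = 80)
  prof <- ratio_profiles(ds, pairs)
  expect_equal(nrow(prof), 5)  # missing gene_b in s6 drops that ratio
  expect_equal(prof$ratio[prof$sample == "s1"], 3)
  expect_equal(sort(prof$ratio), sort(c(3, 2, 1, 0, -1)))
})

test_that("d0 = 0 reduces the moderated test to the ordinary pooled t", {
  set.seed(5)
  m <- rbind(matrix(rnorm(40 * 6, 20, 0.5), 40, 6))
  rownames(m) <- sprintf("a%02d", 1:40)
  m2 <- matrix(rnorm(40 * 6, 20, 0.5), 40, 6)
  rownames(m2) <- sprintf("b%02d", 1:40)
  mm <- rbind(m, m2)
  colnames(mm) <- paste0("s", 1:6)
  ds <- make_dataset(mm, conditions = rep(c("t0", "t1"), each = 3),
                     replicates = rep(paste0("r", 1:3), 2),
                     layer = "protein")
  pairs <- tibble::tibble(gene_a = sprintf("a%02d", 1:40),
                          gene_b = sprintf("b%02d", 1:40),
                          identity_ab = 80, identity_ba = 80)
  prof <- ratio_profiles(ds, pairs)
  out <- ratio_change_test(prof, d0 = 0)
  for (pid in out$pair_id[1:5]) {
    r <- prof[prof$pair_id == pid, ]
    tt <- t.test(r$ratio[r$condition == "t1"], r$ratio[r$condition == "t0"],
                 var.equal = TRUE)
    expect_equal(out$t[out$pair_id == pid], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(out$p[out$pair_id == pid], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t follows the posterior-variance closed formula", {
  rt <- c(1.2, 1.0, 1.4); r0 <- c(0.1, -0.1, 0.0)
  prof <- tibble::tibble(
    pair_id = "p", gene_a = "a", gene_b = "b",
    sample = paste0("s", 1:6),
    condition = rep(c("t0", "t1"), each = 3),
    replicate = rep(paste0("r", 1:3), 2),
    species = "sp1", ratio = c(r0, rt))
  d0_fix <- 4
  out <- ratio_change_test(prof, d0 = d0_fix)
  s2 <- (2 * var(rt) + 2 * var(r0)) / 4
  s0_sq <- s2  # single pair: prior variance estimated from it alone
  s2_post <- (d0_fix * s0_sq + 4 * s2) / (d0_fix + 4)
  t_hand <- (mean(rt) - mean(r0)) / sqrt(s2_post * (1 / 3 + 1 / 3))
  expect_equal(out$delta, mean(rt) - mean(r0))
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, 8)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  # identical condition means: delta 0, t 0, p 1
  prof0 <- prof; prof0$ratio <- rep(c(0.2, 0.3, 0.1), 2)
  out0 <- ratio_change_test(prof0, d0 = 0)
  expect_equal(out0$delta, 0)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
})

test_that("the variance prior tightens the ensemble and degrades gracefully", {
  set.seed(11)
  s2 <- rchisq(200, df = 4) / 4 * 0.25   # dispersed variances
  pri <- estimate_var_prior(s2, 4)
  expect_true(is.finite(pri$d0) || pri$d0 == Inf)
  expect_gt(pri$s0_sq, 0)
  # under-dispersed ensemble: infinite prior df, pooled variance
  pri2 <- estimate_var_prior(rep(0.25, 50), 4)
  expect_equal(pri2$d0, Inf)
  expect_equal(pri2$s0_sq, 0.25)
})

test_that("orthogroup aggregation averages deltas and p per the mean rule", {
  changes <- tibble::tibble(
    pair_id = c("p1", "p2"), gene_a = c("x1", "x2"), gene_b = c("y1", "y2"),
    species = "sp1", comparison = "c1_vs_ref",
    delta = c(1.0, 0.5), p = c(0.02, 0.04))
  map <- tibble::tibble(gene = c("x1", "x2", "y1", "y2"), species = "sp1",
                        orthogroup = c("OGA", "OGA", "OGB", "OGB"))
  out <- aggregate_to_orthogroups(changes, map)
  expect_equal(nrow(out), 1)
  expect_equal(out$delta, 0.75)
  expect_equal(out$p, 0.03)
  expect_equal(out$n_gene_pairs, 2)
  # unmapped gene: pair dropped
  map2 <- map[map$gene != "y2", ]
  out2 <- aggregate_to_orthogroups(changes, map2)
  expect_equal(out2$n_gene_pairs, 1)
  expect_equal(out2$delta, 1.0)
})

test_that("orthogroup orientation flips negate deltas consistently", {
  changes <- tibble::tibble(
    pair_id = "p1", gene_a = "x1", gene_b = "y1", species = "sp1",
    comparison = "c1_vs_ref", delta = 1.5, p = 0.01)
  # gene_a maps to the lexicographically LARGER orthogroup
  map <- tibble::tibble(gene = c("x1", "y1"), species = "sp1",
                        orthogroup = c("OGZ", "OGA"))
  out <- aggregate_to_orthogroups(changes, map)
  expect_equal(out$og_a, "OGA")
  expect_equal(out$og_b, "OGZ")
  expect_equal(out$delta, -1.5)
})

test_that("fisher_combine matches identities and the quadrature oracle", {
  # k = 1: chi-square df 2 identity returns p unchanged
  for (p in c(0.01, 0.2, 0.77, 1)) {
    expect_equal(fisher_combine(p), p, tolerance = 1e-12)
  }
  # p = 1 contributes nothing to the statistic
  expect_equal(fisher_combine(c(0.05, 1)),
               pchisq(-2 * log(0.05), 4, lower.tail = FALSE),
               tolerance = 1e-14)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               chisq_tail_oracle(-2 * (2 * log(0.05)), 4),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1))
    expect_equal(fisher_combine(p),
                 chisq_tail_oracle(-2 * sum(log(p)), 2 * length(p)),
                 tolerance = 1e-12)
  }
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "at least one")
})

test_that("fisher_combine is monotone in each component", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(5, 0.05, 1)
    j <- sample(5, 1)
    q <- p; q[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(q), fisher_combine(p))
  }
})

test_that("sign-consistency counting honours the 5-of-7 rule", {
  mk <- function(deltas) {
    tibble::tibble(og_a = "OGA", og_b = "OGB",
                   species = rep(c("s1", "s2", "s3", "s4"),
                                 c(2, 2, 2, 1)),
                   comparison = paste0("c", 1:7),
                   delta = deltas, p = 0.001)
  }
  pass <- conserved_signature(mk(c(1, 1, 1, 1, 1, -1, -1)), n_species = 4)
  expect_equal(pass$n_sign_consistent, 5)
  expect_true(pass$conserved)
  fail <- conserved_signature(mk(c(1, 1, 1, 1, -1, -1, -1)), n_species = 4)
  expect_equal(fail$n_sign_consistent, 4)
  expect_false(fail$conserved)
  # orientation invariance: a globally flipped pair gives the same counts
  flipped <- conserved_signature(mk(-c(1, 1, 1, 1, 1, -1, -1)),
                                 n_species = 4)
  expect_equal(flipped$n_sign_consistent, 5)
  expect_true(flipped$conserved)
  # a pair absent from one species is never conserved
  missing_sp <- mk(c(1, 1, 1, 1, 1, -1, -1))[1:6, ]
  expect_false(conserved_signature(missing_sp, n_species = 4)$conserved)
})

test_that("conservation pipeline is invariant to gene relabeling", {
  cfg <- simulation_config(n_og_pairs = 120, n_conserved = 10, seed = 6)
  ms <- simulate_multispecies_proteomes(cfg)
  run <- function(datasets, pair_tables, og_map) {
    ch <- multispecies_ratio_changes(datasets, pair_tables)
    conserved_signature(aggregate_to_orthogroups(ch, og_map))
  }
  sig1 <- run(ms$datasets, ms$pairs, ms$og_map)
  # relabel every gene id; orthogroups unchanged
  relabel <- function(x) paste0("z_", x)
  ds2 <- lapply(ms$datasets, function(d) {
    rownames(d$values) <- relabel(rownames(d$values)); d
  })
  pairs2 <- lapply(ms$pairs, function(p) {
    p$gene_a <- relabel(p$gene_a); p$gene_b <- relabel(p$gene_b); p
  })
  map2 <- ms$og_map; map2$gene <- relabel(map2$gene)
  sig2 <- run(ds2, pairs2, map2)
  expect_equal(sig1$conserved, sig2$conserved)
  expect_equal(sig1$combined_p, sig2$combined_p, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(8)
  for (n in c(1, 5, 50, 1000)) {
    p <- runif(n)
    expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("ratio PCA separates species and handles degenerate inputs", {
  cfg <- simulation_config(n_og_pairs = 200, n_conserved = 20, seed = 9)
  ms <- simulate_multispecies_proteomes(cfg)
  ch <- multispecies_ratio_changes(ms$datasets, ms$pairs)
  og <- aggregate_to_orthogroups(ch, ms$og_map)
  sig <- conserved_signature(og)
  pc <- ratio_pca(attr(sig, "deltas"))
  expect_equal(nrow(pc$scores), 7)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-12)
  # rank-1 matrix: a single nonzero singular value
  v <- rnorm(6)
  d1 <- tibble::tibble(pair = paste0("p", 1:10),
                       !!!setNames(lapply(v, function(x) x * (1:10)),
                                   paste0("c", 1:6)))
  pc1 <- ratio_pca(d1)
  expect_equal(sum(pc1$sdev > 1e-10), 1)
  # duplicated comparison columns get identical scores
  d2 <- d1; d2$c7 <- d2$c1
  pc2 <- ratio_pca(d2)
  sc <- pc2$scores
  expect_equal(unlist(sc[sc$comparison == "c7", -1]),
               unlist(sc[sc$comparison == "c1", -1]), tolerance = 1e-10)
  expect_error(ratio_pca(d1[1, ]), "at least 2")
})

test_that("tidiers and glance summarise a conserved signature", {
  cfg <- simulation_config(n_og_pairs = 100, n_conserved = 8, seed = 14)
  ms <- simulate_multispecies_proteomes(cfg)
  ch <- multispecies_ratio_changes(ms$datasets, ms$pairs)
  sig <- conserved_signature(aggregate_to_orthogroups(ch, ms$og_map))
  td <- tidy(sig)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 100)
  gl <- glance(sig)
  expect_equal(gl$n_pairs, 100)
  expect_equal(gl$n_conserved, sum(sig$conserved))
})
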
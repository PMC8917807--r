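test_that("pair_correlation matches the direct covariance/sd formula", {
  expect_equal(pair_correlation(c(1, 2, 3), c(2, 4, 6), min_obs = 3)$R, 1)
  expect_equal(pair_correlation(c(1, 2, 3), c(3, 2, 1), min_obs = 3)$R, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 4, 4)
  got <- pair_correlation(x, y)
  expect_equal(got$R, pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(got$n_obs, 5)
  expect_error(pair_correlation(1:3, 1:4), "equal length")
})

test_that("pair_correlation is undefined below min_obs and for constants", {
  expect_true(is.na(pair_correlation(1:4, 4:1)$R))
  expect_true(is.na(pair_correlation(rep(2, 6), 1:6)$R))
  x <- c(1, 2, NA, 4, 5, 6); y <- c(2, 1, 3, NA, 5, 7)
  expect_equal(pair_correlation(x, y)$n_obs, 4)  # pairwise complete
  expect_true(is.na(pair_correlation(x, y)$R))
})

test_that("pair_correlation is symmetric and invariant to affine rescaling", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    a <- pair_correlation(x, y)$R
    expect_equal(a, pair_correlation(y, x)$R, tolerance = 1e-12)
    expect_equal(a, pair_correlation(2.5 * x + 3, y)$R, tolerance = 1e-12)
  }
})

test_that("divergence classification uses the R <= 0 boundary", {
  expect_equal(classify_divergence(c(0.4, 0, -0.7, NA)),
               c("co-regulated", "divergent", "divergent", NA))
})

test_that("coefficient_of_variation follows sd/mean with sample sd", {
  expect_equal(coefficient_of_variation(rep(5, 5)), 0)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  expect_true(is.na(coefficient_of_variation(c(1, 2, 3, 4))))  # < 5 obs
  expect_error(coefficient_of_variation(c(-1, 2, 3, 4, 5)), ">= 0")
})

test_that("co-regulated and divergent fractions partition defined pairs", {
  cfg <- simulation_config(n_pairs = 150, n_singletons = 20,
                           complex_sizes = integer(0), seed = 3)
  sim <- simulate_expression_study(cfg)
  rec <- pair_coexpression(sim$rna, sim$pairs)
  defined <- rec[!is.na(rec$R), ]
  expect_equal(mean(defined$category == "divergent") +
                 mean(defined$category == "co-regulated"), 1)
})

test_that("zero-noise data classify perfectly in both directions", {
  co <- simulate_expression_study(simulation_config(
    n_pairs = 40, n_singletons = 0, noise_sd = 0, divergent_fraction = 0,
    complex_sizes = integer(0), protein_noise_sd = 0, seed = 5))
  rec <- pair_coexpression(co$rna, co$pairs)
  expect_equal(rec$R, rep(1, 40), tolerance = 1e-12)
  expect_true(all(rec$category == "co-regulated"))
  div <- simulate_expression_study(simulation_config(
    n_pairs = 40, n_singletons = 0, noise_sd = 0, divergent_fraction = 1,
    complex_sizes = integer(0), protein_noise_sd = 0, seed = 5))
  rec <- pair_coexpression(div$rna, div$pairs)
  expect_equal(rec$R, rep(-1, 40), tolerance = 1e-12)
  expect_true(all(rec$category == "divergent"))
})

test_that("random_pair_null is seeded and centred near zero on independent genes", {
  set.seed(1)
  m <- matrix(rnorm(400 * 10), 400, 10,
              dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:10)))
  ds <- make_dataset(m)
  null1 <- random_pair_null(ds, n_draws = 4000, seed = 9)
  null2 <- random_pair_null(ds, n_draws = 4000, seed = 9)
  expect_identical(null1, null2)
  expect_lt(abs(mean(null1$R, na.rm = TRUE)), 0.02)
  expect_true(all(null1$gene_a != null1$gene_b))
  tiny <- make_dataset(m[1, , drop = FALSE])
  expect_error(random_pair_null(tiny), "at least 2")
})

test_that("paralog pairs separate from the random-pair null on planted data", {
  sim <- simulate_expression_study(simulation_config(
    n_pairs = 300, n_singletons = 100, divergent_fraction = 0.35,
    complex_sizes = integer(0), seed = 11))
  rec <- pair_coexpression(sim$rna, sim$pairs)
  null <- random_pair_null(sim$rna, n_draws = 3000, seed = 12)
  p <- wilcox.test(rec$R, null$R)$p.value
  expect_lt(p, 0.01)
})

test_that("identity bins are left-closed and the group test behaves", {
  # identical distributions in one bin -> p near 1
  rec <- tibble::tibble(
    gene_a = sprintf("a%02d", 1:40), gene_b = sprintf("b%02d", 1:40),
    mean_identity = 30, layer = "rna", R = rep(seq(-0.5, 0.5, length.out = 20), 2),
    n_obs = 10L, category = "co-regulated",
    same_complex = rep(c(TRUE, FALSE), each = 20))
  out <- identity_bin_compare(rec)
  expect_equal(nrow(out), 1)
  expect_gt(out$p, 0.9)

  # planted downward shift for same-complex pairs -> small p
  set.seed(2)
  shifted <- rec
  shifted$R <- rnorm(40, 0.4, 0.1) - ifelse(shifted$same_complex, 0.5, 0)
  out2 <- identity_bin_compare(shifted)
  expect_lt(out2$p, 0.01)

  # a pair on an interior edge lands in the left-closed bin [50, 75)
  edge <- rec[1:4, ]
  edge$mean_identity <- c(50, 50, 60, 60)
  edge$same_complex <- c(TRUE, FALSE, TRUE, FALSE)
  out3 <- identity_bin_compare(edge)
  expect_equal(as.character(out3$bin), "[50,75)")
  # and the top edge is included in the last bin
  top <- rec[1:2, ]; top$mean_identity <- 100
  expect_equal(as.character(identity_bin_compare(top)$bin), "[75,100]")
})

test_that("delta scores subtract transcript from protein correlations", {
  ra <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"),
                       R = c(0.3, 0.5))
  rp <- tibble::tibble(gene_a = c("a", "e"), gene_b = c("b", "f"),
                       R = c(0.8, 0.2))
  d <- transcript_protein_delta(ra, rp)
  expect_equal(nrow(d), 1)  # pairs missing either layer omitted
  expect_equal(d$delta, 0.5)
  same <- transcript_protein_delta(ra, ra)
  expect_true(all(same$delta == 0))
})

test_that("NED-containing pairs show lower delta on planted protein noise", {
  sim <- simulate_expression_study(simulation_config(seed = 21))
  rr <- pair_coexpression(sim$rna, sim$pairs)
  rp <- pair_coexpression(sim$protein, sim$pairs)
  d <- transcript_protein_delta(rr, rp)
  d <- dplyr::inner_join(d, sim$truth$pairs, by = c("gene_a", "gene_b"))
  p <- wilcox.test(d$delta[d$has_ned], d$delta[!d$has_ned],
                   alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("paralog genes have higher CV than singletons under amplitude boost", {
  sim <- simulate_expression_study(simulation_config(
    n_pairs = 300, n_singletons = 300, complex_sizes = integer(0),
    seed = 13))
  lin <- convert_scale(sim$rna, "linear")
  cvs <- apply(lin$values, 1, coefficient_of_variation)
  hp <- flag_has_paralog(names(cvs), sim$pairs)
  p <- wilcox.test(cvs[hp], cvs[!hp], alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
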
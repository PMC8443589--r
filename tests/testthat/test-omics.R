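test_that("rank_top_genes is a permutation-stable total order with tie-breaks", {
  tab <- toy_deg(p = c(0.5, 0.01, 0.01, 0.2), log2fc = c(2, 1, 3, -4))
  # equal p: the larger |log2fc| ranks first
  expect_equal(rank_top_genes(tab, 2), c("g03", "g02"))
  # n larger than the table: all genes
  expect_equal(length(rank_top_genes(tab, 300)), 4L)
  expect_equal(rank_top_genes(tab, 300)[1:2], c("g03", "g02"))
  # permutation stability
  shuf <- tab[c(3, 1, 4, 2), ]
  expect_equal(rank_top_genes(shuf, 4), rank_top_genes(tab, 4))
  # 300 from a 1,000-gene fixture
  big <- toy_deg(p = seq(0.001, 1, length.out = 1000),
                 genes = sprintf("g%04d", 1:1000))
  expect_length(rank_top_genes(big, 300), 300L)
})

test_that("concordance counts match brute-force filter-and-count", {
  # 12-gene reference, 9 called DE -> 75% overlap
  tab <- deg_table(sprintf("m%02d", 1:12),
                   log2fc = c(rep(2, 6), rep(-2, 6)),
                   p = rep(0.001, 12),
                   fdr = c(rep(0.01, 9), rep(0.5, 3)))
  ref <- marker_set("nafld", setNames(rep(1L, 12), sprintf("m%02d", 1:12)))
  res <- concordance(tab, ref)
  expect_equal(res$pct_overlap, 75)
  oracle <- brute_concordance(tab, ref$members)
  expect_equal(res$n_de, oracle$n_de)
  expect_equal(res$n_directional, oracle$n_directional)

  # parameterised: random tables vs the brute-force oracle
  set.seed(404)
  for (i in 1:10) {
    genes <- sprintf("r%03d", 1:60)
    tab <- deg_table(genes, log2fc = rnorm(60), p = runif(60),
                     fdr = runif(60))
    members <- setNames(sample(c(-1L, 0L, 1L), 25, replace = TRUE),
                        sample(sprintf("r%03d", 1:80), 25))
    res <- concordance(tab, marker_set("s", members))
    oracle <- brute_concordance(tab, members)
    expect_equal(res[c("n_ref", "n_measured", "n_de", "n_directional")],
                 oracle)
    expect_true(res$n_directional <= res$n_de &&
                  res$n_de <= res$n_measured && res$n_measured <= res$n_ref)
  }

  # all DE with matching signs: both percentages 100
  tab <- deg_table(c("a", "b"), c(1.2, -0.8), c(1e-5, 1e-5))
  res <- concordance(tab, marker_set("s", c(a = 1L, b = -1L)))
  expect_equal(res$pct_overlap, 100)
  expect_equal(res$pct_directional, 100)
  # wrong sign counts as DE but not directional
  res2 <- concordance(tab, marker_set("s", c(a = 1L, b = 1L)))
  expect_equal(res2$n_de, 2)
  expect_equal(res2$n_directional, 1)
  # no reference gene measured: flagged NA, not an error
  res3 <- concordance(tab, marker_set("s", c(zz = 1L)))
  expect_true(res3$no_measured_members)
  expect_true(is.na(res3$pct_overlap))
})

test_that("enrich equals the exhaustive hypergeometric tail for N <= 25", {
  u <- sprintf("u%02d", 1:20)
  e <- enrich(u[1:5], list(S = u[c(1:4, 10)]), u)
  expect_equal(e$p, brute_hyper_tail(4, 5, 5, 20))
  expect_equal(e$gene_ratio, 4 / 5)
  # k = 0: upper tail P(X >= 0) = 1
  e0 <- enrich(u[1:5], list(S = u[16:20]), u)
  expect_equal(e0$k, 0)
  expect_equal(e0$p, 1)
  # single set: Bonferroni m = 1 leaves p unchanged
  expect_equal(e$p_adj, e$p)
  # parameterised sweep against the enumeration oracle
  set.seed(77)
  for (i in 1:20) {
    N <- sample(5:25, 1)
    u <- sprintf("x%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    set <- sample(u, K); lst <- sample(u, n)
    e <- enrich(lst, list(S = set), u)
    expect_equal(e$p, brute_hyper_tail(length(intersect(lst, set)),
                                       K, n, N))
  }
  # Bonferroni over the sets tested in the call, capped at 1
  e2 <- enrich(u[1:3], list(A = u[1:3], B = u[1:4], C = rev(u)[1:3]), u)
  expect_true(all(e2$p_adj == pmin(1, e2$p * 3)))
  expect_true(!is.unsorted(e2$p))
  expect_error(enrich("a", list(S = "a"), character(0)), "universe")
})

test_that("compare_clusters keeps significant terms per condition", {
  u <- sprintf("g%03d", 1:200)
  sets <- list(fibrosis = u[1:20], inflammation = u[21:40])
  # a list that IS one set: term retained with gene_ratio K/n
  res <- compare_clusters(list(tgfb = u[1:20]), sets, u)
  expect_equal(res$condition, "tgfb")
  expect_equal(res$term, "fibrosis")
  expect_equal(res$gene_ratio, 1)
  # a random list w.r.t. the collection: no rows (seeded fixture)
  set.seed(11)
  rnd <- sample(u, 20)
  res_rnd <- compare_clusters(list(rand = rnd), sets, u, p_cut = 1e-4)
  expect_false("rand" %in% res_rnd$condition)
  # a shared enriched term appears under both conditions
  res2 <- compare_clusters(list(a = u[1:15], b = u[3:18]), sets, u)
  expect_setequal(res2$condition[res2$term == "fibrosis"], c("a", "b"))
})

test_that("zscore_matrix standardises rows over the unmasked cells", {
  z <- zscore_matrix(matrix(c(1, 2, 3), 1))
  expect_equal(as.vector(z$z), c(-1, 0, 1))
  # every complete row: mean 0, sample sd 1 to 1e-12
  set.seed(5)
  m <- matrix(rnorm(60, 10, 4), 6)
  zz <- zscore_matrix(m)
  expect_true(all(abs(rowMeans(zz$z)) < 1e-12))
  expect_true(all(abs(apply(zz$z, 1, sd) - 1) < 1e-12))
  # constant row: zeros, degenerate flag
  zc <- zscore_matrix(matrix(7, 1, 4))
  expect_equal(as.vector(zc$z), rep(0, 4))
  expect_true(zc$degenerate_rows)
  # masked cells stay masked and are excluded from the statistics
  mask <- matrix(FALSE, 1, 4); mask[1, 4] <- TRUE
  zm <- zscore_matrix(matrix(c(1, 2, 3, 100), 1), mask)
  expect_true(is.na(zm$z[1, 4]))
  expect_equal(zm$z[1, 1:3], c(-1, 0, 1))
  # a row with <2 unmasked cells is fully masked
  z1 <- zscore_matrix(matrix(c(1, NA, NA), 1))
  expect_true(all(z1$mask))
})

test_that("simple_de calls synthetic DE genes and is calibrated under the null", {
  # power: strong effects at tight residual sd are recovered
  sp <- expr_spec(n_genes = 200, n_reps_per_group = 5,
                  de_genes = setNames(rep(2, 10), sprintf("G%05d", 1:10)),
                  batch_sd = 0, residual_sd = 0.2, seed = 42)
  g <- gen_expression(sp)
  de <- simple_de(g$matrix, g$sample_info$group)
  expect_true(all(de$de[de$gene %in% sprintf("G%05d", 1:10)]))
  expect_equal(de$log2fc[de$gene == "G00001"], 2, tolerance = 0.3)
  # null: ~5% raw p < 0.05, ~0 at FDR
  spn <- expr_spec(n_genes = 1000, n_reps_per_group = 5, batch_sd = 0,
                   residual_sd = 0.5, seed = 7)
  gn <- gen_expression(spn)
  den <- simple_de(gn$matrix, gn$sample_info$group)
  expect_gt(mean(den$p < 0.05), 0.02)
  expect_lt(mean(den$p < 0.05), 0.08)
  expect_lt(sum(den$de), 3)
  expect_error(simple_de(gn$matrix[, 1:3], gn$sample_info$group[1:3]),
               "two groups")
})

test_that("Benjamini-Hochberg matches the hand computation on the toy", {
  # hand: p * m / rank, enforced monotone from the largest p down
  tab <- toy_deg(p = c(0.01, 0.02, 0.03, 0.5))
  expect_equal(tab$fdr, c(0.04, 0.04, 0.04, 0.5))
})

test_that("batch error simulation is calibrated and monotone in batch_sd", {
  # zero spread: no errors at all
  b0 <- simulate_batch_error(n_genes = 100, batch_sd = 0, residual_sd = 0,
                             n_repeats = 3, seed = 1)
  expect_equal(b0$mean_error_rate, 0)
  # pure null with a nominal-level test: error near alpha
  bn <- simulate_batch_error(n_genes = 4000, batch_sd = 0,
                             residual_sd = 0.5, n_repeats = 10, seed = 2)
  se <- sqrt(0.05 * 0.95 / (4000 * 10))
  expect_lt(abs(bn$mean_error_rate / 100 - 0.05), 4 * se + 0.002)
  # fixed-seed ladder: error rate non-decreasing in batch_sd
  rates <- vapply(c(0, 0.4, 0.8), function(s)
    simulate_batch_error(n_genes = 1500, batch_sd = s, residual_sd = 0.5,
                         n_repeats = 8, seed = 5)$mean_error_rate,
    numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("signed GMT round-trips through write_gmt/read_gmt", {
  sets <- list(up = marker_set("up", c(COL1A1 = 1L, ACTA2 = 1L)),
               mixed = marker_set("mixed", c(TIMP1 = 1L, ALB = -1L,
                                             IL6 = 0L)))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$up$members, sets$up$members)
  expect_equal(back$mixed$members, sets$mixed$members)
})
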
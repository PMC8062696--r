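test_that("flag enrichment builds the stratum x flag table and tests it", {
  # 10 background all flag-negative, 10 hits all flag-positive
  sc <- make_scores(c(rep(0, 10), rep(4, 10)))
  flag <- setNames(c(rep("no", 10), rep("yes", 10)), sc$protein_id)
  res <- flag_enrichment_test(sc, flag, k = 1, test = "fisher_exact")
  expect_equal(sort(as.vector(res$table)), c(0, 0, 10, 10))
  expect_equal(res$p_value, oracle_fisher_2x2(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-10)
  expect_equal(res$p_value, 1.08e-5, tolerance = 1e-6 / 1.08e-5)

  # identical proportions: no association
  sc2 <- make_scores(c(rep(0, 10), rep(2, 10)))
  flag2 <- setNames(rep(c("yes", "no"), 10), sc2$protein_id)
  expect_equal(
    flag_enrichment_test(sc2, flag2, k = 1, test = "fisher_exact")$p_value,
    1)

  # [[8,2],[2,8]] via a partially associated flag
  sc3 <- make_scores(c(rep(0, 10), rep(3, 10)))
  flag3 <- setNames(c(rep("no", 8), "yes", "yes",
                      rep("yes", 8), "no", "no"), sc3$protein_id)
  res3 <- flag_enrichment_test(sc3, flag3, k = 1, test = "fisher_exact")
  expect_equal(res3$p_value, 0.0230, tolerance = 5e-4 / 0.0230)
  expect_equal(res3$p_value, oracle_fisher_2x2(rbind(c(8, 2), c(2, 8))),
               tolerance = 1e-10)
})

test_that("three-outcome flags run through chi-square, not Fisher", {
  sc <- make_scores(c(rep(0, 30), rep(2, 30)))
  flag <- setNames(rep(c("up", "none", "down"), 20), sc$protein_id)
  res <- flag_enrichment_test(sc, flag, k = 1, test = "chi_square")
  expect_equal(dim(res$table), c(2L, 3L))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(flag_enrichment_test(sc, flag, k = 1, test = "fisher_exact"),
               "binary")
  expect_error(flag_enrichment_test(make_scores(rep(4, 10)),
                                    setNames(rep("yes", 10),
                                             sprintf("P%03d", 1:10)),
                                    k = 1),
               "empty stratum")
})

test_that("overlap test matches hypergeometric enumeration and is symmetric", {
  universe <- sprintf("U%03d", 1:100)
  a <- universe[1:10]
  res <- overlap_test(a, a, universe)
  expect_equal(res$overlap, 10L)
  expect_equal(res$fold, 10)
  expect_equal(res$p, 5.78e-14, tolerance = 1e-15 / 5.78e-14)
  expect_equal(res$p, oracle_fisher_2x2(rbind(c(10, 0), c(0, 90))),
               tolerance = 1e-10)

  b <- universe[11:15]
  disj <- overlap_test(universe[1:5], b, universe)
  expect_equal(disj$overlap, 0L)
  expect_equal(disj$fold, 0)
  expect_gte(disj$p, 0.05)
  expect_equal(disj$p, oracle_fisher_2x2(rbind(c(0, 5), c(5, 90))),
               tolerance = 1e-10)

  # symmetry and degenerate empty set
  x <- universe[3:40]; y <- universe[20:60]
  expect_equal(overlap_test(x, y, universe)$p,
               overlap_test(y, x, universe)$p)
  empty <- overlap_test(character(0), b, universe)
  expect_equal(empty$overlap, 0L)
  expect_equal(empty$p, 1)
  expect_error(overlap_test(c("nope"), b, universe), "universe")
})

test_that("Fisher p-values agree with enumeration across random 2x2 tables", {
  set.seed(99)
  universe_n <- 40
  for (i in 1:100) {
    # random 2x2 with total <= 40 realised through overlap_test's set route
    na <- sample(0:universe_n, 1)
    nb <- sample(0:universe_n, 1)
    u <- sprintf("u%02d", seq_len(universe_n))
    a <- sample(u, na)
    b <- sample(u, nb)
    got <- overlap_test(a, b, u)$p
    tab <- rbind(c(sum(a %in% b), na - sum(a %in% b)),
                 c(nb - sum(a %in% b), universe_n - na - nb + sum(a %in% b)))
    want <- if (na == 0 || nb == 0) 1 else oracle_fisher_2x2(tab)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("BKY two-stage adjustment follows the hand-run procedure", {
  expect_identical(bky_adjust(numeric(0)), numeric(0))
  expect_equal(bky_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bky_adjust(c(0.5, 1.2)), "0, 1")

  # hand execution at q = 0.05: q' = 0.047619; BH-adjusted p are
  # (0.004, 0.02, 0.0267, 0.8) so stage 1 rejects 3 and m0 = 1; stage-2
  # step-up with m0 = 1 gives p_(i)/i, already monotone.
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(bky_adjust(p, q = 0.05),
               c(0.001, 0.005, 0.02 / 3, 0.2), tolerance = 1e-12)

  # input order is preserved
  perm <- c(3, 1, 4, 2)
  expect_equal(bky_adjust(p[perm]), bky_adjust(p)[perm])
})

test_that("BKY reduces to Benjamini-Hochberg when stage 1 rejects nothing", {
  set.seed(4)
  p <- runif(20, 0.2, 1)
  expect_equal(bky_adjust(p, q = 0.05), p.adjust(p, method = "BH"),
               tolerance = 1e-12)
})

test_that("abundance shift tests flag a downward shift and not the null", {
  set.seed(31)
  n <- 200
  sc <- make_scores(c(rep(0, n / 2), rep(2, n / 2)),
                    protein_id = sprintf("Q%03d", 1:n))
  # null: same lognormal abundance in both strata
  ab_null <- setNames(10^rnorm(n, 1, 0.5), sc$protein_id)
  res_null <- abundance_shift_test(sc, ab_null, strata = 1L)
  expect_gt(res_null$p, 0.05)

  # hits shifted down 10-fold
  ab_shift <- ab_null
  ab_shift[sc$score >= 1] <- ab_shift[sc$score >= 1] / 10
  res_shift <- abundance_shift_test(sc, ab_shift, strata = c(1L, 2L))
  expect_true(all(res_shift$adj_p < 0.01))
  expect_equal(res_shift$n_background, c(100L, 100L))

  # single stratum with too little data errors
  sc_small <- make_scores(c(0, 0, 4))
  expect_error(
    abundance_shift_test(sc_small,
                         setNames(c(1, 2, 3), sc_small$protein_id),
                         strata = 1L),
    "insufficient")
})

test_that("secretome ortholog enrichment applies the >= 2 data-set rule", {
  map <- data.frame(
    protein_id = c("H1", "H1", "H2", "B1", "B2"),
    ortholog_id = c("o1", "o2", "o3", "o4", "o9"),
    stringsAsFactors = FALSE)
  datasets <- list(c("o1", "o3"), c("o2", "o3"), c("o4"))
  # H1: o1 in ds1, o2 in ds2 -> 2 data sets -> positive
  # H2: o3 in ds1+ds2 -> positive; B1: o4 only in ds3 -> negative
  res <- secretome_ortholog_enrichment(c("H1", "H2"), c("B1", "B2"),
                                       map, datasets, min_datasets = 2)
  expect_equal(unname(res$table["hit", "positive"]), 2)
  expect_equal(unname(res$table["background", "positive"]), 0)

  # perfect split of 10 vs 10 reproduces the exact hypergeometric p
  map2 <- data.frame(protein_id = c(sprintf("H%02d", 1:10),
                                    sprintf("B%02d", 1:10)),
                     ortholog_id = c(sprintf("oh%02d", 1:10),
                                     sprintf("ob%02d", 1:10)))
  ds2 <- list(sprintf("oh%02d", 1:10), sprintf("oh%02d", 1:10))
  res2 <- secretome_ortholog_enrichment(sprintf("H%02d", 1:10),
                                        sprintf("B%02d", 1:10),
                                        map2, ds2)
  expect_equal(res2$p_value, 1.08e-5, tolerance = 1e-6 / 1.08e-5)
  expect_error(secretome_ortholog_enrichment("H1", "B1",
                                             map[0, ], datasets),
               "empty ortholog map")
})

test_that("t-test hit calling normalizes channels and adjusts p-values", {
  set.seed(8)
  n <- 50
  ch <- matrix(rnorm(n * 6), n, 6,
               dimnames = list(NULL, c(paste0("bait", 1:3),
                                       paste0("ctrl", 1:3))))
  shifted <- c(rep(TRUE, 10), rep(FALSE, n - 10))
  ch[shifted, 1:3] <- ch[shifted, 1:3] + 3
  tab <- toy_quant_table(matrix(rnorm(n * 4), n), channels = ch)
  res <- ttest_hit_calling(tab, paste0("bait", 1:3), paste0("ctrl", 1:3))
  expect_true(all(res$adj_p >= res$p_value))
  expect_true(all(res$adj_p >= 0 & res$adj_p <= 1))
  # each group has n = 3 with unit noise, so individual estimates wobble;
  # the shifted block still separates clearly on average
  expect_gt(mean(res$log_fc[shifted]), 2)
  expect_gt(min(res$log_fc[shifted]), 0.5)

  # identical groups: p = 1, log_fc = 0
  same <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c(paste0("bait", 1:3),
                                         paste0("ctrl", 1:3))))
  tab_same <- toy_quant_table(matrix(0, 2, 4), channels = same)
  res_same <- ttest_hit_calling(tab_same, paste0("bait", 1:3),
                                paste0("ctrl", 1:3), normalize = FALSE)
  expect_equal(res_same$p_value, c(1, 1))
  expect_equal(res_same$log_fc, c(0, 0))

  # near-zero-variance separation
  jitter <- matrix(rnorm(6, 0, 1e-6), 1, 6,
                   dimnames = list(NULL, colnames(same)))
  jitter[1, 1:3] <- jitter[1, 1:3] + 3
  tab_j <- toy_quant_table(matrix(0, 1, 4), channels = jitter)
  res_j <- ttest_hit_calling(tab_j, paste0("bait", 1:3),
                             paste0("ctrl", 1:3), normalize = FALSE)
  expect_lt(res_j$p_value, 1e-6)
  expect_equal(res_j$log_fc, 3, tolerance = 1e-4)

  # a protein missing one group is skipped with a message
  ch_na <- ch
  ch_na[1, c("bait2", "bait3")] <- NA
  tab_na <- toy_quant_table(matrix(0, n, 4), channels = ch_na)
  expect_message(
    res_na <- ttest_hit_calling(tab_na, paste0("bait", 1:3),
                                paste0("ctrl", 1:3)),
    "skipped 1")
  expect_equal(nrow(res_na), n - 1L)
})

test_that("concordance is the Spearman correlation over shared proteins", {
  sc <- make_scores(1:10)
  tt <- data.frame(protein_id = sc$protein_id,
                   log_fc = 1, p_value = 0,
                   adj_p = 10^(-(1:10)))  # monotone with score
  expect_equal(concordance(sc, tt), 1)
  tt_rev <- tt; tt_rev$adj_p <- rev(tt$adj_p)
  expect_equal(concordance(sc, tt_rev), -1)
  expect_error(concordance(make_scores(1:2),
                           tt[1:2, ]), ">= 3")
})
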
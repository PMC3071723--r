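test_that("conditional point probability matches the factorial oracle", {
  sizes_grid <- list(library_sizes(1e3, 1e3),
                     library_sizes(5e5, 2.5e5),
                     library_sizes(7e5, 3.5e5))
  for (s in sizes_grid) {
    for (x in c(0, 1, 3, 7, 12)) for (y in c(0, 1, 5, 12)) {
      expect_equal(ac_point_probability(x, y, s),
                   brute_mass(x, y, s$n_a, s$n_b),
                   tolerance = 1e-12)
    }
  }
  # frozen spot values
  expect_equal(ac_point_probability(0, 0, library_sizes(1000, 1000)), 1)
  expect_equal(ac_point_probability(10, 0, library_sizes(7e5, 7e5)),
               0.0009765625)
  expect_equal(ac_point_probability(3, 7, library_sizes(5e5, 2.5e5)),
               brute_mass(3, 7, 5e5, 2.5e5), tolerance = 1e-12)
})

test_that("p-values match the brute-force tail oracle and its frozen values", {
  eq <- library_sizes(7e5, 7e5)
  expect_equal(ac_pvalue(5, 5, eq), 1)                 # 2 * 0.6230 capped
  expect_equal(ac_pvalue(10, 0, eq), 2 * 0.5^10)       # 1.953125e-3
  for (s in list(eq, library_sizes(3e5, 6e5))) {
    for (x in c(0, 2, 9, 20)) for (y in c(1, 4, 15)) {
      expect_equal(ac_pvalue(x, y, s),
                   brute_pvalue(x, y, s$n_a, s$n_b), tolerance = 1e-10)
      expect_equal(ac_pvalue(x, y, s, "one_sided"),
                   brute_pvalue(x, y, s$n_a, s$n_b, two_sided = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("p-values survive study-scale counts without overflow", {
  s <- library_sizes(742771, 721543)
  # extreme imbalance underflows to 0 rather than overflowing to NaN/Inf
  p <- ac_pvalue(5e5, 2e5, s)
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_equal(ac_pvalue(360000, 360000, library_sizes(7e5, 7e5)), 1)
  expect_lt(ac_pvalue(1000, 10, s), 1e-100)
})

test_that("label-swap symmetry holds for p-values and folds", {
  set.seed(11)
  s <- library_sizes(742771, 721543)
  sw <- library_sizes(721543, 742771)
  for (i in 1:25) {
    x <- rpois(1, 20); y <- rpois(1, 8)
    if (x + y == 0) next
    # the two tails are computed from opposite ends of the distribution, so
    # agreement is to rounding, not bitwise
    expect_equal(ac_pvalue(x, y, s), ac_pvalue(y, x, sw), tolerance = 1e-12)
    expect_equal(fold_enrichment(x, y, s), fold_enrichment(y, x, sw),
                 tolerance = 1e-12)
  }
})

test_that("x = y = 0 is a warning with p = 1; invalid inputs error", {
  s <- library_sizes(1e3, 1e3)
  expect_warning(p <- ac_pvalue(0, 0, s), "x = y = 0")
  expect_equal(p, 1)
  expect_error(ac_pvalue(-1, 2, s), "non-negative")
  expect_error(ac_point_probability(1.5, 2, s), "non-negative integers")
  expect_error(library_sizes(0, 10), "positive")
  expect_error(fold_enrichment(0, 0, s), "undefined")
})

test_that("fold enrichment normalizes by library size and handles zeros", {
  expect_equal(fold_enrichment(10, 10, library_sizes(1e3, 1e3)), 1)
  expect_equal(fold_enrichment(200, 2, library_sizes(1e3, 1e3)), 100)
  expect_equal(fold_enrichment(100, 5, library_sizes(7e5, 3.5e5)), 10)
  expect_identical(fold_enrichment(5, 0, library_sizes(1e3, 1e3)), Inf)
})

test_that("partition classification and summary conserve counts", {
  tbl <- data.frame(contig_id = paste0("c", 1:5),
                    count_a = c(3, 0, 7, 1, 0),
                    count_b = c(2, 5, 0, 1, 9))
  res <- classify_partition(tbl)
  expect_equal(res$partition, c("mixed", "b_only", "a_only", "mixed", "b_only"))
  s <- res$summary
  expect_equal(c(s$mixed, s$a_only, s$b_only), c(2, 1, 2))
  expect_equal(s$mixed + s$a_only + s$b_only, nrow(tbl))
  expect_equal(c(s$reads_a, s$reads_b), c(11, 17))

  one <- classify_partition(data.frame(contig_id = "c1", count_a = 1, count_b = 0))
  expect_equal(one$summary$a_only, 1)

  set.seed(3)
  for (i in 1:5) {
    n <- sample(5:50, 1)
    t2 <- data.frame(contig_id = paste0("x", 1:n),
                     count_a = rpois(n, 2), count_b = rpois(n, 2))
    t2 <- t2[t2$count_a + t2$count_b > 0, ]
    s2 <- classify_partition(t2)$summary
    expect_equal(s2$mixed + s2$a_only + s2$b_only, nrow(t2))
    expect_equal(s2$reads_a, sum(t2$count_a))
  }

  expect_error(classify_partition(
    data.frame(contig_id = c("a", "bad"), count_a = c(1, 0), count_b = c(1, 0))),
    "bad")
  expect_error(classify_partition(
    data.frame(contig_id = c("a", "a"), count_a = c(1, 1), count_b = c(1, 1))),
    "duplicate")
})

test_that("enrichment calling applies cutoff, direction and exclusivity rules", {
  s <- library_sizes(7e5, 7e5)
  tbl <- data.frame(contig_id = c("hot", "cold", "aonly", "tie"),
                    count_a = c(150, 3, 40, 6),
                    count_b = c(1, 1, 0, 6))
  calls <- call_enrichment(tbl, s)
  expect_equal(calls$contig_id, tbl$contig_id)  # input order preserved
  expect_true(calls$enriched[1] && calls$direction[1] == "A")
  expect_lt(calls$p_value[1], 1e-30)
  expect_false(calls$enriched[2])               # 2 * P(Y<=1 | 4, .5) = 0.625
  expect_equal(calls$p_value[2], 0.625)
  expect_true(is.na(calls$p_value[3]))          # exclusive untested by default
  expect_false(calls$enriched[3])
  expect_equal(calls$direction[4], "none")      # exact rate tie, never enriched

  inc <- call_enrichment(tbl, s, enrichment_config(include_exclusive = TRUE))
  expect_equal(inc$p_value[3], 2 * 0.5^40)
  expect_true(inc$enriched[3])

  expect_equal(nrow(call_enrichment(tbl[0, ], s)), 0)
})

test_that("swapping libraries swaps directions but not p-values", {
  set.seed(21)
  n <- 200
  tbl <- data.frame(contig_id = paste0("c", 1:n),
                    count_a = rpois(n, 10), count_b = rpois(n, 10))
  tbl <- tbl[tbl$count_a + tbl$count_b > 0, ]
  s <- library_sizes(742771, 721543)
  sw_tbl <- data.frame(contig_id = tbl$contig_id,
                       count_a = tbl$count_b, count_b = tbl$count_a)
  a <- call_enrichment(tbl, s)
  b <- call_enrichment(sw_tbl, library_sizes(721543, 742771))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold, b$fold)
  expect_equal(a$direction == "A", b$direction == "B")
  expect_equal(a$partition == "a_only", b$partition == "b_only")
})

test_that("robust filtering follows the configured magnitude rule", {
  s <- library_sizes(7e5, 7e5)
  tbl <- data.frame(contig_id = c("bigfold", "manyreads", "weak", "notsig"),
                    count_a = c(60, 300, 20, 12),
                    count_b = c(0, 90, 4, 6))
  cfg <- function(rule) enrichment_config(robust_rule = rule,
                                          include_exclusive = TRUE)
  calls_e <- call_enrichment(tbl, s, cfg("either"))
  # bigfold: fold Inf >= 100; manyreads: fold < 100 but max reads 300 > 100
  expect_setequal(robust_candidates(calls_e)$contig_id,
                  c("bigfold", "manyreads"))
  expect_equal(robust_candidates(call_enrichment(tbl, s, cfg("fold")))$contig_id,
               "bigfold")
  expect_equal(robust_candidates(call_enrichment(tbl, s, cfg("reads")))$contig_id,
               "manyreads")
  # robust set is always a subset of the enriched set
  expect_true(all(robust_candidates(calls_e)$enriched))
  # p >= alpha is dropped no matter the fold
  expect_false("notsig" %in% robust_candidates(calls_e)$contig_id)
  expect_error(enrichment_config(robust_rule = "both"))
})

test_that("BH adjustment is available and more conservative than raw cutoff", {
  set.seed(5)
  n <- 500
  tbl <- data.frame(contig_id = paste0("c", 1:n),
                    count_a = rpois(n, 10) + 1, count_b = rpois(n, 10) + 1)
  s <- library_sizes(7e5, 7e5)
  raw <- call_enrichment(tbl, s, enrichment_config(alpha = 0.05))
  bh <- call_enrichment(tbl, s, enrichment_config(alpha = 0.05, p_adjust = "BH"))
  expect_lte(sum(bh$enriched), sum(raw$enriched))
})
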
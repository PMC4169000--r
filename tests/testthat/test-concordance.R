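test_that("class-by-pattern counting groups patterns as configured", {
  recs <- data.frame(
    dge_class = c(1, 1, 1, 2, 2, 3, 4, 4),
    pattern = c("O", "O_endo", "IE", "IE", "IE", "A", "D", "D_A")
  )
  cpt <- class_pattern_table(recs)
  expect_equal(sum(cpt$counts), nrow(recs))
  expect_equal(unname(cpt$counts["1", "O"]), 2)  # O_endo folded into O
  expect_equal(unname(cpt$counts["1", "IE"]), 1)
  expect_equal(unname(cpt$counts["4", "D"]), 1)
  expect_equal(unname(cpt$counts["4", "D_A"]), 1)
  expect_equal(unname(cpt$class_totals["2"]), 2)
  expect_error(class_pattern_table(data.frame(dge_class = 1,
                                              pattern = "weird")),
               "unknown pattern")
})

test_that("pearson correlation matches a two-path computation", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6.5)
  r <- pearson_correlation(x, y)
  # independent covariance / SD route
  r2 <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(r, r2, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # invariant under positive affine maps
  set.seed(9)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(pearson_correlation(a, b),
               pearson_correlation(3 * a + 7, 0.5 * b - 2),
               tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})

test_that("exact 2x2 test agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 2), c(2, 2)))$p, 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p, 2 / 252,
               tolerance = 1e-12)
  t3 <- rbind(c(35, 58), c(2, 31))
  expect_equal(fisher_exact_2x2(t3)$p, oracle_fisher_p(35, 58, 2, 31),
               tolerance = 1e-12)
  # odds ratios
  expect_equal(fisher_exact_2x2(rbind(c(4, 2), c(1, 3)))$odds_ratio, 6)
  expect_true(is.infinite(fisher_exact_2x2(rbind(c(5, 0),
                                                 c(0, 5)))$odds_ratio))
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), "margins")
})

test_that("exact test equals enumeration and the stats reference on a sweep", {
  # exhaustive over modest totals here; the full sweep to 60 runs with the
  # acceptance checks
  for (tot in c(8, 13, 21)) {
    for (r1 in 1:(tot - 1)) {
      for (c1 in 1:(tot - 1)) {
        amin <- max(0, r1 + c1 - tot)
        amax <- min(r1, c1)
        for (a in amin:amax) {
          tab <- rbind(c(a, r1 - a), c(c1 - a, tot - r1 - c1 + a))
          p <- fisher_exact_2x2(tab)$p
          expect_equal(p, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                          tab[2, 1], tab[2, 2]),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # independent reference implementation on a few random tables
  set.seed(33)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 10) + 1, 2)
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("taxon enrichment compares restricted proportions across groups", {
  recs <- data.frame(
    dge_class = c(rep(1:3, length.out = 93), rep(4, 33)),
    restricted = c(rep(TRUE, 30), rep(FALSE, 63), rep(TRUE, 2),
                   rep(FALSE, 31)),
    orf_complete = TRUE
  )
  enr <- taxon_enrichment(recs, group_a = 1:3, group_b = 4)
  expect_equal(enr$proportion_a, 30 / 93, tolerance = 1e-12)
  expect_equal(enr$proportion_b, 2 / 33, tolerance = 1e-12)
  expect_equal(enr$fisher$p, oracle_fisher_p(30, 63, 2, 31),
               tolerance = 1e-12)
  # swapping groups swaps proportions, p unchanged
  swapped <- taxon_enrichment(recs, group_a = 4, group_b = 1:3)
  expect_equal(swapped$proportion_a, enr$proportion_b)
  expect_equal(swapped$fisher$p, enr$fisher$p, tolerance = 1e-12)
  # incomplete-ORF records are excluded
  recs2 <- recs
  recs2$orf_complete[1:10] <- FALSE
  expect_lt(taxon_enrichment(recs2, 1:3, 4)$proportion_a,
            enr$proportion_a)
  # no restricted transcripts anywhere: odds ratio undefined, signalled
  recs3 <- recs
  recs3$restricted <- FALSE
  expect_message(enr3 <- taxon_enrichment(recs3, 1:3, 4), "undefined")
  expect_null(enr3$fisher)
  expect_equal(enr3$proportion_a, 0)
})

test_that("qPCR expression levels halve per extra cycle", {
  expect_equal(qpcr_expression(0), 1)
  expect_equal(qpcr_expression(10), 2^-10)
  ct <- seq(5, 30, by = 0.5)
  expect_true(all(diff(qpcr_expression(ct)) < 0))
  expect_equal(qpcr_expression(ct - 1) / qpcr_expression(ct),
               rep(2, length(ct)))
  expect_error(qpcr_expression(NA))
})

test_that("reference-normalized fold changes agree across assay types", {
  # ddCt of -1 doubles expression: gene Ct drops by 1 vs a flat reference
  expect_equal(normalized_fold_change(gene = c(20, 19),
                                      reference = c(15, 15),
                                      type = "qpcr"), 2)
  expect_equal(normalized_fold_change(c(20, 20), c(15, 15), "qpcr"), 1)
  expect_equal(normalized_fold_change(gene = c(50, 400),
                                      reference = c(100, 100),
                                      type = "counts"), 8)
  expect_error(normalized_fold_change(c(50, 400), c(0, 100), "counts"),
               "reference")
})
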
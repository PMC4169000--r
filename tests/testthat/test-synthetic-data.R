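test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(dispersion = -1), "non-negative")
  expect_error(sim_config(planted_fractions = c(class1 = 0.5, class2 = 0.5,
                                                class3 = 0, class4 = 0,
                                                artifact = 0,
                                                contaminant = 0,
                                                null = 0.1)),
               "sum to 1")
  expect_error(sim_config(library_sizes = c(a_1 = -5)), "positive")
})

all_null_fractions <- c(class1 = 0, class2 = 0, class3 = 0, class4 = 0,
                        artifact = 0, contaminant = 0, null = 1)

test_that("all-null configurations plant no effects anywhere", {
  sim <- simulate_experiment(sim_config(n_genes = 500, mean_depth = 50,
                                        planted_fractions =
                                          all_null_fractions, seed = 5))
  lfc_cols <- grep("^lfc_", names(sim$truth), value = TRUE)
  expect_true(all(sim$truth[lfc_cols] == 0))
  expect_true(all(sim$truth$label == "null"))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 800, mean_depth = 60, seed = 99)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(sim_config(n_genes = 800, mean_depth = 60,
                                       seed = 100))
  expect_false(identical(s1$tables, s3$tables))
})

test_that("realized library totals track the configured sizes", {
  cfg <- sim_config(n_genes = 5000, mean_depth = 80, seed = 21)
  sim <- simulate_experiment(cfg)
  totals <- do.call(c, unname(lapply(sim$tables,
                                     function(t) colSums(t$counts))))
  declared <- cfg$library_sizes[names(totals)]
  expect_true(all(abs(totals - declared) / declared < 0.02))
  # the stored totals equal the column sums (nothing filtered)
  for (t in sim$tables) expect_equal(unname(t$totals),
                                     unname(colSums(t$counts)))
})

test_that("planted labels shape the right conditions", {
  cfg <- sim_config(n_genes = 2000, seed = 3)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth
  e <- cfg$effect_log2fc
  expect_true(all(tr$lfc_wnt3[tr$label == "class1"] == -e))
  expect_true(all(tr$lfc_fz1[tr$label == "class1"] == 0))
  expect_true(all(tr$lfc_fz1[tr$label == "class2"] == -e))
  expect_true(all(tr$lfc_stbm[tr$label == "class4"] == e))
  expect_true(all(tr$lfc_fz3[tr$label == "artifact"] == e))
  expect_true(all(tr$lfc_fz3[tr$label == "contaminant"] == log2(0.1)))
  expect_true(all(tr$lfc_uninjected == 0))
})

test_that("recovery evaluation is exact on a perfect screen", {
  sim <- simulate_experiment(sim_config(n_genes = 1000, seed = 8))
  tr <- sim$truth
  screen <- data.frame(
    gene = tr$gene,
    artifact_flag = tr$label == "artifact",
    contaminant_flag = tr$label == "contaminant",
    dge_class = match(tr$label, paste0("class", 1:4))
  )
  rec <- evaluate_recovery(screen, tr)
  expect_true(all(rec$stats$precision == 1))
  expect_true(all(rec$stats$recall == 1))
  expect_equal(rec$class_recovery, 1)
  expect_error(evaluate_recovery(screen[-1, ], tr), "gene universe")
})

test_that("labels absent from the truth are omitted, not divided by zero", {
  sim <- simulate_experiment(sim_config(n_genes = 400, mean_depth = 50,
                                        planted_fractions =
                                          all_null_fractions, seed = 13))
  tr <- sim$truth
  screen <- data.frame(gene = tr$gene, artifact_flag = FALSE,
                       contaminant_flag = FALSE, dge_class = NA_integer_)
  rec <- evaluate_recovery(screen, tr)
  expect_identical(rec$stats$label, "null")
  expect_true(is.na(rec$class_recovery))
})

test_that("class recovery improves with effect size and with depth", {
  recover_at <- function(effect, depth) {
    res <- run_pipeline(sim_config(n_genes = 4000, mean_depth = depth,
                                   effect_log2fc = effect, seed = 17),
                        verbose = FALSE)
    res$recovery$class_recovery
  }
  by_effect <- vapply(c(1, 2, 4), recover_at, numeric(1), depth = 100)
  expect_true(all(diff(by_effect) >= 0))
  expect_gt(by_effect[3], by_effect[1])
  by_depth <- vapply(c(10, 40, 150), function(d) recover_at(4, d),
                     numeric(1))
  expect_true(all(diff(by_depth) >= 0))
  expect_gt(by_depth[3], by_depth[1])
})
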
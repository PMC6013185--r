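test_that("scenario runs are deterministic and tidily shaped", {
  spec <- scenario_spec(10)
  a <- run_scenario(spec, methods = "anova_raw05", replicates = 2, base_seed = 5)
  b <- run_scenario(spec, methods = "anova_raw05", replicates = 2, base_seed = 5)
  expect_identical(a, b)
  expect_named(a, c("scenario", "p", "rho", "n", "method", "alpha", "metric",
                    "delta_or_block", "estimate", "mc_se", "n_replicates"))
  # one type1 row, one power row per delta, one corr_select row per block
  expect_equal(sum(a$metric == "type1"), 1)
  expect_equal(a$delta_or_block[a$metric == "power"], c(0.2, 0.5, 0.8))
  expect_equal(a$delta_or_block[a$metric == "corr_select"], c(1, 2, 3))
  expect_true(all(a$estimate >= 0 & a$estimate <= 1))
  c <- run_scenario(spec, methods = "anova_raw05", replicates = 2, base_seed = 6)
  expect_false(identical(a$estimate, c$estimate))
  expect_error(run_scenario(spec, methods = "anova_raw05", replicates = 0),
               ">= 1")
  expect_error(run_scenario(spec, methods = "pls_da", replicates = 1),
               "unknown method")
})

test_that("ridge selects everything: all estimates exactly 1", {
  res <- run_scenario(scenario_spec(10), methods = "enet:0",
                      replicates = 1, base_seed = 2)
  expect_true(all(res$estimate == 1))
})

test_that("a grid run covers every scenario and supports resume", {
  dir <- withr::local_tempdir()
  grid <- scenario_grid(p = 205, rho = c(0.4, 0.8), n = c(10, 20))
  res <- run_grid(grid, methods = "anova_raw05", replicates = 2,
                  base_seed = 3, out_dir = dir, verbose = FALSE)
  expect_equal(length(unique(res$scenario)), 4)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # a second run without resume refuses to clobber
  expect_error(run_grid(grid, methods = "anova_raw05", replicates = 2,
                        base_seed = 3, out_dir = dir, verbose = FALSE),
               "resume")
  res2 <- run_grid(grid, methods = "anova_raw05", replicates = 2,
                   base_seed = 3, out_dir = dir, resume = TRUE,
                   verbose = FALSE)
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-12)
})

test_that("doubling replicates keeps estimates within Monte-Carlo error", {
  spec <- scenario_spec(30)
  r1 <- run_scenario(spec, methods = "anova_raw05", replicates = 40,
                     base_seed = 9)
  r2 <- run_scenario(spec, methods = "anova_raw05", replicates = 80,
                     base_seed = 9)
  se <- pmax(sqrt(r1$mc_se^2 + r2$mc_se^2), 1e-3)
  expect_true(all(abs(r1$estimate - r2$estimate) <= 3.5 * se))
})

test_that("a written dataset re-analyzed through the table interface matches", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(scenario_spec(20, seed = 13))
  paths <- write_dataset(ds, dir)
  # table interface wants features x samples
  wide <- t(ds$values)
  labels <- data.frame(sample_id = rownames(ds$values), group = ds$labels)
  out <- apply_to_table(wide, labels, methods = c("anova_raw05", "anova_fdr20"))
  screen <- anova_screen(ds$values, ds$labels)
  expect_equal(out$selected$anova_raw05,
               screen$feature_id[screen$selected_raw05])
  expect_equal(out$selected$anova_fdr20,
               screen$feature_id[screen$selected_fdr20])
  expect_equal(out$overlap["anova_raw05", "anova_fdr20"],
               length(intersect(out$selected$anova_raw05,
                                out$selected$anova_fdr20)))
})

test_that("per-stratum BH on identical halves equals global BH per half", {
  ds <- simulate_dataset(scenario_spec(20, seed = 17))
  # duplicate the matrix so the two strata carry identical p-values
  wide <- t(ds$values)
  dup <- rbind(wide, wide)
  rownames(dup) <- c(paste0("pos_", rownames(wide)), paste0("neg_", rownames(wide)))
  labels <- data.frame(sample_id = rownames(ds$values), group = ds$labels)
  strata <- data.frame(feature_id = rownames(dup),
                       stratum = rep(c("pos", "neg"), each = nrow(wide)))
  out <- apply_to_table(dup, labels, methods = "anova_fdr20", strata = strata)
  global <- anova_screen(ds$values, ds$labels)
  expect_equal(out$screen$p_adj[1:nrow(wide)], global$p_adj)
  expect_equal(out$screen$p_adj[(nrow(wide) + 1):(2 * nrow(wide))], global$p_adj)
})

test_that("table validation catches unlabeled samples and bad input", {
  ds <- simulate_dataset(scenario_spec(10, seed = 19))
  wide <- t(ds$values)
  labels <- data.frame(sample_id = rownames(ds$values)[-1],
                       group = ds$labels[-1])
  expect_error(apply_to_table(wide, labels, methods = "anova_raw05"), "S01")
  bad_labels <- data.frame(sample_id = rownames(ds$values),
                           group = c(1, 2, 3, rep(1, 7)))
  expect_error(apply_to_table(wide, bad_labels, methods = "anova_raw05"),
               "two groups")
  dup <- wide[c(1, 1, 2), ]
  expect_error(apply_to_table(dup, data.frame(sample_id = rownames(ds$values),
                                              group = ds$labels),
                              methods = "anova_raw05"), "duplicate")
})
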
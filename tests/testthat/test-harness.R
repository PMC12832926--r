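make_pipeline_table <- function(n = 250, seed = 1) {
  g <- generate_cohort(cohort_config(n, seed = seed))
  run_pipeline(g$table)$table
}

test_that("the default grid has one panel per family x ratio and is deterministic", {
  tab <- make_pipeline_table(250, 2)
  plan <- experiment_plan(ratios = c("80:20", "90:10"),
                          families = c("lr", "gnb"), mode = "default")
  rep1 <- run_default_grid(tab, plan)
  expect_length(rep1$cells, 4)
  rep2 <- run_default_grid(tab, plan)
  for (nm in names(rep1$cells))
    expect_equal(unclass(rep1$cells[[nm]]$counts),
                 unclass(rep2$cells[[nm]]$counts))
  # panels regenerate exactly from their stored counts
  for (nm in names(rep1$cells)) {
    cell <- rep1$cells[[nm]]
    expect_equal(unclass(metric_panel(cell$counts, zero_division = "zero")),
                 unclass(cell$panel), ignore_attr = TRUE)
  }
})

test_that("every family clears 90% held-out accuracy on a wide-margin cohort", {
  cfg <- cohort_config(500, informative_features = c("oldpeak", "thalach", "cp"),
                       effect_sizes = c(oldpeak = 12, thalach = 12, cp = 12),
                       noise_scale = 0.1, seed = 14)
  tab <- run_pipeline(generate_cohort(cfg)$table)$table
  rep <- run_default_grid(tab, experiment_plan(ratios = "80:20", mode = "default"))
  for (nm in names(rep$cells))
    expect_gte(rep$cells[[nm]]$panel$accuracy, 0.9)
})

test_that("split assignment is fully determined by ratio and seed", {
  y <- rbinom(200, 1, 0.5)
  s1 <- stratified_split(y, 0.1, seed = 0)
  s2 <- stratified_split(y, 0.1, seed = 0)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_along(y))
  # stratification: class balance preserved within 1 subject per class
  expect_equal(sum(y[s1$test] == 1), round(sum(y == 1) * 0.1), tolerance = 1)
})

test_that("optimized grid stores specs, histories and passes the leakage audit", {
  tab <- make_pipeline_table(200, 5)
  plan <- experiment_plan(ratios = "90:10", families = "gnb", mode = "ipso")
  rep <- run_optimized_grid(tab, plan,
                            swarm_config(n_particles = 5, max_iterations = 3,
                                         seed = 1),
                            fitness_protocol(k_folds = 3))
  cell <- rep$cells[["gnb@90:10"]]
  expect_s3_class(cell$spec, "model_spec")
  expect_length(cell$history, 4)
  expect_true(all(diff(cell$history) >= 0))
  expect_true(cell$leakage_audit$disjoint)
  expect_setequal(cell$leakage_audit$fitness_rows, cell$split$train)
  expect_length(intersect(cell$leakage_audit$fitness_rows, cell$split$test), 0)
})

test_that("standard-pso mode degenerates the engine", {
  tab <- make_pipeline_table(150, 6)
  plan <- experiment_plan(ratios = "90:10", families = "lda",
                          mode = "standard-pso")
  rep <- run_optimized_grid(tab, plan,
                            swarm_config(n_particles = 4, max_iterations = 2,
                                         seed = 2),
                            fitness_protocol(k_folds = 3))
  expect_length(rep$cells, 1)
  expect_s3_class(rep$cells[[1]]$spec, "model_spec")
})

test_that("the ablation grid has four labelled arms", {
  g <- generate_cohort(cohort_config(220, seed = 7))
  cc <- corrupt_cohort(g$table, corruption_plan(220, seed = 7))
  ab <- run_ablation(cc$table,
                     swarm_config(n_particles = 4, max_iterations = 2, seed = 3),
                     fitness_protocol(k_folds = 3))
  expect_equal(nrow(ab), 4)
  expect_equal(ab$configuration, c("A", "B", "C", "D"))
  expect_true(all(is.finite(ab$accuracy)))
})

test_that("paired t-test matches its closed form and error contracts", {
  r <- paired_ttest(c(2, 1), c(1, 2))  # differences [1, -1]
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # differences [1, 2, 3]: t = mean/(sd/sqrt(n)) = 2/(1/sqrt(3))
  r2 <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  t_oracle <- 2 / (1 / sqrt(3))
  expect_equal(r2$t, t_oracle, tolerance = 1e-6)
  expect_equal(r2$t, 3.4641, tolerance = 1e-4)
  expect_equal(r2$df, 2)
  expect_equal(r2$p, 2 * pt(-t_oracle, df = 2))  # independent distribution oracle
  expect_equal(r2$p, 0.0742, tolerance = 1e-3)

  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_error(paired_ttest(1:3, 1:2), "length")
  expect_error(paired_ttest(1, 2), "two pairs")
})

test_that("selection frequencies are exact fractions over runs", {
  runs <- list(model_spec("lr", c("cp", "ca")),
               model_spec("lr", c("cp", "thal")),
               model_spec("lr", c("cp", "ca", "thal")))
  freq <- selection_frequency(runs, c("cp", "ca", "thal", "fbs"))
  expect_equal(freq[["cp"]], 1)
  expect_equal(freq[["ca"]], 2 / 3)
  expect_equal(freq[["fbs"]], 0)
  expect_error(selection_frequency(list()), "non-empty")
})
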
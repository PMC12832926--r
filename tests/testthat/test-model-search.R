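feats13 <- schema_features()

test_that("search spaces have the documented structure", {
  xgb <- build_space("xgb", feats13)
  expect_equal(xgb$n_dims, 13 + 5)
  expect_setequal(xgb$dims$name[14:18],
                  c("nrounds", "max_depth", "eta", "subsample",
                    "colsample_bytree"))
  gnb <- build_space("gnb", feats13)
  expect_equal(gnb$n_dims, 13 + 1)
  hyper_counts <- c(lr = 1, lda = 1, svc = 2)
  for (fam in names(hyper_counts)) {
    sp <- build_space(fam, feats13)
    expect_equal(sp$n_dims, 13 + hyper_counts[[fam]])
    expect_equal(sum(sp$dims$kind == "mask"), 13)
  }
  expect_error(build_space("mlp", feats13), "arg")
})

test_that("particle decoding maps masks, log dims and integers correctly", {
  sp <- build_space("lr", feats13)  # 13 masks + C on log[1e-3, 1e3]
  all_on <- decode_particle(c(rep(1, 13), 0.5), sp)
  expect_setequal(all_on$selected_features, feats13)
  expect_equal(all_on$hyperparams$C, 1)  # midpoint of log10 [-3, 3] is 10^0

  # empty mask repaired by argmax
  pos <- c(rep(0, 13), 0.5); pos[4] <- 0.3
  repaired <- decode_particle(pos, sp)
  expect_equal(repaired$selected_features, feats13[4])

  # integer rounding half-up
  xgb <- build_space("xgb", feats13)
  u_depth <- (5.5 - 2) / (10 - 2)  # affine preimage of exactly 5.5
  pos <- c(rep(1, 13), 0.5, u_depth, 0.5, 0.5, 0.5)
  dec <- decode_particle(pos, xgb)
  expect_equal(dec$hyperparams$max_depth, 6)
  expect_true(dec$hyperparams$nrounds >= 50 && dec$hyperparams$nrounds <= 500)
  expect_error(decode_particle(rep(0.5, 3), xgb), "dimension")

  # mask round trip on a grid of thresholds
  set.seed(6)
  for (i in 1:10) {
    mask <- rbinom(13, 1, 0.5)
    if (sum(mask) == 0) mask[1] <- 1
    dec <- decode_particle(c(mask, 0.5), sp)
    expect_setequal(dec$selected_features, feats13[mask == 1])
  }
})

test_that("cv fitness is 1 for an oracle stub and 0 for always-negative", {
  # stub predictors exercised through the fold-level F1 helper
  y <- rbinom(40, 1, 0.5)
  expect_equal(cardiopso:::fold_f1(y, y), 1)
  expect_equal(cardiopso:::fold_f1(y, rep(0, 40)), 0)
})

test_that("a wide-margin separable cohort is learnable by every family", {
  cfg <- cohort_config(300, informative_features = c("oldpeak", "thalach"),
                       effect_sizes = c(oldpeak = 4, thalach = 4),
                       noise_scale = 0.1, seed = 15)
  tab <- run_pipeline(generate_cohort(cfg)$table)$table
  spec <- default_spec("lr", feats13)
  f1 <- cv_fitness(spec, tab, fitness_protocol(k_folds = 5, eval_seed = 1))
  expect_gte(f1, 0.9)
})

test_that("fitness is invariant to feature-column order", {
  g <- generate_cohort(cohort_config(200, seed = 44))
  tab <- run_pipeline(g$table)$table
  spec <- default_spec("lda", feats13)
  f_a <- cv_fitness(spec, tab, fitness_protocol(k_folds = 3, eval_seed = 2))
  shuffled <- as.data.frame(tab)[, c(rev(feats13), "target")]
  f_b <- cv_fitness(spec, shuffled, fitness_protocol(k_folds = 3, eval_seed = 2))
  expect_equal(f_a, f_b)
})

test_that("fitted predictors are deterministic and honour the feature mask", {
  g <- generate_cohort(cohort_config(150, seed = 23))
  tab <- run_pipeline(g$table)$table
  probe <- tab[1:20, ]
  for (fam in c("lr", "lda", "gnb", "svc", "xgb")) {
    spec <- decode_particle(c(rep(1, 13), rep(0.5, build_space(fam, feats13)$n_dims - 13)),
                            build_space(fam, feats13))
    m1 <- fit_final(spec, tab, seed = 5)
    m2 <- fit_final(spec, tab, seed = 5)
    expect_equal(predict(m1, probe, type = "label"),
                 predict(m2, probe, type = "label"))
    expect_true(all(predict(m1, probe, type = "label") %in% c(0, 1)))
    expect_equal(length(predict(m1, probe, type = "score")), 20)
  }
  # single-feature mask consumes exactly one column
  one <- model_spec("lr", "oldpeak", list(C = 1))
  m <- fit_final(one, tab)
  probe2 <- probe
  probe2[, setdiff(feats13, "oldpeak")] <- 0  # other columns irrelevant
  expect_equal(predict(m, probe, type = "score"),
               predict(m, probe2, type = "score"))
})

test_that("shrinkage LDA at zero shrinkage agrees with the reference fit", {
  g <- generate_cohort(cohort_config(200, seed = 31))
  tab <- run_pipeline(g$table)$table
  spec <- model_spec("lda", feats13, list(shrinkage = 0))
  m <- fit_final(spec, tab)
  ours <- predict(m, tab, type = "label")
  ref <- MASS::lda(as.matrix(as.data.frame(tab)[, feats13]),
                   grouping = factor(tab$target))
  theirs <- as.integer(as.character(
    predict(ref, as.matrix(as.data.frame(tab)[, feats13]))$class))
  expect_gte(mean(ours == theirs), 0.99)
})

test_that("informative features beat decoys for a trained predictor", {
  cfg <- cohort_config(400, informative_features = c("oldpeak", "thalach", "cp"),
                       effect_sizes = c(oldpeak = 1.5, thalach = 1.5, cp = 1.5),
                       noise_scale = 0.3, seed = 19)
  tab <- run_pipeline(generate_cohort(cfg)$table)$table
  prot <- fitness_protocol(k_folds = 5, eval_seed = 3)
  f_inf <- cv_fitness(model_spec("lr", c("oldpeak", "thalach", "cp"),
                                 list(C = 1)), tab, prot)
  f_dec <- cv_fitness(model_spec("lr", c("age", "chol", "fbs"),
                                 list(C = 1)), tab, prot)
  expect_gt(f_inf, f_dec)
})

test_that("tuned fitness matches re-evaluating the decoded best spec", {
  g <- generate_cohort(cohort_config(150, seed = 8))
  tab <- run_pipeline(g$table)$table
  prot <- fitness_protocol(k_folds = 3, eval_seed = 1)
  tuned <- tune_model("gnb", tab,
                      swarm_config(n_particles = 6, max_iterations = 4, seed = 4),
                      prot)
  expect_equal(cv_fitness(tuned$spec, tab, prot), tuned$fitness)
})
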
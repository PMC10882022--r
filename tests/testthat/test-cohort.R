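test_that("cohort generation is deterministic and honors the configured sizes", {
  cfg <- cohort_config(n_examples = 50, F = 6, T = 8, seed = 7)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(lapply(d1$examples, `[[`, "values"),
                   lapply(d2$examples, `[[`, "values"))
  expect_identical(d1$task_labels, d2$task_labels)
  expect_identical(d1$attributes, d2$attributes)
  expect_identical(d1$split, d2$split)
  expect_length(d1$examples, 50)
  expect_equal(dim(d1$examples[[1]]$values), c(6, 8))
  expect_true(all(c("train", "validation", "test") %in% d1$split))
  expect_setequal(sort(unique(d1$attributes$ethnicity)), 0:2)
  d3 <- generate_cohort(cohort_config(n_examples = 50, F = 6, T = 8, seed = 8))
  expect_false(identical(d1$examples[[1]]$values, d3$examples[[1]]$values))
})

test_that("realized label prevalence stays within the binomial sampling bound", {
  cfg <- cohort_config(n_examples = 2000, F = 3, T = 4, prevalence = 0.3, seed = 7)
  ds <- generate_cohort(cfg)
  expect_lt(abs(mean(ds$task_labels) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("the degenerate generator collapses each class to identical baselines", {
  cfg <- cohort_config(n_examples = 30, F = 4, T = 8, noise_sd = 0,
                       task_effect_size = 0,
                       latent_attrs = list(list(name = "sex", n_classes = 2,
                                                effect_size = 0)),
                       seed = 3)
  ds <- generate_cohort(cfg)
  ref <- ds$examples[[1]]$values
  for (e in ds$examples) expect_equal(e$values, ref)
})

test_that("attribute draws are independent of the task label by construction", {
  ds <- generate_cohort(cohort_config(n_examples = 4000, F = 2, T = 4, seed = 11))
  for (a in names(ds$attributes)) {
    expect_lt(abs(cor(ds$task_labels, ds$attributes[[a]])), 3 / sqrt(4000))
  }
})

test_that("cohorts round-trip through wide and long CSV identically", {
  ds <- make_tiny_cohort(n = 10, F = 3, T = 6, seed = 5)
  dw <- withr::local_tempdir()
  dl <- withr::local_tempdir()
  cohort_to_files(ds, dw, format = "wide")
  cohort_to_files(ds, dl, format = "long")
  w <- load_cohort(dw)
  l <- load_cohort(dl)
  expect_equal(lapply(w$examples, `[[`, "values"),
               lapply(ds$examples, `[[`, "values"), tolerance = 1e-12)
  expect_equal(lapply(l$examples, `[[`, "values"),
               lapply(w$examples, `[[`, "values"), tolerance = 1e-12)
  expect_identical(w$task_labels, ds$task_labels)
  expect_identical(w$split, ds$split)
  expect_equal(w$attributes$sex, ds$attributes$sex)
  expect_identical(l$attributes, w$attributes)
})

test_that("loading reports malformed inputs with context", {
  ds <- make_tiny_cohort(n = 6, F = 2, T = 4, seed = 6)
  d <- withr::local_tempdir()
  cohort_to_files(ds, d)
  file.remove(file.path(d, "labels.csv"))
  err <- expect_error(load_cohort(d), class = "enctsf_parse_error")
  expect_match(conditionMessage(err), "labels")
  expect_error(load_cohort(withr::local_tempdir()), class = "enctsf_parse_error")
})

test_that("planted signals are linearly recoverable at default effect sizes", {
  # task and attribute probes on flattened raw features at the default
  # cohort shape (44 x 48); effect size 0 is chance
  ds <- generate_cohort(cohort_config(n_examples = 800, seed = 9))
  model <- train_target_model(ds, "linear", seed = 1, epochs = 40)
  te <- ds$split == "test"
  expect_gte(auroc(predict_score(model, ds)[te], ds$task_labels[te]), 0.8)
  pr <- probe_latent(model, ds, "sex", seed = 1, epochs = 100)
  expect_gte(pr$auroc, 0.8)
  # the ordinal 3-class attribute: extreme classes are linearly separable
  # one-vs-rest; the middle class is not (by construction of the
  # amplitude-modulation planting), so only the extremes are asserted
  pr2 <- probe_latent(model, ds, "ethnicity", seed = 1, epochs = 100)
  expect_gte(pr2$per_class[["class0"]], 0.7)
  expect_gte(pr2$per_class[["class2"]], 0.7)

  null_cfg <- cohort_config(n_examples = 800, seed = 9,
                            task_effect_size = 0,
                            latent_attrs = list(list(name = "sex", n_classes = 2,
                                                     effect_size = 0)))
  ds0 <- generate_cohort(null_cfg)
  m0 <- train_target_model(ds0, "linear", seed = 1, epochs = 15)
  te0 <- ds0$split == "test"
  expect_lt(abs(auroc(predict_score(m0, ds0)[te0], ds0$task_labels[te0]) - 0.5), 0.15)
})
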
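make_separable_cohort <- function(n = 200, seed = 1) {
  # task effect huge, noise tiny: linearly separable by construction
  generate_cohort(cohort_config(n_examples = n, F = 4, T = 8, seed = seed,
                                task_effect_size = 8, noise_sd = 0.05,
                                latent_attrs = list(list(name = "sex", n_classes = 2,
                                                         effect_size = 1))))
}

test_that("AUROC matches exhaustive pair counting, with and without ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(2)
  for (i in 1:10) {
    scores <- round(runif(40), 1)            # coarse grid forces ties
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("rank-formula AUROC agrees with pROC on tied and untied scores", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    scores <- if (i %% 2 == 0) round(runif(80), 1) else rnorm(80)
    labels <- rbinom(80, 1, 0.4)
    expect_equal(auroc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("AUROC is invariant to strictly monotone score transforms", {
  set.seed(3)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.4)
  a <- auroc(scores, labels)
  expect_equal(auroc(qlogis(plogis(scores)), labels), a)
  expect_equal(auroc(exp(scores), labels), a)
  expect_equal(auroc(scores * 100 - 7, labels), a)
})

test_that("target models reach AUROC 1 on separable data and chance on shuffled labels", {
  ds <- make_separable_cohort(seed = 4)
  te <- ds$split == "test"
  for (arch in c("linear", "mlp")) {
    m <- train_target_model(ds, arch, seed = 1, epochs = 80)
    expect_equal(auroc(predict_score(m, ds)[te], ds$task_labels[te]), 1)
  }
  shuffled <- ds
  set.seed(9)
  shuffled$task_labels <- sample(ds$task_labels)
  m <- train_target_model(shuffled, "mlp", seed = 1, epochs = 20)
  expect_lt(abs(auroc(predict_score(m, shuffled)[te], shuffled$task_labels[te]) - 0.5), 0.35)
})

test_that("the recurrent architecture trains and exposes a 32-d embedding", {
  ds <- make_separable_cohort(seed = 5)
  m <- train_target_model(ds, "recurrent", seed = 1, epochs = 30)
  te <- ds$split == "test"
  expect_equal(ncol(embed(m, ds)), 32)
  expect_gte(auroc(predict_score(m, ds)[te], ds$task_labels[te]), 0.9)
})

test_that("training is deterministic given a seed and rejects single-class labels", {
  ds <- make_separable_cohort(seed = 6)
  m1 <- train_target_model(ds, "mlp", seed = 3, epochs = 4)
  m2 <- train_target_model(ds, "mlp", seed = 3, epochs = 4)
  expect_identical(m1$params, m2$params)
  bad <- ds; bad$task_labels <- rep(0L, length(bad$task_labels))
  expect_error(train_target_model(bad, "mlp", seed = 1),
               class = "enctsf_training_error")
})

test_that("probes recover attributes encoded in the embedding and not otherwise", {
  ds <- make_separable_cohort(n = 120, seed = 7)
  # a model whose 'embedding' IS the one-hot attribute: probe must hit 1
  model <- structure(list(arch = "identity-fixture"), class = "embedding_model")
  onehot <- cbind(ds$attributes$sex, 1 - ds$attributes$sex)
  with_mocked_bindings(
    model_forward = function(model, ds2) list(score = rep(0.5, nrow(onehot)), embed = onehot),
    {
      pr <- probe_latent(model, ds, "sex", seed = 1, epochs = 200)
      expect_equal(pr$auroc, 1)
    },
    .package = "enctsf")
  # embeddings independent of the attribute: chance
  set.seed(8)
  noise_emb <- matrix(rnorm(length(ds$examples) * 8), ncol = 8)
  with_mocked_bindings(
    model_forward = function(model, ds2) list(score = rep(0.5, nrow(noise_emb)), embed = noise_emb),
    {
      pr <- probe_latent(model, ds, "sex", seed = 1, epochs = 50)
      expect_lt(abs(pr$auroc - 0.5), 0.35)
    },
    .package = "enctsf")
  # constant embeddings: degenerate-input warning, AUROC 0.5
  const_emb <- matrix(1, length(ds$examples), 4)
  with_mocked_bindings(
    model_forward = function(model, ds2) list(score = rep(0.5, nrow(const_emb)), embed = const_emb),
    {
      expect_warning(pr <- probe_latent(model, ds, "sex", seed = 1), "constant")
      expect_equal(pr$auroc, 0.5)
    },
    .package = "enctsf")
})

test_that("multiclass attributes are probed one-vs-rest with macro averaging", {
  ds <- generate_cohort(cohort_config(n_examples = 150, F = 6, T = 8, seed = 10))
  m <- train_target_model(ds, "mlp", seed = 1, epochs = 5)
  pr <- probe_latent(m, ds, "ethnicity", seed = 1, epochs = 5)
  expect_length(pr$per_class, 3)
  expect_equal(pr$auroc, mean(pr$per_class))
  expect_error(probe_latent(m, ds, "nope"), class = "enctsf_validation_error")
})
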
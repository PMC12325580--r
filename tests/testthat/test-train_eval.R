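# Metric suite, training procedure semantics and activation maps.

test_that("perfect predictions give unit metrics and a diagonal confusion", {
  y <- factor(rep(c("Normal", "KIRC", "KIRP", "KICH"), each = 5),
              levels = c("Normal", "KIRC", "KIRP", "KICH"))
  rep <- metrics_report(y, y)
  expect_true(all(rep$per_class$precision == 1))
  expect_true(all(rep$per_class$f1 == 1))
  expect_equal(rep$overall$accuracy, 1)
  expect_equal(sum(rep$confusion), 20)
  expect_equal(sum(diag(rep$confusion)), 20)
})

test_that("hand-computed binary confusion metrics are reproduced", {
  # confusion [[2,1],[0,3]]: class a truth 3 (2 right), class b truth 3
  truth <- factor(c("a", "a", "a", "b", "b", "b"), levels = c("a", "b"))
  pred <- factor(c("a", "a", "b", "b", "b", "b"), levels = c("a", "b"))
  rep <- metrics_report(truth, pred)
  expect_equal(unclass(rep$confusion)[1, ], c(a = 2, b = 1))
  expect_equal(rep$per_class$precision[1], 1.0)
  expect_equal(rep$per_class$recall[1], 2 / 3)
  # cross-check against an established implementation
  cm <- caret::confusionMatrix(pred, truth)
  expect_equal(unname(rep$overall$accuracy),
               unname(cm$overall[["Accuracy"]]))
})

test_that("confusion-matrix margins are conserved and balanced data ties micro to macro", {
  set.seed(30)
  y <- factor(rep(c("Normal", "KIRC", "KIRP", "KICH"), each = 25))
  pred <- factor(sample(levels(y), 100, replace = TRUE), levels = levels(y))
  rep <- metrics_report(y, pred)
  expect_equal(unname(rowSums(rep$confusion)), unname(table(y)),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(rep$confusion)), unname(table(pred)),
               ignore_attr = TRUE)
  expect_equal(rep$overall$accuracy, macro_average(rep$per_class$recall),
               tolerance = 1e-12)
})

test_that("roc_auc equals the pair-counting statistic and reverses cleanly", {
  # perfect separation
  y <- factor(c(rep("a", 5), rep("b", 5)), levels = c("a", "b"))
  s <- cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  expect_equal(unname(roc_auc(s, y)), c(1, 1))
  # random interleaved scores vs the Mann-Whitney oracle
  for (seed in 1:3) {
    set.seed(seed)
    n <- 40
    yy <- factor(sample(c("a", "b"), n, replace = TRUE), levels = c("a", "b"))
    sc <- matrix(stats::runif(2 * n), n, 2)
    got <- roc_auc(sc, yy)
    expect_equal(unname(got["a"]), pairwise_auc(sc[, 1], yy == "a"),
                 tolerance = 1e-12)
    expect_equal(unname(got["b"]), pairwise_auc(sc[, 2], yy == "b"),
                 tolerance = 1e-12)
    # reversing scores maps AUC to 1 - AUC
    rev_auc <- roc_auc(-sc, yy)
    expect_equal(unname(rev_auc), unname(1 - got), tolerance = 1e-12)
  }
  # both classes are degenerate here, so one warning per class
  w <- capture_warnings(
    out <- roc_auc(matrix(runif(10), 5, 2),
                   factor(rep("a", 5), levels = c("a", "b"))))
  expect_match(w, "single-class", all = TRUE)
  expect_true(all(is.na(out)))
})

test_that("training rejects empty sets, decreases loss and keeps lr non-increasing", {
  tiny <- tiny_data_fixture()
  set.seed(1)
  model <- build_variant(variant_spec("Proposed"), input_size = 8)
  expect_error(train_model(model, tiny$x[, , , 0, drop = FALSE],
                           factor(character(0)), train_config()),
               "empty")
  fit <- train_model(model, tiny$x, tiny$y,
                     train_config(epochs = 3, seed = 2, val_frac = 0.2))
  expect_equal(nrow(fit$history), 3)
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("best-weight restore reproduces the best recorded validation accuracy", {
  tiny <- tiny_data_fixture()
  set.seed(5)
  model <- build_variant(variant_spec("CNN-1"), input_size = 8)
  n <- dim(tiny$x)[4]
  val <- seq(1, n, by = 3)
  fit <- train_model(model, tiny$x[, , , -val, drop = FALSE], tiny$y[-val],
                     train_config(epochs = 4, seed = 5),
                     x_val = tiny$x[, , , val, drop = FALSE],
                     y_val = tiny$y[val])
  pv <- evaluate_model(model, tiny$x[, , , val, drop = FALSE], tiny$y[val])
  expect_equal(pv$overall$accuracy, max(fit$history$val_acc),
               tolerance = 1e-12)
})

test_that("trial averaging stays inside the per-trial envelope", {
  tiny <- tiny_data_fixture()
  res <- run_trials(variant_spec("CNN-1"), renalnet_config(),
                    tiny$x, tiny$y, tiny$x, tiny$y,
                    train_config(epochs = 1, val_frac = 0.2), seeds = c(1, 2))
  accs <- sapply(res$trials, function(r) r$overall$accuracy)
  expect_gte(res$average$overall$accuracy, min(accs) - 1e-12)
  expect_lte(res$average$overall$accuracy, max(accs) + 1e-12)
  expect_length(res$trials, 2)
  # identical trials average to the single report
  one <- res$trials[[1]]
  avg <- renalnet:::average_reports(list(one, one))
  expect_equal(avg$overall$f1, one$overall$f1)
})

test_that("cross-validation rotates every fold through the test position", {
  tiny <- tiny_data_fixture()
  folds <- rep(1:3, length.out = dim(tiny$x)[4])
  res <- cross_validate(variant_spec("CNN-1"), renalnet_config(),
                        tiny$x, tiny$y, folds,
                        train_config(epochs = 1, val_frac = 0.3))
  expect_length(res$per_fold, 3)
  ns <- sapply(res$per_fold, function(r) r$n)
  expect_equal(unname(ns), unname(as.vector(table(folds))))
  accs <- sapply(res$per_fold, function(r) r$overall$accuracy)
  expect_equal(res$average$overall$accuracy, mean(accs), tolerance = 1e-12)
})

test_that("activation maps are normalized, banded and warn when degenerate", {
  set.seed(8)
  model <- build_variant(variant_spec("Proposed"), input_size = 8)
  img <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  cam <- activation_map(model, img, 2L)
  expect_true(all(cam$map >= 0 & cam$map <= 1))
  expect_true(all(cam$bands %in% 1:3))
  expect_equal(dim(cam$overlay), c(8, 8, 3))
  # a zeroed model produces a uniform (all-low) map with a warning
  renalnet:::module_zero_params(model)
  expect_warning(cam0 <- activation_map(model, img, 1L), "uniform")
  expect_true(all(cam0$map == 0))
  expect_true(all(cam0$bands == 1L))
})
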
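# Shared heavyweight fixtures, computed once per test run.
#
# The smoke-training fixture is the package's reduced-scale study: 60
# patches per class over 12 cases per class rendered at 32 x 32 (the same
# field of view as the reference patches at reduced resolution), a
# slide-wise split of 10 test patches per class, and the reference model
# trained with the standard protocol at 8 epochs.

.fixture_env <- new.env(parent = emptyenv())

smoke_training_fixture <- function() {
  if (!is.null(.fixture_env$smoke)) return(.fixture_env$smoke)
  man <- generate_dataset(60, 12, seed = 11)
  sp <- slidewise_split(man, seed = 11, test_per_class = 10)
  tr <- dataset_tensors(sp$train, size = 32)
  te <- dataset_tensors(sp$test, size = 32)
  set.seed(11)
  model <- build_variant(variant_spec("Proposed"), input_size = 32)
  fit <- train_model(model, tr$x, tr$y, train_config(epochs = 8, seed = 11),
                     case_id = sp$train$case_id)
  report <- evaluate_model(model, te$x, te$y)
  .fixture_env$smoke <- list(split = sp, model = model, fit = fit,
                             report = report, test = te)
  .fixture_env$smoke
}

# A throwaway micro-scale dataset (8 x 8 patches) for procedure-level tests
# where classification quality is irrelevant.
tiny_data_fixture <- function() {
  if (!is.null(.fixture_env$tiny)) return(.fixture_env$tiny)
  man <- generate_dataset(6, 2, seed = 3)
  dat <- dataset_tensors(man, size = 8)
  .fixture_env$tiny <- list(manifest = man, x = dat$x, y = dat$y)
  .fixture_env$tiny
}
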
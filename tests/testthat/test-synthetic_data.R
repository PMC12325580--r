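# Synthetic dataset generator, split/fold protocol and preprocessing.

test_that("generated manifests are balanced and case-structured", {
  man <- generate_dataset(20, 5, seed = 1)
  expect_equal(nrow(man), 80)
  expect_equal(unname(table(man$class)), rep(20L, 4), ignore_attr = TRUE)
  expect_equal(length(unique(man$case_id)), 20)
  # every patch belongs to exactly one case; a case has one class
  expect_false(any(duplicated(man$patch_id)))
  case_class <- unique(man[, c("case_id", "class")])
  expect_false(any(duplicated(case_class$case_id)))
  # uneven division spreads the remainder over cases
  man2 <- generate_dataset(23, 5, seed = 1)
  sizes <- table(man2$case_id[man2$class == "KIRC"])
  expect_true(all(sizes %in% c(4L, 5L)))
})

test_that("an empty request yields an empty manifest and no files", {
  man <- generate_dataset(0)
  expect_equal(nrow(man), 0)
  expect_true(all(c("patch_id", "case_id", "class") %in% names(man)))
})

test_that("generation is deterministic under a seed", {
  m1 <- generate_dataset(10, 2, seed = 7)
  m2 <- generate_dataset(10, 2, seed = 7)
  expect_identical(m1, m2)
  r <- m1[5, ]
  img1 <- render_patch(r$class, r$patch_seed, case_stain_jitter(r$case_seed),
                       size = 48)
  img2 <- render_patch(r$class, r$patch_seed, case_stain_jitter(r$case_seed),
                       size = 48)
  expect_identical(img1, img2)
  m3 <- generate_dataset(10, 2, seed = 8)
  r3 <- m3[5, ]
  img3 <- render_patch(r3$class, r3$patch_seed,
                       case_stain_jitter(r3$case_seed), size = 48)
  expect_false(identical(img1, img3))
})

test_that("written PNG files round-trip the rendered patch", {
  d <- tempfile("synthpng")
  man <- generate_dataset(2, 1, seed = 3, size = 24, dir = d)
  expect_true(all(file.exists(man$path)))
  img <- png::readPNG(man$path[1])
  expect_equal(dim(img), c(24, 24, 3))
  unlink(d, recursive = TRUE)
})

test_that("slide-wise splits never leak cases and hit exact test counts", {
  man <- generate_dataset(60, 12, seed = 2)
  for (seed in c(1, 2, 3)) {
    sp <- slidewise_split(man, seed = seed, test_per_class = 10)
    expect_length(intersect(unique(sp$train$case_id),
                            unique(sp$test$case_id)), 0)
    expect_equal(unname(table(sp$test$class)), rep(10L, 4),
                 ignore_attr = TRUE)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(man))
  }
  # infeasible target (case sizes are all 5 here)
  expect_error(slidewise_split(man, seed = 1, test_per_class = 12),
               "no combination")
})

test_that("folds are case-respecting, disjoint, exhaustive and balanced", {
  man <- generate_dataset(60, 15, seed = 5)   # case size 4: 3 cases per fold
  fm <- make_folds(man, k = 5, seed = 9)
  expect_false(any(is.na(fm$fold)))
  expect_equal(sort(unique(fm$fold)), 1:5)
  # case-respecting: each case sits in exactly one fold
  cf <- unique(fm[, c("case_id", "fold")])
  expect_false(any(duplicated(cf$case_id)))
  # per-fold per-class balance: 60 / 5 = 12
  tab <- table(fm$class, fm$fold)
  expect_true(all(tab == 12))
  expect_error(make_folds(man, k = 1), "at least 2")
})

test_that("preprocessing standardizes channels and resizes", {
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  out <- preprocess_patch(img, size = 32)
  expect_equal(dim(out), c(32, 32, 3))
  for (ch in 1:3) {
    expect_lt(abs(mean(out[, , ch])), 1e-6)
    expect_equal(mean(out[, , ch]^2), 1, tolerance = 1e-4)
  }
  # constant image degenerates to all zero under the variance floor
  flat <- array(0.5, c(16, 16, 3))
  expect_true(all(abs(preprocess_patch(flat, 16)) < 1e-2))
  expect_error(preprocess_patch(array(0, c(8, 8)), 8), "RGB")
  # native-size input downscales to the target side
  big <- array(stats::runif(96 * 96 * 3), c(96, 96, 3))
  expect_equal(dim(preprocess_patch(big, size = 24)), c(24, 24, 3))
})

test_that("class appearance parameters are distinct across classes", {
  m <- class_appearance_model()
  expect_setequal(names(m$classes), c("Normal", "KIRC", "KIRP", "KICH"))
  sig <- vapply(m$classes, function(p) paste(names(p), collapse = ","), "")
  expect_gt(length(unique(sig)), 1)
})
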
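test_that("cube extraction centres, zero-pads, and validates", {
  vol <- array(rnorm(31^3), dim = c(31, 31, 31))
  ctr <- tibble::tibble(z = 15, y = 15, x = 15)
  cube <- extract_cubes(vol, ctr)$cube[[1]]
  expect_equal(cube, vol[11:21, 11:21, 11:21])

  corner <- extract_cubes(vol, tibble::tibble(z = 0, y = 0, x = 0))$cube[[1]]
  expect_equal(dim(corner), c(11, 11, 11))
  expect_true(all(corner[1:5, , ] == 0))    # out-of-bounds planes
  expect_equal(corner[6:11, 6:11, 6:11], vol[1:6, 1:6, 1:6])

  const <- array(3, dim = c(15, 15, 15))
  cubes <- extract_cubes(const, tibble::tibble(z = c(7, 7), y = c(7, 7),
                                               x = c(7, 8)))
  expect_true(all(vapply(cubes$cube, function(a) all(a == 3), logical(1))))

  expect_error(extract_cubes(vol, tibble::tibble(z = 31, y = 0, x = 0)),
               class = "fishmap_error_bounds")
  expect_error(extract_cubes(vol, ctr, size = 10),
               class = "fishmap_error_validation")
})

test_that("stratified split uses floor rounding per class and stays disjoint", {
  mk <- function(n, lab) tibble::tibble(
    z = seq_len(n), y = 0, x = 0, label = lab,
    cube = replicate(n, array(rnorm(27), dim = c(3, 3, 3)), simplify = FALSE))
  cubes <- dplyr::bind_rows(mk(7, "punctate"), mk(5, "diffuse"))
  sp <- split_cubes(cubes, 0.8, seed = 2)
  expect_equal(sum(sp$train$label == "punctate"), floor(0.8 * 7))
  expect_equal(sum(sp$train$label == "diffuse"), floor(0.8 * 5))
  expect_equal(nrow(sp$train) + nrow(sp$test), 12L)
  key <- function(d) paste(d$z, d$y, d$x, d$label)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)

  ten <- mk(10, "punctate")
  ten$label[6:10] <- "diffuse"
  sp10 <- split_cubes(ten, 0.8, seed = 1)
  expect_equal(nrow(sp10$train), 8L)
  expect_equal(nrow(sp10$test), 2L)

  expect_error(split_cubes(mk(1, "punctate"), 0.8),
               class = "fishmap_error_validation")
})

test_that("augmentation is exactly 7-fold with pairwise-distinct transforms", {
  one <- tibble::tibble(z = 0, y = 0, x = 0, label = "punctate",
                        cube = list(array(rnorm(11^3), dim = c(11, 11, 11))))
  aug <- augment_cubes(one)
  expect_equal(nrow(aug), 7L)
  expect_true(all(aug$label == "punctate"))
  # all seven results differ on a generic asymmetric cube
  for (i in 1:6) for (j in (i + 1):7) {
    expect_false(identical(aug$cube[[i]], aug$cube[[j]]))
  }
  # horizontal flip is an involution; four quarter-turns restore the cube
  a <- one$cube[[1]]
  hf <- fishmap:::aug_hflip
  expect_equal(hf(hf(a)), a)
  r <- fishmap:::aug_rot_p90
  expect_equal(r(r(r(r(a)))), a)
  # +90 then -90 is the identity
  expect_equal(fishmap:::aug_rot_m90(r(a)), a)
  # translations vacate zero-filled planes
  sh <- fishmap:::aug_shift(a, 2)
  expect_true(all(sh[, , 1:2] == 0))
  expect_equal(sh[, , 3:11], a[, , 1:9])
})

test_that("split and 7-fold augmentation reproduce the printed training totals", {
  mk <- function(n, lab) tibble::tibble(
    z = seq_len(n), y = 0, x = 0, label = lab,
    cube = replicate(n, array(0, dim = c(3, 3, 3)), simplify = FALSE))
  cubes <- dplyr::bind_rows(mk(2448, "punctate"), mk(1916, "diffuse"))
  sp <- split_cubes(cubes, 0.8, seed = 1)
  n_punct <- sum(sp$train$label == "punctate")
  n_diff <- sum(sp$train$label == "diffuse")
  expect_equal(n_punct, 1958L)
  expect_equal(n_diff, 1532L)
  expect_equal(sum(sp$test$label == "punctate"), 490L)
  expect_equal(sum(sp$test$label == "diffuse"), 384L)
  aug <- augment_cubes(sp$train)
  expect_equal(sum(aug$label == "punctate"), 13706L)
  expect_equal(sum(aug$label == "diffuse"), 10724L)
})

test_that("backpropagation matches finite-difference gradients", {
  model <- stain_model_config(n_filters1 = 2, n_filters2 = 3)
  geom <- fishmap:::stain_geometry(9, model)
  set.seed(5)
  params <- fishmap:::stain_init_params(geom)
  X <- matrix(rnorm(4 * 9^3), nrow = 4)
  Y <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  wd <- 5e-4
  loss_fn <- function(p) {
    fw <- fishmap:::stain_forward(p, geom, X)
    pr <- fishmap:::softmax_rows(fw$logits)
    -mean(log(rowSums(pr * Y))) +
      wd / 2 * (sum(p$W1^2) + sum(p$W2^2) + sum(p$W3^2))
  }
  fw <- fishmap:::stain_forward(params, geom, X, want_cache = TRUE)
  pr <- fishmap:::softmax_rows(fw$logits)
  gr <- fishmap:::stain_backward(params, geom, fw, (pr - Y) / 4, wd)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(params)) {
    for (k in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
      up <- params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(gr[[nm]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("classifier separates synthetic punctate from diffuse cubes", {
  clf <- trained_classifier()
  hist <- tidy(clf)
  expect_true(all(is.finite(hist$loss)))
  expect_equal(hist$accuracy[nrow(hist)], 1.0)
  test_set <- stain_split()$test
  pred <- classify_cubes(clf, test_set)
  acc <- mean(pred$.pred_class == test_set$label)
  expect_gte(acc, 0.95)
  # training is deterministic under a fixed seed
  tr <- stain_split()$train
  small <- tr[c(head(which(tr$label == "punctate"), 5),
                head(which(tr$label == "diffuse"), 5)), ]
  c1 <- train_stain_classifier(small, stain_train_config(epochs = 2, seed = 7))
  c2 <- train_stain_classifier(small, stain_train_config(epochs = 2, seed = 7))
  expect_identical(c1$params, c2$params)
})

test_that("label-shuffled training carries no held-out signal", {
  sp <- stain_split()
  shuffled <- sp$train
  set.seed(13)
  shuffled$label <- sample(shuffled$label)
  clf <- train_stain_classifier(shuffled, stain_train_config(epochs = 10,
                                                             seed = 1))
  pred <- classify_cubes(clf, sp$test)
  acc <- mean(pred$.pred_class == sp$test$label)
  # binomial null around 0.5 on 24 held-out cubes
  expect_lt(abs(acc - 0.5), 0.3)
})

test_that("classification scores are per-cube and batch-order invariant", {
  clf <- trained_classifier()
  test_set <- stain_split()$test
  dup <- test_set[c(1, 1, 2), ]
  pred <- classify_cubes(clf, dup)
  expect_equal(pred$.prob_diffuse[1], pred$.prob_diffuse[2])
  perm <- rev(seq_len(nrow(test_set)))
  p1 <- classify_cubes(clf, test_set)
  p2 <- classify_cubes(clf, test_set[perm, ])
  expect_equal(p2$.prob_diffuse, p1$.prob_diffuse[perm])
  bad <- tibble::tibble(cube = list(array(0, dim = c(5, 5, 5))))
  expect_error(classify_cubes(clf, bad), class = "fishmap_error_validation")
})
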
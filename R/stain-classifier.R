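#' Extract labeled cubes around cell centres
#'
#' Cuts an odd-sided cube (default 11x11x11 voxels) centred on each cell
#' from an intensity volume. Neighbourhoods that extend past the volume
#' boundary are zero-padded, so every cube has the exact requested extent.
#'
#' @param volume 3-D numeric array (z, y, x).
#' @param centers Data frame with 0-based voxel-index columns `z`, `y`,
#'   `x`; an optional `stain_class` column becomes the cube label.
#' @param size Cube side length in voxels; must be odd (default 11).
#' @return A `cube_set` tibble: `z`, `y`, `x`, `label` (`NA` if
#'   unlabeled), and a `cube` list-column of `size^3` arrays.
#' @export
extract_cubes <- function(volume, centers, size = 11) {
  if (size %% 2 != 1) abort("cube size must be odd", class = "fishmap_error_validation")
  centers <- as_tibble(centers)
  stopifnot(all(c("z", "y", "x") %in% names(centers)))
  dm <- dim(volume)
  h <- (size - 1) / 2
  pos <- cbind(centers$z, centers$y, centers$x)
  if (nrow(pos) > 0 &&
      (any(pos < 0) || any(pos[, 1] >= dm[1]) || any(pos[, 2] >= dm[2]) ||
       any(pos[, 3] >= dm[3]))) {
    abort("cube centre outside the volume", class = "fishmap_error_bounds")
  }
  cubes <- lapply(seq_len(nrow(centers)), function(i) {
    out <- array(0, dim = c(size, size, size))
    lo <- pos[i, ] - h; hi <- pos[i, ] + h
    src_lo <- pmax(lo, 0); src_hi <- pmin(hi, dm - 1)
    dst_lo <- src_lo - lo
    out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1] + 1),
        (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2] + 1),
        (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3] + 1)] <-
      volume[(src_lo[1] + 1):(src_hi[1] + 1),
             (src_lo[2] + 1):(src_hi[2] + 1),
             (src_lo[3] + 1):(src_hi[3] + 1)]
    out
  })
  tibble(z = centers$z, y = centers$y, x = centers$x,
         label = if ("stain_class" %in% names(centers)) centers$stain_class
                 else NA_character_,
         cube = cubes)
}

#' Stratified train/test split of labeled cubes
#'
#' Splits each class separately with `floor(train_fraction * n_class)`
#' cubes in the training set (the remainder is the test set), after a
#' seeded shuffle. Floor rounding on the training side keeps the training
#' multiples exact for the 7-fold augmentation bookkeeping.
#'
#' @param cubes A `cube_set` tibble with a non-`NA` `label` column.
#' @param train_fraction Fraction of each class for training, in (0, 1).
#' @param seed RNG seed for the shuffle.
#' @return A list with tibbles `train` and `test` (disjoint, union =
#'   input).
#' @export
split_cubes <- function(cubes, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)", class = "fishmap_error_validation")
  }
  cubes <- as_tibble(cubes)
  if (nrow(cubes) == 0 || anyNA(cubes$label)) {
    abort("cubes must be non-empty and labeled", class = "fishmap_error_validation")
  }
  classes <- sort(unique(cubes$label))
  counts <- table(cubes$label)
  if (any(counts < 2)) abort("every class needs at least 2 cubes",
                             class = "fishmap_error_validation")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in classes) {
    idx <- which(cubes$label == cl)
    idx <- sample(idx)
    n_train <- floor(train_fraction * length(idx))
    train_idx <- c(train_idx, idx[seq_len(n_train)])
  }
  list(train = cubes[sort(train_idx), , drop = FALSE],
       test = cubes[setdiff(seq_len(nrow(cubes)), train_idx), , drop = FALSE])
}

# the six non-identity augmentation transforms (z, y, x cube arrays);
# "horizontal" = x axis, rotations act in the xy plane
aug_hflip <- function(a) a[, , dim(a)[3]:1, drop = FALSE]
aug_vflip <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
aug_rot_p90 <- function(a) aperm(a, c(1, 3, 2))[, dim(a)[3]:1, , drop = FALSE]
aug_rot_m90 <- function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1, drop = FALSE]
aug_shift <- function(a, px) {
  out <- array(0, dim = dim(a))
  nx <- dim(a)[3]
  if (px >= 0) out[, , (1 + px):nx] <- a[, , 1:(nx - px)]
  else out[, , 1:(nx + px)] <- a[, , (1 - px):nx]
  out
}

#' 7-fold augmentation of a training set
#'
#' Expands each training cube into exactly seven examples: the identity
#' plus horizontal flip, vertical flip, +/-90 degree in-plane rotations,
#' and +/-2-voxel horizontal translations (vacated planes zero-filled).
#' Labels are preserved. Test data are never augmented.
#'
#' @param train A `cube_set` tibble.
#' @param shift_px Magnitude of the horizontal translations (default 2).
#' @return A `cube_set` tibble with `7 * nrow(train)` rows and a
#'   `transform` column.
#' @export
augment_cubes <- function(train, shift_px = 2L) {
  train <- as_tibble(train)
  transforms <- list(
    identity = function(a) a,
    hflip = aug_hflip,
    vflip = aug_vflip,
    rot_p90 = aug_rot_p90,
    rot_m90 = aug_rot_m90,
    shift_pos = function(a) aug_shift(a, shift_px),
    shift_neg = function(a) aug_shift(a, -shift_px)
  )
  purrr::map_dfr(names(transforms), function(tn) {
    out <- train
    out$cube <- lapply(train$cube, transforms[[tn]])
    out$transform <- tn
    out
  })
}

#' Architecture of the compact 3-D convolutional classifier
#'
#' Two 3x3x3 valid convolutions with ReLU, a 2x2x2 max-pool between them,
#' and a dense 2-way softmax head: for an 11-cube, conv (11 -> 9), pool
#' (9 -> 4), conv (4 -> 2), flatten, dense. The layer table lives in this
#' one object so the architecture can be swapped without touching the
#' training loop.
#'
#' @param n_filters1,n_filters2 Filters in the two convolution layers.
#' @param kernel Convolution kernel side (default 3).
#' @param pool Max-pool window/stride (default 2).
#' @return A `stain_model_config` list.
#' @export
stain_model_config <- function(n_filters1 = 8, n_filters2 = 16,
                               kernel = 3, pool = 2) {
  structure(list(n_filters1 = n_filters1, n_filters2 = n_filters2,
                 kernel = kernel, pool = pool),
            class = "stain_model_config")
}

#' Training hyperparameters for the stain classifier
#'
#' Defaults follow standard practice for a small 3-D conv net on
#' augmented cube data: batch size 32, weight decay 5e-4, learning rate
#' 1e-4 (Adam), 500 epochs.
#'
#' @param batch_size,weight_decay,learning_rate,epochs Positive scalars.
#' @param seed RNG seed governing init and batch shuffling.
#' @return A `stain_train_config` list.
#' @export
stain_train_config <- function(batch_size = 32, weight_decay = 5e-4,
                               learning_rate = 1e-4, epochs = 500,
                               seed = 1L) {
  vals <- c(batch_size, weight_decay, learning_rate, epochs)
  if (any(vals <= 0)) abort("all training hyperparameters must be positive",
                            class = "fishmap_error_validation")
  structure(list(batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "stain_train_config")
}

# ---- im2col plumbing -------------------------------------------------------

# linear indices (first dim fastest) into a d^3 grid for every valid
# kernel placement: rows = output positions, cols = kernel offsets
conv_index <- function(d, k) {
  o <- d - k + 1
  outs <- as.matrix(expand.grid(z = 0:(o - 1), y = 0:(o - 1), x = 0:(o - 1)))
  offs <- as.matrix(expand.grid(kz = 0:(k - 1), ky = 0:(k - 1), kx = 0:(k - 1)))
  idx <- matrix(0L, nrow(outs), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    p <- sweep(outs, 2, offs[j, ], `+`)
    idx[, j] <- 1L + p[, 1] + d * p[, 2] + d * d * p[, 3]
  }
  idx
}

# pooling groups: rows = pooled positions in an o^3 grid, cols = the
# pool^3 source positions (floor division; trailing remainder dropped)
pool_index <- function(d, pool) {
  o <- d %/% pool
  outs <- as.matrix(expand.grid(z = 0:(o - 1), y = 0:(o - 1), x = 0:(o - 1)))
  offs <- as.matrix(expand.grid(kz = 0:(pool - 1), ky = 0:(pool - 1),
                                kx = 0:(pool - 1)))
  idx <- matrix(0L, nrow(outs), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    p <- sweep(outs * pool, 2, offs[j, ], `+`)
    idx[, j] <- 1L + p[, 1] + d * p[, 2] + d * d * p[, 3]
  }
  idx
}

cube_matrix <- function(cubes, size) {
  X <- t(vapply(cubes, function(a) {
    if (!identical(dim(a), rep(as.integer(size), 3L))) {
      abort(sprintf("cube is not %dx%dx%d", size, size, size),
            class = "fishmap_error_validation")
    }
    as.vector(a)
  }, numeric(size^3)))
  matrix(X, nrow = length(cubes))
}

stain_forward <- function(params, geom, X, want_cache = FALSE) {
  B <- nrow(X)
  M1 <- matrix(array(X[, as.vector(geom$I1), drop = FALSE],
                     c(B, geom$n1, geom$k3)), B * geom$n1, geom$k3)
  Z1 <- sweep(M1 %*% params$W1, 2, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  A1arr <- array(A1, c(B, geom$n1, geom$F1))

  np <- nrow(geom$P); nj <- ncol(geom$P)
  Asub <- array(A1arr[, as.vector(geom$P), , drop = FALSE],
                c(B, np, nj, geom$F1))
  pooled <- Asub[, , 1, , drop = FALSE]
  amax <- array(1L, dim = dim(pooled))
  for (j in 2:nj) {
    cand <- Asub[, , j, , drop = FALSE]
    better <- cand > pooled
    pooled[better] <- cand[better]
    amax[better] <- j
  }
  pooled <- array(pooled, c(B, np, geom$F1))
  amax <- array(amax, c(B, np, geom$F1))

  M2 <- matrix(array(pooled[, as.vector(geom$I2), , drop = FALSE],
                     c(B, geom$n2, geom$k3, geom$F1)),
               B * geom$n2, geom$k3 * geom$F1)
  Z2 <- sweep(M2 %*% params$W2, 2, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  Fmat <- matrix(array(A2, c(B, geom$n2, geom$F2)), B, geom$n2 * geom$F2)
  logits <- sweep(Fmat %*% params$W3, 2, params$b3, `+`)

  if (!want_cache) return(list(logits = logits))
  list(logits = logits, M1 = M1, Z1 = Z1, amax = amax, M2 = M2, Z2 = Z2,
       Fmat = Fmat, B = B)
}

stain_backward <- function(params, geom, cache, dlogits, wd) {
  B <- cache$B
  gr <- list()
  gr$W3 <- crossprod(cache$Fmat, dlogits) + wd * params$W3
  gr$b3 <- colSums(dlogits)
  dF <- dlogits %*% t(params$W3)
  dA2 <- matrix(array(dF, c(B, geom$n2, geom$F2)), B * geom$n2, geom$F2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  gr$W2 <- crossprod(cache$M2, dZ2) + wd * params$W2
  gr$b2 <- colSums(dZ2)

  dM2 <- dZ2 %*% t(params$W2)
  dM2arr <- array(dM2, c(B, geom$n2, geom$k3, geom$F1))
  np <- nrow(geom$P)
  dpooled <- array(0, c(B, np, geom$F1))
  for (k in seq_len(geom$k3)) {
    tgt <- geom$I2[, k]
    dpooled[, tgt, ] <- dpooled[, tgt, ] + dM2arr[, , k, ]
  }

  dA1arr <- array(0, c(B, geom$n1, geom$F1))
  for (j in seq_len(ncol(geom$P))) {
    mask <- cache$amax == j
    contrib <- dpooled * mask
    tgt <- geom$P[, j]
    dA1arr[, tgt, ] <- dA1arr[, tgt, ] + contrib
  }
  dZ1 <- matrix(dA1arr, B * geom$n1, geom$F1) * (cache$Z1 > 0)
  gr$W1 <- crossprod(cache$M1, dZ1) + wd * params$W1
  gr$b1 <- colSums(dZ1)
  gr
}

stain_geometry <- function(size, model) {
  k <- model$kernel
  o1 <- size - k + 1
  p1 <- o1 %/% model$pool
  o2 <- p1 - k + 1
  if (o2 < 1) abort("cube too small for this architecture",
                    class = "fishmap_error_validation")
  list(size = size, k3 = k^3, F1 = model$n_filters1, F2 = model$n_filters2,
       n1 = o1^3, n2 = o2^3,
       I1 = conv_index(size, k), P = pool_index(o1, model$pool),
       I2 = conv_index(p1, k))
}

stain_init_params <- function(geom) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = he(geom$k3, geom$F1), b1 = rep(0, geom$F1),
       W2 = he(geom$k3 * geom$F1, geom$F2), b2 = rep(0, geom$F2),
       W3 = he(geom$n2 * geom$F2, 2), b3 = rep(0, 2))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the punctate/diffuse stain classifier
#'
#' Trains the compact 3-D convolutional network of [stain_model_config()]
#' with mini-batch Adam under the hyperparameters of
#' [stain_train_config()]. Training is deterministic for a fixed seed.
#' Errors with diagnostics if the loss goes non-finite.
#'
#' @param train A labeled `cube_set` tibble (typically the augmented
#'   training set from [augment_cubes()]); both classes must be present.
#' @param config A [stain_train_config()].
#' @param model A [stain_model_config()].
#' @return A `stain_classifier` object holding the fitted weights, the
#'   input normalisation, the class levels, and a per-epoch training
#'   history (see `tidy()`/`glance()` methods).
#' @export
train_stain_classifier <- function(train, config = stain_train_config(),
                                   model = stain_model_config()) {
  train <- as_tibble(train)
  classes <- sort(unique(train$label))
  if (length(classes) != 2) abort("need exactly two classes present",
                                  class = "fishmap_error_validation")
  size <- dim(train$cube[[1]])[1]
  geom <- stain_geometry(size, model)

  X <- cube_matrix(train$cube, size)
  mu <- mean(X); sdv <- sd(X)
  if (sdv == 0) sdv <- 1
  X <- (X - mu) / sdv
  yi <- match(train$label, classes)
  Y <- cbind(yi == 1, yi == 2) * 1

  set.seed(config$seed)
  params <- stain_init_params(geom)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(X)
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0); correct <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      fw <- stain_forward(params, geom, X[idx, , drop = FALSE],
                          want_cache = TRUE)
      pr <- softmax_rows(fw$logits)
      yb <- Y[idx, , drop = FALSE]
      loss <- -mean(log(pmax(rowSums(pr * yb), 1e-12)))
      if (!is.finite(loss)) {
        abort(sprintf("training diverged at epoch %d (loss %s)", epoch, loss),
              class = "fishmap_error_divergence")
      }
      losses <- c(losses, loss)
      correct <- correct + sum(max.col(pr) == max.col(yb))
      dlogits <- (pr - yb) / length(idx)
      gr <- stain_backward(params, geom, fw, dlogits, config$weight_decay)
      step <- step + 1L
      for (nm in names(params)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gr[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gr[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
                               accuracy = correct / n)
  }

  structure(list(params = params, geom = geom, model = model,
                 config = config, classes = classes,
                 normalization = c(mean = mu, sd = sdv),
                 history = dplyr::bind_rows(history)),
            class = "stain_classifier")
}

#' @export
print.stain_classifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<stain_classifier> classes: %s; %d epochs, final loss %.4f, train accuracy %.3f\n",
    paste(x$classes, collapse = "/"), nrow(x$history), h$loss, h$accuracy))
  invisible(x)
}

#' @rdname train_stain_classifier
#' @param x A `stain_classifier`.
#' @param ... Unused.
#' @exportS3Method
tidy.stain_classifier <- function(x, ...) x$history

#' @rdname train_stain_classifier
#' @exportS3Method
glance.stain_classifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble(epochs = nrow(x$history), final_loss = h$loss,
         train_accuracy = h$accuracy,
         n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' Classify stain cubes
#'
#' Applies a fitted classifier to a set of cubes. Scores are per-cube and
#' independent of batch composition or order.
#'
#' @param classifier A fitted `stain_classifier`.
#' @param cubes A `cube_set` tibble (labels optional and ignored).
#' @param batch_size Forward-pass batch size.
#' @return The input tibble (minus the `cube` column) with `.pred_class`
#'   and one probability column per class (`.prob_<class>`).
#' @export
classify_cubes <- function(classifier, cubes, batch_size = 256L) {
  stopifnot(inherits(classifier, "stain_classifier"))
  cubes <- as_tibble(cubes)
  X <- cube_matrix(cubes$cube, classifier$geom$size)
  X <- (X - classifier$normalization[["mean"]]) / classifier$normalization[["sd"]]
  n <- nrow(X)
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- stain_forward(classifier$params, classifier$geom,
                        X[idx, , drop = FALSE])
    probs[idx, ] <- softmax_rows(fw$logits)
  }
  out <- cubes[, setdiff(names(cubes), "cube"), drop = FALSE]
  out$.pred_class <- classifier$classes[max.col(probs)]
  out[[paste0(".prob_", classifier$classes[1])]] <- probs[, 1]
  out[[paste0(".prob_", classifier$classes[2])]] <- probs[, 2]
  out
}
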
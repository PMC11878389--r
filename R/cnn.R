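#' @useDynLib topotype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Specification of the small convolutional classifier
#'
#' The network is one or more pairs of convolution and 2x2 max-pooling
#' layers followed by a dense ReLU layer and a 4-way softmax. The default —
#' two pairs (5x5 with 8 filters, then 3x3 with 16 filters) on a 32x32
#' two-plane input (filled contour mask + hue), with 64 dense units — is
#' the smallest configuration that separates the four synthetic pattern
#' classes quickly on a single CPU.
#'
#' @param input_size Input side, pixels.
#' @param channels Input planes (1 = contour mask only, 2 = mask + hue).
#' @param blocks List of `c(kernel, filters)` pairs; each is followed by a
#'   2x2 max-pool.
#' @param dense_units Units in the dense layer.
#' @param classes Output classes.
#' @return A `cnn_spec` list, validated.
#' @export
cnn_spec <- function(input_size = 32, channels = 2,
                     blocks = list(c(5, 8), c(3, 16)),
                     dense_units = 64, classes = 4) {
  if (length(blocks) < 1) {
    abort("at least one convolution/max-pool pair is required",
          class = "topotype_config_error")
  }
  s <- input_size
  for (blk in blocks) {
    s <- s - blk[1] + 1
    if (s < 2 || s %% 2 != 0) {
      abort(sprintf(
        "invalid spec: conv output side %d before pooling (must be even, >= 2)",
        s), class = "topotype_config_error")
    }
    s <- s / 2
  }
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 blocks = purrr::map(blocks, as.integer),
                 dense_units = as.integer(dense_units),
                 classes = as.integer(classes),
                 flat_size = as.integer(s * s * blocks[[length(blocks)]][2])),
            class = "cnn_spec")
}

#' Initialise a model from a spec
#'
#' He-scaled Gaussian weights, zero biases; fully determined by `seed`.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed.
#' @return A `cnn_model`.
#' @export
build_model <- function(spec, seed = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  layers <- list()
  c_in <- spec$channels
  for (i in seq_along(spec$blocks)) {
    k <- spec$blocks[[i]][1]; f <- spec$blocks[[i]][2]
    fan_in <- c_in * k * k
    set.seed(split_seed(seed, "conv", i))
    layers[[i]] <- list(
      W = matrix(rnorm(f * fan_in, 0, sqrt(2 / fan_in)), f, fan_in),
      b = numeric(f), k = k, c_in = c_in, f = f
    )
    c_in <- f
  }
  set.seed(split_seed(seed, "dense"))
  W1 <- matrix(rnorm(spec$dense_units * spec$flat_size, 0,
                     sqrt(2 / spec$flat_size)),
               spec$dense_units, spec$flat_size)
  set.seed(split_seed(seed, "out"))
  W2 <- matrix(rnorm(spec$classes * spec$dense_units, 0,
                     sqrt(2 / spec$dense_units)),
               spec$classes, spec$dense_units)
  structure(list(spec = spec, conv = layers,
                 W1 = W1, b1 = numeric(spec$dense_units),
                 W2 = W2, b2 = numeric(spec$classes),
                 seed = as.integer(seed), trained_epochs = 0L),
            class = "cnn_model")
}

# forward pass; x is an array (channels, h, w, B). Returns softmax
# probabilities (classes x B) and, if keep_cache, the intermediates needed
# for backprop.
cnn_forward <- function(model, x, keep_cache = FALSE) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1); d <- dim(x) }
  if (d[1] != spec$channels || d[2] != spec$input_size ||
      d[3] != spec$input_size) {
    abort("input shape does not match the model spec",
          class = "topotype_input_error")
  }
  B <- d[4]
  cache <- list(B = B)
  h <- w <- spec$input_size
  cur <- x
  for (i in seq_along(model$conv)) {
    ly <- model$conv[[i]]
    cols <- im2col_cf(as.numeric(cur), ly$c_in, h, w, B, ly$k)
    pre <- ly$W %*% cols + ly$b
    act <- pre * (pre > 0)
    oh <- h - ly$k + 1
    pooled <- maxpool_cf(as.numeric(act), ly$f, oh, oh, B)
    if (keep_cache) {
      cache[[paste0("cols", i)]] <- cols
      cache[[paste0("relu", i)]] <- pre > 0
      cache[[paste0("amax", i)]] <- pooled$argmax
      cache[[paste0("dims", i)]] <- c(ly$c_in, h, w, oh)
    }
    h <- w <- oh / 2L
    cur <- array(pooled$out, dim = c(ly$f, h, w, B))
  }
  Z <- matrix(as.numeric(cur), spec$flat_size, B)
  pre1 <- model$W1 %*% Z + model$b1
  A1 <- pre1 * (pre1 > 0)
  logits <- model$W2 %*% A1 + model$b2
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  if (keep_cache) {
    cache$Z <- Z; cache$relu_dense <- pre1 > 0; cache$A1 <- A1
  }
  list(probs = probs, cache = cache)
}

# one SGD step on a minibatch; returns updated model, mean loss and the
# pre-update predictions
cnn_step <- function(model, x, y, lr) {
  fw <- cnn_forward(model, x, keep_cache = TRUE)
  probs <- fw$probs; cache <- fw$cache
  B <- cache$B
  loss <- -mean(log(pmax(probs[cbind(y, seq_len(B))], 1e-12)))

  dlogits <- probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B

  dW2 <- dlogits %*% t(cache$A1)
  db2 <- rowSums(dlogits)
  dA1 <- t(model$W2) %*% dlogits
  dA1 <- dA1 * cache$relu_dense
  dW1 <- dA1 %*% t(cache$Z)
  db1 <- rowSums(dA1)
  dZ <- t(model$W1) %*% dA1

  spec <- model$spec
  nblk <- length(model$conv)
  # reshape dZ back to the last pooled activation
  dcur <- as.numeric(dZ)
  grads <- vector("list", nblk)
  for (i in rev(seq_len(nblk))) {
    ly <- model$conv[[i]]
    dm <- cache[[paste0("dims", i)]]
    oh <- dm[4]
    dact <- maxpool_bwd_cf(dcur, cache[[paste0("amax", i)]],
                           as.integer(ly$f * oh * oh * B))
    dpre <- matrix(dact, ly$f, oh * oh * B) * cache[[paste0("relu", i)]]
    cols <- cache[[paste0("cols", i)]]
    grads[[i]] <- list(dW = dpre %*% t(cols), db = rowSums(dpre))
    if (i > 1) {
      dcols <- t(ly$W) %*% dpre
      dcur <- col2im_cf(dcols, dm[1], dm[2], dm[3], B, ly$k)
    }
  }
  for (i in seq_len(nblk)) {
    model$conv[[i]]$W <- model$conv[[i]]$W - lr * grads[[i]]$dW
    model$conv[[i]]$b <- model$conv[[i]]$b - lr * grads[[i]]$db
  }
  model$W1 <- model$W1 - lr * dW1
  model$b1 <- model$b1 - lr * db1
  model$W2 <- model$W2 - lr * dW2
  model$b2 <- model$b2 - lr * db2
  list(model = model, loss = loss,
       pred = max.col(t(probs), ties.method = "first"))
}

#' Training configuration
#'
#' @param epochs Training epochs ("seasons"); the per-epoch held-out
#'   accuracy curve has this length.
#' @param batch_size Minibatch size.
#' @param learning_rate SGD learning rate.
#' @param seed Seed fixing shuffling, augmentation and initialisation.
#' @param augment Apply small random rotations (within `rot_max` degrees)
#'   to training inputs each epoch. Vertical flips are never used: the
#'   superior/inferior distinction is diagnostic.
#' @param rot_max Maximum augmentation rotation, degrees.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 32, learning_rate = 0.01,
                         seed = 0, augment = TRUE, rot_max = 10) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = isTRUE(augment), rot_max = rot_max),
            class = "train_config")
}

# nearest-neighbour rotation index maps for integer angles; index 0 means
# "outside the frame" (filled with 0)
rotation_maps <- function(n, rot_max) {
  angles <- seq(-round(rot_max), round(rot_max))
  ctr <- (n + 1) / 2
  gx <- rep(seq_len(n), each = n) - ctr   # col offsets
  gy <- rep(seq_len(n), times = n) - ctr  # row offsets
  maps <- purrr::map(angles, function(a) {
    th <- deg2rad(a)
    sx <- round(cos(th) * gx - sin(th) * gy + ctr)
    sy <- round(sin(th) * gx + cos(th) * gy + ctr)
    ok <- sx >= 1 & sx <= n & sy >= 1 & sy <= n
    idx <- ifelse(ok, (sx - 1) * n + sy, 0L)
    as.integer(idx)
  })
  names(maps) <- as.character(angles)
  maps
}

apply_rotation <- function(xi, map) {
  # xi: (channels, h, w) slice flattened; map indexes pixels of an h x w
  # plane
  d <- dim(xi)
  out <- xi
  for (ch in seq_len(d[1])) {
    plane <- xi[ch, , ]
    rot <- numeric(length(map))
    ok <- map > 0
    rot[ok] <- plane[map[ok]]
    out[ch, , ] <- matrix(rot, d[2], d[3])
  }
  out
}

#' Train the classifier and record the per-epoch accuracy curve
#'
#' Minibatch SGD on the cross-entropy loss. After every epoch the held-out
#' test accuracy is evaluated; the returned curve has one row per epoch
#' with the training accuracy (measured on the fly, before each update) and
#' test accuracy, both in percent. All stochastic choices (shuffling,
#' augmentation) derive from `cfg$seed`, so a fixed seed reproduces the
#' curve exactly on one thread.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param train_set,test_set Datasets from [build_dataset()] (lists with
#'   `x`: array `(channels, n, n, N)` and `y`: integer labels 1..4).
#' @param cfg A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return A list: `model` (trained), `curve` (tibble `epoch`,
#'   `train_acc`, `test_acc`, class `epoch_curve`).
#' @export
train_cnn <- function(model, train_set, test_set, cfg = train_config(),
                      quiet = TRUE) {
  y <- as.integer(train_set$y)
  if (length(unique(y)) < model$spec$classes) {
    abort("every class must be present in the training set",
          class = "topotype_config_error")
  }
  N <- length(y)
  n <- model$spec$input_size
  maps <- if (cfg$augment) rotation_maps(n, cfg$rot_max) else NULL
  curve <- matrix(NA_real_, cfg$epochs, 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (ep in seq_len(cfg$epochs)) {
    set.seed(split_seed(cfg$seed, "epoch", ep))
    ord <- sample.int(N)
    correct <- 0
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, N)]
      xb <- train_set$x[, , , idx, drop = FALSE]
      if (cfg$augment) {
        a <- sample(names(maps), length(idx), replace = TRUE)
        for (j in seq_along(idx)) {
          if (a[j] != "0") xb[, , , j] <- apply_rotation(xb[, , , j], maps[[a[j]]])
        }
      }
      st <- cnn_step(model, xb, y[idx], cfg$learning_rate)
      model <- st$model
      correct <- correct + sum(st$pred == y[idx])
    }
    test_acc <- accuracy(model, test_set)
    curve[ep, ] <- c(100 * correct / N, test_acc)
    if (!quiet) {
      message(sprintf("epoch %3d  train %5.1f%%  test %5.1f%%",
                      ep, curve[ep, 1], curve[ep, 2]))
    }
  }
  model$trained_epochs <- model$trained_epochs + cfg$epochs
  curve <- tibble(epoch = seq_len(cfg$epochs),
                  train_acc = curve[, 1], test_acc = curve[, 2])
  class(curve) <- c("epoch_curve", class(curve))
  list(model = model, curve = curve)
}

#' Predict class labels for a batch of inputs
#'
#' The label is the arg-max of the softmax scores; exact ties resolve to
#' the lowest-index (least severe) class.
#'
#' @param model A `cnn_model`.
#' @param x Input array `(channels, n, n, N)` (or a single
#'   `(channels, n, n)` slice), or a dataset list with an `x` element.
#' @return A tibble with `label` and one score column per class.
#' @export
predict_cnn <- function(model, x) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  probs <- cnn_forward(model, x)$probs
  lab <- CLASS_LABELS[max.col(t(probs), ties.method = "first")]
  out <- tibble(label = lab)
  for (i in seq_len(nrow(probs))) out[[CLASS_LABELS[i]]] <- probs[i, ]
  out
}

accuracy <- function(model, dataset, chunk = 256) {
  N <- dim(dataset$x)[4]
  pred <- integer(N)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    probs <- cnn_forward(model, dataset$x[, , , idx, drop = FALSE])$probs
    pred[idx] <- max.col(t(probs), ties.method = "first")
  }
  100 * mean(pred == as.integer(dataset$y))
}

#' Serialize a model to a single JSON archive
#'
#' Stores the spec and all weight arrays as text; [read_model()] restores
#' an identical model.
#'
#' @param model A `cnn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    conv = purrr::map(model$conv, function(ly) {
      list(W = as.numeric(ly$W), b = ly$b, k = ly$k, c_in = ly$c_in, f = ly$f)
    }),
    W1 = as.numeric(model$W1), b1 = model$b1,
    W2 = as.numeric(model$W2), b2 = model$b2,
    seed = model$seed, trained_epochs = model$trained_epochs
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(cnn_spec, c(
    list(input_size = p$spec$input_size, channels = p$spec$channels,
         dense_units = p$spec$dense_units, classes = p$spec$classes),
    list(blocks = purrr::map(seq_len(nrow_or_len(p$spec$blocks)), function(i) {
      if (is.matrix(p$spec$blocks)) p$spec$blocks[i, ] else p$spec$blocks[[i]]
    }))
  ))
  conv <- purrr::map(seq_len(nrow_or_len(p$conv)), function(i) {
    ly <- if (is.data.frame(p$conv)) lapply(p$conv, `[[`, i) else p$conv[[i]]
    list(W = matrix(as.numeric(unlist(ly$W)), ly$f, ly$c_in * ly$k * ly$k),
         b = as.numeric(unlist(ly$b)), k = ly$k, c_in = ly$c_in, f = ly$f)
  })
  structure(list(spec = spec, conv = conv,
                 W1 = matrix(p$W1, spec$dense_units, spec$flat_size),
                 b1 = as.numeric(p$b1),
                 W2 = matrix(p$W2, spec$classes, spec$dense_units),
                 b2 = as.numeric(p$b2),
                 seed = as.integer(p$seed),
                 trained_epochs = as.integer(p$trained_epochs)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  blocks <- paste(vapply(s$blocks, function(b)
    sprintf("%dx%dx%d+pool", b[1], b[1], b[2]), character(1)),
    collapse = ", ")
  cat(sprintf("CNN %dx%dx%d -> [%s] -> dense %d -> %d classes (%s)\n",
              s$input_size, s$input_size, s$channels, blocks,
              s$dense_units, s$classes,
              if (x$trained_epochs > 0)
                sprintf("trained %d epochs", x$trained_epochs)
              else "untrained"))
  invisible(x)
}

#' Tidy a model into one row per layer
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @return Tibble with `layer`, `kind`, `shape`, `n_params`.
#' @export
tidy.cnn_model <- function(x, ...) {
  rows <- purrr::imap(x$conv, function(ly, i) {
    tibble(layer = paste0("conv", i), kind = "conv+pool",
           shape = sprintf("%dx%dx%d", ly$k, ly$k, ly$f),
           n_params = length(ly$W) + length(ly$b))
  })
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble(layer = "dense", kind = "dense",
           shape = as.character(x$spec$dense_units),
           n_params = length(x$W1) + length(x$b1)),
    tibble(layer = "output", kind = "softmax",
           shape = as.character(x$spec$classes),
           n_params = length(x$W2) + length(x$b2))
  )
}

#' One-row model summary
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @export
glance.cnn_model <- function(x, ...) {
  tibble(input_size = x$spec$input_size, channels = x$spec$channels,
         blocks = length(x$conv),
         n_params = sum(tidy(x)$n_params),
         trained_epochs = x$trained_epochs, seed = x$seed)
}

#' Plot a training curve
#'
#' @param object An `epoch_curve` tibble from [train_cnn()].
#' @param ... Unused.
#' @return A ggplot object: per-epoch train and held-out accuracy.
#' @export
autoplot.epoch_curve <- function(object, ...) {
  df <- tibble(
    epoch = rep(object$epoch, 2),
    accuracy = c(object$train_acc, object$test_acc),
    set = rep(c("train", "test"), each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training epoch", y = "accuracy (%)", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
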
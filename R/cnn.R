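#' Layer specification of the spectrogram-regression CNN
#'
#' A fixed 18-layer architecture for regressing compression depth from a
#' single-channel spectrogram image: image input, then
#' conv(3x3, 8) - batchnorm - ReLU - avgpool(2x2, stride 2),
#' conv(3x3, 32) - batchnorm - ReLU - avgpool(2x2, stride 2),
#' conv(3x3, 32) - batchnorm - ReLU, conv(3x3, 32) - batchnorm - ReLU,
#' a 32-unit fully connected layer, a 1-unit fully connected layer and a
#' mean-squared-error regression output. Convolutions use same-padding.
#' At 64 x 64 input this network has 283,329 trainable parameters.
#'
#' @param input_size Integer `c(height, width)`; both must be divisible by 4
#'   (two stride-2 poolings).
#' @return Object of class `cnn_spec` (ordered list of layer descriptors).
#' @examples
#' sp <- cnn_spec()
#' length(sp$layers)  # 18
#' @export
cnn_spec <- function(input_size = c(64L, 64L)) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 4L != 0L))
    stop("input size must be divisible by 4 (two 2x2 stride-2 poolings)",
         call. = FALSE)
  layers <- list(
    list(type = "input", size = input_size, channels = 1L),
    list(type = "conv", kernel = 3L, filters = 8L),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "avgpool", size = 2L, stride = 2L),
    list(type = "conv", kernel = 3L, filters = 32L),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "avgpool", size = 2L, stride = 2L),
    list(type = "conv", kernel = 3L, filters = 32L),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "conv", kernel = 3L, filters = 32L),
    list(type = "batchnorm"),
    list(type = "relu"),
    list(type = "fc", units = 32L),
    list(type = "fc", units = 1L),
    list(type = "regression")
  )
  structure(list(layers = layers, input_size = input_size), class = "cnn_spec")
}

#' Build (initialize) the CNN
#'
#' Validates the layer ordering against the canonical architecture of
#' [cnn_spec()], allocates parameters with He-normal initialization and
#' reports the trainable parameter count.
#'
#' @param spec A `cnn_spec`.
#' @param seed Integer seed controlling the initial weights; identical seeds
#'   give identical initializations.
#' @return Object of class `cnn_model` with fields `spec`, `params`,
#'   `running` (batch-norm inference statistics) and `n_params`.
#' @examples
#' m <- build_cnn(cnn_spec(), seed = 1)
#' m$n_params  # 283329
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1L) {
  if (!inherits(spec, "cnn_spec")) stop("`spec` must be a cnn_spec", call. = FALSE)
  canon <- vapply(cnn_spec(spec$input_size)$layers, `[[`, "", "type")
  given <- vapply(spec$layers, `[[`, "", "type")
  if (!identical(canon, given))
    stop("non-conforming layer ordering; the architecture is fixed", call. = FALSE)

  h <- spec$input_size[1]; w <- spec$input_size[2]
  cin <- 1L
  params <- list()
  running <- list()
  with_seed(seed, {
    for (i in seq_along(spec$layers)) {
      ly <- spec$layers[[i]]
      id <- paste0("L", i)
      if (ly$type == "conv") {
        fan_in <- ly$kernel^2 * cin
        params[[id]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                     fan_in, ly$filters),
          b = numeric(ly$filters))
        cin <- ly$filters
      } else if (ly$type == "batchnorm") {
        params[[id]] <- list(gamma = rep(1, cin), beta = numeric(cin))
        running[[id]] <- list(mean = numeric(cin), var = rep(1, cin))
      } else if (ly$type == "avgpool") {
        h <- h %/% ly$stride; w <- w %/% ly$stride
      } else if (ly$type == "fc") {
        # fc after fc sees the previous unit count, otherwise the flattened map
        fan_in <- if (spec$layers[[i - 1L]]$type == "fc")
          spec$layers[[i - 1L]]$units else h * w * cin
        params[[id]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$units, 0, sqrt(2 / fan_in)),
                     fan_in, ly$units),
          b = numeric(ly$units))
        cin <- ly$units
      }
    }
  })
  n_par <- sum(vapply(params, function(p)
    sum(vapply(p, length, integer(1))), integer(1)))
  structure(list(spec = spec, params = params, running = running,
                 n_params = n_par, bn_eps = 1e-5),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model>  %d layers, %s trainable parameters, input %dx%d\n",
              length(x$spec$layers), format(x$n_params, big.mark = ","),
              x$spec$input_size[1], x$spec$input_size[2]))
  invisible(x)
}

# ---- geometry caches -------------------------------------------------------
# Feature maps are stored as (H*W*B) x C matrices, pixel index fastest,
# batch index next. Same-padding 3x3 neighbours and 2x2 pool members are
# precomputed per (H, W, B); out-of-image references point at a zero row.

.geom_cache <- new.env(parent = emptyenv())

conv_indices <- function(h, w, b) {
  key <- sprintf("conv|%d|%d|%d", h, w, b)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  n_pix <- h * w
  row_i <- rep(seq_len(h), w)
  col_i <- rep(seq_len(w), each = h)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  zero_row <- n_pix * b + 1L          # index of the appended zero row
  idx <- matrix(0L, n_pix * b, 9L)
  base <- rep((seq_len(b) - 1L) * n_pix, each = n_pix)
  for (k in 1:9) {
    rr <- row_i + offs$dr[k]
    cc <- col_i + offs$dc[k]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    pix <- ifelse(ok, (cc - 1L) * h + rr, NA_integer_)
    glob <- rep(pix, b) + base
    glob[is.na(glob)] <- zero_row
    idx[, k] <- glob
  }
  .geom_cache[[key]] <- idx
  idx
}

pool_indices <- function(h, w, b) {
  key <- sprintf("pool|%d|%d|%d", h, w, b)
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- h %/% 2L; wo <- w %/% 2L
  ro <- rep(seq_len(ho), wo)
  co <- rep(seq_len(wo), each = ho)
  idx <- matrix(0L, ho * wo, 4L)
  k <- 1L
  for (dc in 0:1) for (dr in 0:1) {
    rr <- 2L * ro - 1L + dr
    cc <- 2L * co - 1L + dc
    idx[, k] <- (cc - 1L) * h + rr
    k <- k + 1L
  }
  full <- matrix(0L, ho * wo * b, 4L)
  n_pix <- h * w
  for (k in 1:4)
    full[, k] <- rep(idx[, k], b) + rep((seq_len(b) - 1L) * n_pix, each = ho * wo)
  .geom_cache[[key]] <- full
  full
}

im2col <- function(M, idx) {
  cin <- ncol(M)
  Mz <- rbind(M, 0)
  P <- matrix(0, nrow(idx), 9L * cin)
  for (k in 1:9)
    P[, ((k - 1L) * cin + 1L):(k * cin)] <- Mz[idx[, k], , drop = FALSE]
  P
}

col2im <- function(dP, idx, n_rows, cin) {
  dM <- matrix(0, n_rows + 1L, cin)
  for (k in 1:9) {
    blk <- dP[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    tgt <- idx[, k]
    # for a fixed offset each target row appears at most once
    dM[tgt, ] <- dM[tgt, , drop = FALSE] + blk
  }
  dM[seq_len(n_rows), , drop = FALSE]
}

# ---- forward / backward ----------------------------------------------------

cnn_forward <- function(model, X, train = TRUE, batch_stats = NULL) {
  # X: (H*W*B) x 1 matrix of images, pixel-major; B inferred
  spec <- model$spec
  h <- spec$input_size[1]; w <- spec$input_size[2]
  b <- nrow(X) / (h * w)
  cache <- list()
  M <- X
  cin <- 1L
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    id <- paste0("L", i)
    if (ly$type == "conv") {
      idx <- conv_indices(h, w, b)
      P <- im2col(M, idx)
      cache[[id]] <- list(P = P, h = h, w = w, b = b, cin = cin)
      M <- P %*% model$params[[id]]$W +
        matrix(model$params[[id]]$b, nrow(P), ly$filters, byrow = TRUE)
      cin <- ly$filters
    } else if (ly$type == "batchnorm") {
      p <- model$params[[id]]
      if (train) {
        mu <- colMeans(M)
        va <- colMeans(M^2) - mu^2
      } else {
        mu <- model$running[[id]]$mean
        va <- model$running[[id]]$var
      }
      xhat <- sweep(sweep(M, 2, mu), 2, sqrt(va + model$bn_eps), "/")
      cache[[id]] <- list(xhat = xhat, var = va, mu = mu)
      M <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
    } else if (ly$type == "relu") {
      cache[[id]] <- list(mask = M > 0)
      M <- M * cache[[id]]$mask
    } else if (ly$type == "avgpool") {
      idx <- pool_indices(h, w, b)
      cache[[id]] <- list(h = h, w = w, b = b, cin = cin)
      Mp <- (M[idx[, 1], , drop = FALSE] + M[idx[, 2], , drop = FALSE] +
               M[idx[, 3], , drop = FALSE] + M[idx[, 4], , drop = FALSE]) / 4
      M <- Mp
      h <- h %/% 2L; w <- w %/% 2L
    } else if (ly$type == "fc") {
      if (spec$layers[[i - 1L]]$type != "fc") {
        # flatten (H*W*B) x C -> B x (H*W*C)
        cache[[id]] <- list(flatten = TRUE, h = h, w = w, b = b, cin = cin)
        M <- flatten_features(M, h * w, b, cin)
      } else cache[[id]] <- list(flatten = FALSE)
      cache[[id]]$X <- M
      M <- M %*% model$params[[id]]$W +
        matrix(model$params[[id]]$b, nrow(M), ly$units, byrow = TRUE)
    }
  }
  list(out = drop(M), cache = cache, batch = b)
}

flatten_features <- function(M, n_pix, b, cin) {
  # rows of sample s are (s-1)*n_pix + 1:n_pix; output row s = c(M[rows, ])
  out <- matrix(0, b, n_pix * cin)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * n_pix + 1L):(s * n_pix)
    out[s, ] <- as.numeric(M[rows, , drop = FALSE])
  }
  out
}

unflatten_features <- function(G, n_pix, b, cin) {
  out <- matrix(0, n_pix * b, cin)
  for (s in seq_len(b)) {
    rows <- ((s - 1L) * n_pix + 1L):(s * n_pix)
    out[rows, ] <- matrix(G[s, ], n_pix, cin)
  }
  out
}

cnn_backward <- function(model, fwd, y) {
  spec <- model$spec
  b <- fwd$batch
  grads <- list()
  dM <- matrix(2 * (fwd$out - y) / b, ncol = 1)   # d MSE / d output
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    id <- paste0("L", i)
    ch <- fwd$cache[[id]]
    if (ly$type == "fc") {
      p <- model$params[[id]]
      grads[[id]] <- list(W = crossprod(ch$X, dM), b = colSums(dM))
      dM <- dM %*% t(p$W)
      if (isTRUE(ch$flatten))
        dM <- unflatten_features(dM, ch$h * ch$w, ch$b, ch$cin)
    } else if (ly$type == "avgpool") {
      idx <- pool_indices(ch$h, ch$w, ch$b)
      up <- matrix(0, ch$h * ch$w * ch$b, ncol(dM))
      for (k in 1:4) up[idx[, k], ] <- up[idx[, k], , drop = FALSE] + dM / 4
      dM <- up
    } else if (ly$type == "relu") {
      dM <- dM * ch$mask
    } else if (ly$type == "batchnorm") {
      p <- model$params[[id]]
      n <- nrow(dM)
      dgamma <- colSums(dM * ch$xhat)
      dbeta <- colSums(dM)
      inv_sd <- 1 / sqrt(ch$var + model$bn_eps)
      dxhat <- sweep(dM, 2, p$gamma, "*")
      dM <- sweep(dxhat - matrix(dbeta_term <- colMeans(dxhat), n, ncol(dM), byrow = TRUE) -
                    ch$xhat * matrix(colMeans(dxhat * ch$xhat), n, ncol(dM), byrow = TRUE),
                  2, inv_sd, "*")
      grads[[id]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$type == "conv") {
      p <- model$params[[id]]
      grads[[id]] <- list(W = crossprod(ch$P, dM), b = colSums(dM))
      dP <- dM %*% t(p$W)
      idx <- conv_indices(ch$h, ch$w, ch$b)
      dM <- col2im(dP, idx, ch$h * ch$w * ch$b, ch$cin)
    }
  }
  grads
}

# Update running batch-norm statistics after a training forward pass.
update_running <- function(model, fwd, momentum = 0.1) {
  for (id in names(model$running)) {
    ch <- fwd$cache[[id]]
    model$running[[id]]$mean <- (1 - momentum) * model$running[[id]]$mean +
      momentum * ch$mu
    model$running[[id]]$var <- (1 - momentum) * model$running[[id]]$var +
      momentum * ch$var
  }
  model
}

stack_images <- function(images) {
  # list of HxW matrices -> (H*W*B) x 1 column, pixel-major
  matrix(unlist(lapply(images, as.numeric), use.names = FALSE), ncol = 1)
}

#' Predict depths for a list of spectrogram images
#'
#' @param object A trained `cnn_model`.
#' @param newdata List of `input_size` matrices in `[0, 1]` (see
#'   [tf_to_image()]).
#' @param ... Unused.
#' @return Numeric vector of predicted depths (cm). Batch-norm uses the
#'   running statistics accumulated during training.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  X <- stack_images(newdata)
  out <- cnn_forward(object, X, train = FALSE)$out
  if (!is.null(object$label_scale))
    out <- out * object$label_scale + object$label_center
  out
}

#' Train the CNN with SGD-momentum and early stopping
#'
#' Minimizes the mean-squared-error regression loss with stochastic
#' gradient descent with momentum. After every epoch the validation loss is
#' evaluated; training stops when it has not improved for `patience` epochs
#' (or at `max_epochs`), and the returned weights are those of the epoch
#' with the lowest validation loss.
#'
#' Labels are standardized internally (z-score of the training labels) and
#' predictions mapped back to cm: without this, the gradient of the wide
#' flattened fully-connected layer makes plain SGD unstable at any useful
#' learning rate. A global gradient-norm clip bounds individual steps.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param images List of input matrices; `labels` numeric depths (cm).
#' @param labels Reference depths, cm.
#' @param val_images,val_labels Held-out validation split (must be disjoint
#'   from the training data; the function cannot verify subject identity,
#'   see [loso_evaluate()] for subject-exclusive protocol).
#' @param learning_rate,momentum SGD hyper-parameters.
#' @param max_epochs,patience Early-stopping schedule.
#' @param batch_size Minibatch size.
#' @param clip_norm Global L2 gradient-norm threshold; gradients larger
#'   than this are rescaled.
#' @param seed Seed for shuffling; with a fixed seed training is
#'   deterministic.
#' @param verbose Print per-epoch losses.
#' @return The model at the best-validation epoch, with `history` (data
#'   frame `epoch`, `train_loss`, `val_loss`, both in standardized label
#'   units) and `best_epoch` attached.
#' @export
train_cnn <- function(model, images, labels, val_images, val_labels,
                      learning_rate = 1e-4, momentum = 0.9,
                      max_epochs = 100L, patience = 10L,
                      batch_size = 32L, clip_norm = 5,
                      seed = 1L, verbose = FALSE) {
  stopifnot(length(images) == length(labels), length(images) > 0,
            length(val_images) == length(val_labels), length(val_images) > 0)
  n <- length(images)
  Xval <- stack_images(val_images)

  y_center <- mean(labels)
  y_scale <- stats::sd(labels)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  model$label_center <- y_center
  model$label_scale <- y_scale
  labels_s <- (labels - y_center) / y_scale
  val_labels_s <- (val_labels - y_center) / y_scale

  vel <- lapply(model$params, function(p) lapply(p, function(q) q * 0))
  best <- list(loss = Inf, params = model$params, running = model$running,
               epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0L
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        take <- ord[b0:min(b0 + batch_size - 1L, n)]
        X <- stack_images(images[take])
        y <- labels_s[take]
        fwd <- cnn_forward(model, X, train = TRUE)
        if (!all(is.finite(fwd$out)))
          stop("non-finite network output during training (diverged); ",
               "lower the learning rate", call. = FALSE)
        model <- update_running(model, fwd)
        grads <- cnn_backward(model, fwd, y)
        gn <- sqrt(sum(vapply(grads, function(g)
          sum(vapply(g, function(q) sum(q^2), numeric(1))), numeric(1))))
        if (is.finite(gn) && gn > clip_norm)
          grads <- lapply(grads, function(g) lapply(g, `*`, clip_norm / gn))
        for (id in names(grads)) for (nm in names(grads[[id]])) {
          vel[[id]][[nm]] <- momentum * vel[[id]][[nm]] -
            learning_rate * grads[[id]][[nm]]
          model$params[[id]][[nm]] <- model$params[[id]][[nm]] + vel[[id]][[nm]]
        }
        tr_loss <- tr_loss + mean((fwd$out - y)^2)
        nb <- nb + 1L
      }
      val_pred <- cnn_forward(model, Xval, train = FALSE)$out
      val_loss <- mean((val_pred - val_labels_s)^2)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = tr_loss / nb,
                                           val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        tr_loss / nb, val_loss))
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, params = model$params,
                     running = model$running, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  model$params <- best$params
  model$running <- best$running
  model$history <- history
  model$best_epoch <- best$epoch
  model
}

#' Evaluate a trained CNN on held-out data
#'
#' @param model A trained `cnn_model`.
#' @param images,labels Held-out spectrogram images and reference depths
#'   (cm).
#' @return RMSE in cm.
#' @export
evaluate_cnn <- function(model, images, labels) {
  if (length(images) == 0) stop("empty test set", call. = FALSE)
  rmse(predict(model, images), labels)
}
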
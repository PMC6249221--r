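#' CNN family configuration
#'
#' The five selection parameters of the 1-D CNN family plus fixed
#' architectural constants. The network is `Ns` sections; section `s` holds
#' `Nd` blocks, a block being one convolution (kernel 101, stride 1, padding
#' 50, `10 * 2^(s-1)` filters) followed by ReLU; each section ends in a max
#' pooling layer (kernel 11, stride 2). Two fully connected layers follow:
#' the first with `fc_width` outputs (the deep feature vector), the last with
#' 2 outputs for the binary softmax.
#'
#' @param Ns number of sections (>= 1).
#' @param Nd blocks per section (>= 1); the network depth knob.
#' @param Lr learning rate of stochastic gradient descent, in (0, 1).
#' @param Mo momentum coefficient, in `[0, 1)`.
#' @param Re regularization strength, interpreted as the dropout probability
#'   on the first fully connected layer, in (0, 1).
#' @param input_len samples per channel (default 2000 = 8 s at 250 Hz).
#' @param n_channels input channels (default 3: pECG, SH, NSH).
#' @param fc_width width of the first fully connected layer (default 100).
#' @param epochs,batch_size training-schedule defaults used when
#'   [train_cnne()] is not given explicit values.
#' @return an object of class `cnn_config`.
#' @export
cnn_config <- function(Ns = 3, Nd = 1, Lr = 0.005, Mo = 0.9, Re = 0.15,
                       input_len = 2000, n_channels = 3, fc_width = 100,
                       epochs = 40, batch_size = 32) {
  stopifnot(Ns >= 1, Nd >= 1, Lr >= 0, Lr < 1, Mo >= 0, Mo < 1,
            Re > 0, Re < 1, input_len >= 1, n_channels >= 1, fc_width >= 1)
  cfg <- structure(list(Ns = as.integer(Ns), Nd = as.integer(Nd), Lr = Lr,
                        Mo = Mo, Re = Re, input_len = as.integer(input_len),
                        n_channels = as.integer(n_channels),
                        fc_width = as.integer(fc_width),
                        kernel = 101L, pad = 50L,
                        pool_kernel = 11L, pool_stride = 2L,
                        epochs = as.integer(epochs),
                        batch_size = as.integer(batch_size)),
                   class = "cnn_config")
  tr <- forward_shapes(cfg)
  if (any(tr$length < 1))
    stop("configuration error: temporal length collapses to zero")
  cfg
}

#' Per-layer temporal-length trace of a configuration
#'
#' Audits the shape arithmetic of the architecture: a convolution maps length
#' `L` to `floor((L + 2*50 - 101)/1) + 1` (length-preserving at the default
#' kernel/padding) and a pooling layer to `floor((L - 11)/2) + 1`. The trace
#' ends with the flattened width entering the first fully connected layer.
#'
#' @param config a [cnn_config()].
#' @return data frame with columns `layer`, `type`, `length`, `channels`;
#'   attribute `fc_input_width` is `length * channels` after the last pool.
#' @export
forward_shapes <- function(config) {
  L <- config$input_len
  ch <- config$n_channels
  rows <- list(data.frame(layer = "input", type = "input",
                          length = L, channels = ch))
  for (s in seq_len(config$Ns)) {
    nf <- as.integer(10 * 2^(s - 1))
    for (d in seq_len(config$Nd)) {
      L <- (L + 2L * config$pad - config$kernel) + 1L
      ch <- nf
      rows[[length(rows) + 1L]] <-
        data.frame(layer = sprintf("conv_s%d_d%d", s, d), type = "conv",
                   length = L, channels = ch)
    }
    L <- (L - config$pool_kernel) %/% config$pool_stride + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("pool_s%d", s), type = "maxpool",
                 length = L, channels = ch)
  }
  out <- do.call(rbind, rows)
  attr(out, "fc_input_width") <- out$length[nrow(out)] * out$channels[nrow(out)]
  out
}

he_init <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
}

#' Build a CNN of the parameterized family
#'
#' Instantiates the network defined by a [cnn_config()] with He-initialized
#' weights: `Ns` sections of `Nd` (conv + ReLU) blocks each ending in max
#' pooling, then flatten, first FC (`fc_width` outputs, ReLU, dropout `Re`),
#' last FC (2 outputs) and softmax. With `Ns = 3, Nd = 1` this is the
#' selected 11-layer extractor: filter counts 10/20/40 and a first FC fed by
#' 9680 inputs.
#'
#' @param config a [cnn_config()].
#' @param init_seed RNG seed for weight initialization (default 1).
#' @return an object of class `cnn_model`.
#' @export
build_cnne <- function(config, init_seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  with_seed(init_seed, {
    layers <- list()
    ch <- config$n_channels
    for (s in seq_len(config$Ns)) {
      nf <- as.integer(10 * 2^(s - 1))
      for (d in seq_len(config$Nd)) {
        layers[[length(layers) + 1L]] <-
          list(type = "conv", kernel = config$kernel, stride = 1L,
               pad = config$pad, n_filters = nf,
               W = he_init(nf, ch * config$kernel), b = numeric(nf))
        layers[[length(layers) + 1L]] <- list(type = "relu")
        ch <- nf
      }
      layers[[length(layers) + 1L]] <-
        list(type = "maxpool", kernel = config$pool_kernel,
             stride = config$pool_stride)
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    tr <- forward_shapes(config)
    flat <- attr(tr, "fc_input_width")
    layers[[length(layers) + 1L]] <-
      list(type = "fc", n_out = config$fc_width,
           W = he_init(config$fc_width, flat), b = numeric(config$fc_width))
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- list(type = "dropout", p = config$Re)
    layers[[length(layers) + 1L]] <-
      list(type = "fc", n_out = 2L, W = he_init(2L, config$fc_width),
           b = numeric(2L))
    layers[[length(layers) + 1L]] <- list(type = "softmax")
    structure(list(layers = layers, config = config, trained = FALSE,
                   train_log = data.frame(), train_records = character()),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cnn_model Ns=%d Nd=%d (Lr=%g Mo=%g Re=%g), input %d x %d%s>\n",
              cfg$Ns, cfg$Nd, cfg$Lr, cfg$Mo, cfg$Re, cfg$n_channels,
              cfg$input_len, if (x$trained) ", trained" else ""))
  for (l in x$layers) {
    cat(" ", switch(l$type,
      conv = sprintf("conv(kernel %d, %d filters, stride %d, pad %d)",
                     l$kernel, l$n_filters, l$stride, l$pad),
      maxpool = sprintf("maxpool(kernel %d, stride %d)", l$kernel, l$stride),
      fc = sprintf("fc(%d outputs)", l$n_out),
      dropout = sprintf("dropout(p = %g)", l$p),
      l$type), "\n")
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param model a [cnn_model()] (or a [cnn_config()], which is built first).
#' @return integer parameter count.
#' @export
cnn_n_params <- function(model) {
  if (inherits(model, "cnn_config")) model <- build_cnne(model)
  sum(vapply(model$layers, function(l)
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L, numeric(1)))
}

# stacks -> (channels x length x batch) array
stacks_to_array <- function(stacks) {
  B <- length(stacks)
  L <- length(stacks[[1]]$pecg)
  X <- array(0, dim = c(3L, L, B))
  for (i in seq_len(B)) X[, , i] <- as_channel_matrix(stacks[[i]])
  X
}

# forward pass; returns final activation and (optionally) per-layer cache.
# Dropout masks are drawn from the active RNG stream when train = TRUE.
cnn_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  A <- X
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (keep_cache) cache[[i]] <- list(input = A)
    A <- switch(l$type,
      input = A,
      conv = .conv1d_fw(A, l$W, l$b, l$kernel, l$pad),
      relu = {
        if (is.array(A) || is.matrix(A)) pmax(A, 0) else pmax(A, 0)
      },
      maxpool = {
        res <- .maxpool1d_fw(A, l$kernel, l$stride)
        if (keep_cache) cache[[i]]$idx <- res$idx
        res$Y
      },
      flatten = {
        d <- dim(A)
        matrix(A, d[1] * d[2], d[3])
      },
      fc = sweep(l$W %*% A, 1, l$b, `+`),
      dropout = {
        if (train) {
          mask <- matrix(stats::rbinom(length(A), 1L, 1 - l$p) / (1 - l$p),
                         nrow(A), ncol(A))
          if (keep_cache) cache[[i]]$mask <- mask
          A * mask
        } else A
      },
      softmax = {
        Z <- sweep(A, 2, apply(A, 2, max), `-`)
        E <- exp(Z)
        sweep(E, 2, colSums(E), `/`)
      },
      stop("unknown layer type: ", l$type))
  }
  list(out = A, cache = cache)
}

# backward pass from softmax + cross-entropy; Y is a 2 x B one-hot matrix.
# Returns per-layer gradients (NULL for parameterless layers).
cnn_backward <- function(model, fw, Y) {
  B <- ncol(Y)
  grads <- vector("list", length(model$layers))
  # softmax + CE combined: dZ at the last fc output
  dA <- (fw$out - Y) / B
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cc <- fw$cache[[i]]
    dA <- switch(l$type,
      softmax = dA,  # folded into the CE gradient above
      fc = {
        grads[[i]] <- list(dW = dA %*% t(cc$input), db = rowSums(dA))
        t(l$W) %*% dA
      },
      dropout = if (!is.null(cc$mask)) dA * cc$mask else dA,
      relu = dA * (cc$input > 0),
      flatten = {
        d <- dim(cc$input)
        array(dA, dim = d)
      },
      maxpool = .maxpool1d_bw(dA, cc$idx, dim(cc$input)[2]),
      conv = {
        g <- .conv1d_bw(cc$input, l$W, dA, l$kernel, l$pad)
        grads[[i]] <- list(dW = g$dW, db = g$db)
        g$dX
      },
      input = dA)
  }
  grads
}

#' Train a CNN by stochastic gradient descent with momentum
#'
#' Minimizes the softmax cross-entropy over labeled channel stacks with
#' mini-batch SGD: velocity `v <- Mo * v - Lr * grad`, `W <- W + v`. Dropout
#' (probability `Re`, inverted scaling) is active on the first FC during
#' training only. All randomness (shuffling, dropout masks) is driven by
#' `seed`, so a given data/seed pair reproduces the run bit for bit.
#'
#' @param model a [build_cnne()] model.
#' @param stacks list of labeled [channel_stack()] objects; both classes must
#'   be present.
#' @param epochs,batch_size training schedule; defaults from the model's
#'   config.
#' @param seed RNG seed (default 1).
#' @param verbose print per-epoch loss.
#' @return the trained model; `$train_log` holds per-epoch mean loss and
#'   training accuracy, `$train_records` the record ids seen (used by the
#'   leakage guard in [validate_cv()]).
#' @export
train_cnne <- function(model, stacks, epochs = NULL, batch_size = NULL,
                       seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), length(stacks) >= 2)
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  y <- vapply(stacks, function(s) s$label, integer(1))
  if (length(unique(y)) < 2) stop("training data contain a single class")
  X <- stacks_to_array(stacks)
  if (dim(X)[2] != cfg$input_len)
    stop(sprintf("stack length %d != configured input_len %d",
                 dim(X)[2], cfg$input_len))
  n <- length(y)
  vel <- lapply(model$layers, function(l)
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL)
  log <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      tot_correct <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        Xb <- X[, , idx, drop = FALSE]
        Yb <- rbind(1 - y[idx], y[idx])  # row 1 = class 0, row 2 = class 1
        fw <- cnn_forward(model, Xb, train = TRUE, keep_cache = TRUE)
        p <- fw$out
        loss <- -mean(log(pmax(colSums(p * Yb), 1e-12)))
        if (!is.finite(loss))
          stop("NaN/Inf loss during training (epoch ", ep,
               "); lower the learning rate")
        tot_loss <- tot_loss + loss * length(idx)
        tot_correct <- tot_correct +
          sum((p[2, ] > p[1, ]) == (y[idx] == 1))
        grads <- cnn_backward(model, fw, Yb)
        for (i in seq_along(model$layers)) {
          if (is.null(grads[[i]])) next
          vel[[i]]$W <- cfg$Mo * vel[[i]]$W - cfg$Lr * grads[[i]]$dW
          vel[[i]]$b <- cfg$Mo * vel[[i]]$b - cfg$Lr * grads[[i]]$db
          model$layers[[i]]$W <- model$layers[[i]]$W + vel[[i]]$W
          model$layers[[i]]$b <- model$layers[[i]]$b + vel[[i]]$b
        }
      }
      log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / n,
                                   acc = tot_correct / n))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, train acc %.3f",
                        ep, tot_loss / n, tot_correct / n))
    }
  })
  model$trained <- TRUE
  model$train_log <- log
  model$train_records <- unique(stats::na.omit(
    vapply(stacks, function(s) s$record_id, character(1))))
  model
}

#' Extract the deep feature vector of a segment
#'
#' Returns the activations of the first fully connected layer (post-ReLU,
#' dropout disabled): the 100-dimensional learned-feature vector fed to the
#' secondary classifiers. Deterministic given the model weights.
#'
#' @param model a trained [cnn_model()].
#' @param stack a [channel_stack()], or a list of them for a feature matrix.
#' @return numeric vector of length `fc_width`, or an n x `fc_width` matrix
#'   for a list input.
#' @export
extract_features <- function(model, stack) {
  stopifnot(inherits(model, "cnn_model"))
  stacks <- if (inherits(stack, "channel_stack")) list(stack) else stack
  X <- stacks_to_array(stacks)
  A <- X
  for (l in model$layers) {
    A <- switch(l$type,
      conv = .conv1d_fw(A, l$W, l$b, l$kernel, l$pad),
      relu = pmax(A, 0),
      maxpool = .maxpool1d_fw(A, l$kernel, l$stride)$Y,
      flatten = matrix(A, dim(A)[1] * dim(A)[2], dim(A)[3]),
      fc = sweep(l$W %*% A, 1, l$b, `+`),
      stop("hit layer '", l$type, "' before the first FC"))
    if (l$type == "fc") {
      A <- pmax(A, 0)  # feature vector is post-ReLU
      break
    }
  }
  if (inherits(stack, "channel_stack")) as.numeric(A) else t(A)
}

#' Classify with the full CNN (fCNN)
#'
#' Runs the whole network including the 2-output softmax; the label is the
#' argmax class (1 = shockable). Dropout is disabled, so inference is a pure
#' function of the weights and the input.
#'
#' @param model a trained [cnn_model()].
#' @param stack a [channel_stack()], or a list of them.
#' @return for a single stack, a list with `label` and `probs`
#'   (named `c(nsh, sh)`, summing to 1); for a list, a data frame with
#'   columns `label`, `p_nsh`, `p_sh`.
#' @export
predict_fcnn <- function(model, stack) {
  stopifnot(inherits(model, "cnn_model"))
  single <- inherits(stack, "channel_stack")
  stacks <- if (single) list(stack) else stack
  P <- cnn_forward(model, stacks_to_array(stacks))$out
  labels <- as.integer(P[2, ] > P[1, ])
  if (single) {
    list(label = labels[1], probs = c(nsh = P[1, 1], sh = P[2, 1]))
  } else {
    data.frame(label = labels, p_nsh = P[1, ], p_sh = P[2, ])
  }
}
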
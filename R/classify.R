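#' Specification of a secondary classifier
#'
#' The six conventional learners applied to deep feature vectors: support
#' vector machine (`"SVM"`, RBF kernel, cost 1), k-nearest neighbours
#' (`"KNN"`, k = 5), random forest (`"RF"`, 100 trees), bagging (`"BG"`,
#' 100 bootstrap trees), boosting (`"BS"`, AdaBoost.M1 over depth-1 decision
#' stumps, 100 rounds -- the shock-advice default) and L2-regularized
#' logistic regression (`"LR"`). Features are not standardized by default;
#' set `scale = TRUE` in `params` to z-score them (the scaling learned on
#' the training features is reapplied at prediction).
#'
#' @param name one of `"BS"`, `"SVM"`, `"KNN"`, `"RF"`, `"BG"`, `"LR"`.
#' @param params named list of learner-specific hyperparameters overriding
#'   the defaults above (`cost`, `k`, `ntree`, `nbag`, `rounds`, `lambda`,
#'   `scale`).
#' @param seed RNG seed used when fitting.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("BS", "SVM", "KNN", "RF", "BG", "LR"),
                            params = list(), seed = 1L) {
  name <- match.arg(name)
  defaults <- switch(name,
    SVM = list(cost = 1, scale = FALSE),
    KNN = list(k = 5, scale = FALSE),
    RF  = list(ntree = 100),
    BG  = list(nbag = 100),
    BS  = list(rounds = 100),
    LR  = list(lambda = 1e-2, scale = FALSE))
  defaults[names(params)] <- params
  structure(list(name = name, params = defaults, seed = as.integer(seed)),
            class = "classifier_spec")
}

scale_apply <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center, `-`), 2, scale, `/`)
}

# AdaBoost.M1 with rpart stumps. Labels in {0,1}; internal coding {-1,+1}.
fit_adaboost <- function(x, y, rounds) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y, levels = c(0, 1)), x)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(-alpha * ifelse(pred == y, 1, -1))
    w <- w / sum(w)
    if (err < 1e-9) break  # perfect stump; committee is decided
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x)
  score <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- as.integer(as.character(predict(fit$stumps[[m]], df,
                                            type = "class")))
    score <- score + fit$alphas[m] * (2 * pred - 1)
  }
  as.integer(score > 0)
}

fit_bagging <- function(x, y, nbag) {
  n <- nrow(x)
  df <- data.frame(y = factor(y, levels = c(0, 1)), x)
  lapply(seq_len(nbag), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(y ~ ., data = df[idx, ], method = "class",
                 control = rpart::rpart.control(minsplit = 4, cp = 0.01,
                                                xval = 0))
  })
}

predict_bagging <- function(fit, x) {
  df <- data.frame(x)
  votes <- rowSums(vapply(fit, function(tr)
    as.integer(as.character(predict(tr, df, type = "class"))),
    numeric(nrow(df))))
  as.integer(votes > length(fit) / 2)
}

#' Train a secondary classifier on deep features
#'
#' Fits the learner named in the spec on a feature matrix (one row per
#' segment, typically the 100 first-FC activations). Fitting is deterministic
#' given the spec's seed.
#'
#' @param spec a [classifier_spec()].
#' @param features numeric matrix, n x p.
#' @param labels binary labels (1 = shockable), length n; both classes must
#'   be present.
#' @return an object of class `saa_classifier`.
#' @export
train_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) stop("feature/label length mismatch")
  if (length(unique(labels)) < 2) stop("training data contain a single class")
  p <- spec$params
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  ctr <- NULL; scl <- NULL
  if (isTRUE(p$scale)) {
    ctr <- colMeans(features)
    scl <- apply(features, 2, stats::sd)
    features <- scale_apply(features, ctr, scl)
  }
  fit <- with_seed(spec$seed, switch(spec$name,
    SVM = e1071::svm(features, factor(labels, levels = c(0, 1)),
                     kernel = "radial", cost = p$cost, scale = FALSE),
    KNN = list(x = features, y = labels, k = p$k),  # lazy learner
    RF  = randomForest::randomForest(features,
                                     factor(labels, levels = c(0, 1)),
                                     ntree = p$ntree),
    BG  = fit_bagging(features, labels, p$nbag),
    BS  = fit_adaboost(features, labels, p$rounds),
    LR  = glmnet::glmnet(features, factor(labels, levels = c(0, 1)),
                         family = "binomial", alpha = 0, lambda = p$lambda)))
  structure(list(spec = spec, fit = fit, n_features = ncol(features),
                 center = ctr, scale = scl),
            class = "saa_classifier")
}

#' Predict shockable/non-shockable labels from features
#'
#' @param object a fitted [train_classifier()] model.
#' @param features numeric matrix (or single feature vector) with the same
#'   number of columns the classifier was trained on.
#' @param ... unused.
#' @return integer vector of labels in `{0, 1}` (1 = shockable), one per row.
#' @export
predict.saa_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != object$n_features)
    stop(sprintf("feature dimension %d != expected %d",
                 ncol(features), object$n_features))
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  if (!is.null(object$center))
    features <- scale_apply(features, object$center, object$scale)
  spec <- object$spec
  out <- with_seed(spec$seed, switch(spec$name,
    SVM = as.integer(as.character(predict(object$fit, features))),
    KNN = as.integer(as.character(class::knn(object$fit$x, features,
                                             factor(object$fit$y),
                                             k = object$fit$k))),
    RF  = as.integer(as.character(predict(object$fit, features))),
    BG  = predict_bagging(object$fit, features),
    BS  = predict_adaboost(object$fit, features),
    LR  = as.integer(predict(object$fit, features, type = "class"))))
  as.integer(out)
}
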
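#' Classification metrics for shock advice
#'
#' Computes the confusion counts and the four standard measures on the
#' percent scale, with the shockable class (1) positive: sensitivity
#' `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Ac = (TP+TN)/n` and balanced error rate `BER = 100 - (Se+Sp)/2`. When a
#' class is absent from the truth the corresponding rate is `NA` and BER
#' falls back to the available rate, with a warning.
#'
#' @param truth,pred equal-length vectors of labels in `{0, 1}`.
#' @return an object of class `metrics_report`: list with `TP`, `FN`, `TN`,
#'   `FP`, `Ac`, `Se`, `Sp`, `BER`.
#' @export
compute_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (!length(truth)) stop("empty input")
  if (length(truth) != length(pred)) stop("label vectors differ in length")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1))
    stop("labels must be 0/1")
  TP <- sum(truth == 1 & pred == 1); FN <- sum(truth == 1 & pred == 0)
  TN <- sum(truth == 0 & pred == 0); FP <- sum(truth == 0 & pred == 1)
  Se <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  Sp <- if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_
  Ac <- 100 * (TP + TN) / length(truth)
  if (is.na(Se) || is.na(Sp)) {
    warning("one class absent from the truth; BER uses the available rate")
    BER <- 100 - mean(c(Se, Sp), na.rm = TRUE)
  } else {
    BER <- 100 - (Se + Sp) / 2
  }
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 Ac = Ac, Se = Se, Sp = Sp, BER = BER),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Ac %.2f%%  Se %.2f%%  Sp %.2f%%  BER %.2f%%  (TP %d FN %d TN %d FP %d)\n",
              x$Ac, x$Se, x$Sp, x$BER, x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

#' Record-wise fold plan
#'
#' Assigns whole records to folds so that no patient contributes segments to
#' both the training and the testing side of any split. Fold sizes are as
#' equal as possible (e.g. 17 records at k = 5 give sizes 4,4,3,3,3) and the
#' shuffle is seeded, so a plan is reproducible.
#'
#' @param record_ids character vector (duplicates allowed; unique ids are
#'   assigned).
#' @param k number of folds.
#' @param seed RNG seed.
#' @return an object of class `fold_plan`: list with `k`, `seed` and
#'   `assignment`, a named integer vector mapping record id to fold.
#' @export
make_record_folds <- function(record_ids, k = 5, seed = 1L) {
  ids <- unique(as.character(record_ids))
  if (length(ids) < k) stop("fewer records than folds")
  with_seed(seed, {
    shuffled <- sample(ids)
    sizes <- rep(length(ids) %/% k, k) +
      as.integer(seq_len(k) <= length(ids) %% k)
    assignment <- rep(seq_len(k), times = sizes)
    names(assignment) <- shuffled
    structure(list(k = as.integer(k), seed = seed, assignment = assignment),
              class = "fold_plan")
  })
}

fold_split <- function(plan, record_ids, fold) {
  f <- plan$assignment[as.character(record_ids)]
  test <- unname(which(f == fold))
  train <- unname(which(f != fold))
  if (length(intersect(record_ids[train], record_ids[test])))
    stop("leakage: a record appears in both train and test")  # unreachable guard
  list(train = train, test = test)
}

# shared helper: record-wise CV of one CNN config on a set of stacks,
# scoring the fCNN softmax and each selector classifier on first-FC features.
cv_config_ber <- function(stacks, config, selectors, k, epochs, seed) {
  rec <- vapply(stacks, function(s) s$record_id, character(1))
  y <- vapply(stacks, function(s) s$label, integer(1))
  plan <- make_record_folds(rec, k, seed)
  scorers <- c("fCNN", selectors)
  bers <- matrix(NA_real_, k, length(scorers),
                 dimnames = list(NULL, scorers))
  for (fold in seq_len(k)) {
    sp <- fold_split(plan, rec, fold)
    if (length(unique(y[sp$train])) < 2 || !length(sp$test)) next
    net <- tryCatch(
      train_cnne(build_cnne(config, init_seed = seed),
                 stacks[sp$train], epochs = epochs, seed = seed + fold),
      error = function(e) NULL)
    # divergence guard: aborted training (NaN loss), a final loss far above
    # the chance level, or non-finite/overflowing activations all mark the
    # config-fold as unusable and score the worst-case BER
    final_loss <- if (is.null(net)) Inf else
      net$train_log$loss[nrow(net$train_log)]
    if (!is.finite(final_loss) || final_loss > 10) {
      bers[fold, ] <- 50
      next
    }
    pred_f <- predict_fcnn(net, stacks[sp$test])$label
    if (anyNA(pred_f)) {
      bers[fold, ] <- 50
      next
    }
    bers[fold, "fCNN"] <- compute_metrics(y[sp$test], pred_f)$BER
    if (length(selectors)) {
      ftr <- extract_features(net, stacks[sp$train])
      fte <- extract_features(net, stacks[sp$test])
      huge <- 1e30
      if (!all(is.finite(ftr)) || !all(is.finite(fte)) ||
          max(abs(ftr)) > huge || max(abs(fte)) > huge) {
        bers[fold, selectors] <- 50
        next
      }
      for (sel in selectors) {
        fit <- train_classifier(classifier_spec(sel, seed = seed), ftr,
                                y[sp$train])
        bers[fold, sel] <- compute_metrics(y[sp$test],
                                           predict(fit, fte))$BER
      }
    }
  }
  colMeans(bers, na.rm = TRUE)
}

#' Grid search with record-wise cross-validation for CNN selection
#'
#' Scores every candidate configuration by record-wise k-fold CV on the
#' training stacks: per fold a network is trained on the fold-train side and
#' scored (a) by its own softmax (the fCNN scorer) and (b) by each selector
#' classifier trained on fold-train first-FC features and tested on
#' fold-test features. Per scorer the configuration with minimum mean BER
#' wins; ties break toward fewer parameters, then lower learning rate. A
#' configuration whose training diverges (non-finite loss, a final loss far
#' above the chance level, or overflowing activations) scores the
#' worst-case BER of 50.
#'
#' @param stacks list of labeled [channel_stack()] objects with record ids.
#' @param grid data frame with columns `Ns`, `Nd`, `Lr`, `Mo`, `Re`, one row
#'   per candidate.
#' @param selectors classifier names used as selection scorers
#'   (default `c("SVM", "KNN", "RF")`).
#' @param k folds (default 5).
#' @param epochs training epochs per fold fit.
#' @param seed RNG seed; a rerun with the same seed reproduces the winners.
#' @param input_len,n_channels forwarded to [cnn_config()].
#' @return an object of class `grid_search_result`: list with `winners`
#'   (named list mapping scorer to the winning config row, with its CV BER)
#'   and `ber_table` (grid x scorers matrix of mean BERs).
#' @export
grid_search_select <- function(stacks, grid,
                               selectors = c("SVM", "KNN", "RF"),
                               k = 5, epochs = 10, seed = 1L,
                               input_len = NULL, n_channels = 3) {
  if (!nrow(grid)) stop("empty grid")
  stopifnot(all(c("Ns", "Nd", "Lr", "Mo", "Re") %in% names(grid)))
  if (is.null(input_len)) input_len <- length(stacks[[1]]$pecg)
  scorers <- c("fCNN", selectors)
  ber_table <- matrix(NA_real_, nrow(grid), length(scorers),
                      dimnames = list(NULL, scorers))
  n_params <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- cnn_config(Ns = grid$Ns[g], Nd = grid$Nd[g], Lr = grid$Lr[g],
                      Mo = grid$Mo[g], Re = grid$Re[g],
                      input_len = input_len, n_channels = n_channels)
    n_params[g] <- cnn_n_params(cfg)
    ber_table[g, ] <- cv_config_ber(stacks, cfg, selectors, k, epochs, seed)
  }
  winners <- lapply(scorers, function(sc) {
    b <- ber_table[, sc]
    best <- which(b == min(b))
    if (length(best) > 1) best <- best[order(n_params[best],
                                             grid$Lr[best])][1]
    c(as.list(grid[best, c("Ns", "Nd", "Lr", "Mo", "Re")]),
      list(cv_ber = unname(b[best]), grid_row = unname(best)))
  })
  names(winners) <- scorers
  structure(list(winners = winners, ber_table = ber_table,
                 n_params = n_params, grid = grid, seed = seed),
            class = "grid_search_result")
}

#' Repeated record-wise cross-validation of a classifier on deep features
#'
#' The validation stage: features are extracted once from the evaluation
#' stacks by the pre-trained extractor, then for each repetition a fresh
#' record-wise fold plan is drawn and the secondary classifier is trained on
#' the fold-train features and tested on the fold-test features; the
#' confusion counts of the k folds are pooled into one report per
#' repetition. A hard error is raised if any evaluation record was seen by
#' the extractor during its training (record-level leakage guard).
#'
#' With `spec = "fCNN"` the network itself is the classifier: it is
#' retrained per fold from the extractor's configuration and scored by its
#' softmax output.
#'
#' @param stacks evaluation [channel_stack()] list.
#' @param extractor a trained [cnn_model()].
#' @param spec a [classifier_spec()], or the string `"fCNN"`.
#' @param k folds per repetition (default 5).
#' @param reps repetitions (default 100); repetition r uses seed `seed + r`.
#' @param seed base RNG seed.
#' @param epochs training epochs for the per-fold fCNN refits.
#' @return an object of class `cv_report`: list with `summary` (data frame
#'   of mean and sd of Ac/Se/Sp/BER over repetitions) and `per_rep` (one row
#'   per repetition).
#' @export
validate_cv <- function(stacks, extractor, spec = classifier_spec("BS"),
                        k = 5, reps = 100, seed = 1L, epochs = 10) {
  stopifnot(inherits(extractor, "cnn_model"))
  rec <- vapply(stacks, function(s) s$record_id, character(1))
  y <- vapply(stacks, function(s) s$label, integer(1))
  overlap <- intersect(unique(rec), extractor$train_records)
  if (length(overlap))
    stop("leakage: evaluation records also trained the extractor: ",
         paste(overlap, collapse = ", "))
  use_fcnn <- identical(spec, "fCNN")
  if (!use_fcnn) features <- extract_features(extractor, stacks)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    plan <- make_record_folds(rec, k, seed + r)
    truth_all <- integer(); pred_all <- integer()
    for (fold in seq_len(k)) {
      sp <- fold_split(plan, rec, fold)
      if (!length(sp$test)) next
      if (length(unique(y[sp$train])) < 2) next
      pred <- if (use_fcnn) {
        net <- train_cnne(build_cnne(extractor$config, init_seed = seed + r),
                          stacks[sp$train], epochs = epochs,
                          seed = seed + r * 100 + fold)
        predict_fcnn(net, stacks[sp$test])$label
      } else {
        sp_spec <- spec
        sp_spec$seed <- seed + r
        fit <- train_classifier(sp_spec, features[sp$train, , drop = FALSE],
                                y[sp$train])
        predict(fit, features[sp$test, , drop = FALSE])
      }
      truth_all <- c(truth_all, y[sp$test])
      pred_all <- c(pred_all, pred)
    }
    m <- compute_metrics(truth_all, pred_all)
    per_rep[[r]] <- data.frame(rep = r, Ac = m$Ac, Se = m$Se, Sp = m$Sp,
                               BER = m$BER)
  }
  per_rep <- do.call(rbind, per_rep)
  summ <- data.frame(
    metric = c("Ac", "Se", "Sp", "BER"),
    mean = vapply(c("Ac", "Se", "Sp", "BER"),
                  function(m) mean(per_rep[[m]]), numeric(1)),
    sd = vapply(c("Ac", "Se", "Sp", "BER"),
                function(m) stats::sd(per_rep[[m]]), numeric(1)))
  if (reps == 1) summ$sd <- 0
  structure(list(summary = summ, per_rep = per_rep, k = k, reps = reps,
                 seed = seed, classifier = if (use_fcnn) "fCNN" else spec$name),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s, %d-fold x %d rep(s)>\n",
              x$classifier, x$k, x$reps))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-3s %6.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
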
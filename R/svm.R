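#' Cross-validation / permutation configuration
#'
#' @param k_folds number of outer folds (inner model selection rotates over
#'   the \code{k_folds - 1} training folds).
#' @param c_grid ordered positive misclassification-cost values tried in the
#'   inner loop (default 1..10, unit step); ties in inner accuracy go to the
#'   smallest c.
#' @param n_permutations repetitions of nested CV for the null distribution
#'   (and, by default, for the true-run average).
#' @param n_true_reps repetitions averaged for the true accuracy; defaults
#'   to \code{n_permutations}. Set to 1 for null-calibration studies, where
#'   averaging the true statistic concentrates the permutation p-value.
#' @param weight_z_threshold |z| above which a feature weight is flagged.
#' @param p_add_one if TRUE use the (count+1)/(n+1) p-value; default is
#'   count/n.
#' @param seed integer seed; all fold draws and label shuffles derive from
#'   it.
#' @return list of class \code{"cv_config"}.
#' @export
cv_config <- function(k_folds = 4L, c_grid = 1:10, n_permutations = 1000L,
                      n_true_reps = n_permutations,
                      weight_z_threshold = 1.96, p_add_one = FALSE,
                      seed = 1L) {
  stopifnot(k_folds >= 2L, length(c_grid) >= 1L, all(c_grid > 0),
            n_permutations >= 1L, n_true_reps >= 1L)
  structure(
    list(k_folds = as.integer(k_folds), c_grid = sort(as.numeric(c_grid)),
         n_permutations = as.integer(n_permutations),
         n_true_reps = as.integer(n_true_reps),
         weight_z_threshold = weight_z_threshold,
         p_add_one = isTRUE(p_add_one), seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' Assemble a feature matrix for classification
#'
#' One row per (participant, condition); columns are the per-node mean
#' values of a local metric (\code{pc}/\code{bc}) or the single global mean
#' (\code{e_global}/\code{q}).
#'
#' @param table long table from [metrics_long_table()] (local metrics) or
#'   global table from [metrics_global_table()] (global metrics).
#' @param metric \code{"pc"}, \code{"bc"}, \code{"e_global"} or \code{"q"}.
#' @return list of class \code{"feature_matrix"}: \code{x} (numeric matrix),
#'   \code{y} (labels \code{"fear"}/\code{"neutral"}), \code{participant_id},
#'   \code{dataset_id}, \code{feature_names}.
#' @export
feature_matrix <- function(table, metric = c("pc", "bc", "e_global", "q")) {
  metric <- match.arg(metric)
  value_col <- paste0("mean_", metric)
  if (!value_col %in% names(table))
    stop("table lacks column ", value_col, call. = FALSE)
  if (metric %in% c("pc", "bc")) {
    nodes <- sort(unique(table$node_id))
    key <- paste(table$participant_id, table$condition)
    rows <- !duplicated(key)
    meta <- table[rows, c("participant_id", "dataset_id", "condition")]
    x <- matrix(NA_real_, nrow(meta), length(nodes),
                dimnames = list(NULL, paste0("node_", nodes)))
    ridx <- match(key, key[rows])
    cidx <- match(table$node_id, nodes)
    x[cbind(ridx, cidx)] <- table[[value_col]]
  } else {
    meta <- table[, c("participant_id", "dataset_id", "condition")]
    x <- matrix(table[[value_col]], ncol = 1L,
                dimnames = list(NULL, metric))
  }
  if (anyNA(x)) stop("feature matrix has missing values", call. = FALSE)
  tab <- table(meta$participant_id)
  if (any(tab != 2L))
    stop("every participant needs exactly one row per condition",
         call. = FALSE)
  structure(
    list(x = x, y = meta$condition, participant_id = meta$participant_id,
         dataset_id = meta$dataset_id, feature_names = colnames(x)),
    class = "feature_matrix"
  )
}

#' Stratified participant-level fold assignment
#'
#' Participants (never single rows) are assigned to folds so that both
#' condition rows of a participant share a fold, and each dataset
#' contributes an approximately equal number of participants to every fold
#' (per-dataset counts differ by at most 1). If some dataset has fewer
#' participants than folds, stratification is impossible and assignment
#' falls back to global balancing with a warning.
#'
#' @param participants unique participant ids.
#' @param strata dataset id per participant (same length).
#' @param k number of folds.
#' @param seed integer seed (assignment is reproducible).
#' @return integer vector of fold ids (1..k), named by participant.
#' @export
make_folds <- function(participants, strata, k, seed) {
  stopifnot(length(participants) == length(strata),
            !anyDuplicated(participants), k >= 2L)
  .with_seed(seed, {
    fold <- integer(length(participants))
    names(fold) <- participants
    small <- tapply(participants, strata, length) < k
    if (any(small)) {
      warning("dataset(s) with fewer participants than folds; ",
              "falling back to global fold balancing", call. = FALSE)
      ord <- sample(length(participants))
      fold[ord] <- rep_len(seq_len(k), length(participants))
    } else {
      for (ds in unique(strata)) {
        ids <- participants[strata == ds]
        ids <- ids[sample(length(ids))]
        start <- sample.int(k, 1L)            # rotate remainder across folds
        fold[ids] <- ((start - 1L + seq_along(ids) - 1L) %% k) + 1L
      }
    }
    fold
  })
}

# Fit the linear SVM on standardized features (bias as augmented constant
# feature, LIBLINEAR-style). y in {+1 fear, -1 neutral}.
.svm_fit <- function(x, y01, C, seed) {
  xa <- cbind(x, bias = 1)
  fit <- linsvm_dcd(xa, y01, C, max_epochs = 1000L, tol = 1e-4,
                    seed = seed)
  p <- ncol(x)
  list(w = fit$w[seq_len(p)], b = fit$w[p + 1L], alpha = fit$alpha)
}

.svm_predict <- function(model, x) {
  f <- as.vector(x %*% model$w) + model$b
  ifelse(f >= 0, "fear", "neutral")
}

.standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  n <- nrow(x_train)
  v <- colMeans(x_train * x_train) - mu * mu
  sd <- sqrt(pmax(v, 0) * n / max(n - 1L, 1L))
  sd[sd == 0 | is.na(sd)] <- 1
  list(apply = function(x) t((t(x) - mu) / sd))
}

#' Macro dice coefficient
#'
#' Per-class dice \eqn{2TP_c / (2TP_c + FP_c + FN_c)}, averaged unweighted
#' over the two condition classes. A class absent from both vectors
#' contributes 1 by convention. A constant single-class prediction on a
#' balanced set gives \eqn{(2/3 + 0)/2 = 1/3}.
#'
#' @param truth,pred equal-length label vectors.
#' @param classes class labels to average over (default both conditions).
#' @return scalar in [0, 1].
#' @export
macro_dice <- function(truth, pred, classes = c("fear", "neutral")) {
  if (length(truth) != length(pred))
    stop("label vectors differ in length", call. = FALSE)
  d <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(d)
}

#' One round of nested cross-validated linear SVM
#'
#' For each outer fold, the inner loop rotates over the remaining training
#' folds to pick the misclassification cost c maximizing inner pooled
#' accuracy (ties to the smallest c); the classifier is then refit on the
#' whole training set with that c and applied to the held-out fold.
#' Features are standardized with training-fold means/SDs only (applied to
#' the test fold), so no information leaks across the split. Outer test
#' predictions are pooled across folds for accuracy and macro dice; primal
#' weight vectors (standardized scale) are averaged across folds.
#'
#' @param features a [feature_matrix()].
#' @param folds participant-level fold assignment from [make_folds()].
#' @param config a [cv_config()].
#' @param labels optional label vector overriding \code{features$y} (used
#'   for permutation nulls).
#' @param seed seed for the deterministic SVM solver sweeps.
#' @return list: accuracy (percent), dice, weights (per feature), truth,
#'   predictions (pooled, in row order of the feature matrix).
#' @export
nested_cv <- function(features, folds, config, labels = NULL, seed = 1L) {
  x <- features$x
  y <- if (is.null(labels)) features$y else labels
  row_fold <- folds[features$participant_id]
  k <- config$k_folds
  pred <- character(nrow(x))
  w_sum <- numeric(ncol(x))
  for (f in sort(unique(row_fold))) {
    test <- row_fold == f
    train <- !test
    if (length(unique(y[train])) < 2L)
      stop("training folds contain a single class", call. = FALSE)
    std <- .standardizer(x[train, , drop = FALSE])
    xtr <- std$apply(x[train, , drop = FALSE])
    ytr <- ifelse(y[train] == "fear", 1, -1)
    inner_folds <- sort(setdiff(unique(row_fold), f))
    inner_hits <- numeric(length(config$c_grid))
    tr_fold <- row_fold[train]
    for (g in inner_folds) {
      fit_rows <- tr_fold != g
      xfit <- xtr[fit_rows, , drop = FALSE]
      yfit <- ytr[fit_rows]
      if (length(unique(yfit)) < 2L)
        stop("training folds contain a single class", call. = FALSE)
      xval <- xtr[!fit_rows, , drop = FALSE]
      yval <- ytr[!fit_rows]
      for (ci in seq_along(config$c_grid)) {
        m <- .svm_fit(xfit, yfit, config$c_grid[ci], seed = seed + g)
        f_val <- as.vector(xval %*% m$w) + m$b
        inner_hits[ci] <- inner_hits[ci] +
          sum((f_val >= 0) == (yval > 0))
      }
    }
    inner_acc <- inner_hits / sum(train)
    best_c <- config$c_grid[which.max(inner_acc)]   # ties -> smallest c
    m <- .svm_fit(xtr, ytr, best_c, seed = seed + f)
    pred[test] <- .svm_predict(m, std$apply(x[test, , drop = FALSE]))
    w_sum <- w_sum + m$w
  }
  acc <- 100 * mean(pred == y)
  list(accuracy = acc, dice = macro_dice(y, pred),
       weights = w_sum / length(unique(row_fold)),
       truth = y, predictions = pred)
}

# Swap the two condition labels of a random subset of participants
# (the exchangeable unit of the paired design).
.shuffle_within_participant <- function(y, participant_id) {
  flip_ids <- unique(participant_id)[stats::runif(length(unique(participant_id))) < 0.5]
  y2 <- y
  swap <- participant_id %in% flip_ids
  y2[swap] <- ifelse(y[swap] == "fear", "neutral", "fear")
  y2
}

#' Permutation-tested nested-CV classification
#'
#' The true accuracy/dice/weights are averaged over
#' \code{config$n_true_reps} repetitions of [nested_cv()], each with a
#' freshly drawn stratified fold assignment. The null distribution comes
#' from \code{config$n_permutations} repetitions in which each
#' participant's two condition labels are swapped at random (within-pair
#' shuffling, the exchangeable unit of the paired design), again with
#' fresh folds. The permutation p-value is the fraction of null accuracies
#' at or above the true mean accuracy (count/n by default). Mean feature
#' weights are standardized across features into z-scores,
#' \eqn{z_f = (\bar w_f - mean(\bar w)) / sd(\bar w)}, and features with
#' \eqn{|z|} above \code{weight_z_threshold} are flagged.
#'
#' @param features a [feature_matrix()].
#' @param config a [cv_config()].
#' @return list of class \code{"classification_result"}: mean_accuracy
#'   (percent), mean_dice, p_perm, mean_weights, weight_z,
#'   flagged_features, null_accuracies, true_accuracies, last_predictions,
#'   last_truth.
#' @export
permutation_classification <- function(features, config) {
  stopifnot(inherits(features, "feature_matrix"), inherits(config, "cv_config"))
  parts <- unique(features$participant_id)
  strata <- features$dataset_id[match(parts, features$participant_id)]
  .with_seed(config$seed, {
    max_seed <- .Machine$integer.max - 1L
    true_seeds <- sample.int(max_seed, config$n_true_reps)
    null_seeds <- sample.int(max_seed, config$n_permutations)
    shuffle_seeds <- sample.int(max_seed, config$n_permutations)

    run_one <- function(s, shuffle_seed = NULL) {
      folds <- suppressWarnings(make_folds(parts, strata, config$k_folds, s))
      labels <- if (!is.null(shuffle_seed)) {
        .with_seed(shuffle_seed,
                   .shuffle_within_participant(features$y,
                                               features$participant_id))
      } else NULL
      nested_cv(features, folds, config, labels = labels, seed = s)
    }

    true_runs <- lapply(true_seeds, run_one)
    true_acc <- vapply(true_runs, `[[`, numeric(1L), "accuracy")
    true_dice <- vapply(true_runs, `[[`, numeric(1L), "dice")
    w <- rowMeans(matrix(vapply(true_runs, `[[`, numeric(ncol(features$x)),
                                "weights"), nrow = ncol(features$x)))
    null_acc <- vapply(seq_len(config$n_permutations), function(r)
      run_one(null_seeds[r], shuffle_seed = shuffle_seeds[r])$accuracy,
      numeric(1L))

    mean_acc <- mean(true_acc)
    n <- config$n_permutations
    hits <- sum(null_acc >= mean_acc)
    p <- if (config$p_add_one) (hits + 1) / (n + 1) else hits / n

    sdw <- stats::sd(w)
    z <- if (length(w) > 1L && sdw > 0) (w - mean(w)) / sdw else
      rep(0, length(w))
    names(z) <- names(w) <- features$feature_names
    flagged <- features$feature_names[abs(z) > config$weight_z_threshold]

    last <- true_runs[[length(true_runs)]]
    structure(
      list(mean_accuracy = mean_acc, mean_dice = mean(true_dice),
           p_perm = p, mean_weights = w, weight_z = z,
           flagged_features = flagged, null_accuracies = null_acc,
           true_accuracies = true_acc,
           last_predictions = last$predictions, last_truth = last$truth),
      class = "classification_result"
    )
  })
}

#' Diagnose a degenerate (single-class) classifier
#'
#' Flags prediction vectors that collapse onto one class and reports the
#' arithmetic such a classifier forces: on a balanced set, overall accuracy
#' is exactly 50\% and macro dice is 1/3 (the predicted class scores
#' \eqn{2/3}, the other 0).
#'
#' @param truth,pred label vectors (e.g. \code{last_truth} /
#'   \code{last_predictions} of a \code{classification_result}).
#' @return list: collapsed (logical), predicted_class (or NA), accuracy
#'   (percent), dice, forced_accuracy, forced_dice (the analytic values
#'   implied by the class balance when collapsed; NA otherwise).
#' @export
degenerate_report <- function(truth, pred) {
  if (length(pred) == 0L) stop("empty prediction vector", call. = FALSE)
  if (length(truth) != length(pred))
    stop("label vectors differ in length", call. = FALSE)
  collapsed <- length(unique(pred)) == 1L
  acc <- 100 * mean(truth == pred)
  dice <- macro_dice(truth, pred)
  forced_acc <- forced_dice <- NA_real_
  cls <- NA_character_
  if (collapsed) {
    cls <- pred[1L]
    share <- mean(truth == cls)
    forced_acc <- 100 * share
    forced_dice <- if (share == 1) 1 else (2 * share / (1 + share)) / 2
  }
  list(collapsed = collapsed, predicted_class = cls, accuracy = acc,
       dice = dice, forced_accuracy = forced_acc, forced_dice = forced_dice)
}
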
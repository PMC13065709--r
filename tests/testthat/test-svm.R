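# Paired toy feature matrices built without the generator: n_part
# participants, one fear and one neutral row each, p features; `shift` moves
# the fear rows along feature 1.
toy_features <- function(n_part = 12, p = 4, shift = 0, seed = 1,
                         n_ds = 2) {
  set.seed(seed)
  pid <- sprintf("p%02d", seq_len(n_part))
  ds <- rep(LETTERS[seq_len(n_ds)], length.out = n_part)
  x <- matrix(rnorm(2 * n_part * p), 2 * n_part, p)
  y <- rep(c("fear", "neutral"), each = n_part)
  x[y == "fear", 1] <- x[y == "fear", 1] + shift
  structure(
    list(x = x, y = y, participant_id = rep(pid, 2),
         dataset_id = rep(ds, 2), feature_names = paste0("f", seq_len(p))),
    class = "feature_matrix"
  )
}

test_that("stratified folds balance datasets and keep pairs together", {
  parts <- sprintf("p%d", 1:8)
  strata <- rep(c("A", "B"), each = 4)
  f <- make_folds(parts, strata, k = 4, seed = 1)
  expect_setequal(unique(f), 1:4)
  for (ds in c("A", "B"))
    expect_true(all(table(f[strata == ds]) == 1))
  # determinism
  expect_identical(f, make_folds(parts, strata, 4, seed = 1))
  expect_false(identical(f, make_folds(parts, strata, 4, seed = 2)))
  # per-dataset counts never differ by more than 1
  set.seed(3)
  parts2 <- sprintf("q%d", 1:23)
  strata2 <- sample(c("A", "B", "C"), 23, replace = TRUE,
                    prob = c(.5, .3, .2))
  if (min(table(strata2)) >= 4) {
    f2 <- make_folds(parts2, strata2, 4, seed = 5)
    for (ds in unique(strata2)) {
      cnt <- tabulate(f2[strata2 == ds], 4)
      expect_lte(diff(range(cnt)), 1L)
    }
  }
  # too-small dataset: warning + global balancing
  expect_warning(f3 <- make_folds(sprintf("r%d", 1:9),
                                  c(rep("A", 7), "B", "B"), 4, seed = 1),
                 "fewer participants")
  expect_lte(diff(range(tabulate(f3, 4))), 1L)
})

test_that("macro dice matches its closed forms", {
  y <- rep(c("fear", "neutral"), each = 4)
  expect_equal(macro_dice(y, y), 1)
  expect_equal(macro_dice(y, rep("neutral", 8)), 1 / 3)
  expect_equal(macro_dice(y, rev(y)), 0)
  expect_error(macro_dice(y, y[-1]), "length")
  # random balanced predictions: expected macro dice ~ 0.5
  set.seed(41)
  d <- replicate(2000, macro_dice(y, sample(c("fear", "neutral"), 8,
                                            replace = TRUE)))
  expect_lt(abs(mean(d) - 0.5), 0.02)
})

test_that("the dual coordinate descent solver satisfies the KKT conditions", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 30
    p <- 5
    x <- cbind(matrix(rnorm(n * p), n, p), 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    C <- sample(c(0.5, 1, 5), 1)
    fit <- netcontrast:::linsvm_dcd(x, y, C, max_epochs = 5000,
                                    tol = 1e-10, seed = rep)
    w <- fit$w
    a <- fit$alpha
    marg <- y * as.vector(x %*% w)
    eps <- 1e-6
    # complementary slackness of the box-constrained dual
    expect_true(all(marg[a < eps] >= 1 - 1e-5))
    expect_true(all(marg[a > C - eps] <= 1 + 1e-5))
    free <- a > eps & a < C - eps
    if (any(free)) expect_lt(max(abs(marg[free] - 1)), 1e-5)
    # stationarity: w = sum_i alpha_i y_i x_i
    expect_lt(max(abs(w - as.vector(t(x) %*% (a * y)))), 1e-8)
  }
})

test_that("the solver recovers the closed-form max-margin separator", {
  # two points at x = -1 and x = +1: hard margin solution w = 1, b = 0
  x <- matrix(c(-1, 1), 2, 1)
  fit <- netcontrast:::.svm_fit(x, c(-1, 1), C = 100, seed = 1)
  expect_equal(fit$w, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
})

test_that("the solver agrees with an independent hinge-loss implementation", {
  # scikit-learn's LinearSVC with loss='hinge' solves the identical
  # objective (L2 penalty on [w; b], bias as a regularized unit feature)
  set.seed(61)
  n <- 40
  p <- 3
  x <- matrix(rnorm(n * p), n, p)
  y <- ifelse(x[, 1] + 0.5 * rnorm(n) > 0, 1, -1)
  C <- 2
  fit <- netcontrast:::.svm_fit(x, y, C = C, seed = 1)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(y = y, x), csv, row.names = FALSE)
  script <- sprintf(paste0(
    "import pandas as pd, json, numpy as np\n",
    "from sklearn.svm import LinearSVC\n",
    "d = pd.read_csv(%s)\n",
    "m = LinearSVC(C=%g, loss='hinge', tol=1e-10, max_iter=2000000)\n",
    "m.fit(d.iloc[:,1:].values, d['y'].values)\n",
    "print(json.dumps({'w': m.coef_[0].tolist(), 'b': float(m.intercept_[0])}))\n"),
    deparse(csv), C)
  out <- system2("python", "-", stdout = TRUE, stderr = FALSE, input = script)
  ref <- jsonlite::fromJSON(out[length(out)])
  expect_equal(fit$w, ref$w, tolerance = 1e-3)
  expect_equal(fit$b, ref$b, tolerance = 1e-3)
})

test_that("nested CV separates separable classes perfectly", {
  feats <- toy_features(n_part = 20, p = 4, shift = 10, seed = 2)
  folds <- make_folds(unique(feats$participant_id),
                      feats$dataset_id[!duplicated(feats$participant_id)],
                      4, seed = 3)
  cfg <- cv_config(n_permutations = 5, seed = 1)
  res <- nested_cv(feats, folds, cfg, seed = 4)
  expect_equal(res$accuracy, 100)
  expect_equal(res$dice, 1)
})

test_that("nested CV sits at chance for uninformative features", {
  cfg <- cv_config(c_grid = 1:3, n_permutations = 5, seed = 1)
  accs <- vapply(1:50, function(i) {
    feats <- toy_features(n_part = 50, p = 4, shift = 0, seed = 100 + i)
    folds <- make_folds(unique(feats$participant_id),
                        feats$dataset_id[!duplicated(feats$participant_id)],
                        4, seed = i)
    nested_cv(feats, folds, cfg, seed = i)$accuracy
  }, numeric(1))
  # binomial null on n = 100 rows per repeat
  expect_lt(abs(mean(accs) / 100 - 0.5), 3 * sqrt(0.25 / 100))
})

test_that("permutation classification flags the informative feature", {
  feats <- toy_features(n_part = 16, p = 20, shift = 3, seed = 5)
  cfg <- cv_config(c_grid = 1:5, n_permutations = 40, n_true_reps = 10,
                   seed = 7)
  res <- permutation_classification(feats, cfg)
  expect_gt(res$mean_accuracy, 65)
  expect_identical(unname(which.max(abs(res$weight_z))), 1L)
  expect_true("f1" %in% res$flagged_features)
  expect_true(res$p_perm <= 0.05)
  expect_length(res$null_accuracies, 40L)
})

test_that("weight z-scores are equivariant under feature reordering", {
  feats <- toy_features(n_part = 10, p = 6, shift = 2, seed = 8)
  perm <- c(4, 1, 6, 2, 5, 3)
  feats2 <- feats
  feats2$x <- feats$x[, perm]
  feats2$feature_names <- feats$feature_names[perm]
  cfg <- cv_config(c_grid = 1:2, n_permutations = 5, n_true_reps = 3,
                   seed = 9)
  r1 <- permutation_classification(feats, cfg)
  r2 <- permutation_classification(feats2, cfg)
  expect_equal(unname(r2$weight_z), unname(r1$weight_z[perm]),
               tolerance = 1e-10)
})

test_that("degenerate single-class classifiers are reported with their forced arithmetic", {
  y <- rep(c("fear", "neutral"), 10)
  rep_neutral <- degenerate_report(y, rep("neutral", 20))
  expect_true(rep_neutral$collapsed)
  expect_equal(rep_neutral$accuracy, 50)
  expect_equal(rep_neutral$forced_accuracy, 50)
  expect_equal(round(rep_neutral$dice, 3), 0.333)
  expect_equal(rep_neutral$dice, rep_neutral$forced_dice)

  mixed <- degenerate_report(y, c(rep("neutral", 19), "fear"))
  expect_false(mixed$collapsed)
  expect_error(degenerate_report(character(0), character(0)), "empty")
})

test_that("no participant ever straddles a train/test split", {
  feats <- toy_features(n_part = 9, p = 3, shift = 1, seed = 10, n_ds = 3)
  for (s in 1:5) {
    folds <- make_folds(unique(feats$participant_id),
                        feats$dataset_id[!duplicated(feats$participant_id)],
                        3, seed = s)
    row_fold <- folds[feats$participant_id]
    for (f in unique(row_fold)) {
      test_parts <- unique(feats$participant_id[row_fold == f])
      train_parts <- unique(feats$participant_id[row_fold != f])
      expect_length(intersect(test_parts, train_parts), 0L)
    }
  }
})
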
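#' Cross-validation specification
#'
#' Five repetitions of stratified five-fold cross-validation by default
#' (25 test-fold accuracies in total).
#'
#' @param n_folds folds per repetition (default 5).
#' @param n_repeats repetitions (default 5).
#' @param stratified keep class proportions per fold (default TRUE).
#' @param seed integer seed for the fold assignments.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(n_folds = 5, n_repeats = 5, stratified = TRUE, seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

#' PCA reduction fitted on the training set only
#'
#' Centers and rotates with components estimated from the training rows
#' alone; keeps the smallest number of leading components whose cumulative
#' explained variance reaches `variance_target`; maps the test rows with
#' the same centering and rotation (no leakage).
#'
#' @param train_features,test_features numeric matrices (rows = trials).
#' @param variance_target cumulative explained-variance target in (0, 1],
#'   default 0.99.
#' @return List with `train`, `test` (score matrices), `rotation`,
#'   `center`, `k` (components kept), `explained` (cumulative ratio).
#' @export
pca_reduce <- function(train_features, test_features,
                       variance_target = 0.99) {
  if (!(variance_target > 0 && variance_target <= 1))
    stop("variance_target must lie in (0, 1]")
  if (nrow(train_features) < 2) stop("need >= 2 training rows for PCA")
  center <- colMeans(train_features)
  Xc <- sweep(train_features, 2, center)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  ratio <- cumsum(ev) / sum(ev)
  k <- which(ratio >= variance_target)[1]
  rot <- sv$v[, seq_len(k), drop = FALSE]
  list(train = Xc %*% rot,
       test = sweep(test_features, 2, center) %*% rot,
       rotation = rot, center = center, k = k,
       explained = ratio[seq_len(k)])
}

#' Two-class linear discriminant classification
#'
#' Fits a linear discriminant with shared covariance on the training rows
#' and predicts the test rows. If the pooled covariance is singular, a
#' manual ridge-stabilized discriminant (jitter 1e-8 on the covariance
#' diagonal) is used instead, with a message.
#'
#' @param train numeric matrix of training rows.
#' @param labels factor (or coercible) of two classes.
#' @param test numeric matrix of test rows.
#' @return Factor of predicted test labels.
#' @export
lda_fit_predict <- function(train, labels, test) {
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("exactly two classes required, got ", nlevels(labels))
  fit <- tryCatch(
    suppressWarnings(MASS::lda(train, grouping = labels)),
    error = function(e) NULL)
  if (!is.null(fit))
    return(stats::predict(fit, test)$class)
  message("singular pooled covariance; ridge-stabilizing with jitter 1e-8")
  lda_ridge_predict(train, labels, test)
}

# pooled-covariance linear discriminant with diagonal jitter, used when
# MASS::lda refuses a (near-)singular problem
lda_ridge_predict <- function(train, labels, test) {
  lev <- levels(labels)
  m1 <- colMeans(train[labels == lev[1], , drop = FALSE])
  m2 <- colMeans(train[labels == lev[2], , drop = FALSE])
  n <- nrow(train)
  S <- (crossprod(sweep(train[labels == lev[1], , drop = FALSE], 2, m1)) +
        crossprod(sweep(train[labels == lev[2], , drop = FALSE], 2, m2))) /
    (n - 2)
  S <- S + 1e-8 * mean(diag(S) + 1e-12) * diag(ncol(S))
  w <- solve(S, m1 - m2)
  thr <- as.numeric(crossprod(w, (m1 + m2) / 2)) -
    log(mean(labels == lev[1]) / mean(labels == lev[2]))
  scores <- as.numeric(test %*% w)
  factor(ifelse(scores > thr, lev[1], lev[2]), levels = lev)
}

stratified_folds <- function(labels, n_folds, stratified, seed) {
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      for (lv in unique(labels)) {
        idx <- sample(which(labels == lv))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  fold
}

#' Repeated stratified cross-validated decoding accuracy
#'
#' For each repetition, assigns stratified folds, then per fold fits PCA
#' (training rows only) and the linear discriminant (training rows only)
#' and scores the held-out fold: accuracy = correct / total. Returns all
#' `n_repeats * n_folds` accuracies.
#'
#' @param features trials x features matrix.
#' @param labels two-class labels (one per trial).
#' @param cv a [cv_spec()].
#' @param variance_target PCA target (default 0.99).
#' @param paper_mode if TRUE, the PCA projection is fitted once on all
#'   trials before cross-validation (the global-fit variant); default
#'   FALSE (leak-free).
#' @return Numeric vector of per-fold accuracies with attribute `"mean"`.
#' @export
cross_validate <- function(features, labels, cv = cv_spec(),
                           variance_target = 0.99, paper_mode = FALSE) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < cv$n_folds))
    stop("every class needs at least n_folds members (smallest: ",
         min(counts), ")")
  if (paper_mode) {
    global <- pca_reduce(features, features, variance_target)
    features <- global$train
  }
  acc <- numeric(0)
  for (rep_i in seq_len(cv$n_repeats)) {
    fold <- stratified_folds(labels, cv$n_folds, cv$stratified,
                             cv$seed + rep_i)
    for (f in seq_len(cv$n_folds)) {
      tr <- fold != f
      te <- !tr
      if (paper_mode) {
        train_x <- features[tr, , drop = FALSE]
        test_x <- features[te, , drop = FALSE]
      } else {
        red <- pca_reduce(features[tr, , drop = FALSE],
                          features[te, , drop = FALSE], variance_target)
        train_x <- red$train
        test_x <- red$test
      }
      pred <- lda_fit_predict(train_x, labels[tr], test_x)
      acc <- c(acc, mean(pred == labels[te]))
    }
  }
  attr(acc, "mean") <- mean(acc)
  acc
}

#' Decoding accuracy under opposite-hand movement (W-OHM)
#'
#' Splits the trials by the opposite-hand label, cross-validates the
#' primary-direction (L vs R) decoder separately within the F subset and
#' within the B subset, and returns the mean of the two subset mean
#' accuracies.
#'
#' @param features trials x features matrix.
#' @param labels data.frame with columns `primary` ("L"/"R") and
#'   `opposite` ("F"/"B").
#' @param cv a [cv_spec()].
#' @param variance_target PCA target.
#' @param paper_mode see [cross_validate()].
#' @return Scalar accuracy with attribute `"per_subset"` (named means) and
#'   `"folds"` (list of per-fold accuracies).
#' @export
wohm_accuracy <- function(features, labels, cv = cv_spec(),
                          variance_target = 0.99, paper_mode = FALSE) {
  stopifnot(all(c("primary", "opposite") %in% names(labels)))
  subsets <- c("F", "B")
  if (!all(subsets %in% labels$opposite))
    stop("both opposite-hand subsets (F, B) must be present")
  folds <- lapply(subsets, function(s) {
    idx <- labels$opposite == s
    cross_validate(features[idx, , drop = FALSE], labels$primary[idx],
                   cv, variance_target, paper_mode)
  })
  names(folds) <- subsets
  per_subset <- vapply(folds, function(a) attr(a, "mean"), numeric(1))
  out <- mean(per_subset)
  attr(out, "per_subset") <- per_subset
  attr(out, "folds") <- folds
  out
}

# deterministic reservoir seed per grid cell: global seed + parameter hash
grid_cell_seed <- function(seed, c, NN) {
  as.integer(seed) + 1000L * as.integer(NN) + as.integer(round(100 * c))
}

select_best <- function(surface) {
  ord <- order(-surface$accuracy, surface$NN, surface$c)
  surface[ord[1], , drop = FALSE]
}

#' Mesh grid search over reservoir sparse degree and size
#'
#' Evaluates the W-OHM cross-validated accuracy for every `(c, NN)` cell
#' of the default grids (`c` in 0.1..0.9 step 0.1; `NN` in 10..70 step
#' 10), each cell with its own deterministic frozen reservoir derived from
#' the global seed, and selects the maximizing cell. Ties are broken
#' toward smaller `NN`, then smaller `c`.
#'
#' @param epochs a z-scored `eeg_epochs` (decoding window).
#' @param c_grid,nn_grid hyperparameter grids.
#' @param cv a [cv_spec()].
#' @param variance_target PCA target.
#' @param rho,lambda_r fixed reservoir parameters.
#' @param seed global seed from which each cell's reservoir seed derives.
#' @param paper_mode see [cross_validate()].
#' @param verbose print one line per cell.
#' @return An object of class `grid_search_result`: `surface` (data.frame
#'   `c`, `NN`, `accuracy`), `selected` (best row), `accuracy` (best value).
#' @export
grid_search <- function(epochs, c_grid = seq(0.1, 0.9, by = 0.1),
                        nn_grid = seq(10L, 70L, by = 10L),
                        cv = cv_spec(), variance_target = 0.99,
                        rho = 0.98, lambda_r = 1e-4, seed = 1,
                        paper_mode = FALSE, verbose = FALSE) {
  if (!length(c_grid) || !length(nn_grid))
    stop("grids must be non-empty")
  cells <- expand.grid(c = c_grid, NN = as.integer(nn_grid))
  cells <- cells[order(cells$NN, cells$c), ]
  C <- dim(epochs$data)[2]
  acc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- esn_config(NN = cells$NN[i], c = cells$c[i], rho = rho,
                      lambda_r = lambda_r,
                      seed = grid_cell_seed(seed, cells$c[i], cells$NN[i]))
    model <- init_reservoir(cfg, C)
    feats <- extract_features(epochs, model)
    acc[i] <- as.numeric(wohm_accuracy(feats, epochs$labels, cv,
                                       variance_target, paper_mode))
    if (verbose)
      message(sprintf("c=%.1f NN=%d acc=%.4f", cells$c[i], cells$NN[i],
                      acc[i]))
  }
  surface <- data.frame(c = cells$c, NN = cells$NN, accuracy = acc)
  rownames(surface) <- NULL
  best <- select_best(surface)
  structure(list(surface = surface, selected = best,
                 accuracy = best$accuracy), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d cells; best c=%.1f NN=%d acc=%.4f\n",
              nrow(x$surface), x$selected$c, x$selected$NN, x$accuracy))
  invisible(x)
}
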
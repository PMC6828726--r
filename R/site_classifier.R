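# Stage 2: sequon-level RBF-SVM classifier over the concatenated feature
# vector (23 normalised GDRs, then the SA and SS one-hot pattern blocks; 156
# features with the reference vocabulary sizes). Hyperparameters come from a
# cross-validated grid search on accuracy; the decision threshold is chosen
# on training folds by maximising MCC.

DEFAULT_C_GRID <- 2^seq(-5, 15, by = 2)       # 11 values
DEFAULT_GAMMA_GRID <- 2^seq(-15, 3, by = 2)   # 10 values
DEFAULT_THRESHOLD_GRID <- seq(0.25, 0.75, by = 0.05)

#' Assemble the full second-stage feature matrix
#'
#' Concatenates the 23 gapped-dipeptide features with the SA and SS one-hot
#' pattern blocks, in that fixed order.
#'
#' @param windows Character vector of 25-mer sequon windows.
#' @param sa,ss Annotation strings (window length) for the same sequons.
#' @param gdr A normalised `gdr_table`.
#' @param vocabs A `pattern_vocab_set`.
#' @return Numeric matrix, one row per sequon.
#' @export
assemble_features <- function(windows, sa, ss, gdr, vocabs) {
  cbind(encode_gd(windows, gdr), encode_patterns(sa, ss, vocabs))
}

.make_folds <- function(labels, nfold, group = NULL) {
  # stratified by label, or by group (e.g. protein id) when given so that
  # all sequons of a protein land in one fold
  if (is.null(group)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(nfold), length(i)))
    }
  } else {
    g <- unique(group)
    gf <- setNames(sample(rep_len(seq_len(nfold), length(g))), g)
    fold <- unname(gf[group])
  }
  fold
}

.svm_fit <- function(x, y, C, gamma, probability = FALSE) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE,
             probability = probability)
}

.svm_prob <- function(fit, x) {
  p <- attr(predict(fit, x, probability = TRUE), "probabilities")
  unname(p[, "pos"])
}

.best_threshold <- function(scores, lab, threshold_grid) {
  mccs <- vapply(threshold_grid, function(t) {
    mcc(confusion(scores > t, lab))
  }, numeric(1))
  threshold_grid[which.max(mccs)]
}

#' Train the sequon classifier with a cross-validated grid search
#'
#' Two steps mirror the training protocol: (1) an `nfold` cross-validated
#' grid search over `(C, gamma)` selects the cell with the highest mean
#' accuracy; (2) with the selected cell, each fold model picks its decision
#' threshold by maximising MCC on its training folds, is evaluated on its
#' test fold, and the fold model with the highest test-fold MCC is retained
#' (with its threshold) as the final classifier.
#'
#' All randomness (fold assignment, probability calibration) derives from
#' `seed`, so training is bit-reproducible.
#'
#' @param x Feature matrix (rows = sequons).
#' @param labels Binary labels (logical or `"positive"`/`"negative"`), at
#'   least 10 per class.
#' @param seed Integer seed (required).
#' @param C_grid,gamma_grid Hyperparameter grids; defaults are
#'   `2^(-5,-3,...,15)` and `2^(-15,-13,...,3)` (110 cells).
#' @param nfold Number of cross-validation folds (default 10).
#' @param threshold_grid Candidate decision thresholds (default 0.25..0.75
#'   by 0.05).
#' @param group Optional grouping vector (e.g. protein ids): folds are
#'   assigned per group to avoid within-protein leakage.
#' @return A `trained_model`: the fitted SVM, `C`, `gamma`,
#'   `score_threshold`, the grid-search table (`cv_grid`), per-fold MCCs
#'   (`fold_mcc`), and `feature_names`.
#' @export
grid_search_train <- function(x, labels, seed,
                              C_grid = DEFAULT_C_GRID,
                              gamma_grid = DEFAULT_GAMMA_GRID,
                              nfold = 10L,
                              threshold_grid = DEFAULT_THRESHOLD_GRID,
                              group = NULL) {
  lab <- .as_binary_label(labels)
  if (sum(lab) < 10L || sum(!lab) < 10L) {
    stop("grid_search_train needs at least 10 samples in each class")
  }
  if (missing(seed)) stop("seed is required for reproducible training")
  x <- as.matrix(x)
  y <- factor(ifelse(lab, "pos", "neg"), levels = c("neg", "pos"))
  set.seed(seed)
  fold <- .make_folds(y, nfold, group)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L; total <- 0L
    for (f in seq_len(nfold)) {
      tr <- fold != f; te <- fold == f
      if (!any(te) || length(unique(y[tr])) < 2L) next
      fit <- .svm_fit(x[tr, , drop = FALSE], y[tr], grid$C[gi], grid$gamma[gi])
      pred <- predict(fit, x[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
      total <- total + sum(te)
    }
    grid$accuracy[gi] <- correct / total
  }
  best <- which.max(grid$accuracy)
  C <- grid$C[best]; gamma <- grid$gamma[best]

  fold_mcc <- rep(NA_real_, nfold)
  fold_threshold <- rep(NA_real_, nfold)
  fold_models <- vector("list", nfold)
  for (f in seq_len(nfold)) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(y[tr])) < 2L) next
    fit <- .svm_fit(x[tr, , drop = FALSE], y[tr], C, gamma, probability = TRUE)
    thr <- .best_threshold(.svm_prob(fit, x[tr, , drop = FALSE]), lab[tr],
                           threshold_grid)
    fold_threshold[f] <- thr
    fold_mcc[f] <- mcc(confusion(.svm_prob(fit, x[te, , drop = FALSE]) > thr,
                                 lab[te]))
    fold_models[[f]] <- fit
  }
  keep <- which.max(fold_mcc)
  structure(list(
    svm = fold_models[[keep]], C = C, gamma = gamma,
    score_threshold = fold_threshold[keep],
    cv_grid = grid, fold_mcc = fold_mcc, best_fold = keep,
    seed = seed, nfold = nfold,
    feature_names = colnames(x)),
    class = "trained_model")
}

#' Predict glycosite probability scores
#'
#' @param model A `trained_model` from [grid_search_train()].
#' @param x Feature matrix with the training feature layout.
#' @return Numeric vector of probability scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), " features, got ", ncol(x))
  }
  .svm_prob(model$svm, x)
}
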
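# End-to-end pipeline: fit featurizers + classifier on a labelled annotated
# dataset, predict new sequons, integrate stage-1 protein scores, and
# cross-validate with fold-hygienic featurizer fitting.

#' Fit the second-stage featurizers on a labelled annotated dataset
#'
#' @param dataset data.frame with columns `window`, `label`
#'   (`"positive"`/`"negative"`), `sa`, `ss`.
#' @param rare_threshold Rare-pattern floor for vocabularies (default 0.01).
#' @param pseudocount GDR smoothing constant (default 0).
#' @return List with `gdr` (normalised `gdr_table`) and `vocabs`
#'   (`pattern_vocab_set`).
#' @export
fit_featurizers <- function(dataset, rare_threshold = 0.01, pseudocount = 0) {
  lab <- dataset$label
  gdr <- normalize_gdr(fit_gdr(dataset$window, lab, pseudocount))
  vocabs <- fit_pattern_vocabularies(dataset$sa, dataset$ss, lab, rare_threshold)
  list(gdr = gdr, vocabs = vocabs)
}

#' Train the full second-stage model on an annotated dataset
#'
#' Fits the GDR table and pattern vocabularies on the whole training set,
#' assembles the feature matrix, and runs the grid-search SVM training.
#'
#' @inheritParams fit_featurizers
#' @param seed Integer seed for all stochastic steps.
#' @param group_by_protein Assign cross-validation folds per protein id to
#'   prevent within-protein leakage (default `TRUE`).
#' @param ... Passed to [grid_search_train()] (`C_grid`, `gamma_grid`,
#'   `nfold`, `threshold_grid`).
#' @return A `glysite_model`: featurizers plus the `trained_model`, with
#'   `l` and package format version recorded.
#' @export
train_glysite <- function(dataset, seed, group_by_protein = TRUE,
                          rare_threshold = 0.01, pseudocount = 0, ...) {
  feats <- fit_featurizers(dataset, rare_threshold, pseudocount)
  x <- assemble_features(dataset$window, dataset$sa, dataset$ss,
                         feats$gdr, feats$vocabs)
  group <- if (group_by_protein) dataset$protein_id else NULL
  clf <- grid_search_train(x, dataset$label, seed = seed, group = group, ...)
  structure(list(gdr = feats$gdr, vocabs = feats$vocabs, classifier = clf,
                 l = unique(nchar(dataset$window)),
                 rare_threshold = rare_threshold, pseudocount = pseudocount,
                 format_version = 1L),
            class = "glysite_model")
}

#' Predict glycosites for annotated sequon windows
#'
#' Computes second-stage scores, applies the first-stage adjustment when a
#' protein score is available (x0.8 below 0.4, x1.1 above 0.8, otherwise
#' unchanged), and calls glycosites at final score > `final_threshold`.
#'
#' @param model A `glysite_model` from [train_glysite()].
#' @param dataset data.frame with columns `protein_id`, `position`, `window`,
#'   `sa`, `ss`.
#' @param stage1_scores Optional named numeric vector of protein scores (from
#'   [score_proteins()]); proteins missing from it get no adjustment.
#' @param final_threshold Final call cutoff (default 0.6, strict `>`).
#' @param additive Use additive stage-1 adjustment (default multiplicative).
#' @return data.frame of prediction records: `protein_id`, `position`,
#'   `stage2_score`, `stage1_score`, `final_score`, `call`.
#' @export
predict_glysite <- function(model, dataset, stage1_scores = NULL,
                            final_threshold = 0.6, additive = FALSE) {
  stopifnot(inherits(model, "glysite_model"))
  x <- assemble_features(dataset$window, dataset$sa, dataset$ss,
                         model$gdr, model$vocabs)
  s2 <- predict_scores(model$classifier, x)
  s1 <- rep(NA_real_, nrow(dataset))
  if (!is.null(stage1_scores)) {
    m <- match(dataset$protein_id, names(stage1_scores))
    s1 <- unname(stage1_scores[m])
  }
  final <- s2
  for (pid in unique(dataset$protein_id)) {
    i <- which(dataset$protein_id == pid)
    final[i] <- adjust_scores(s2[i], s1[i][1], additive = additive)
  }
  data.frame(protein_id = dataset$protein_id, position = dataset$position,
             stage2_score = s2, stage1_score = s1, final_score = final,
             call = final > final_threshold,
             stringsAsFactors = FALSE)
}

#' Cross-validate the second-stage pipeline with fold-hygienic featurizers
#'
#' For each fold the GDR table and pattern vocabularies are fitted on the
#' training folds only — held-out windows never contribute counts — then a
#' classifier is trained and the held-out fold scored.
#'
#' @inheritParams train_glysite
#' @param nfold Number of folds (default 10).
#' @param keep_models Also return the per-fold `glysite_model`s (for
#'   inspecting fold-level featurizers; default `FALSE`).
#' @param ... Passed to [grid_search_train()].
#' @return List with `predictions` (out-of-fold data.frame: `fold`, `label`,
#'   `score`, `call`), `fold_metrics` (per-fold MCC and accuracy), `fold`
#'   (the fold assignment), and optionally `models`.
#' @export
cv_glysite <- function(dataset, seed, nfold = 10L, group_by_protein = TRUE,
                       rare_threshold = 0.01, pseudocount = 0,
                       keep_models = FALSE, ...) {
  set.seed(seed)
  lab <- .as_binary_label(dataset$label)
  group <- if (group_by_protein) dataset$protein_id else NULL
  fold <- .make_folds(dataset$label, nfold, group)
  preds <- vector("list", nfold)
  models <- vector("list", nfold)
  fm <- data.frame(fold = seq_len(nfold), mcc = NA_real_, accuracy = NA_real_)
  for (f in seq_len(nfold)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (!length(te) || length(unique(lab[tr])) < 2L) next
    model <- train_glysite(dataset[tr, , drop = FALSE], seed = seed + f,
                           group_by_protein = group_by_protein,
                           rare_threshold = rare_threshold,
                           pseudocount = pseudocount, ...)
    x <- assemble_features(dataset$window[te], dataset$sa[te], dataset$ss[te],
                           model$gdr, model$vocabs)
    sc <- predict_scores(model$classifier, x)
    call <- sc > model$classifier$score_threshold
    cm <- confusion(call, lab[te])
    fm$mcc[f] <- mcc(cm)
    fm$accuracy[f] <- metrics(cm)$accuracy
    preds[[f]] <- data.frame(fold = f, index = te, label = dataset$label[te],
                             score = sc, call = call, stringsAsFactors = FALSE)
    if (keep_models) models[[f]] <- model
  }
  out <- list(predictions = do.call(rbind, preds), fold_metrics = fm,
              fold = fold)
  if (keep_models) out$models <- models
  out
}

#' Save / load a trained model bundle
#'
#' The bundle is a directory holding the featurizers as inspectable TSVs
#' (GDR table, pattern vocabularies), the fitted classifier as an RDS file,
#' and a plain-text manifest with format version and parameters.
#'
#' @param model A `glysite_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_model_bundle` returns `dir` invisibly; `load_model_bundle`
#'   the reconstructed `glysite_model`.
#' @export
save_model_bundle <- function(model, dir) {
  stopifnot(inherits(model, "glysite_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gdr_table(model$gdr, file.path(dir, "gdr_table.tsv"))
  vdf <- do.call(rbind, lapply(names(model$vocabs), function(nm) {
    v <- model$vocabs[[nm]]
    rbind(
      data.frame(block = nm, feature_type = v$feature_type, region = v$region,
                 w = v$w, pattern = v$patterns$pattern, e = v$patterns$e,
                 n = v$patterns$n, n_windows = v$n_windows, z = v$z,
                 stringsAsFactors = FALSE),
      data.frame(block = nm, feature_type = v$feature_type, region = v$region,
                 w = v$w, pattern = "__other__", e = v$other[["e"]],
                 n = v$other[["n"]], n_windows = v$n_windows, z = v$z,
                 stringsAsFactors = FALSE))
  }))
  write.table(vdf, file.path(dir, "pattern_vocabularies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(model$classifier, file.path(dir, "classifier.rds"))
  manifest <- c(
    paste0("format_version: ", model$format_version),
    paste0("l: ", model$l),
    paste0("rare_threshold: ", model$rare_threshold),
    paste0("pseudocount: ", model$pseudocount),
    paste0("C: ", model$classifier$C),
    paste0("gamma: ", model$classifier$gamma),
    paste0("score_threshold: ", model$classifier$score_threshold))
  writeLines(manifest, file.path(dir, "MANIFEST"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  man <- readLines(file.path(dir, "MANIFEST"))
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ": "), man, value = TRUE)
    sub(paste0("^", key, ": "), "", ln)
  }
  fv <- as.integer(get_field("format_version"))
  if (!identical(fv, 1L)) stop("unsupported model bundle format version: ", fv)
  gdr <- read_gdr_table(file.path(dir, "gdr_table.tsv"))
  vdf <- read.delim(file.path(dir, "pattern_vocabularies.tsv"),
                    stringsAsFactors = FALSE)
  vocabs <- lapply(split(vdf, vdf$block), function(b) {
    other_row <- b$pattern == "__other__"
    structure(list(
      feature_type = b$feature_type[1], region = b$region[1], w = b$w[1],
      patterns = data.frame(pattern = b$pattern[!other_row],
                            e = b$e[!other_row], n = b$n[!other_row],
                            stringsAsFactors = FALSE),
      other = c(e = sum(b$e[other_row]), n = sum(b$n[other_row])),
      n_windows = b$n_windows[1], z = b$z[1], rare_threshold = NA_real_),
      class = "pattern_vocab")
  })
  vocabs <- structure(vocabs[c("sa_n", "sa_seq", "sa_c",
                               "ss_n", "ss_seq", "ss_c")],
                      class = "pattern_vocab_set")
  structure(list(gdr = gdr, vocabs = vocabs,
                 classifier = readRDS(file.path(dir, "classifier.rds")),
                 l = as.integer(get_field("l")),
                 rare_threshold = as.numeric(get_field("rare_threshold")),
                 pseudocount = as.numeric(get_field("pseudocount")),
                 format_version = fv),
            class = "glysite_model")
}
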
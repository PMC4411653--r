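# Dataset assembly, grouped splitting, hyperparameter tuning and the
# damaging/tolerated classifier (random forest or logistic regression).

CLASS_LEVELS <- c("tolerated", "damaging")

# Run expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs expr as-is.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.BOOKKEEPING_COLS <- c("label", "group_key", "transcript_id",
                       "cons_missing", "variant_class", "frequency", "id")

.numeric_feature_cols <- function(data) {
  numeric_ok <- vapply(data, is.numeric, TRUE)
  setdiff(names(data)[numeric_ok], .BOOKKEEPING_COLS)
}

#' Assemble a labeled dataset with the frequency and synonymous filters
#'
#' Damaging candidates observed at background frequency above 5\% are
#' dropped (likely mislabeled); tolerated candidates are kept only when
#' their population frequency exceeds 0.05 (common, hence benign).
#' Synonymous rows are removed from both sides, tolerated rows duplicated
#' across sources are deduplicated, and a provenance ledger of the counts
#' removed at each stage is attached.
#'
#' @param damaging,tolerated Feature data.frames (see
#'   \code{\link{encode_variant}}) with columns \code{group_key},
#'   \code{frequency} and optionally \code{variant_class}.
#' @param freq_cutoff Frequency threshold (default 0.05).
#' @param exclude_fr_sc_sd Also drop frameshift/stop-gain/stop-loss rows
#'   (used when building evaluation sets; the final model trains with them).
#' @return Object of class \code{labeled_dataset}: list with \code{rows}
#'   (labeled feature data.frame) and \code{provenance} (named counts).
#' @export
assemble_dataset <- function(damaging, tolerated, freq_cutoff = 0.05,
                             exclude_fr_sc_sd = FALSE) {
  conflict <- intersect(unique(damaging$group_key),
                        unique(tolerated$group_key))
  if (length(conflict))
    stop("variant(s) labeled both damaging and tolerated: ",
         paste(utils::head(conflict, 5), collapse = ", "))
  prov <- c(initial = nrow(damaging) + nrow(tolerated))

  keep_d <- is.na(damaging$frequency) | damaging$frequency <= freq_cutoff
  prov["removed_freq_damaging"] <- sum(!keep_d)
  damaging <- damaging[keep_d, ]
  keep_t <- !is.na(tolerated$frequency) & tolerated$frequency > freq_cutoff
  prov["removed_freq_tolerated"] <- sum(!keep_t)
  tolerated <- tolerated[keep_t, ]

  dedup <- duplicated(tolerated[c("group_key", "transcript_id")])
  prov["removed_duplicate_tolerated"] <- sum(dedup)
  tolerated <- tolerated[!dedup, ]

  damaging$label <- "damaging"
  tolerated$label <- "tolerated"
  rows <- rbind(damaging, tolerated)

  if ("variant_class" %in% names(rows)) {
    syn <- rows$variant_class == "synonymous"
    prov["removed_syn"] <- sum(syn)
    rows <- rows[!syn, ]
    if (exclude_fr_sc_sd) {
      fr <- rows$variant_class %in% c("frameshift", "stop_gain", "stop_loss")
      prov["removed_frscsd"] <- sum(fr)
      rows <- rows[!fr, ]
    } else prov["removed_frscsd"] <- 0L
  } else {
    prov["removed_syn"] <- 0L
    prov["removed_frscsd"] <- 0L
  }
  prov["final"] <- nrow(rows)
  rownames(rows) <- NULL
  structure(list(rows = rows, provenance = as.list(prov)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$rows), "rows (",
      sum(x$rows$label == "damaging"), "damaging /",
      sum(x$rows$label == "tolerated"), "tolerated )\n")
  cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Cap the majority class for quasi-balanced sets
#'
#' Groups (not rows) of the majority class are randomly dropped until the
#' class ratio is at most \code{max_ratio}.
#'
#' @param ds A \code{labeled_dataset} or labeled data.frame.
#' @param max_ratio Maximum majority/minority row ratio.
#' @param seed RNG seed for the group subsample.
#' @return Same type as the input, with the majority class capped.
#' @export
balance_classes <- function(ds, max_ratio = 1.3, seed = NULL) {
  rows <- if (inherits(ds, "labeled_dataset")) ds$rows else ds
  n <- table(factor(rows$label, levels = CLASS_LEVELS))
  maj <- names(n)[which.max(n)]
  minr <- min(n)
  if (max(n) <= max_ratio * minr) return(ds)
  keep_rows <- .with_seed(seed, {
    g <- unique(rows$group_key[rows$label == maj])
    g <- sample(g)
    sizes <- table(rows$group_key[rows$label == maj])[g]
    k <- which(cumsum(sizes) <= max_ratio * minr)
    kept <- g[seq_len(if (length(k)) max(k) else 1L)]
    rows$label != maj | rows$group_key %in% kept
  })
  out <- rows[keep_rows, ]
  rownames(out) <- NULL
  if (inherits(ds, "labeled_dataset")) {
    ds$rows <- out
    ds$provenance$removed_balancing <- sum(!keep_rows)
    ds
  } else out
}

#' Grouped train/test split
#'
#' All rows sharing a \code{group_key} (the transcript isoforms of one
#' genomic variant) land on the same side.  Groups are shuffled under the
#' seed and assigned to the training side until its row fraction is as
#' close as possible to \code{train_fraction}.
#'
#' @param ds A \code{labeled_dataset} or data.frame with \code{group_key}.
#' @param train_fraction Target fraction of rows in the training set.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return List with data.frames \code{train} and \code{test}.
#' @export
split_grouped <- function(ds, train_fraction = 0.7, seed = NULL) {
  rows <- if (inherits(ds, "labeled_dataset")) ds$rows else ds
  groups <- unique(rows$group_key)
  if (length(groups) < 2L)
    stop("cannot split: fewer than two variant groups")
  order_g <- .with_seed(seed, sample(groups))
  sizes <- table(rows$group_key)[order_g]
  cum <- cumsum(sizes)
  k <- which.min(abs(cum / nrow(rows) - train_fraction))
  k <- min(max(k, 1L), length(groups) - 1L)
  train_groups <- order_g[seq_len(k)]
  in_train <- rows$group_key %in% train_groups
  list(train = rows[in_train, , drop = FALSE],
       test = rows[!in_train, , drop = FALSE])
}

#' Features-per-node (mtry) heuristic
#'
#' The default interprets the grid's heuristic entry as the standard
#' floor(log2(p)) + 1 over the number of features p; \code{"literal"}
#' evaluates the printed floor(log(trees)) + 1 form instead.
#'
#' @param n_features Number of predictor columns.
#' @param trees Number of trees (used by the literal form only).
#' @param mode \code{"log2features"} or \code{"literal"}.
#' @return Integer mtry.
#' @export
mtry_heuristic <- function(n_features, trees = 250L,
                           mode = c("log2features", "literal")) {
  mode <- match.arg(mode)
  if (mode == "literal") as.integer(floor(log(trees)) + 1)
  else as.integer(floor(log2(n_features)) + 1)
}

#' The published tuned hyperparameters
#'
#' Cross-validation on every training set selected the same optimum:
#' weight 0.1, 12 tiers, 250 trees, 2 features per node.
#' @return Named list (w, lambda, trees, mtry).
#' @export
default_params <- function()
  list(w = 0.1, lambda = 12L, trees = 250L, mtry = 2L)

#' The hyperparameter tuning grid
#'
#' @return data.frame over trees, mtry (NA = heuristic), lambda and w.
#' @export
default_grid <- function()
  expand.grid(trees = c(5L, 10L, 50L, 100L, 150L, 200L, 250L, 300L, 350L),
              mtry = c(NA_integer_, 2L, 4L),
              lambda = c(4L, 8L, 12L, 16L, 20L),
              w = c(0.5, 0.1))

#' Fit the damaging/tolerated classifier
#'
#' The core fitting function: a random forest (posterior = fraction of
#' trees voting damaging, averaged over leaves) or a logistic regression
#' on the same feature block.
#'
#' @param formula Model formula; the default uses every numeric feature
#'   column (bookkeeping columns \code{group_key}, \code{transcript_id},
#'   \code{cons_missing} are never used as predictors).
#' @param data Labeled feature data.frame or \code{labeled_dataset}.
#' @param method \code{"rf"} or \code{"lr"}.
#' @param trees,mtry Random-forest size and features per node; \code{mtry =
#'   NA} applies \code{\link{mtry_heuristic}}.
#' @param lambda,w PseAAC parameters the features were encoded with
#'   (recorded so scoring can refuse mismatched feature blocks).
#' @param seed RNG seed for the forest.
#' @param ... Passed to the underlying fitter.
#' @return Object of class \code{pseaac_clf} with \code{print},
#'   \code{summary}, \code{predict}, \code{coef} (lr) and \code{plot} (rf
#'   variable importance) methods.
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(n_variants = 300, seed = 7))
#' fit <- fit_classifier(data = sim$features, method = "rf", seed = 7)
#' predict(fit, sim$features[1:3, ])
#' }
#' @export
fit_classifier <- function(formula = label ~ ., data,
                           method = c("rf", "lr"), trees = 250L, mtry = 2L,
                           lambda = 12L, w = 0.1, seed = NULL, ...) {
  method <- match.arg(method)
  rows <- if (inherits(data, "labeled_dataset")) data$rows else data
  if (any(is.na(rows$label))) stop("all rows must carry a label")
  if (length(unique(rows$label)) < 2L)
    stop("training data contains a single class")
  feat_cols <- .numeric_feature_cols(rows)
  mf <- stats::model.frame(formula,
                           rows[c("label", feat_cols)])
  x <- mf[setdiff(names(mf), "label")]
  y <- factor(mf$label, levels = CLASS_LEVELS)
  if (is.na(mtry)) mtry <- mtry_heuristic(ncol(x), trees)
  fitobj <- .with_seed(seed, {
    if (method == "rf")
      randomForest::randomForest(x = x, y = y, ntree = trees,
                                 mtry = mtry, ...)
    else
      suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                  data = cbind(y = as.integer(y) - 1L, x),
                                  ...))
  })
  structure(list(method = method, fit = fitobj,
                 feature_order = names(x),
                 params = list(trees = if (method == "rf") trees else NA,
                               mtry = if (method == "rf") mtry else NA,
                               lambda = as.integer(lambda), w = w),
                 n = nrow(x), class_counts = table(y), seed = seed),
            class = "pseaac_clf")
}

#' @export
print.pseaac_clf <- function(x, ...) {
  cat("Coding-variant deleteriousness classifier (",
      if (x$method == "rf") "random forest" else "logistic regression",
      ")\n", sep = "")
  cat("  features:", length(x$feature_order),
      sprintf("(lambda = %d, w = %g)", x$params$lambda, x$params$w), "\n")
  if (x$method == "rf")
    cat("  trees:", x$params$trees, " mtry:", x$params$mtry, "\n")
  cat("  trained on", x$n, "rows (",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
summary.pseaac_clf <- function(object, ...) {
  print(object)
  if (object$method == "rf") {
    imp <- randomForest::importance(object$fit)
    top <- utils::head(imp[order(-imp[, 1]), , drop = FALSE], 10)
    cat("  top features by Gini decrease:\n")
    print(round(top, 3))
  } else {
    cat("  coefficient summary:\n")
    cf <- summary(object$fit)$coefficients
    print(cf[seq_len(min(10L, nrow(cf))), ])
  }
  invisible(object)
}

#' @export
coef.pseaac_clf <- function(object, ...) {
  if (object$method != "lr")
    stop("coefficients are defined for the logistic model only")
  stats::coef(object$fit)
}

#' @export
plot.pseaac_clf <- function(x, ...) {
  if (x$method == "rf") randomForest::varImpPlot(x$fit, main = "", ...)
  else plot(x$fit, ...)
  invisible(x)
}

#' Score feature vectors with a fitted classifier
#'
#' @param object A \code{pseaac_clf}.
#' @param newdata Feature data.frame with the columns the model was
#'   trained on (extra bookkeeping columns are ignored).
#' @param type \code{"prediction"} (class/score data.frame),
#'   \code{"prob"} (posterior of damaging) or \code{"class"}.
#' @param ... Unused.
#' @return See \code{type}; scores are posterior probabilities of the
#'   damaging class and \code{class} is damaging iff score >= 0.5.
#' @export
predict.pseaac_clf <- function(object, newdata,
                               type = c("prediction", "prob", "class"),
                               ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$feature_order, names(newdata))
  if (length(missing_cols))
    stop("feature mismatch: model was fitted with lambda = ",
         object$params$lambda, "; missing column(s) ",
         paste(utils::head(missing_cols, 4), collapse = ", "))
  x <- newdata[object$feature_order]
  p <- if (object$method == "rf")
    unname(stats::predict(object$fit, x, type = "prob")[, "damaging"])
  else
    unname(stats::predict(object$fit, x, type = "response"))
  cls <- ifelse(p >= 0.5, "damaging", "tolerated")
  switch(type,
         prob = p,
         class = cls,
         prediction = data.frame(class = cls, score = p,
                                 source = object$method,
                                 stringsAsFactors = FALSE))
}

#' Deleterious-by-rule shortcut for very short mutant sequences
#'
#' A mutant snippet shorter than lambda + 1 residues cannot be represented
#' in PseAAC; this only happens when a premature stop lands near the start
#' of the protein, and such variants are labeled deleterious outright.
#'
#' @param cc A \code{coding_change}.
#' @param lambda PseAAC tier count in force.
#' @return data.frame(class = "damaging", score = 1, source = "rule"), or
#'   \code{NULL} to signal pass-through to the classifier.
#' @export
rule_score <- function(cc, lambda = 12L) {
  if (cc$variant_class == "synonymous") return(NULL)
  if (cc$protein_len_mut == 0L)
    return(data.frame(class = "damaging", score = 1, source = "rule",
                      stringsAsFactors = FALSE))
  sn <- extract_snippets(cc)
  if (sn$mutant$L < lambda + 1L)
    data.frame(class = "damaging", score = 1, source = "rule",
               stringsAsFactors = FALSE)
  else NULL
}

#' Save / load a fitted classifier with its feature manifest
#'
#' The file carries a format version and the feature_order manifest;
#' loading refuses files written by an incompatible version, and scoring
#' with a model whose manifest does not match the feature block fails
#' (see \code{\link{predict.pseaac_clf}}).
#'
#' @param object A \code{pseaac_clf}.
#' @param path Output file.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "pseaac_clf"))
  saveRDS(list(format = "pseaac_clf", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pseaac_clf") || !identical(obj$version, 1L))
    stop("not a recognized classifier file (or incompatible version)")
  obj$model
}

#' Grouped k-fold cross-validated hyperparameter search
#'
#' Because lambda changes the feature dimensionality, the search works
#' through an \code{encoder} callback that re-encodes the training rows
#' for each (lambda, w) pair.  Selection is by mean CV accuracy; ties are
#' broken by higher AUC, then by smaller model (fewer trees, smaller
#' lambda).
#'
#' @param encoder function(lambda, w) returning a labeled feature
#'   data.frame with \code{group_key}.
#' @param grid data.frame of candidate (trees, mtry, lambda, w); NA mtry
#'   means the heuristic.  Default \code{\link{default_grid}}.
#' @param folds Number of grouped CV folds.
#' @param seed RNG seed controlling fold assignment and forests.
#' @return List: \code{best} (named list trees/mtry/lambda/w) and
#'   \code{results} (the grid with cv_accuracy and cv_auc columns).
#' @export
tune_classifier <- function(encoder, grid = default_grid(), folds = 10L,
                            seed = NULL) {
  grid$cv_accuracy <- NA_real_
  grid$cv_auc <- NA_real_
  enc_cache <- list()
  for (r in seq_len(nrow(grid))) {
    key <- paste(grid$lambda[r], grid$w[r])
    if (is.null(enc_cache[[key]])) enc_cache[[key]] <- encoder(grid$lambda[r],
                                                              grid$w[r])
    data <- enc_cache[[key]]
    groups <- unique(data$group_key)
    fold_of <- .with_seed(seed,
      stats::setNames(sample(rep_len(seq_len(folds), length(groups))),
                      sample(groups)))
    acc <- auc <- numeric(folds)
    for (f in seq_len(folds)) {
      test_idx <- fold_of[data$group_key] == f
      tr <- data[!test_idx, ]; te <- data[test_idx, ]
      if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L)
        stop("fold ", f, " contains a single class; use fewer folds")
      fit <- fit_classifier(data = tr, method = "rf",
                            trees = grid$trees[r], mtry = grid$mtry[r],
                            lambda = grid$lambda[r], w = grid$w[r],
                            seed = if (is.null(seed)) NULL else seed + f)
      p <- predict(fit, te, type = "prob")
      acc[f] <- mean((p >= 0.5) == (te$label == "damaging"))
      auc[f] <- as.numeric(pROC::auc(pROC::roc(
        response = factor(te$label, levels = CLASS_LEVELS),
        predictor = p, quiet = TRUE, direction = "<")))
    }
    grid$cv_accuracy[r] <- mean(acc)
    grid$cv_auc[r] <- mean(auc)
  }
  ord <- order(-grid$cv_accuracy, -grid$cv_auc, grid$trees, grid$lambda)
  best <- grid[ord[1], ]
  mtry <- if (is.na(best$mtry))
    mtry_heuristic(20L + 2L * best$lambda + 6L, best$trees) else best$mtry
  list(best = list(trees = best$trees, mtry = mtry,
                   lambda = best$lambda, w = best$w),
       results = grid)
}
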
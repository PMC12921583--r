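## Supervised UMAP embedding and random-forest classification under Monte
## Carlo cross-validation.

.feature_matrix <- function(table, feature_subset = NULL) {
  df <- as.data.frame(table)
  if (!"class" %in% names(df)) stop("table needs a 'class' column")
  y <- factor(df$class)
  X <- df[vapply(df, is.numeric, TRUE)]
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, names(X))
    if (length(missing))
      stop("unknown features: ", paste(missing, collapse = ", "))
    X <- X[feature_subset]
  }
  list(X = as.matrix(X), y = y)
}

#' Supervised UMAP embedding of a feature table
#'
#' Two-dimensional UMAP embedding of the numeric features, by default in
#' supervised mode (the class labels steer the layout, as used to
#' visualise class separation of the trapped-particle cohorts). Defaults
#' follow the study protocol: 50 nearest neighbours and minimum distance
#' 0. Features are z-scaled before embedding. The embedding is
#' deterministic given `seed` (SGD runs single-threaded).
#'
#' @param table a `feature_table` (numeric columns + `class`).
#' @param n_neighbors number of nearest neighbours; clamped to
#'   `nrow - 1` with a warning when the table is smaller.
#' @param min_dist minimum embedding distance.
#' @param supervised use the class labels during embedding (requires at
#'   least 2 classes).
#' @param seed integer seed.
#' @param feature_subset optional character vector of feature columns.
#' @return object of class `"trap_umap"`: `coords` (n x 2 matrix),
#'   `labels`, `settings`.
#' @export
embed_umap <- function(table, n_neighbors = 50, min_dist = 0.0,
                       supervised = TRUE, seed = 1, feature_subset = NULL) {
  fm <- .feature_matrix(table, feature_subset)
  n <- nrow(fm$X)
  if (supervised && nlevels(droplevels(fm$y)) < 2)
    stop("supervised embedding needs at least 2 classes")
  if (n_neighbors > n - 1) {
    warning("n_neighbors reduced to n - 1 = ", n - 1)
    n_neighbors <- n - 1
  }
  set.seed(seed)
  coords <- uwot::umap(scale(fm$X), n_neighbors = n_neighbors,
                       min_dist = min_dist,
                       y = if (supervised) fm$y else NULL,
                       n_threads = 1, n_sgd_threads = 1)
  structure(list(coords = coords, labels = fm$y,
                 settings = list(n_neighbors = n_neighbors,
                                 min_dist = min_dist,
                                 supervised = supervised, seed = seed,
                                 features = colnames(fm$X))),
            class = "trap_umap")
}

#' @export
print.trap_umap <- function(x, ...) {
  cat(sprintf("UMAP embedding: %d points, %d classes (n_neighbors = %d, min_dist = %g, %s)\n",
              nrow(x$coords), nlevels(x$labels), x$settings$n_neighbors,
              x$settings$min_dist,
              if (x$settings$supervised) "supervised" else "unsupervised"))
  invisible(x)
}

#' @export
plot.trap_umap <- function(x, col = NULL, pch = 19, ...) {
  k <- nlevels(x$labels)
  col <- col %||% grDevices::hcl.colors(max(k, 2), "Dark 3")
  graphics::plot(x$coords, col = col[as.integer(x$labels)], pch = pch,
                 xlab = "UMAP 1", ylab = "UMAP 2", ...)
  graphics::legend("topright", legend = levels(x$labels),
                   col = col[seq_len(k)], pch = pch, bty = "n", cex = 0.85)
  invisible(x)
}

## stratified train/test split; returns train indices
.stratified_split <- function(y, test_fraction) {
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, length(idx) - n_test))
  }
  sort(train)
}

#' Random-forest classification under Monte Carlo cross-validation
#'
#' Repeats `n_iter` times: draw a fresh random 80/20 train/test split
#' (stratified by class by default), train a random forest on the training
#' rows, and record the test-set accuracy, the forest's out-of-bag error
#' and its normalized (sum-to-one) impurity-decrease feature importances.
#' One master seed deterministically spawns the per-iteration split and
#' forest seeds, so a full run is bit-reproducible.
#'
#' @param table a `feature_table`.
#' @param n_iter number of Monte Carlo iterations (default 300).
#' @param test_fraction fraction held out for testing, in `(0, 0.5]`.
#' @param forest_settings list with any of `ntree`, `mtry`, `nodesize`,
#'   `maxnodes` passed to [randomForest::randomForest()].
#' @param feature_subset optional character vector of feature columns.
#' @param stratified draw splits stratified by class (default); when
#'   `FALSE`, a split missing a class in training is redrawn (count
#'   reported in the result).
#' @param seed master seed.
#' @return object of class `"trap_mccv"`: `accuracies` (length `n_iter`),
#'   `mean_acc`, `min_acc`, `max_acc`, `oob_errors`, `importances`
#'   (`n_iter` x p matrix, rows sum to 1), `mean_importance`, `settings`,
#'   `n_resampled`.
#' @examples
#' tab <- data.frame(a = c(rnorm(10), rnorm(10, 6)), b = rnorm(20),
#'                   class = rep(c("u", "v"), each = 10))
#' mccv(tab, n_iter = 20, seed = 1)
#' @export
mccv <- function(table, n_iter = 300, test_fraction = 0.2,
                 forest_settings = list(), feature_subset = NULL,
                 stratified = TRUE, seed = 1) {
  fm <- .feature_matrix(table, feature_subset)
  y <- droplevels(fm$y)
  if (any(tabulate(y) < 2)) stop("every class needs at least 2 rows")
  if (test_fraction <= 0 || test_fraction > 0.5)
    stop("test_fraction must be in (0, 0.5]")
  fs <- utils::modifyList(list(ntree = 300, mtry = NULL, nodesize = 1,
                               maxnodes = NULL), forest_settings)
  p <- ncol(fm$X)
  mtry <- fs$mtry %||% max(1, floor(sqrt(p)))

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, 2 * n_iter)
  acc <- oob <- numeric(n_iter)
  imp <- matrix(0, n_iter, p, dimnames = list(NULL, colnames(fm$X)))
  n_resampled <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[2 * i - 1])
    repeat {
      train <- if (stratified) .stratified_split(y, test_fraction)
      else sort(sample(seq_along(y), round(length(y) * (1 - test_fraction))))
      if (nlevels(droplevels(y[train])) == nlevels(y)) break
      n_resampled <- n_resampled + 1L
    }
    test <- setdiff(seq_along(y), train)
    set.seed(iter_seeds[2 * i])
    args <- list(x = fm$X[train, , drop = FALSE], y = y[train],
                 ntree = fs$ntree, mtry = min(mtry, p),
                 nodesize = fs$nodesize)
    if (!is.null(fs$maxnodes)) args$maxnodes <- fs$maxnodes
    rf <- do.call(randomForest::randomForest, args)
    pred <- stats::predict(rf, fm$X[test, , drop = FALSE])
    acc[i] <- mean(pred == y[test])
    oob[i] <- unname(rf$err.rate[fs$ntree, "OOB"])
    gi <- rf$importance[, "MeanDecreaseGini"]
    imp[i, ] <- if (sum(gi) > 0) gi / sum(gi) else 1 / p
  }
  structure(list(accuracies = acc, mean_acc = mean(acc), min_acc = min(acc),
                 max_acc = max(acc), oob_errors = oob, importances = imp,
                 mean_importance = colMeans(imp),
                 n_resampled = n_resampled,
                 settings = list(n_iter = n_iter,
                                 test_fraction = test_fraction,
                                 forest = fs, mtry = min(mtry, p),
                                 stratified = stratified,
                                 features = colnames(fm$X), seed = seed,
                                 n_rows = length(y),
                                 classes = levels(y))),
            class = "trap_mccv")
}

#' @export
print.trap_mccv <- function(x, ...) {
  cat(sprintf("MCCV random forest: %d iterations on %d rows, %d classes\n",
              x$settings$n_iter, x$settings$n_rows,
              length(x$settings$classes)))
  cat(sprintf("  accuracy: mean %.3f  min %.3f  max %.3f;  mean OOB error %.3f\n",
              x$mean_acc, x$min_acc, x$max_acc, mean(x$oob_errors)))
  invisible(x)
}

#' @export
summary.trap_mccv <- function(object, ...) {
  imp <- sort(object$mean_importance, decreasing = TRUE)
  structure(list(mean_acc = object$mean_acc, min_acc = object$min_acc,
                 max_acc = object$max_acc, sd_acc = stats::sd(object$accuracies),
                 mean_oob = mean(object$oob_errors),
                 importance = imp, settings = object$settings),
            class = "summary.trap_mccv")
}

#' @export
print.summary.trap_mccv <- function(x, ...) {
  cat(sprintf("MCCV summary (%d iterations): accuracy %.3f +/- %.3f (min %.3f, max %.3f)\n",
              x$settings$n_iter, x$mean_acc, x$sd_acc, x$min_acc, x$max_acc))
  cat(sprintf("mean out-of-bag error: %.3f\n\nMean feature importances:\n",
              x$mean_oob))
  print(round(x$importance, 4))
  invisible(x)
}

#' @export
plot.trap_mccv <- function(x, which = c("accuracy", "importance"), ...) {
  which <- match.arg(which)
  if (which == "accuracy") {
    graphics::plot(x$accuracies, type = "l", col = "grey40",
                   xlab = "MCCV iteration", ylab = "Test accuracy",
                   ylim = c(0, 1), ...)
    graphics::abline(h = x$mean_acc, col = "red", lty = 2)
  } else {
    imp <- sort(x$mean_importance)
    op <- graphics::par(mar = c(4, 9, 1, 1))
    on.exit(graphics::par(op))
    graphics::barplot(imp, horiz = TRUE, las = 1,
                      xlab = "Mean feature importance", ...)
  }
  invisible(x)
}

#' Grid search over forest settings and feature subsets
#'
#' Exhaustively evaluates every combination of forest hyperparameters and
#' candidate feature subsets by mean MCCV accuracy at a reduced iteration
#' count. Ties are broken in favour of fewer features, then fewer trees.
#'
#' @param table a `feature_table`.
#' @param grid data.frame of forest settings, columns among `ntree`,
#'   `mtry`, `nodesize`, `maxnodes` (default: trees in 100/300/500 crossed
#'   with mtry sqrt(p) or p).
#' @param feature_subsets list of character vectors (`NULL` entry = all
#'   features).
#' @param n_iter MCCV iterations per configuration (default 50).
#' @param test_fraction,seed as in [mccv()].
#' @return list with `best` (settings, features, mean accuracy, the full
#'   [mccv()] result rerun at the same n_iter) and `report` (one row per
#'   configuration).
#' @export
tune_mccv <- function(table, grid = NULL, feature_subsets = list(NULL),
                      n_iter = 50, test_fraction = 0.2, seed = 1) {
  fm <- .feature_matrix(table)
  p <- ncol(fm$X)
  grid <- grid %||% expand.grid(ntree = c(100, 300, 500),
                                mtry = c(floor(sqrt(p)), p))
  if (nrow(grid) == 0 || length(feature_subsets) == 0)
    stop("empty tuning grid")
  rows <- list(); results <- list()
  cfg_i <- 0
  for (si in seq_along(feature_subsets)) {
    sub <- feature_subsets[[si]]
    nfeat <- if (is.null(sub)) p else length(sub)
    for (gi in seq_len(nrow(grid))) {
      cfg_i <- cfg_i + 1
      fs <- as.list(grid[gi, , drop = FALSE])
      res <- mccv(table, n_iter = n_iter, test_fraction = test_fraction,
                  forest_settings = fs, feature_subset = sub, seed = seed)
      results[[cfg_i]] <- res
      rows[[cfg_i]] <- data.frame(
        subset = si, n_features = nfeat,
        ntree = fs$ntree %||% 300, mtry = res$settings$mtry,
        mean_acc = res$mean_acc, sd_acc = stats::sd(res$accuracies))
    }
  }
  report <- do.call(rbind, rows)
  ord <- order(-report$mean_acc, report$n_features, report$ntree)
  best_i <- ord[1]
  list(best = list(settings = as.list(grid[(best_i - 1) %% nrow(grid) + 1, ,
                                           drop = FALSE]),
                   features = feature_subsets[[report$subset[best_i]]],
                   mean_acc = report$mean_acc[best_i],
                   result = results[[best_i]]),
       report = report)
}

#' Rank features by mean importance across MCCV iterations
#'
#' @param result a [mccv()] result, or a list of them (importances are
#'   pooled; features never present in any run's subset are reported as
#'   unused).
#' @param all_features optional character vector of the full feature set,
#'   so that features excluded from every subset can be listed as unused.
#' @return list with `ranking` (data.frame: feature, mean_importance,
#'   ordered decreasing) and `unused` (character).
#' @export
importance_summary <- function(result, all_features = NULL) {
  results <- if (inherits(result, "trap_mccv")) list(result) else result
  imp_all <- list()
  for (r in results) {
    stopifnot(inherits(r, "trap_mccv"))
    imp_all[[length(imp_all) + 1]] <-
      colMeans(r$importances) * r$settings$n_iter
  }
  feats <- unique(unlist(lapply(imp_all, names)))
  total <- stats::setNames(numeric(length(feats)), feats)
  n_tot <- 0
  for (i in seq_along(imp_all)) {
    total[names(imp_all[[i]])] <- total[names(imp_all[[i]])] + imp_all[[i]]
    n_tot <- n_tot + results[[i]]$settings$n_iter
  }
  ranking <- data.frame(feature = feats,
                        mean_importance = unname(total[feats]) / n_tot)
  ranking <- ranking[order(-ranking$mean_importance), ]
  rownames(ranking) <- NULL
  unused <- if (is.null(all_features)) character(0)
  else setdiff(all_features, feats)
  list(ranking = ranking, unused = unused)
}
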
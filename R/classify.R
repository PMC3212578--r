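# Sample clustering and classification on pathway activity profiles.

#' Hierarchical clustering of activity profiles
#'
#' Complete-linkage clustering on Euclidean distances, either of samples
#' (columns, profiles over pathways) or of pathways (rows, profiles over
#' samples).
#'
#' @param activity pathways x samples matrix.
#' @param on `"samples"` or `"pathways"`.
#' @param k optional number of flat clusters to cut the tree into.
#' @return list with `hclust` (the dendrogram), `clusters` (named integer
#'   vector when `k` is given, else `NULL`) and `on`.
#' @export
hier_cluster <- function(activity, on = c("samples", "pathways"), k = NULL) {
  .check_matrix(activity, "activity matrix")
  on <- match.arg(on)
  M <- if (on == "samples") t(activity) else activity
  if (nrow(M) < 2L) .stopf("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(M, method = "euclidean"),
                      method = "complete")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k)
  list(hclust = hc, clusters = clusters, on = on)
}

#' Select discriminating pathways by t-test P-value
#'
#' Pathways whose activity differs between the two groups at P < `p_cut`
#' (two-sided Welch t-test), ordered by P.
#'
#' @param activity pathways x samples matrix.
#' @param labels sample group labels (two groups).
#' @param p_cut selection threshold.
#' @param groups optional group order.
#' @return character vector of pathway names ordered by increasing P.
#' @export
select_pathways <- function(activity, labels, p_cut = 1e-5, groups = NULL) {
  dt <- t_test_pathways(activity, labels, groups)
  sel <- dt$pathway[dt$p < p_cut]
  if (!length(sel))
    .stopf("no pathway passes p_cut = %g; consider a looser cut", p_cut)
  sel
}

#' Leave-one-out cross-validated SVM classification
#'
#' Trains a linear-kernel support vector machine (cost C, default 1) on all
#' samples but one and predicts the left-out sample, repeating until every
#' sample has been left out once; accuracy is the fraction of correct
#' predictions.  Discriminating pathways can be fixed (`pathways`), selected
#' once on the full data (`selection_mode = "global"`, the historically
#' common but leakage-prone procedure), or re-selected inside every training
#' fold (`"per_fold"`, the default, which never sees the left-out sample).
#'
#' @param activity pathways x samples matrix.
#' @param labels sample group labels (two groups, each with >= 3 samples).
#' @param pathways optional fixed pathway list used as features.
#' @param selection_mode `"per_fold"` or `"global"` (ignored when `pathways`
#'   is given).
#' @param p_cut selection threshold for [select_pathways()].
#' @param cost SVM regularization parameter C.
#' @param groups optional group order.
#' @return a `loocv_report`: list with `accuracy`, `predicted`, `truth`
#'   (named character vectors), `mode`, `p_cut`, `cost` and `selected`
#'   (character vector, or per-fold list for `"per_fold"`).
#' @export
loocv_classify <- function(activity, labels, pathways = NULL,
                           selection_mode = c("per_fold", "global"),
                           p_cut = 1e-5, cost = 1, groups = NULL) {
  .check_matrix(activity, "activity matrix")
  selection_mode <- match.arg(selection_mode)
  f <- .align_labels(labels, colnames(activity), groups)
  if (any(table(f) < 3L))
    .stopf("each class needs at least 3 samples for leave-one-out CV")
  samples <- names(f)
  act <- activity[, samples, drop = FALSE]
  mode <- if (!is.null(pathways)) "fixed" else selection_mode
  sel_global <- switch(mode,
    fixed  = intersect(pathways, rownames(act)),
    global = select_pathways(act, f, p_cut),
    NULL)
  if (mode %in% c("fixed", "global") && length(sel_global) == 0L)
    .stopf("no usable classifier pathways")
  preds <- character(length(samples))
  names(preds) <- samples
  per_fold <- vector("list", length(samples))
  names(per_fold) <- samples
  for (i in seq_along(samples)) {
    train <- samples[-i]
    y <- f[train]
    if (nlevels(droplevels(y)) < 2L)
      .stopf("training fold for sample '%s' contains a single class",
             samples[i])
    sel <- if (mode == "per_fold")
      select_pathways(act[, train, drop = FALSE], y, p_cut)
    else sel_global
    per_fold[[i]] <- sel
    Xtr <- t(act[sel, train, drop = FALSE])
    fit <- e1071::svm(Xtr, y, kernel = "linear", cost = cost, scale = FALSE)
    Xte <- t(act[sel, samples[i], drop = FALSE])
    preds[i] <- as.character(stats::predict(fit, Xte))
  }
  truth <- stats::setNames(as.character(f), samples)
  structure(list(accuracy = mean(preds == truth),
                 predicted = preds, truth = truth,
                 mode = mode, p_cut = p_cut, cost = cost,
                 selected = if (mode == "per_fold") per_fold
                            else sel_global),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out SVM classification (linear kernel, C = %g, %s pathway selection)\n",
              x$cost, x$mode))
  cat(sprintf("  %d samples, accuracy = %.3f (%d correct)\n",
              length(x$truth), x$accuracy,
              sum(x$predicted == x$truth)))
  invisible(x)
}
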
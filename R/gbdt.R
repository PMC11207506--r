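# R-facing wrapper around the compiled gradient-boosted tree learner
# (binary logistic loss, exact greedy splits, no subsampling - fully
# deterministic for fixed data and hyperparameters).

#' Fit a gradient-boosted tree binary classifier
#'
#' @param X Numeric feature matrix (n x p).
#' @param y Binary 0/1 response vector.
#' @param nrounds Number of boosting rounds.
#' @param eta Learning rate.
#' @param max_depth Maximum tree depth.
#' @param lambda L2 leaf regularisation.
#' @param min_child_weight Minimum hessian sum per leaf.
#' @return An object of class `qappg_gbdt`.
#' @export
gbdt_train <- function(X, y, nrounds = 100L, eta = 0.3, max_depth = 3L,
                       lambda = 1, min_child_weight = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2)
    stop("gbdt_train: degenerate training: labels contain a single class")
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  base_margin <- log(p0 / (1 - p0))
  trees <- gbdt_fit_cpp(X, y, as.integer(nrounds), eta, as.integer(max_depth),
                        lambda, min_child_weight, base_margin)
  structure(list(trees = trees, eta = eta, base_margin = base_margin,
                 nrounds = nrounds, max_depth = max_depth, lambda = lambda,
                 feature_names = colnames(X)),
            class = "qappg_gbdt")
}

#' @param object A `qappg_gbdt` model.
#' @param newdata Numeric matrix with the training column order.
#' @param type `"response"` (probability) or `"margin"` (log-odds; does not
#'   saturate, so it ranks confidently classified rows where probabilities
#'   round to 0 or 1).
#' @param ... Unused.
#' @return Predicted probabilities in `[0, 1]`, or margins.
#' @rdname gbdt_train
#' @export
predict.qappg_gbdt <- function(object, newdata,
                               type = c("response", "margin"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  as.numeric(gbdt_predict_cpp(object$trees, newdata, object$eta,
                              object$base_margin, type == "margin"))
}
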
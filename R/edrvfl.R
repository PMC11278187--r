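# Ensemble deep random vector functional link (edRVFL) classifier.
#
# Architecture: a stack of hidden layers with frozen random weights (drawn
# uniformly from [-1, 1] once, never trained), direct links (the raw
# standardized input concatenated into every layer's design matrix), and one
# closed-form ridge output head per layer. Prediction aggregates the
# per-layer heads (mean score or majority vote).
#
#   H_1 = act(X W_1 + b_1)            D_1 = [H_1 | X | 1]
#   H_l = act([H_{l-1} | X] W_l + b_l)  D_l = [H_l | X | 1]   (l >= 2)
#   head_l: W = (D'D + I/C)^{-1} D'Y  (inverse_c convention; direct_lambda
#                                      uses D'D + C I), Y one-hot targets.
#
# The constant-1 design column plays the role of the output bias; the
# trailing identity block of the ridge solve therefore also penalizes it,
# which is the convention adopted here.

ACTIVATIONS <- list(
  tanh = tanh,
  relu = function(x) pmax(x, 0),
  sigmoid = function(x) 1 / (1 + exp(-x))
)

#' Control parameters for the edRVFL classifier
#'
#' Defaults are the operating point used throughout: 10 enhancement nodes
#' per layer, regularization parameter 100, 10 hidden layers, tanh
#' activation.
#'
#' @param n_nodes enhancement (hidden) nodes per layer; 0 gives pure direct
#'   links (plain ridge on the inputs).
#' @param reg_c positive regularization parameter C. Under
#'   `ridge_convention = "inverse_c"` the penalty is `I/C` (large C = weak
#'   regularization, the dominant RVFL convention); under `"direct_lambda"`
#'   the penalty is `C * I`.
#' @param n_layers number of stacked hidden layers (>= 1).
#' @param activation one of `"tanh"`, `"relu"`, `"sigmoid"`.
#' @param aggregation `"mean_score"` (average of per-layer score matrices) or
#'   `"majority_vote"` (per-layer argmax, vote shares returned).
#' @param bagging_fraction fraction in (0, 1] of training rows each layer's
#'   head is fitted on; 1 means every layer sees all rows.
#' @param ridge_convention see `reg_c`.
#' @return an `edrvfl_control` list.
#' @export
edrvfl_control <- function(n_nodes = 10L, reg_c = 100, n_layers = 10L,
                           activation = c("tanh", "relu", "sigmoid"),
                           aggregation = c("mean_score", "majority_vote"),
                           bagging_fraction = 1.0,
                           ridge_convention = c("inverse_c", "direct_lambda")) {
  n_nodes <- as.integer(n_nodes); n_layers <- as.integer(n_layers)
  if (n_nodes < 0L) stopf("n_nodes must be >= 0")
  if (n_layers < 1L) stopf("n_layers must be >= 1")
  if (!is.numeric(reg_c) || reg_c <= 0) stopf("reg_c must be positive")
  if (bagging_fraction <= 0 || bagging_fraction > 1)
    stopf("bagging_fraction must be in (0, 1]")
  structure(list(n_nodes = n_nodes, reg_c = reg_c, n_layers = n_layers,
                 activation = match.arg(activation),
                 aggregation = match.arg(aggregation),
                 bagging_fraction = bagging_fraction,
                 ridge_convention = match.arg(ridge_convention)),
            class = "edrvfl_control")
}

# draw the frozen random layers for input dimension d
init_layers <- function(d, control, seed) {
  with_seed(seed, lapply(seq_len(control$n_layers), function(l) {
    d_in <- if (l == 1L) d else control$n_nodes + d
    list(W = matrix(stats::runif(d_in * control$n_nodes, -1, 1), d_in, control$n_nodes),
         b = stats::runif(control$n_nodes, -1, 1))
  }))
}

# per-layer design blocks D_1..D_L for standardized input X
hidden_stack <- function(layers, X, activation, n_nodes) {
  act <- ACTIVATIONS[[activation]]
  one <- matrix(1, nrow(X), 1)
  out <- vector("list", length(layers))
  H <- NULL
  for (l in seq_along(layers)) {
    if (n_nodes > 0L) {
      Zin <- if (l == 1L) X else cbind(H, X)
      H <- act(sweep(Zin %*% layers[[l]]$W, 2, layers[[l]]$b, "+"))
      out[[l]] <- cbind(H, X, one)
    } else {
      out[[l]] <- cbind(X, one)
    }
  }
  out
}

ridge_solve <- function(D, Y, reg_c, convention) {
  lambda <- if (convention == "inverse_c") 1 / reg_c else reg_c
  A <- crossprod(D) + diag(lambda, ncol(D))
  # A is symmetric positive definite by construction (lambda > 0)
  ch <- chol(A)
  backsolve(ch, forwardsolve(t(ch), crossprod(D, Y)))
}

#' Fit an ensemble deep RVFL classifier
#'
#' Trains the closed-form classifier: features are standardized (training
#' mean/SD), labels one-hot encoded, the frozen random hidden stack is
#' built, and each layer's output head solves a ridge system exactly. No
#' iterative optimization is involved; the fit is deterministic given
#' `(x, y, control, seed)`.
#'
#' @param x numeric feature matrix (rows = samples) or, for the formula
#'   method, a model formula.
#' @param y factor or character vector of class labels (>= 2 classes
#'   present).
#' @param control an [edrvfl_control()].
#' @param seed integer seed for the frozen random weights (and the per-layer
#'   row subsamples when `bagging_fraction < 1`).
#' @param ... passed between methods.
#' @return an object of class `"edrvfl"` with components `control`,
#'   `classes`, `layers`, `heads`, `center`/`scale` (standardizer), `seed`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- edrvfl(x, y, seed = 7)
#' table(predict(fit, x), y)
#' @export
edrvfl <- function(x, ...) UseMethod("edrvfl")

#' @rdname edrvfl
#' @export
edrvfl.default <- function(x, y, control = edrvfl_control(), seed = 1L, ...) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stopf("`x` must be a numeric matrix")
  if (nrow(x) < 2L) stopf("need at least 2 samples")
  if (nrow(x) != length(y)) stopf("`x` and `y` lengths differ")
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stopf("`y` must contain at least 2 classes")
  if (anyNA(x) || any(!is.finite(x))) stopf("`x` contains non-finite values")

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  Y <- outer(as.integer(y), seq_along(classes), function(i, j) as.numeric(i == j))

  layers <- init_layers(ncol(x), control, seed)
  D <- hidden_stack(layers, Xs, control$activation, control$n_nodes)
  n <- nrow(Xs)
  heads <- lapply(seq_along(D), function(l) {
    rows <- if (control$bagging_fraction < 1) {
      with_seed(child_seed(seed, l), {
        k <- max(2L, as.integer(round(control$bagging_fraction * n)))
        sort(sample.int(n, k))
      })
    } else seq_len(n)
    ridge_solve(D[[l]][rows, , drop = FALSE], Y[rows, , drop = FALSE],
                control$reg_c, control$ridge_convention)
  })

  structure(list(control = control, classes = classes, layers = layers,
                 heads = heads, center = center, scale = scale_,
                 seed = as.integer(seed), n_train = n, d = ncol(x),
                 call = match.call()),
            class = "edrvfl")
}

#' @rdname edrvfl
#' @param formula model formula; the response is the class label.
#' @param data data.frame holding the formula's variables.
#' @export
edrvfl.formula <- function(formula, data, control = edrvfl_control(),
                           seed = 1L, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- edrvfl.default(x, y, control = control, seed = seed, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

edrvfl_design <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object$d)
    stopf("newdata has %d columns; model expects %d", ncol(x), object$d)
  Xs <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  hidden_stack(object$layers, Xs, object$control$activation, object$control$n_nodes)
}

#' Predict from a fitted edRVFL model
#'
#' `type = "class"` returns labels (argmax of the aggregated scores, ties
#' broken toward the class earliest in `object$classes`); `type = "score"`
#' returns the per-class aggregate score matrix. Under `mean_score`
#' aggregation scores are the average of the per-layer head outputs; under
#' `majority_vote` they are per-class vote shares (rows sum to 1).
#'
#' @param object fitted `"edrvfl"` model.
#' @param newdata numeric feature matrix (or data.frame for formula fits).
#' @param type `"class"` or `"score"`.
#' @param ... unused.
#' @return factor of labels, or a numeric score matrix with one column per
#'   class.
#' @export
predict.edrvfl <- function(object, newdata,
                           type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$heads)) stopf("model has no fitted output heads")
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    newdata <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  D <- edrvfl_design(object, newdata)
  per_layer <- lapply(seq_along(D), function(l) D[[l]] %*% object$heads[[l]])
  L <- length(per_layer)
  scores <- if (object$control$aggregation == "mean_score") {
    Reduce(`+`, per_layer) / L
  } else {
    votes <- matrix(0, nrow(per_layer[[1]]), length(object$classes))
    for (s in per_layer) {
      win <- max.col(s, ties.method = "first")
      votes[cbind(seq_len(nrow(s)), win)] <- votes[cbind(seq_len(nrow(s)), win)] + 1
    }
    votes / L
  }
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.edrvfl <- function(x, ...) {
  cat("Ensemble deep RVFL classifier\n")
  cat(sprintf("  layers: %d, nodes/layer: %d, activation: %s\n",
              x$control$n_layers, x$control$n_nodes, x$control$activation))
  cat(sprintf("  ridge C = %g (%s), aggregation: %s\n",
              x$control$reg_c, x$control$ridge_convention, x$control$aggregation))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained on %d samples, %d features (seed %d)\n",
              x$n_train, x$d, x$seed))
  invisible(x)
}

#' @export
summary.edrvfl <- function(object, ...) {
  head_norms <- vapply(object$heads, function(W) sqrt(sum(W^2)), 0)
  out <- list(control = object$control, classes = object$classes,
              n_train = object$n_train, d = object$d,
              head_frobenius = head_norms)
  class(out) <- "summary.edrvfl"
  out
}

#' @export
print.summary.edrvfl <- function(x, ...) {
  cat(sprintf("edRVFL: %d layers x %d nodes, %d classes, %d training samples\n",
              x$control$n_layers, x$control$n_nodes, length(x$classes), x$n_train))
  cat("Per-layer output-head Frobenius norms:\n")
  print(round(x$head_frobenius, 4))
  invisible(x)
}

#' Output-head coefficients of an edRVFL model
#'
#' @param object fitted `"edrvfl"` model.
#' @param ... unused.
#' @return list (one element per layer) of head weight matrices; rows are
#'   design columns (hidden nodes, then direct links, then the constant
#'   bias column), columns are classes.
#' @export
coef.edrvfl <- function(object, ...) {
  lapply(object$heads, function(W) {
    colnames(W) <- object$classes
    W
  })
}
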
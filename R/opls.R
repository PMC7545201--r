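# OPLS-DA after Trygg & Wold's O-PLS: a single predictive component for a
# two-class response, preceded by removal of n_ortho X-components orthogonal
# to the response. Written from first principles on purpose — this, not a
# wrapped library call, is the package's modelling core.

#' Learn a column scaling from training rows
#'
#' @param X numeric matrix (training rows only).
#' @param mode `"none"`, `"center"`, `"pareto"` (divisor sqrt(sd)) or
#'   `"unit_variance"` (divisor sd). Zero-sd columns get divisor 1 and are
#'   counted in `$n_zero_sd` (a warning is emitted unless
#'   `options(metabopls.warn_zero_sd = FALSE)`).
#' @return object of class `scaling_spec` with `$center` and `$divisor`.
#' @export
learn_scaling <- function(X, mode = c("unit_variance", "pareto", "center",
                                      "none")) {
  mode <- match.arg(mode)
  p <- ncol(X)
  center <- if (mode == "none") rep(0, p) else colMeans(X)
  divisor <- rep(1, p)
  n_zero <- 0L
  if (mode %in% c("pareto", "unit_variance")) {
    sdv <- col_sds(X)
    zero <- sdv == 0
    n_zero <- sum(zero)
    if (n_zero && isTRUE(getOption("metabopls.warn_zero_sd", TRUE)))
      warning(sprintf("%d zero-variance column(s); divisor set to 1", n_zero),
              call. = FALSE)
    sdv[zero] <- 1
    divisor <- if (mode == "pareto") sqrt(sdv) else sdv
  }
  structure(list(mode = mode, center = center, divisor = divisor,
                 n_zero_sd = n_zero),
            class = "scaling_spec")
}

#' Apply a learned scaling
#' @param X numeric matrix with the training columns.
#' @param spec a `scaling_spec` from [learn_scaling()].
#' @export
apply_scaling <- function(X, spec) {
  stopifnot(inherits(spec, "scaling_spec"), ncol(X) == length(spec$center))
  sweep(sweep(X, 2, spec$center, "-"), 2, spec$divisor, "/")
}

code_response <- function(y, positive_class = NULL) {
  yc <- as.character(y)
  classes <- unique(yc)
  if (length(classes) != 2L)
    stop_f("exactly two classes required, got %d (%s)", length(classes),
           paste(classes, collapse = ", "))
  if (is.null(positive_class)) positive_class <- classes[2L]
  if (!positive_class %in% classes)
    stop_f("positive_class %s is not a label of y", positive_class)
  negative_class <- setdiff(classes, positive_class)
  list(y_num = ifelse(yc == positive_class, 1, -1),
       positive = positive_class, negative = negative_class)
}

#' Fit a two-class OPLS-DA model
#'
#' The response is coded +1 (treated-like / positive class) and -1
#' (control-like) and centred. On the column-scaled X, the predictive weight
#' is `w = X'y / ||X'y||`; `n_ortho` orthogonal components are then extracted
#' iteratively (`w_o` proportional to `p - (w'p) w`, `t_o = X w_o`, X deflated
#' by `t_o p_o'`) before the final single predictive component. Because
#' `t_o' y = 0` by construction, the predictive direction is unchanged by the
#' deflation; what changes is the score `t` and hence the model's loadings
#' and explained variance.
#'
#' @param X numeric matrix or `binned_matrix` (samples x variables).
#' @param y two-class labels (factor/character/numeric), >= 2 per class.
#' @param n_ortho number of orthogonal components (>= 0).
#' @param scaling scaling mode, see [learn_scaling()].
#' @param positive_class label mapped to +1; defaults to the second distinct
#'   value of `y` in order of appearance.
#' @return an object of class `opls_model`.
#' @seealso [predict.opls_model()], [vip()]
#' @export
fit_opls_da <- function(X, y, n_ortho = 1L,
                        scaling = "unit_variance", positive_class = NULL) {
  if (inherits(X, "binned_matrix")) X <- model_matrix(X)
  X <- as.matrix(X)
  n_ortho <- assert_count(n_ortho, "n_ortho", lower = 0L)
  if (length(y) != nrow(X)) stop_f("length(y) != nrow(X)")
  code <- code_response(y, positive_class)
  tab <- table(code$y_num)
  if (any(tab < 2L)) stop_f("each class needs >= 2 samples")
  if (n_ortho >= min(nrow(X) - 1L, ncol(X)))
    stop_f("n_ortho = %d >= rank bound min(n - 1, p) = %d; reduce n_ortho",
           n_ortho, min(nrow(X) - 1L, ncol(X)))
  spec <- learn_scaling(X, scaling)
  Xs <- apply_scaling(X, spec)
  ybar <- mean(code$y_num)
  yc <- code$y_num - ybar
  ss_x <- sum(Xs^2)
  ss_y <- sum(yc^2)

  wraw <- crossprod(Xs, yc)
  nw <- sqrt(sum(wraw^2))
  if (nw < .Machine$double.eps^0.5)
    stop_f("X carries no covariance with the response; cannot fit")
  w <- as.vector(wraw / nw)

  Xd <- Xs
  W_o <- T_o <- P_o <- NULL
  for (j in seq_len(n_ortho)) {
    t <- as.vector(Xd %*% w)
    p <- as.vector(crossprod(Xd, t)) / sum(t^2)
    w_o <- p - sum(w * p) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-12)
      stop_f("orthogonal component %d exceeds the rank of X; reduce n_ortho",
             j)
    w_o <- w_o / nwo
    t_o <- as.vector(Xd %*% w_o)
    if (sum(t_o^2) < 1e-24)
      stop_f("orthogonal component %d is degenerate; reduce n_ortho", j)
    p_o <- as.vector(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o)
  }
  t <- as.vector(Xd %*% w)
  p <- as.vector(crossprod(Xd, t)) / sum(t^2)
  c_y <- sum(yc * t) / sum(t^2)

  expl_pred <- sum(t^2) * sum(p^2)
  expl_orth <- if (n_ortho > 0)
    sum(vapply(seq_len(n_ortho), function(j)
      sum(T_o[, j]^2) * sum(P_o[, j]^2), numeric(1))) else 0
  r2x <- min(1, (expl_pred + expl_orth) / ss_x)
  r2y <- min(1, c_y^2 * sum(t^2) / ss_y)

  structure(list(w = w, t = t, p = p, c = c_y,
                 W_o = W_o, T_o = T_o, P_o = P_o, n_ortho = n_ortho,
                 scaling = spec, y_mean = ybar,
                 classes = c(positive = code$positive,
                             negative = code$negative),
                 R2X = r2x, R2Y = r2y,
                 n = nrow(X), n_vars = ncol(X),
                 var_names = colnames(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(paste0("<opls_model: 1 predictive + %d orthogonal component(s),",
                     " %d x %d, R2X %.3f, R2Y %.3f>\n"),
              x$n_ortho, x$n, x$n_vars, x$R2X, x$R2Y))
  invisible(x)
}

#' Predict class membership with a fitted OPLS-DA model
#'
#' New rows are scaled with the training parameters, deflated by the model's
#' orthogonal components, then scored: `t_new = X w`, `y_hat = t_new * c +
#' mean(y_train)`. The class is the sign of the centred prediction; an exact
#' tie is assigned to the control-like (negative) class.
#'
#' @param object an `opls_model`.
#' @param newdata matrix with the model's variables (columns checked by name
#'   when both sides carry names).
#' @param ... unused.
#' @return data.frame with `score` (predictive score t), `y_hat` and `class`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "binned_matrix")) newdata <- model_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_vars)
    stop_f("newdata has %d columns, model expects %d", ncol(newdata),
           object$n_vars)
  if (!is.null(colnames(newdata)) && !is.null(object$var_names) &&
      !identical(colnames(newdata), object$var_names))
    stop_f("newdata column names do not match the training variables")
  Xs <- apply_scaling(newdata, object$scaling)
  for (j in seq_len(object$n_ortho)) {
    t_o <- as.vector(Xs %*% object$W_o[, j])
    Xs <- Xs - tcrossprod(t_o, object$P_o[, j])
  }
  t_new <- as.vector(Xs %*% object$w)
  y_hat <- t_new * object$c + object$y_mean
  centred <- t_new * object$c
  cls <- ifelse(centred > 0, object$classes[["positive"]],
                object$classes[["negative"]])
  data.frame(score = t_new, y_hat = y_hat, class = cls,
             row.names = rownames(newdata), stringsAsFactors = FALSE)
}

#' Variable importance in projection
#'
#' VIP on the single predictive component: with `||w|| = 1` the standard
#' formula reduces to `VIP_j = sqrt(K) * |w_j|` (K retained variables), so
#' the squared scores average to exactly 1. Orthogonal variation does not
#' contribute: VIP here measures discriminatory relevance only.
#'
#' @param model an `opls_model`.
#' @return named numeric vector of VIP scores (class `vip_vector`).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  v <- sqrt(model$n_vars) * abs(model$w)
  names(v) <- model$var_names
  class(v) <- c("vip_vector", class(v))
  v
}
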
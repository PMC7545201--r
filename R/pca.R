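# Exploratory PCA with configurable (default pareto) scaling, via SVD of the
# scaled data matrix.

#' Principal component analysis of a binned matrix
#'
#' Columns are centred and scaled per `scaling` (pareto by default — the
#' usual choice for spectral bin tables, damping intense peaks without
#' inflating noise), then decomposed by SVD. Scores are `U D`, loadings `V`;
#' explained variance is the squared singular value fraction.
#'
#' @param X numeric matrix or `binned_matrix`.
#' @param n_components number of components (<= min(n - 1, p)).
#' @param scaling see [learn_scaling()].
#' @return list with `scores`, `loadings`, `explained_variance` (fractions,
#'   non-increasing), `sdev`, `scaling`; class `pca_model`.
#' @export
fit_pca <- function(X, n_components = 2L, scaling = "pareto") {
  if (inherits(X, "binned_matrix")) X <- model_matrix(X)
  X <- as.matrix(X)
  n_components <- assert_count(n_components, "n_components", lower = 1L)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax)
    stop_f("n_components = %d exceeds min(samples - 1, bins) = %d",
           n_components, kmax)
  spec <- learn_scaling(X, scaling)
  Xs <- apply_scaling(X, spec)
  sv <- svd(Xs, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sweep(sv$u, 2, d, "*")
  rownames(scores) <- rownames(X)
  rownames(sv$v) <- colnames(X)
  colnames(scores) <- colnames(sv$v) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, loadings = sv$v,
                 explained_variance = sv$d[seq_len(n_components)]^2 /
                   sum(sv$d^2),
                 sdev = sv$d / sqrt(max(1, nrow(X) - 1)),
                 scaling = spec),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components, explained variance %s>\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance),
                    collapse = ", ")))
  invisible(x)
}
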
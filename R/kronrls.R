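#' Kronecker regularized least squares (KronRLS)
#'
#' Fits regularized least squares over the full drug-target pair space with
#' the pairwise kernel \eqn{K = K_D \otimes K_T}, without ever forming the
#' Kronecker product.  The dual system \eqn{(K_D \otimes K_T + \lambda I) a
#' = vec(Y)} is solved through the eigendecompositions
#' \eqn{K_D = Q_D \Lambda_D Q_D^T}, \eqn{K_T = Q_T \Lambda_T Q_T^T}:
#' with \eqn{M = Q_T^T Y Q_D}, the dual coefficient matrix is
#' \deqn{A = Q_T C Q_D^T, \qquad C_{ij} = \frac{M_{ij}}{\Lambda_T(i)
#'   \Lambda_D(j) + \lambda}.}
#' `Y` is oriented targets x drugs and `vec` is column-major throughout,
#' so `a = as.vector(A)`.
#'
#' @param K_d drug kernel matrix (`n_d` x `n_d`), symmetric, aligned with
#'   `net$drugs`.
#' @param K_t target kernel matrix (`n_t` x `n_t`), aligned with
#'   `net$targets`.
#' @param net a [dti_network()].
#' @param lambda positive regularization parameter.
#' @return an object of class `kronrls`: list with the dual coefficient
#'   matrix `A` (targets x drugs), `lambda`, the training kernels and
#'   network, and the call.  Methods: [predict.kronrls()], `fitted`,
#'   `residuals`, `print`.
#' @examples
#' net <- dti_network(matrix(c(1, 0, 0, 1), 2), c("d1", "d2"), c("t1", "t2"))
#' fit <- kronrls(diag(2), diag(2), net, lambda = 1)
#' all.equal(fit$A, net$Y / 2, check.attributes = FALSE)
#' @export
kronrls <- function(K_d, K_t, net, lambda) {
  stopifnot(inherits(net, "dti_network"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number")
  K_d <- as.matrix(K_d); K_t <- as.matrix(K_t)
  if (!all(dim(K_d) == net$n_drugs))
    stop("drug kernel must be ", net$n_drugs, " x ", net$n_drugs)
  if (!all(dim(K_t) == net$n_targets))
    stop("target kernel must be ", net$n_targets, " x ", net$n_targets)
  ed <- eigen((K_d + t(K_d)) / 2, symmetric = TRUE)
  et <- eigen((K_t + t(K_t)) / 2, symmetric = TRUE)
  if (min(ed$values) < -1e-8 || min(et$values) < -1e-8)
    warning("kernel has eigenvalues below -1e-8; consider make_psd()")
  M <- crossprod(et$vectors, net$Y) %*% ed$vectors
  C <- M / (outer(et$values, ed$values) + lambda)
  A <- et$vectors %*% C %*% t(ed$vectors)
  dimnames(A) <- dimnames(net$Y)
  structure(
    list(A = A, lambda = lambda, K_d = K_d, K_t = K_t, net = net,
         call = match.call()),
    class = "kronrls")
}

#' Predict interaction scores from a KronRLS model
#'
#' Scores arbitrary (drug, target) grids, including entities unseen in
#' training, from cross-kernels against the training entities:
#' \eqn{F = K_T^{new} A (K_D^{new})^T}.  With the training kernels
#' (the default) this reproduces the fitted training-grid scores.
#'
#' @param object a fitted [kronrls()] model.
#' @param K_d_cross matrix of similarities, new drugs x training drugs.
#' @param K_t_cross matrix of similarities, new targets x training targets.
#' @param ... unused.
#' @return score matrix, new targets x new drugs.
#' @export
predict.kronrls <- function(object, K_d_cross = NULL, K_t_cross = NULL, ...) {
  training_grid <- is.null(K_d_cross) && is.null(K_t_cross)
  if (is.null(K_d_cross)) K_d_cross <- object$K_d
  if (is.null(K_t_cross)) K_t_cross <- object$K_t
  K_d_cross <- as.matrix(K_d_cross); K_t_cross <- as.matrix(K_t_cross)
  if (ncol(K_d_cross) != ncol(object$A) ||
      ncol(K_t_cross) != nrow(object$A))
    stop("cross-kernel columns must match the training entities")
  F_ <- K_t_cross %*% object$A %*% t(K_d_cross)
  dimnames(F_) <- if (training_grid) dimnames(object$A) else
    list(rownames(K_t_cross), rownames(K_d_cross))
  F_
}

#' @export
fitted.kronrls <- function(object, ...) predict(object)

#' @export
residuals.kronrls <- function(object, ...) object$net$Y - fitted(object)

#' @export
print.kronrls <- function(x, ...) {
  cat("KronRLS model\n")
  cat(sprintf("  grid: %d targets x %d drugs (%d pairs)\n",
              x$net$n_targets, x$net$n_drugs, x$net$n_pairs))
  cat(sprintf("  lambda: %g\n", x$lambda))
  cat(sprintf("  ||A||_F: %.6g\n", sqrt(sum(x$A^2))))
  invisible(x)
}
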
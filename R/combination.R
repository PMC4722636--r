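#' Weighted combination of base kernels
#'
#' Forms the combined kernel \eqn{K^* = \sum_i w_i K_i} from a list of base
#' kernels sharing one entity set.
#'
#' @param kernels list of square matrices with identical dimensions
#'   (a kernel collection).
#' @param weights numeric vector, one weight per kernel.
#' @return the combined matrix.
#' @export
weighted_combination <- function(kernels, weights) {
  kernels <- .as_kernel_collection(kernels)
  if (length(weights) != length(kernels))
    stop("got ", length(weights), " weights for ", length(kernels),
         " kernels")
  out <- weights[1L] * kernels[[1L]]
  for (i in seq_along(kernels)[-1L]) out <- out + weights[i] * kernels[[i]]
  out
}

#' @rdname weighted_combination
#' @export
mean_combination <- function(kernels) {
  kernels <- .as_kernel_collection(kernels)
  weighted_combination(kernels, rep(1 / length(kernels), length(kernels)))
}

.as_kernel_collection <- function(kernels) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  if (!is.list(kernels) || length(kernels) == 0L)
    stop("a kernel collection must be a non-empty list of matrices")
  d <- dim(kernels[[1L]])
  for (K in kernels)
    if (!identical(dim(as.matrix(K)), d))
      stop("kernels in a collection must share dimensions")
  kernels
}

#' Kernel-target alignment
#'
#' Normalized Frobenius inner product between a kernel and an ideal
#' (label-derived) kernel,
#' \deqn{A(K, YY^T) = \frac{\langle K, YY^T\rangle_F}{n \sqrt{\langle K,
#'   K\rangle_F}},}
#' where `n` is the side length.  Invariant to positive scaling of `K`.
#'
#' @param K square kernel matrix.
#' @param ideal square matrix of the same size (typically a Gram matrix of
#'   labels or interaction profiles).
#' @return a scalar alignment.
#' @export
kernel_alignment <- function(K, ideal) {
  K <- as.matrix(K); ideal <- as.matrix(ideal)
  if (!identical(dim(K), dim(ideal))) stop("shape mismatch")
  kk <- sum(K * K)
  if (kk == 0) stop("alignment is undefined for the zero kernel")
  sum(K * ideal) / (nrow(K) * sqrt(kk))
}

#' Kernel-alignment (KA) heuristic weights
#'
#' The closed-form weighting baseline: each base kernel is weighted by its
#' alignment to an ideal kernel built from the interaction labels,
#' normalized to sum to one.  Labels live on drug-target pairs while base
#' kernels are entity-by-entity, so the ideal kernel is the Gram matrix of
#' interaction profiles on the chosen side: for drugs \eqn{Y^T Y}, for
#' targets \eqn{Y Y^T} (with the package's targets x drugs orientation) --
#' the natural lift of \eqn{y y^T} to the entity side.  Negative alignments
#' are floored at zero before normalization so the result is a convex
#' combination.
#'
#' When used inside cross-validation, pass the training-view network so the
#' ideal kernel never sees test labels.
#'
#' @param kernels list of base kernels on one side.
#' @param net a [dti_network()] supplying the labels.
#' @param side `"drug"` or `"target"`.
#' @return named numeric weight vector on the probability simplex.
#' @export
ka_weights <- function(kernels, net, side = c("drug", "target")) {
  side <- match.arg(side)
  stopifnot(inherits(net, "dti_network"))
  kernels <- .as_kernel_collection(kernels)
  ideal <- if (side == "drug") crossprod(net$Y) else tcrossprod(net$Y)
  if (nrow(kernels[[1L]]) != nrow(ideal))
    stop("kernel size does not match the network's ", side, " side")
  a <- vapply(kernels, kernel_alignment, numeric(1L), ideal = ideal)
  a <- pmax(a, 0)
  if (sum(a) <= 0)
    stop("all kernel alignments are non-positive; KA weights undefined")
  w <- a / sum(a)
  names(w) <- names(kernels)
  w
}

#' Write kernel weights as a two-column TSV
#'
#' @param weights named numeric vector.
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  nm <- names(weights)
  if (is.null(nm)) nm <- paste0("K", seq_along(weights))
  utils::write.table(
    data.frame(kernel = nm, weight = as.numeric(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
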
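#' Residual target for the weight subproblems
#'
#' The alternating optimization rewrites the fitting objective, for fixed
#' dual coefficients, as a regularized least squares on the modified label
#' vector \eqn{u = y - \lambda a / 2}; in matrix form
#' \eqn{U = Y - (\lambda/2) A}.
#'
#' @param net a [dti_network()].
#' @param A dual coefficient matrix (targets x drugs).
#' @param lambda regularization parameter of the dual fit.
#' @return matrix `U`, targets x drugs.
#' @export
residual_target <- function(net, A, lambda) {
  stopifnot(inherits(net, "dti_network"))
  A <- as.matrix(A)
  if (!all(dim(A) == dim(net$Y))) stop("A must match the network shape")
  net$Y - (lambda / 2) * A
}

#' Design matrix of a per-side weight subproblem
#'
#' For fixed dual coefficients `A` and a fixed combined kernel on the other
#' side, the predicted score vector is linear in the weights of the side
#' being optimized.  Column `i` of the design is the column-major
#' vectorization of the per-kernel score contribution:
#' `vec(K_T* A t(K_D^i))` when optimizing drug weights,
#' `vec(K_T^j A t(K_D*))` when optimizing target weights.
#'
#' @param kernels base kernel list of the side being optimized.
#' @param fixed_combined combined kernel of the other side.
#' @param A dual coefficient matrix (targets x drugs).
#' @param side `"drug"` or `"target"`.
#' @return numeric matrix with `n_pairs` rows and one column per kernel.
#' @export
weight_design <- function(kernels, fixed_combined, A,
                          side = c("drug", "target")) {
  side <- match.arg(side)
  kernels <- .as_kernel_collection(kernels)
  A <- as.matrix(A); fixed_combined <- as.matrix(fixed_combined)
  cols <- if (side == "drug") {
    FA <- fixed_combined %*% A             # K_T* A, reused across kernels
    lapply(kernels, function(Ki) as.vector(FA %*% t(Ki)))
  } else {
    AF <- A %*% t(fixed_combined)          # A (K_D*)^T
    lapply(kernels, function(Kj) as.vector(Kj %*% AF))
  }
  M <- do.call(cbind, cols)
  colnames(M) <- names(kernels)
  M
}

#' Solve one simplex-constrained weight subproblem
#'
#' Minimizes
#' \deqn{\frac{1}{2\lambda n} \|u - M\beta\|_2^2 + \sigma \|\beta\|_2^2}
#' over the probability simplex \eqn{\{\beta \ge 0, \sum_i \beta_i = 1\}}.
#' This is a small convex quadratic program (P is the number of base
#' kernels, typically <= 10); it is solved exactly and deterministically by
#' enumerating active sets: for every support the equality-constrained KKT
#' system is solved in closed form, infeasible candidates are discarded,
#' and the feasible candidate with the smallest objective is returned
#' (ties broken by enumeration order).  Rank-deficient KKT systems (e.g.
#' duplicated design columns with `sigma = 0`) use the minimum-norm
#' solution, which splits weight equally over identical columns.
#'
#' @param design matrix `M` from [weight_design()] (`n` x `P`).
#' @param u numeric vector of residual targets, length `n`.
#' @param lambda,sigma objective parameters (`lambda > 0`, `sigma >= 0`).
#' @return numeric weight vector of length `P` on the simplex, named after
#'   the design columns; attribute `"objective"` carries the attained
#'   objective value.
#' @export
solve_weight_subproblem <- function(design, u, lambda, sigma) {
  design <- as.matrix(design)
  u <- as.numeric(u)
  P <- ncol(design)
  n <- nrow(design)
  if (length(u) != n) stop("length(u) must equal nrow(design)")
  if (!all(is.finite(design)) || !all(is.finite(u)))
    stop("non-finite values in the weight subproblem")
  stopifnot(lambda > 0, sigma >= 0, P >= 1L)
  obj <- function(beta) {
    r <- u - design %*% beta
    sum(r^2) / (2 * lambda * n) + sigma * sum(beta^2)
  }
  if (P == 1L) {
    beta <- 1
  } else {
    H <- crossprod(design) / (lambda * n) + 2 * sigma * diag(P)
    cvec <- as.vector(crossprod(design, u)) / (lambda * n)
    best <- NULL
    best_obj <- Inf
    for (code in seq_len(2^P - 1L)) {
      S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(P) - 1L)) != 0L)
      m <- length(S)
      KKT <- rbind(cbind(H[S, S, drop = FALSE], rep(1, m)),
                   c(rep(1, m), 0))
      rhs <- c(cvec[S], 1)
      sol <- tryCatch(solve(KKT, rhs),
                      error = function(e) MASS::ginv(KKT) %*% rhs)
      bS <- as.numeric(sol[seq_len(m)])
      if (any(bS < -1e-9)) next
      bS <- pmax(bS, 0)
      bS <- bS / sum(bS)
      beta_cand <- numeric(P)
      beta_cand[S] <- bS
      o <- obj(beta_cand)
      if (o < best_obj - 1e-12) {
        best_obj <- o
        best <- beta_cand
      }
    }
    beta <- best
  }
  names(beta) <- colnames(design)
  attr(beta, "objective") <- obj(beta)
  beta
}

#' Full MKL objective (monitoring)
#'
#' Evaluates the joint objective the alternating scheme works on:
#' \deqn{\frac{1}{2\lambda n}\|u - Ka\|^2 + \frac12 a^T(y - \lambda a) +
#'   \sigma(\|\beta_D\|^2 + \|\beta_T\|^2),}
#' with \eqn{Ka = vec(K_T^* A (K_D^*)^T)} and \eqn{u = y - \lambda a/2}.
#' Used for traces and testing; the alternating steps only guarantee
#' per-step argmin decrease of their own subproblems, not joint
#' monotonicity.
#'
#' @param drug_kernels,target_kernels base kernel lists.
#' @param beta_d,beta_t weight vectors.
#' @param A dual coefficient matrix.
#' @param net a [dti_network()].
#' @param lambda,sigma hyperparameters.
#' @return scalar objective value.
#' @export
mkl_objective <- function(drug_kernels, target_kernels, beta_d, beta_t,
                          A, net, lambda, sigma) {
  Kd <- weighted_combination(drug_kernels, beta_d)
  Kt <- weighted_combination(target_kernels, beta_t)
  a <- as.vector(A)
  y <- as.vector(net$Y)
  u <- y - lambda * a / 2
  Ka <- as.vector(Kt %*% A %*% t(Kd))
  n <- net$n_pairs
  sum((u - Ka)^2) / (2 * lambda * n) +
    0.5 * sum(a * (y - lambda * a)) +
    sigma * (sum(beta_d^2) + sum(beta_t^2))
}

#' KronRLS with multiple kernel learning (KronRLS-MKL)
#'
#' Learns a drug-target interaction predictor together with one convex
#' combination of base kernels per entity side.  The alternating scheme
#' starts from given (default uniform) weights and repeats: (1) combine
#' each side's kernels with the current weights; (2) solve the KronRLS
#' dual system on the combined pair ([kronrls()]); (3) form the residual
#' target \eqn{U = Y - \lambda A/2}; (4) update the drug weights by the
#' simplex-constrained L2-regularized least squares of
#' [solve_weight_subproblem()] with the target combination fixed; (5)
#' update the target weights likewise with the refreshed drug combination.
#' Iteration stops when the largest weight change drops below `tol` or
#' `max_iter` is reached; the dual is refit once with the final weights.
#'
#' `sigma` controls non-sparsity of the weights: at `sigma = 0` the
#' subproblem may concentrate on few kernels, for large `sigma` the L2
#' pull shrinks the weights toward uniform `1/P`.
#'
#' @param drug_kernels named list of `n_d` x `n_d` base kernels.
#' @param target_kernels named list of `n_t` x `n_t` base kernels.
#' @param net a [dti_network()].
#' @param lambda positive dual regularization (selected over
#'   `2^{-15}, 2^{-10}, ..., 2^{30}` in the reference protocol).
#' @param sigma nonnegative weight regularization (reference grid
#'   `0, 0.25, 0.5, 0.75, 1`).
#' @param max_iter maximum number of alternations.
#' @param tol convergence threshold on the max-norm weight change.
#' @param init `"uniform"` or a list with elements `drug`, `target` giving
#'   starting weights.
#' @return object of class `kronrls_mkl`: list with `A`, `beta_drug`,
#'   `beta_target`, `lambda`, `sigma`, `iterations`, `converged`, a
#'   per-iteration `trace` data.frame (objective, weight change, weights),
#'   the training network and kernels.  Methods: `predict`, `coef`,
#'   `summary`, `plot`, `fitted`, `residuals`, `print`.
#' @examples
#' sim <- simulate_dti(n_drugs = 12, n_targets = 8, seed = 1)
#' fit <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
#'                    lambda = 1, sigma = 0.25)
#' coef(fit)
#' @export
kronrls_mkl <- function(drug_kernels, target_kernels, net,
                        lambda = 1, sigma = 0.25,
                        max_iter = 20L, tol = 1e-4, init = "uniform") {
  stopifnot(inherits(net, "dti_network"), lambda > 0, sigma >= 0,
            max_iter >= 1L)
  drug_kernels <- .as_kernel_collection(drug_kernels)
  target_kernels <- .as_kernel_collection(target_kernels)
  if (is.null(names(drug_kernels)))
    names(drug_kernels) <- paste0("D", seq_along(drug_kernels))
  if (is.null(names(target_kernels)))
    names(target_kernels) <- paste0("T", seq_along(target_kernels))
  P_d <- length(drug_kernels); P_t <- length(target_kernels)
  if (nrow(drug_kernels[[1L]]) != net$n_drugs)
    stop("drug kernels must be ", net$n_drugs, " x ", net$n_drugs)
  if (nrow(target_kernels[[1L]]) != net$n_targets)
    stop("target kernels must be ", net$n_targets, " x ", net$n_targets)

  if (identical(init, "uniform")) {
    beta_d <- rep(1 / P_d, P_d)
    beta_t <- rep(1 / P_t, P_t)
  } else {
    beta_d <- .check_simplex(init$drug, P_d)
    beta_t <- .check_simplex(init$target, P_t)
  }
  names(beta_d) <- names(drug_kernels)
  names(beta_t) <- names(target_kernels)

  trace <- vector("list", max_iter)
  converged <- FALSE
  iter <- 0L
  fit <- NULL
  u <- NULL
  for (iter in seq_len(max_iter)) {
    Kd_star <- weighted_combination(drug_kernels, beta_d)
    Kt_star <- weighted_combination(target_kernels, beta_t)
    fit <- kronrls(Kd_star, Kt_star, net, lambda)
    U <- residual_target(net, fit$A, lambda)
    u <- as.vector(U)

    if (P_d > 1L || P_t > 1L) {
      Md <- weight_design(drug_kernels, Kt_star, fit$A, side = "drug")
      beta_d_new <- solve_weight_subproblem(Md, u, lambda, sigma)
      Kd_star <- weighted_combination(drug_kernels, beta_d_new)
      Mt <- weight_design(target_kernels, Kd_star, fit$A, side = "target")
      beta_t_new <- solve_weight_subproblem(Mt, u, lambda, sigma)
    } else {
      beta_d_new <- beta_d
      beta_t_new <- beta_t
    }

    delta <- max(max(abs(beta_d_new - beta_d)), max(abs(beta_t_new - beta_t)))
    beta_d <- beta_d_new; beta_t <- beta_t_new
    objective <- mkl_objective(drug_kernels, target_kernels, beta_d, beta_t,
                               fit$A, net, lambda, sigma)
    trace[[iter]] <- data.frame(
      iteration = iter, objective = objective, delta = delta,
      t(stats::setNames(as.numeric(beta_d),
                        paste0("beta_d.", names(beta_d)))),
      t(stats::setNames(as.numeric(beta_t),
                        paste0("beta_t.", names(beta_t)))),
      check.names = FALSE)
    if (delta < tol) { converged <- TRUE; break }
  }
  # refit the dual so A is consistent with the final weights
  Kd_star <- weighted_combination(drug_kernels, beta_d)
  Kt_star <- weighted_combination(target_kernels, beta_t)
  fit <- kronrls(Kd_star, Kt_star, net, lambda)

  structure(
    list(A = fit$A, beta_drug = .drop_attr(beta_d),
         beta_target = .drop_attr(beta_t),
         lambda = lambda, sigma = sigma,
         iterations = iter, converged = converged,
         trace = do.call(rbind, trace[seq_len(iter)]),
         drug_kernels = drug_kernels, target_kernels = target_kernels,
         K_d = Kd_star, K_t = Kt_star, net = net, call = match.call()),
    class = "kronrls_mkl")
}

.check_simplex <- function(w, P) {
  w <- as.numeric(w)
  if (length(w) != P || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("initial weights must be length ", P, " on the probability simplex")
  w
}

.drop_attr <- function(w) {
  attr(w, "objective") <- NULL
  w
}

#' Predict interaction scores from a KronRLS-MKL model
#'
#' Cross-kernels of the base collections against the training entities are
#' combined with the learned weights and pushed through the KronRLS
#' predictor.  With the defaults, returns the fitted training grid.
#'
#' @param object a fitted [kronrls_mkl()] model.
#' @param drug_cross list of cross-kernels (new drugs x training drugs),
#'   one per base drug kernel, in training order; or a single pre-combined
#'   matrix.
#' @param target_cross likewise for targets.
#' @param ... unused.
#' @return score matrix, new targets x new drugs.
#' @export
predict.kronrls_mkl <- function(object, drug_cross = NULL,
                                target_cross = NULL, ...) {
  comb <- function(x, w, train) {
    if (is.null(x)) return(train)
    if (is.matrix(x)) return(x)
    weighted_combination(x, w)
  }
  training_grid <- is.null(drug_cross) && is.null(target_cross)
  Kd <- comb(drug_cross, object$beta_drug, object$K_d)
  Kt <- comb(target_cross, object$beta_target, object$K_t)
  if (ncol(Kd) != ncol(object$A) || ncol(Kt) != nrow(object$A))
    stop("cross-kernel columns must match the training entities")
  F_ <- Kt %*% object$A %*% t(Kd)
  dimnames(F_) <- if (training_grid) dimnames(object$A) else
    list(rownames(Kt), rownames(Kd))
  F_
}

#' @export
fitted.kronrls_mkl <- function(object, ...) predict(object)

#' @export
residuals.kronrls_mkl <- function(object, ...) object$net$Y - fitted(object)

#' Kernel weights of a fitted KronRLS-MKL model
#'
#' @param object a fitted [kronrls_mkl()] model.
#' @param ... unused.
#' @return list with components `drug` and `target`, each a named weight
#'   vector on the probability simplex.
#' @export
coef.kronrls_mkl <- function(object, ...) {
  list(drug = object$beta_drug, target = object$beta_target)
}

#' @export
print.kronrls_mkl <- function(x, ...) {
  cat("KronRLS-MKL model\n")
  cat(sprintf("  grid: %d targets x %d drugs; %d drug + %d target kernels\n",
              x$net$n_targets, x$net$n_drugs,
              length(x$beta_drug), length(x$beta_target)))
  cat(sprintf("  lambda = %g, sigma = %g\n", x$lambda, x$sigma))
  cat(sprintf("  %s after %d iteration(s)\n",
              if (x$converged) "converged" else "stopped", x$iterations))
  invisible(x)
}

#' @export
summary.kronrls_mkl <- function(object, ...) {
  structure(list(model = object), class = "summary.kronrls_mkl")
}

#' @export
print.summary.kronrls_mkl <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nDrug kernel weights:\n")
  print(round(m$beta_drug, 4))
  cat("\nTarget kernel weights:\n")
  print(round(m$beta_target, 4))
  if (!is.null(m$trace)) {
    cat("\nFinal objective:",
        format(m$trace$objective[nrow(m$trace)], digits = 6), "\n")
  }
  invisible(x)
}

#' Plot kernel weights and the convergence trace
#'
#' Draws barplots of the learned drug and target kernel weights and, when
#' a trace is available, the objective value per alternation.
#'
#' @param x a fitted [kronrls_mkl()] model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.kronrls_mkl <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$trace)) 2 else 3),
                      mar = c(6, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$beta_drug, las = 2, ylim = c(0, 1),
                    main = "Drug kernel weights", ylab = "weight", ...)
  graphics::barplot(x$beta_target, las = 2, ylim = c(0, 1),
                    main = "Target kernel weights", ylab = "weight", ...)
  if (!is.null(x$trace))
    graphics::plot(x$trace$iteration, x$trace$objective, type = "b",
                   xlab = "iteration", ylab = "objective",
                   main = "Alternating optimization")
  invisible(x)
}

#' Serialize a fitted model to a directory
#'
#' Writes the dual coefficient matrix and both weight vectors as labeled
#' TSV files plus a plain-text metadata file (lambda, sigma, iterations,
#' convergence flag), so a run can be inspected or reloaded without R
#' binary formats.
#'
#' @param object a `kronrls` or `kronrls_mkl` fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interaction_table(object$A, file.path(dir, "A.tsv"))
  meta <- c(
    class = class(object)[1L],
    lambda = format(object$lambda, digits = 17),
    sigma = if (is.null(object$sigma)) "" else
      format(object$sigma, digits = 17),
    iterations = if (is.null(object$iterations)) "" else object$iterations,
    converged = if (is.null(object$converged)) "" else object$converged)
  writeLines(paste(names(meta), meta, sep = "\t"),
             file.path(dir, "metadata.tsv"))
  if (inherits(object, "kronrls_mkl")) {
    write_weights(object$beta_drug, file.path(dir, "beta_drug.tsv"))
    write_weights(object$beta_target, file.path(dir, "beta_target.tsv"))
  }
  invisible(dir)
}
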
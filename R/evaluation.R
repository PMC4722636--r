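#' Scenario-aware cross-validation fold plans
#'
#' Partitions the evaluation units of a drug-target network into `k` folds,
#' `repetitions` times, for the three cold-start scenarios used in
#' drug-target interaction benchmarks:
#' * `"pair"` -- all `n_d * n_t` drug-target pairs are split; held-out
#'   cells are treated as unknown during training;
#' * `"new_drug"` -- the drugs are split; every pair of a held-out drug is
#'   test, simulating prediction for compounds with no known targets;
#' * `"new_target"` -- likewise over targets.
#'
#' Fold sizes differ by at most one and, within a repetition, folds
#' partition the unit set.  Plans are deterministic given `seed`.
#'
#' @param net a [dti_network()].
#' @param scenario `"pair"`, `"new_drug"` or `"new_target"`.
#' @param k number of folds (>= 2).
#' @param repetitions number of independent runs.
#' @param seed integer seed.
#' @return object of class `fold_plan`; `assignments[[rep]][[fold]]` holds
#'   the held-out unit indices (pair linear indices, drug positions, or
#'   target positions).
#' @export
make_fold_plan <- function(net, scenario = c("pair", "new_drug", "new_target"),
                           k = 5L, repetitions = 5L, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(net, "dti_network"), k >= 2L, repetitions >= 1L)
  n_units <- switch(scenario, pair = net$n_pairs,
                    new_drug = net$n_drugs, new_target = net$n_targets)
  if (n_units < k)
    stop("cannot make ", k, " folds from ", n_units, " units (", scenario, ")")
  assignments <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    lapply(seq_len(repetitions), function(r) {
      shuffled <- sample.int(n_units)
      fold_of <- rep(seq_len(k), length.out = n_units)
      lapply(seq_len(k), function(f) sort(shuffled[fold_of == f]))
    })
  })
  structure(
    list(scenario = scenario, k = as.integer(k),
         repetitions = as.integer(repetitions), seed = as.integer(seed),
         n_units = n_units, assignments = assignments),
    class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %s scenario, %d x %d-fold over %d units (seed %d)\n",
              x$scenario, x$repetitions, x$k, x$n_units, x$seed))
  invisible(x)
}

#' Training view of one cross-validation fold
#'
#' Builds the leakage-free training data for one (repetition, fold) cell of
#' a [make_fold_plan()]: the training network the model may see, the list
#' of test pairs with their held-out labels, and a full-grid "masked"
#' network (test information zeroed) from which label-derived kernels such
#' as [gip_kernel()] can be computed without leakage.
#'
#' @param net the full [dti_network()].
#' @param plan a [make_fold_plan()] for `net`.
#' @param rep,fold repetition and fold number.
#' @return object of class `training_view`: list with `scenario`,
#'   `train_net` (network restricted to training units), `masked_net`
#'   (full-grid network with test cells zeroed), `train_drugs`,
#'   `train_targets` (position indices into the full network),
#'   `test_pairs` (data.frame with `drug_pos`, `target_pos`, `drug`,
#'   `target`, `label` in full-network coordinates).
#' @export
training_view <- function(net, plan, rep = 1L, fold = 1L) {
  stopifnot(inherits(net, "dti_network"), inherits(plan, "fold_plan"),
            rep >= 1L, rep <= plan$repetitions, fold >= 1L, fold <= plan$k)
  held <- plan$assignments[[rep]][[fold]]
  Y <- net$Y
  all_d <- seq_len(net$n_drugs); all_t <- seq_len(net$n_targets)
  if (plan$scenario == "pair") {
    pos <- pair_from_index(held, net$n_targets)
    Ym <- Y
    Ym[cbind(pos$target_pos, pos$drug_pos)] <- 0
    masked <- dti_network(Ym, net$drugs, net$targets)
    test_pairs <- data.frame(
      drug_pos = pos$drug_pos, target_pos = pos$target_pos,
      drug = net$drugs[pos$drug_pos], target = net$targets[pos$target_pos],
      label = Y[cbind(pos$target_pos, pos$drug_pos)])
    train_d <- all_d; train_t <- all_t
    train_net <- masked
  } else if (plan$scenario == "new_drug") {
    train_d <- setdiff(all_d, held); train_t <- all_t
    Ym <- Y; Ym[, held] <- 0
    masked <- dti_network(Ym, net$drugs, net$targets)
    train_net <- dti_network(Y[, train_d, drop = FALSE],
                             net$drugs[train_d], net$targets)
    grid <- expand.grid(target_pos = all_t, drug_pos = held)
    test_pairs <- data.frame(
      drug_pos = grid$drug_pos, target_pos = grid$target_pos,
      drug = net$drugs[grid$drug_pos], target = net$targets[grid$target_pos],
      label = Y[cbind(grid$target_pos, grid$drug_pos)])
  } else {
    train_d <- all_d; train_t <- setdiff(all_t, held)
    Ym <- Y; Ym[held, ] <- 0
    masked <- dti_network(Ym, net$drugs, net$targets)
    train_net <- dti_network(Y[train_t, , drop = FALSE],
                             net$drugs, net$targets[train_t])
    grid <- expand.grid(target_pos = held, drug_pos = all_d)
    test_pairs <- data.frame(
      drug_pos = grid$drug_pos, target_pos = grid$target_pos,
      drug = net$drugs[grid$drug_pos], target = net$targets[grid$target_pos],
      label = Y[cbind(grid$target_pos, grid$drug_pos)])
  }
  structure(
    list(scenario = plan$scenario, train_net = train_net,
         masked_net = masked, train_drugs = train_d, train_targets = train_t,
         test_pairs = test_pairs, net = net),
    class = "training_view")
}

#' Audit a training view for test-set leakage
#'
#' Checks programmatically that nothing the trained model sees contains
#' held-out information: in cold-start scenarios no test entity appears in
#' the training network, and in every scenario the masked network is zero
#' on all test cells.
#'
#' @param view a [training_view()].
#' @return `TRUE` (invisibly) if the audit passes; otherwise an error.
#' @export
audit_leakage <- function(view) {
  stopifnot(inherits(view, "training_view"))
  tp <- view$test_pairs
  if (view$scenario == "new_drug" &&
      any(unique(tp$drug) %in% view$train_net$drugs))
    stop("leakage: held-out drug present in the training network")
  if (view$scenario == "new_target" &&
      any(unique(tp$target) %in% view$train_net$targets))
    stop("leakage: held-out target present in the training network")
  if (any(view$masked_net$Y[cbind(tp$target_pos, tp$drug_pos)] != 0))
    stop("leakage: masked network carries test labels")
  invisible(TRUE)
}

#' Balanced subsampling of test negatives
#'
#' Keeps every positive test pair and samples `ceiling(ratio * #positives)`
#' negatives without replacement, reproducing the balanced evaluation
#' setting at `ratio = 1`.  If the negative pool is too small, all
#' negatives are kept with a warning.
#'
#' @param test_pairs data.frame with a 0/1 `label` column (as produced by
#'   [training_view()]).
#' @param ratio negatives kept per positive.
#' @param seed integer seed.
#' @return the reduced data.frame (original row order preserved).
#' @export
subsample_negatives <- function(test_pairs, ratio = 1, seed = 1L) {
  pos <- which(test_pairs$label == 1)
  neg <- which(test_pairs$label == 0)
  if (length(pos) == 0L) stop("no positive test pairs to balance against")
  n_neg <- ceiling(ratio * length(pos))
  if (n_neg > length(neg)) {
    warning("requested ", n_neg, " negatives but only ", length(neg),
            " available; keeping all")
    keep_neg <- neg
  } else {
    keep_neg <- withr::with_seed(as.integer(seed) %% 2147483647L,
                                 sample(neg, n_neg))
  }
  test_pairs[sort(c(pos, keep_neg)), , drop = FALSE]
}

#' Area under the precision-recall curve
#'
#' Non-interpolated average precision with tie blocks: pairs are walked in
#' descending score order, the precision is evaluated at the end of each
#' block of tied scores, and each block contributes that precision once
#' per positive it contains.  The mean over all positives is the AUPR.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (at least one of each class).
#' @return scalar in (0, 1].
#' @examples
#' aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # (1 + 2/3) / 2
#' @export
aupr <- function(scores, labels) {
  scores <- as.numeric(scores); labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels)
  if (n_pos == 0 || n_pos == length(labels))
    stop("AUPR needs at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_pos <- cumsum(l)
  ends <- which(c(s[-1L] != s[-length(s)], TRUE))
  pos_in_block <- diff(c(0, cum_pos[ends]))
  prec_at_end <- cum_pos[ends] / ends
  sum(prec_at_end * pos_in_block) / n_pos
}

# deterministic integer sub-seed, kept within 32-bit range
.derive_seed <- function(seed, rep = 0L, fold = 0L, extra = 0L) {
  s <- (as.numeric(seed) * 7919 + rep * 104729 + fold * 1299709 +
          extra * 15485863) %% 2147483629
  as.integer(s) + 1L
}

# Fit the requested method on one training view and score its test pairs.
# Kernels are full-entity-set matrices; restriction/cross-blocks are taken
# here so that cold-start folds never index test entities at train time.
.fit_and_score <- function(view, drug_kernels, target_kernels, method,
                           lambda, sigma, add_gip = FALSE,
                           mkl_control = list()) {
  drug_kernels <- .as_kernel_collection(drug_kernels)
  target_kernels <- .as_kernel_collection(target_kernels)
  if (add_gip) {
    drug_kernels <- c(drug_kernels,
                      list(GIP = gip_kernel(view$masked_net, "drug")))
    target_kernels <- c(target_kernels,
                        list(GIP = gip_kernel(view$masked_net, "target")))
  }
  td <- view$train_drugs; tt <- view$train_targets
  sub <- function(K, rows, cols) K[rows, cols, drop = FALSE]
  kd_train <- lapply(drug_kernels, sub, rows = td, cols = td)
  kt_train <- lapply(target_kernels, sub, rows = tt, cols = tt)
  kd_cross <- lapply(drug_kernels, sub,
                     rows = seq_len(view$net$n_drugs), cols = td)
  kt_cross <- lapply(target_kernels, sub,
                     rows = seq_len(view$net$n_targets), cols = tt)
  net_tr <- view$train_net

  if (method == "kronrls") {
    if (length(kd_train) != 1L || length(kt_train) != 1L)
      stop("method 'kronrls' expects exactly one kernel per side; ",
           "use 'mean', 'ka' or 'kronrls_mkl' for collections")
    fit <- kronrls(kd_train[[1L]], kt_train[[1L]], net_tr, lambda)
    F_ <- predict(fit, kd_cross[[1L]], kt_cross[[1L]])
  } else if (method == "mean") {
    fit <- kronrls(mean_combination(kd_train), mean_combination(kt_train),
                   net_tr, lambda)
    F_ <- predict(fit, mean_combination(kd_cross), mean_combination(kt_cross))
  } else if (method == "ka") {
    wd <- ka_weights(kd_train, net_tr, "drug")
    wt <- ka_weights(kt_train, net_tr, "target")
    fit <- kronrls(weighted_combination(kd_train, wd),
                   weighted_combination(kt_train, wt), net_tr, lambda)
    F_ <- predict(fit, weighted_combination(kd_cross, wd),
                  weighted_combination(kt_cross, wt))
  } else if (method == "kronrls_mkl") {
    args <- c(list(drug_kernels = kd_train, target_kernels = kt_train,
                   net = net_tr, lambda = lambda, sigma = sigma),
              mkl_control)
    fit <- do.call(kronrls_mkl, args)
    F_ <- predict(fit, kd_cross, kt_cross)
  } else stop("unknown method: ", method)
  scores <- F_[cbind(view$test_pairs$target_pos, view$test_pairs$drug_pos)]
  list(scores = scores, fit = fit)
}

#' Cross-validated AUPR at fixed hyperparameters
#'
#' Runs the full repeated k-fold protocol of one scenario with given
#' `lambda` (and `sigma` for the MKL method) and reports per-fold AUPR.
#' Base kernels are supplied over the full entity sets; every fold
#' restricts them to its training entities and, for prediction, uses only
#' cross-similarities of test entities *to* training entities.
#'
#' @param net a [dti_network()].
#' @param drug_kernels,target_kernels named lists of full-size base
#'   kernels (a single matrix is treated as a one-kernel collection).
#' @param method `"kronrls"` (single kernel per side), `"mean"` or `"ka"`
#'   (baseline combinations + KronRLS), or `"kronrls_mkl"`.
#' @param scenario,k,repetitions,seed passed to [make_fold_plan()].
#' @param lambda,sigma hyperparameters.
#' @param balance if `TRUE`, test folds are balanced with
#'   [subsample_negatives()] at `ratio`.
#' @param ratio negatives per positive when balancing.
#' @param add_gip if `TRUE`, a GIP kernel computed from the fold's masked
#'   training network is appended to each side's collection.
#' @param mkl_control list of extra arguments for [kronrls_mkl()].
#' @param plan optionally a precomputed [make_fold_plan()].
#' @return object of class `dti_cv`: `results` data.frame (rep, fold,
#'   lambda, sigma, aupr), `mean`, `sd`, `scenario`, `method`.
#' @export
cv_evaluate <- function(net, drug_kernels, target_kernels,
                        method = c("kronrls_mkl", "kronrls", "mean", "ka"),
                        scenario = c("pair", "new_drug", "new_target"),
                        k = 5L, repetitions = 5L, seed = 1L,
                        lambda = 1, sigma = 0.25,
                        balance = FALSE, ratio = 1, add_gip = FALSE,
                        mkl_control = list(), plan = NULL) {
  method <- match.arg(method)
  scenario <- match.arg(scenario)
  if (is.null(plan))
    plan <- make_fold_plan(net, scenario, k = k, repetitions = repetitions,
                           seed = seed)
  rows <- list()
  for (r in seq_len(plan$repetitions)) {
    for (f in seq_len(plan$k)) {
      view <- training_view(net, plan, r, f)
      audit_leakage(view)
      fs <- .fit_and_score(view, drug_kernels, target_kernels, method,
                           lambda, sigma, add_gip, mkl_control)
      tp <- view$test_pairs
      tp$score <- fs$scores
      if (balance)
        tp <- subsample_negatives(tp, ratio = ratio,
                                  seed = .derive_seed(seed, r, f))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = plan$scenario, rep = r, fold = f,
        lambda = lambda, sigma = sigma,
        aupr = aupr(tp$score, tp$label))
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results, mean = mean(results$aupr),
         sd = stats::sd(results$aupr), scenario = plan$scenario,
         method = method),
    class = "dti_cv")
}

#' @export
print.dti_cv <- function(x, ...) {
  cat(sprintf("%s, %s scenario: AUPR %.4f(±%.4f) over %d folds\n",
              x$method, x$scenario, x$mean,
              if (is.na(x$sd)) 0 else x$sd, nrow(x$results)))
  invisible(x)
}

#' Write cross-validation results as TSV
#'
#' One row per (rep, fold) plus a final summary row formatted
#' `mean(±sd)`.
#'
#' @param x a `dti_cv` result.
#' @param path output path.
#' @export
write_cv_results <- function(x, path) {
  stopifnot(inherits(x, "dti_cv"))
  df <- x$results
  df$aupr <- format(df$aupr, digits = 6)
  summary_row <- df[1L, ]
  summary_row[] <- ""
  summary_row$scenario <- x$scenario
  summary_row$rep <- "summary"
  summary_row$aupr <- sprintf("%.4f(±%.4f)", x$mean,
                              if (is.na(x$sd)) 0 else x$sd)
  utils::write.table(rbind(df, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Nested cross-validation with grid hyperparameter selection
#'
#' The outer loop follows [cv_evaluate()]; within each outer fold an inner
#' `inner_k`-fold plan of the same scenario is drawn on the training view,
#' every grid point is scored by mean inner AUPR, and the best point (ties
#' resolved by grid order) is refit on the full outer training view.  The
#' reference grids are `lambda = 2^{-15}, 2^{-10}, ..., 2^{30}` and, for
#' the MKL method, `sigma = 0, 0.25, 0.5, 0.75, 1`.
#'
#' @inheritParams cv_evaluate
#' @param inner_k inner fold count.
#' @param lambda_grid,sigma_grid candidate values (`sigma_grid` is ignored
#'   for non-MKL methods).
#' @return a `dti_cv` object whose `results` carry the selected `lambda`
#'   and `sigma` per outer fold.
#' @export
nested_cv <- function(net, drug_kernels, target_kernels,
                      method = c("kronrls_mkl", "kronrls", "mean", "ka"),
                      scenario = c("pair", "new_drug", "new_target"),
                      k = 5L, repetitions = 5L, inner_k = 3L, seed = 1L,
                      lambda_grid = 2^seq(-15, 30, by = 5),
                      sigma_grid = c(0, 0.25, 0.5, 0.75, 1),
                      balance = FALSE, ratio = 1, add_gip = FALSE,
                      mkl_control = list()) {
  method <- match.arg(method)
  scenario <- match.arg(scenario)
  stopifnot(length(lambda_grid) >= 1L)
  grid <- if (method == "kronrls_mkl") {
    expand.grid(lambda = lambda_grid, sigma = sigma_grid,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(lambda = lambda_grid, sigma = NA_real_)
  }
  plan <- make_fold_plan(net, scenario, k = k, repetitions = repetitions,
                         seed = seed)
  rows <- list()
  for (r in seq_len(plan$repetitions)) {
    for (f in seq_len(plan$k)) {
      view <- training_view(net, plan, r, f)
      audit_leakage(view)
      if (nrow(grid) > 1L) {
        inner_seed <- .derive_seed(seed, r, f)
        inner_mean <- vapply(seq_len(nrow(grid)), function(g) {
          res <- tryCatch(
            cv_evaluate(view$train_net,
                        lapply(.restricted(drug_kernels, view, "drug"),
                               identity),
                        lapply(.restricted(target_kernels, view, "target"),
                               identity),
                        method = method, scenario = scenario,
                        k = inner_k, repetitions = 1L, seed = inner_seed,
                        lambda = grid$lambda[g], sigma = grid$sigma[g],
                        balance = balance, ratio = ratio, add_gip = add_gip,
                        mkl_control = mkl_control),
            error = function(e) NULL)
          if (is.null(res)) -Inf else res$mean
        }, numeric(1L))
        best <- which.max(inner_mean)   # first max in grid order
      } else best <- 1L
      lam <- grid$lambda[best]
      sig <- if (is.na(grid$sigma[best])) 0.25 else grid$sigma[best]
      fs <- .fit_and_score(view, drug_kernels, target_kernels, method,
                           lam, sig, add_gip, mkl_control)
      tp <- view$test_pairs
      tp$score <- fs$scores
      if (balance)
        tp <- subsample_negatives(tp, ratio = ratio,
                                  seed = .derive_seed(seed, r, f, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = plan$scenario, rep = r, fold = f,
        lambda = lam, sigma = grid$sigma[best],
        aupr = aupr(tp$score, tp$label))
    }
  }
  results <- do.call(rbind, rows)
  structure(
    list(results = results, mean = mean(results$aupr),
         sd = stats::sd(results$aupr), scenario = plan$scenario,
         method = method),
    class = "dti_cv")
}

# restrict a full-entity kernel collection to a view's training entities
.restricted <- function(kernels, view, side) {
  idx <- if (side == "drug") view$train_drugs else view$train_targets
  lapply(.as_kernel_collection(kernels),
         function(K) K[idx, idx, drop = FALSE])
}

#' Rank novel interaction predictions
#'
#' Removes pairs already known in the network and returns the `top_n`
#' remaining pairs by descending score, ties broken lexicographically by
#' (drug id, target id) for reproducibility.
#'
#' @param scores score matrix, targets x drugs (same shape as `net$Y`).
#' @param net a [dti_network()].
#' @param top_n number of pairs to return.
#' @return data.frame with columns `rank`, `drug`, `target`, `score`.
#' @export
rank_novel_predictions <- function(scores, net, top_n = 5L) {
  stopifnot(inherits(net, "dti_network"))
  scores <- as.matrix(scores)
  if (!all(dim(scores) == dim(net$Y)))
    stop("score matrix must match the network shape")
  novel <- which(net$Y == 0)
  pos <- arrayInd(novel, dim(net$Y))
  df <- data.frame(drug = net$drugs[pos[, 2L]],
                   target = net$targets[pos[, 1L]],
                   score = scores[novel])
  df <- df[order(-df$score, df$drug, df$target), , drop = FALSE]
  df <- utils::head(df, top_n)
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}
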
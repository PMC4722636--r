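test_that("fold plans partition the unit set with balanced sizes", {
  net <- rand_net(10, 6, seed = 1)
  plan <- make_fold_plan(net, "new_drug", k = 5, repetitions = 3, seed = 2)
  for (r in 1:3) {
    folds <- plan$assignments[[r]]
    expect_equal(vapply(folds, length, 0L), rep(2L, 5))   # 10 drugs / 5
    expect_setequal(unlist(folds), 1:10)
    expect_equal(anyDuplicated(unlist(folds)), 0L)
  }
  # pair scenario on a 3x4 grid with k = 4: folds of 3 covering all 12 pairs
  small <- rand_net(3, 4, seed = 3)
  pp <- make_fold_plan(small, "pair", k = 4, repetitions = 1, seed = 4)
  expect_equal(sort(unlist(pp$assignments[[1]])), 1:12)
  expect_equal(vapply(pp$assignments[[1]], length, 0L), rep(3L, 4))
  # reproducible per seed; fold sizes never differ by more than one
  pp2 <- make_fold_plan(small, "pair", k = 4, repetitions = 1, seed = 4)
  expect_identical(pp$assignments, pp2$assignments)
  odd <- make_fold_plan(rand_net(7, 3, seed = 5), "new_drug", k = 3,
                        repetitions = 1, seed = 6)
  sizes <- vapply(odd$assignments[[1]], length, 0L)
  expect_lte(diff(range(sizes)), 1L)
  expect_error(make_fold_plan(small, "new_drug", k = 5), "folds from 3")
})

test_that("training views never leak held-out information", {
  net <- rand_net(10, 8, density = 0.3, seed = 7)
  for (scen in c("new_drug", "new_target")) {
    plan <- make_fold_plan(net, scen, k = 5, repetitions = 2, seed = 8)
    for (r in 1:2) for (f in 1:5) {
      v <- training_view(net, plan, r, f)
      expect_true(audit_leakage(v))
      if (scen == "new_drug") {
        expect_length(intersect(unique(v$test_pairs$drug),
                                v$train_net$drugs), 0)
        # every pair of a held-out drug is test
        held <- plan$assignments[[r]][[f]]
        expect_equal(nrow(v$test_pairs), length(held) * net$n_targets)
      }
    }
  }
})

test_that("pair-scenario views zero exactly the held-out cells", {
  net <- rand_net(6, 5, density = 0.4, seed = 9)
  plan <- make_fold_plan(net, "pair", k = 5, repetitions = 1, seed = 10)
  v <- training_view(net, plan, 1, 2)
  expect_equal(sum(net$Y) - sum(v$train_net$Y), sum(v$test_pairs$label))
  # reconstruction round trip
  Y_rec <- v$train_net$Y
  Y_rec[cbind(v$test_pairs$target_pos, v$test_pairs$drug_pos)] <-
    v$test_pairs$label
  expect_equal(Y_rec, net$Y)
})

test_that("balanced subsampling keeps positives and samples negatives", {
  tp <- data.frame(drug_pos = 1, target_pos = 1,
                   label = c(rep(1, 5), rep(0, 100)))
  out <- subsample_negatives(tp, ratio = 1, seed = 3)
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$label), 5)
  out2 <- subsample_negatives(tp, ratio = 1, seed = 3)
  expect_identical(out, out2)                       # determinism
  kept_neg <- which(out$label == 0)
  expect_equal(anyDuplicated(rownames(out)), 0L)    # sampling w/o replacement
  expect_warning(subsample_negatives(tp, ratio = 25, seed = 1),
                 "keeping all")
})

test_that("AUPR is average precision with tie blocks", {
  expect_equal(aupr(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)   # perfect separation
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  # tied block evaluated at the block end
  expect_equal(aupr(c(1, 1, 0), c(1, 0, 1)), (1 / 2 + 2 / 3) / 2)
  expect_error(aupr(c(1, 2), c(1, 1)), "positive and one negative")
  # rank-walk oracle on random instances, with and without ties
  for (s in 1:5) {
    dat <- withr::with_seed(s, {
      n <- sample(20:200, 1)
      list(s = sample(seq(0, 1, 0.05), n, replace = TRUE),
           l = rbinom(n, 1, 0.3))
    })
    if (sum(dat$l) == 0 || sum(dat$l) == length(dat$l)) next
    expect_equal(aupr(dat$s, dat$l), aupr_rank_walk(dat$s, dat$l),
                 tolerance = 1e-12)
  }
})

test_that("a random scorer on balanced labels sits near AUPR 0.5", {
  val <- withr::with_seed(42, {
    labels <- rep(c(0, 1), 1000)
    aupr(runif(2000), labels)
  })
  expect_gt(val, 0.4)
  expect_lt(val, 0.6)
})

test_that("cross-validation drives every method end to end", {
  sim <- simulate_dti(n_drugs = 18, n_targets = 12, density = 0.15,
                      drug_noise = c(0, 1), target_noise = c(0, 1), seed = 21)
  for (m in c("mean", "ka", "kronrls_mkl")) {
    res <- cv_evaluate(sim$net, sim$drug_kernels, sim$target_kernels,
                       method = m, scenario = "pair", k = 3,
                       repetitions = 2, seed = 5, lambda = 1, sigma = 0.25)
    expect_equal(nrow(res$results), 6L)
    expect_true(all(res$results$aupr >= 0 & res$results$aupr <= 1))
    expect_equal(res$mean, mean(res$results$aupr))
  }
  # single kernel per side via the plain method, cold-start scenario
  res2 <- cv_evaluate(sim$net, sim$drug_kernels[1], sim$target_kernels[1],
                      method = "kronrls", scenario = "new_drug", k = 3,
                      repetitions = 1, seed = 6, lambda = 1)
  expect_equal(nrow(res2$results), 3L)
  # determinism
  res3 <- cv_evaluate(sim$net, sim$drug_kernels[1], sim$target_kernels[1],
                      method = "kronrls", scenario = "new_drug", k = 3,
                      repetitions = 1, seed = 6, lambda = 1)
  expect_identical(res2$results, res3$results)
})

test_that("nested CV reduces to plain CV for a single grid point", {
  sim <- simulate_dti(n_drugs = 15, n_targets = 10, density = 0.2,
                      drug_noise = 0, target_noise = 0, seed = 22)
  plain <- cv_evaluate(sim$net, sim$drug_kernels, sim$target_kernels,
                       method = "kronrls", scenario = "pair", k = 3,
                       repetitions = 1, seed = 9, lambda = 2)
  nested <- nested_cv(sim$net, sim$drug_kernels, sim$target_kernels,
                      method = "kronrls", scenario = "pair", k = 3,
                      repetitions = 1, seed = 9, lambda_grid = 2)
  expect_equal(nested$results$aupr, plain$results$aupr)
  expect_true(all(nested$results$lambda == 2))
})

test_that("nested CV picks grid members and recovers a planted optimum", {
  sim <- simulate_dti(density = 0.1, seed = 7)
  planted <- plant_hyperparameter_signal(sim, target_lambda = 2^-5)
  grid <- 2^seq(-15, 30, by = 5)
  res <- nested_cv(planted$net, planted$drug_kernels, planted$target_kernels,
                   method = "mean", scenario = "pair", k = 3,
                   repetitions = 1, inner_k = 3, seed = 101,
                   lambda_grid = grid)
  expect_true(all(res$results$lambda %in% grid))
  expect_gte(sum(res$results$lambda == 2^-5), 2)   # majority of 3 folds
})

test_that("novel predictions exclude known pairs and sort deterministically", {
  net <- rand_net(4, 4, density = 0.4, seed = 30)
  scores <- withr::with_seed(31, matrix(runif(16), 4, 4))
  ranked <- rank_novel_predictions(scores, net, top_n = 5)
  expect_equal(nrow(ranked), 5L)
  known <- paste(net$drugs[which(net$Y == 1, arr.ind = TRUE)[, 2]],
                 net$targets[which(net$Y == 1, arr.ind = TRUE)[, 1]])
  expect_length(intersect(paste(ranked$drug, ranked$target), known), 0)
  # full-sort oracle
  all_ranked <- rank_novel_predictions(scores, net, top_n = 16)
  expect_true(all(diff(all_ranked$score) <= 1e-15))
  # tie-break by drug then target id
  tied <- matrix(0.5, 4, 4)
  rt <- rank_novel_predictions(tied, net, top_n = 3)
  expect_identical(rt$drug, sort(rt$drug))
})
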
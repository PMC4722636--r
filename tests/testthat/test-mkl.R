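test_that("the residual target U = Y - lambda*A/2 is computed elementwise", {
  net <- rand_net(4, 3, density = 0.5, seed = 1)
  expect_equal(residual_target(net, matrix(0, 3, 4), 1), net$Y)
  expect_equal(max(abs(residual_target(net, net$Y, 2))), 0)
  A <- matrix(rnorm(12), 3, 4)
  U <- residual_target(net, A, 0.7)
  for (i in 1:3) for (j in 1:4)
    expect_equal(U[i, j], net$Y[i, j] - 0.35 * A[i, j])
})

test_that("weight designs match per-kernel triple-product loops", {
  net <- rand_net(4, 3, density = 0.5, seed = 2)
  A <- withr::with_seed(3, matrix(rnorm(12), 3, 4))
  # identity kernels with A = Y: every column is vec(Y)
  M0 <- weight_design(list(diag(4), diag(4)), diag(3), net$Y, "drug")
  expect_equal(M0[, 1], as.vector(net$Y))
  expect_equal(M0[, 2], as.vector(net$Y))

  kd <- lapply(1:3, rand_pd, n = 4)
  kt <- lapply(4:5, rand_pd, n = 3)
  Kt_star <- mean_combination(kt)
  Md <- weight_design(kd, Kt_star, A, "drug")
  expect_equal(dim(Md), c(12L, 3L))
  for (h in 1:3)
    expect_equal(Md[, h], as.vector(Kt_star %*% A %*% t(kd[[h]])),
                 tolerance = 1e-12)
  Kd_star <- mean_combination(kd)
  Mt <- weight_design(kt, Kd_star, A, "target")
  for (h in 1:2)
    expect_equal(Mt[, h], as.vector(kt[[h]] %*% A %*% t(Kd_star)),
                 tolerance = 1e-12)
})

test_that("the simplex weight subproblem attains the constrained argmin", {
  expect_equal(as.numeric(solve_weight_subproblem(matrix(1, 5, 1),
                                                  rnorm(5), 1, 0.5)), 1)
  # duplicated columns with sigma > 0 split the weight evenly
  M <- withr::with_seed(1, matrix(rnorm(30), 30, 1))[, c(1, 1)]
  b <- solve_weight_subproblem(M, rnorm(30), 1, 0.3)
  expect_equal(as.numeric(b), c(0.5, 0.5), tolerance = 1e-9)

  # grid-search oracle over the 1-simplex on random 2-kernel toys
  for (s in 1:5) {
    dat <- withr::with_seed(s, list(M = matrix(rnorm(80), 40, 2),
                                    u = rnorm(40),
                                    sigma = sample(c(0, 0.25, 1), 1)))
    lam <- 0.8
    obj <- function(b1) {
      beta <- c(b1, 1 - b1)
      sum((dat$u - dat$M %*% beta)^2) / (2 * lam * 40) +
        dat$sigma * sum(beta^2)
    }
    grid <- seq(0, 1, by = 1e-4)
    grid_obj <- vapply(grid, obj, numeric(1))
    beta <- solve_weight_subproblem(dat$M, dat$u, lam, dat$sigma)
    expect_lte(attr(beta, "objective"), min(grid_obj) + 1e-9)
    expect_lt(abs(beta[1] - grid[which.min(grid_obj)]), 2e-4)
    expect_equal(sum(beta), 1, tolerance = 1e-12)
    expect_true(all(beta >= 0))
  }
})

test_that("each beta-step can only improve its own subproblem objective", {
  net <- rand_net(8, 6, density = 0.3, seed = 11)
  kd <- lapply(1:3, rand_pd, n = 8)
  kt <- lapply(4:6, rand_pd, n = 6)
  lam <- 0.5; sig <- 0.25
  beta_old <- c(0.6, 0.3, 0.1)
  Kt_star <- mean_combination(kt)
  fit <- kronrls(weighted_combination(kd, beta_old), Kt_star, net, lam)
  u <- as.vector(residual_target(net, fit$A, lam))
  Md <- weight_design(kd, Kt_star, fit$A, "drug")
  obj <- function(beta) sum((u - Md %*% beta)^2) / (2 * lam * net$n_pairs) +
    sig * sum(beta^2)
  beta_new <- solve_weight_subproblem(Md, u, lam, sig)
  expect_lte(obj(beta_new), obj(beta_old) + 1e-12)
})

test_that("single-kernel MKL degenerates exactly to KronRLS", {
  net <- rand_net(6, 5, density = 0.3, seed = 12)
  Kd <- rand_pd(6, 12); Kt <- rand_pd(5, 13)
  plain <- kronrls(Kd, Kt, net, lambda = 0.7)
  mkl <- kronrls_mkl(list(Kd), list(Kt), net, lambda = 0.7, sigma = 0.5)
  expect_lt(max(abs(mkl$A - plain$A)), 1e-10)
  expect_lt(max(abs(fitted(mkl) - fitted(plain))), 1e-10)
  expect_equal(unname(mkl$beta_drug), 1)
  expect_true(mkl$converged)
})

test_that("duplicated kernels share their weight under L2 regularization", {
  sim <- simulate_dti(n_drugs = 20, n_targets = 15, density = 0.15,
                      drug_noise = c(0, 1), target_noise = c(0, 1), seed = 4)
  kd <- c(sim$drug_kernels, sim$drug_kernels)
  names(kd) <- paste0("k", 1:4)
  kt <- c(sim$target_kernels, sim$target_kernels)
  names(kt) <- paste0("k", 1:4)
  fit <- kronrls_mkl(kd, kt, sim$net, lambda = 1, sigma = 0.25)
  expect_lt(abs(fit$beta_drug[1] - fit$beta_drug[3]), 1e-6)
  expect_lt(abs(fit$beta_drug[2] - fit$beta_drug[4]), 1e-6)
  expect_lt(abs(fit$beta_target[1] - fit$beta_target[3]), 1e-6)
})

test_that("weights stay on the simplex at every recorded iteration", {
  sim <- simulate_dti(n_drugs = 25, n_targets = 18, density = 0.12, seed = 5)
  fit <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
                     lambda = 0.5, sigma = 0.1)
  bd <- as.matrix(fit$trace[, grep("^beta_d\\.", names(fit$trace))])
  bt <- as.matrix(fit$trace[, grep("^beta_t\\.", names(fit$trace))])
  expect_equal(unname(rowSums(bd)), rep(1, nrow(bd)), tolerance = 1e-12)
  expect_equal(unname(rowSums(bt)), rep(1, nrow(bt)), tolerance = 1e-12)
  expect_true(all(bd >= -1e-15) && all(bt >= -1e-15))
})

test_that("large sigma pulls the weights toward uniform", {
  sim <- simulate_dti(n_drugs = 25, n_targets = 18, density = 0.12, seed = 6)
  P <- length(sim$drug_kernels)
  dist_unif <- vapply(c(0, 0.5, 5, 500), function(sig) {
    fit <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
                       lambda = 1, sigma = sig)
    sqrt(sum((fit$beta_drug - 1 / P)^2))
  }, numeric(1))
  expect_true(all(diff(dist_unif) <= 1e-9))
})

test_that("training is deterministic: identical runs give identical traces", {
  sim <- simulate_dti(n_drugs = 20, n_targets = 15, density = 0.15, seed = 7)
  f1 <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
                    lambda = 1, sigma = 0.25)
  f2 <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
                    lambda = 1, sigma = 0.25)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$A, f2$A)
})

test_that("the informative kernel wins the weights on synthetic data", {
  hits <- 0L
  for (s in 1:3) {
    sim <- simulate_dti(seed = s)    # one informative + three irrelevant
    fit <- kronrls_mkl(sim$drug_kernels, sim$target_kernels, sim$net,
                       lambda = 1, sigma = 0.25)
    hits <- hits + (which.max(fit$beta_drug) == 1L) +
      (which.max(fit$beta_target) == 1L)
  }
  expect_gte(hits, 5L)
})

test_that("the monitoring objective matches an independent evaluation", {
  net <- rand_net(5, 4, density = 0.4, seed = 14)
  kd <- lapply(1:2, rand_pd, n = 5)
  kt <- lapply(3:4, rand_pd, n = 4)
  bd <- c(0.3, 0.7); bt <- c(0.9, 0.1)
  A <- withr::with_seed(15, matrix(rnorm(20), 4, 5))
  lam <- 0.6; sig <- 0.2
  got <- mkl_objective(kd, kt, bd, bt, A, net, lam, sig)
  # independent evaluation through the explicit Kronecker product
  Kd <- bd[1] * kd[[1]] + bd[2] * kd[[2]]
  Kt <- bt[1] * kt[[1]] + bt[2] * kt[[2]]
  Kbig <- kronecker(Kd, Kt)
  a <- as.vector(A); y <- as.vector(net$Y)
  u <- y - lam * a / 2
  ref <- sum((u - Kbig %*% a)^2) / (2 * lam * 20) +
    0.5 * sum(a * (y - lam * a)) + sig * (sum(bd^2) + sum(bt^2))
  expect_equal(got, ref, tolerance = 1e-10)
})
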
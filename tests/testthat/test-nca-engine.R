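test_that("noiseless synthetic data is recovered to machine precision", {
  truth <- simulate_truth(n_genes = 40, n_tfs = 5, noise_sd = 0, seed = 19)
  fit <- nca(truth$expression, truth$prior, n_restarts = 3, seed = 2)
  expect_lt(fit$objective, 1e-10 * sqrt(sum(unclass(truth$expression)^2)))
  canon <- truth_canonical(truth)
  for (tf in rownames(fit$activities))
    expect_gt(abs(cor(fit$activities[tf, ], canon$activities[tf, ])), 0.999)
  for (tf in colnames(fit$strengths))
    expect_gt(abs(cor(fit$strengths[, tf], canon$strengths[, tf])), 0.999)
  # support preserved bit-exactly
  expect_true(all(fit$strengths[!truth$prior$support] == 0))
})

test_that("diagonal support decouples into per-gene scalings", {
  stages <- c("c0", sprintf("s%d", 1:5))
  set.seed(5)
  A_true <- matrix(rnorm(3 * 6), 3, 6, dimnames = list(sprintf("TF%02d", 1:3), stages))
  A_true[, "c0"] <- 0
  attr(A_true, "control_stage") <- "c0"
  s <- diag(c(0.5, -0.8, 0.9))
  dimnames(s) <- list(sprintf("g%d", 1:3), sprintf("TF%02d", 1:3))
  prior <- connectivity_prior(s)
  E <- generate_expression(prior, A_true, noise_sd = 0)
  fit <- nca(E, prior, n_restarts = 2, seed = 1)
  expect_lt(max(abs(fitted(fit) - unclass(E))), 1e-10)
  # each activity row is a scaled copy of the matching expression row
  for (i in 1:3)
    expect_gt(abs(cor(fit$activities[i, ], unclass(E)[i, ])), 0.999999)
})

test_that("ALS trajectories are monotone and respect the support", {
  set.seed(77)
  for (i in 1:15) {
    N <- sample(8:16, 1); L <- sample(2:4, 1); M <- sample(max(L + 1, 5):8, 1)
    truth <- simulate_truth(n_genes = N, n_tfs = L,
                            stage_labels = sprintf("s%02d", seq_len(M)),
                            control_stage = "s01",
                            edges_per_gene = max(1, min(2, L - 1)),
                            noise_sd = 0.2, seed = 100 + i)
    fit <- nca(truth$expression, truth$prior, max_iter = 60, n_restarts = 2,
               seed = i, normalization = "none")
    expect_true(all(diff(fit$objective_trajectory) <= 1e-9))
    expect_true(all(fit$strengths[!truth$prior$support] == 0))
    # best-of-restarts never loses to the coexpression-initialized solution
    expect_lte(fit$objective,
               fit$objective_trajectory[1] + 1e-12)
  }
})

test_that("normalization fixes the diagonal gauge canonically", {
  truth <- simulate_truth(n_genes = 30, n_tfs = 4, noise_sd = 0.05, seed = 8)
  fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 3)
  # idempotence
  again <- normalize_nca(fit, "control-zero")
  expect_equal(again$strengths, fit$strengths, tolerance = 1e-12)
  expect_equal(again$activities, fit$activities, tolerance = 1e-12)
  # gauge invariance: a random nonsingular diagonal X washes out
  set.seed(9)
  x <- runif(4, 0.3, 3) * sample(c(-1, 1), 4, TRUE)
  pert <- fit
  pert$strengths <- fit$strengths %*% diag(x)
  dimnames(pert$strengths) <- dimnames(fit$strengths)
  pert$activities <- diag(1 / x) %*% fit$activities
  dimnames(pert$activities) <- dimnames(fit$activities)
  expect_lt(max(abs(pert$strengths %*% pert$activities -
                    fit$strengths %*% fit$activities)), 1e-10)
  renorm <- normalize_nca(pert, "control-zero")
  expect_equal(renorm$strengths, fit$strengths, tolerance = 1e-8)
  expect_equal(renorm$activities, fit$activities, tolerance = 1e-8)
  # product preserved by normalization itself
  raw <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 3,
             normalization = "none")
  nrm <- normalize_nca(raw, "control-zero")
  expect_lt(max(abs(raw$strengths %*% raw$activities -
                    nrm$strengths %*% nrm$activities)), 1e-10)
  expect_true(all(nrm$activities[, "MP"] == 0))
  # unit-activity-norm convention scales activity rows to unit norm
  uan <- normalize_nca(raw, "unit-activity-norm")
  expect_equal(unname(sqrt(rowSums(uan$activities^2))), rep(1, 4), tolerance = 1e-10)
})

test_that("non-identifiable priors are refused with the diagnostic", {
  s <- matrix(0, 4, 2, dimnames = list(sprintf("g%d", 1:4), c("t1", "t2")))
  s[, 1] <- 0.9; s[, 2] <- 0.8          # identical support columns
  p <- connectivity_prior(s)
  E <- expression_matrix(matrix(rnorm(4 * 3), 4, 3,
                                dimnames = list(rownames(s), c("c0", "s1", "s2"))) *
                           rep(c(0, 1, 1), each = 4),
                         "c0")
  expect_error(nca(E, p), "not identifiable")
})

test_that("reconstruction error reports Frobenius and per-gene residuals", {
  truth <- simulate_truth(n_genes = 20, n_tfs = 3, edges_per_gene = 2, noise_sd = 0, seed = 30)
  fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 1)
  err <- reconstruction_error(fit)
  expect_lt(err$frobenius, 1e-10 * sqrt(sum(unclass(truth$expression)^2)))
  expect_length(err$per_gene, nrow(fit$strengths))
  # S = 0 leaves the full norm of E
  zfit <- fit
  zfit$strengths[] <- 0
  expect_equal(reconstruction_error(zfit)$frobenius,
               sqrt(sum(fit$E^2)), tolerance = 1e-12)
})

test_that("model methods expose the fit coherently", {
  truth <- simulate_truth(n_genes = 24, n_tfs = 3, edges_per_gene = 2, noise_sd = 0.1, seed = 44)
  fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 4)
  expect_identical(coef(fit), fit$strengths)
  expect_identical(coef(fit, "activities"), fit$activities)
  expect_equal(fitted(fit) + residuals(fit), fit$E, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  newA <- fit$activities * 0.5
  expect_equal(predict(fit, newA), fit$strengths %*% newA)
  sims <- simulate(fit, nsim = 2, seed = 7, noise_sd = 0.2)
  expect_length(sims, 2)
  expect_false(identical(unclass(sims[[1]]), unclass(sims[[2]])))
  expect_true(all(unclass(sims[[1]])[, "MP"] == 0))
  expect_output(print(fit), "NCA fit")
  expect_output(print(summary(fit)), "Objective")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("bootstrap intervals degenerate correctly and cover the truth", {
  truth <- simulate_truth(n_genes = 30, n_tfs = 4, noise_sd = 0.05, seed = 15)
  fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 2)
  one <- nca_bootstrap(truth$expression, truth$prior, n_boot = 1, seed = 5, fit = fit)
  expect_equal(one$strength_lower, one$strength_upper)
  expect_equal(one$activity_lower, one$activity_upper)

  # near-noiseless data: interval widths collapse
  tiny <- simulate_truth(n_genes = 30, n_tfs = 4, noise_sd = 1e-4, seed = 16)
  ftiny <- nca(tiny$expression, tiny$prior, n_restarts = 2, seed = 2)
  btiny <- nca_bootstrap(tiny$expression, tiny$prior, n_boot = 20, seed = 6, fit = ftiny)
  widths <- btiny$activity_upper - btiny$activity_lower
  expect_lt(stats::median(widths, na.rm = TRUE), 0.01)

  # coverage at realistic noise: >= 90% of the true activity values fall in the
  # 95% intervals (the activity matrix is a global parameter, for which
  # resampling genes is a consistent bootstrap; per-gene strengths are not --
  # a gene's own measurement noise is never redrawn, so their intervals
  # quantify only the activity-induced uncertainty)
  cov_truth <- simulate_truth(n_genes = 60, n_tfs = 5, noise_sd = 0.2, seed = 3,
                              edges_per_gene = 2,
                              stage_labels = sprintf("S%02d", 1:20),
                              control_stage = "S01")
  cfit <- nca(cov_truth$expression, cov_truth$prior, n_restarts = 3, seed = 3)
  bs <- nca_bootstrap(cov_truth$expression, cov_truth$prior, n_boot = 100,
                      seed = 3, fit = cfit)
  canon <- truth_canonical(cov_truth)
  At <- canon$activities
  inside <- At >= bs$activity_lower - 1e-9 & At <= bs$activity_upper + 1e-9
  expect_gte(mean(inside), 0.9)
  # the reference point estimate sits inside its own intervals
  on_support <- cov_truth$prior$support & !is.na(bs$strength_lower)
  ref_in <- cfit$strengths[on_support] >= bs$strength_lower[on_support] - 1e-9 &
            cfit$strengths[on_support] <= bs$strength_upper[on_support] + 1e-9
  expect_gte(mean(ref_in), 0.8)
})
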
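test_that("the gene-tree log-likelihood nests the MSC and is order-invariant", {
  m0 <- msci_model("INFLOW", tau_T = 0.012, tau_R = 0.03, tau_H = 0.006,
                   tau_O = 0.15, theta = 0.04, gamma = 0)
  tr <- simulate_triples(m0, 200, seed = 601)
  ll <- msci_loglik(m0, tr)
  ll_hand <- sum(mapply(function(k, t1, t2)
    msc_logpdf(as.character(k), t1, t2, 0.012, 0.03, 0.04),
    tr$topology, tr$t1, tr$t2))
  expect_equal(ll, ll_hand, tolerance = 1e-10)
  expect_equal(msci_loglik(m0, tr[sample(nrow(tr)), ]), ll)
  # infeasible ages yield -Inf, not an error
  bad <- data.frame(topology = "ab|c", t1 = 0.001, t2 = 0.05)
  expect_identical(msci_loglik(m0, bad), -Inf)
  expect_error(msci_loglik(m0, data.frame(topology = "ab|c", t1 = 3, t2 = 1)),
               "t1 > t2")
})

test_that("the generating scenario has the highest mean log-likelihood", {
  models <- lapply(c(GHOST = "GHOST", INFLOW = "INFLOW", OUTFLOW = "OUTFLOW"),
                   msci_from_grid, C1 = 0.3, C2 = 0.5, gamma = 0.3)
  tr <- simulate_triples(models$INFLOW, 1000, seed = 602)
  lls <- vapply(models, msci_loglik, 0, data = tr)
  expect_equal(names(which.max(lls)), "INFLOW")
  expect_gt(sort(lls, decreasing = TRUE)[1] - sort(lls, decreasing = TRUE)[2], 20)
})

test_that("fitting recovers the generating parameters", {
  truth <- msci_from_grid("INFLOW", 0.3, 0.5, 0.3)
  tr <- simulate_triples(truth, 800, seed = 603)
  fit <- msci_fit(tr, "INFLOW", n_restarts = 4, seed = 603)
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est[["gamma"]] - 0.3), 0.1)
  expect_lt(abs(est[["tau_R"]] - truth$tau_R) / truth$tau_R, 0.15)
  expect_lt(abs(est[["theta"]] - 0.036) / 0.036, 0.2)
  expect_lt(abs(est[["tau_S"]] - truth$tau_H) / truth$tau_H, 0.5)
  # optimizer contract: the fit is at least as good as the truth
  expect_gte(fit$loglik, msci_loglik(truth, tr) - 1e-6)
  # the logLik method carries the parameter count
  expect_equal(attr(logLik(fit), "df"), 5L)
  # a refit with the same seed is identical
  fit2 <- msci_fit(tr, "INFLOW", n_restarts = 4, seed = 603)
  expect_identical(coef(fit2), coef(fit))
})

test_that("tau_H is flagged unidentifiable for ghost fits, not otherwise", {
  truth <- msci_from_grid("GHOST", 0.3, 0.5, 0.3)
  tr <- simulate_triples(truth, 400, seed = 604)
  fit <- msci_fit(tr, "GHOST", n_restarts = 2, seed = 604)
  expect_false(fit$tau_H_estimable)
  # the ghost likelihood is genuinely constant in tau_H
  m1 <- fit$model; m2 <- fit$model
  m1$tau_H <- 0.2 * m1$tau_T; m2$tau_H <- 0.9 * m2$tau_T
  expect_equal(msci_loglik(m1, tr), msci_loglik(m2, tr))
  fit_in <- msci_fit(tr, "INFLOW", n_restarts = 2, seed = 604)
  expect_true(fit_in$tau_H_estimable)
})

test_that("scenario selection is decisive and seed-deterministic", {
  truth <- msci_from_grid("OUTFLOW", 0.3, 0.5, 0.3)
  tr <- simulate_triples(truth, 800, seed = 605)
  sel <- msci_select(tr, n_restarts = 4, seed = 605)
  expect_equal(sel$best, "OUTFLOW")
  expect_true(all(sel$delta >= 0))
  expect_equal(sel$ranking[1], sel$best)
  sel2 <- msci_select(tr, n_restarts = 4, seed = 605)
  expect_identical(sel2$loglik, sel$loglik)
  # gamma = 0 data: the three scenarios coincide, differences are negligible
  null_tr <- simulate_triples(msci_from_grid("GHOST", 0.3, 0.5, 0), 800,
                              seed = 606)
  sel0 <- msci_select(null_tr, n_restarts = 4, seed = 606)
  expect_lt(max(sel0$delta), 3)
})

test_that("per-population sizes: the root theta is the well-estimated one", {
  truth <- msci_from_grid("INFLOW", 0.3, 0.5, 0.3)
  ests <- t(replicate(6, {
    tr <- simulate_triples(truth, 600)
    fit <- msci_fit(tr, "INFLOW", theta_mode = "per_pop", n_restarts = 3,
                    seed = 607)
    coef(fit)[c("theta_T", "theta_C", "theta_R")]
  }))
  rel_err <- abs(ests - 0.036) / 0.036
  # theta_R (hosting most coalescences) is estimated better than theta_T and
  # theta_C, which see few lineages
  expect_lt(mean(rel_err[, "theta_R"]), mean(rel_err[, "theta_T"]))
  expect_lt(mean(rel_err[, "theta_R"]), mean(rel_err[, "theta_C"]))
})

test_that("estimation error shrinks as loci accumulate", {
  truth <- msci_from_grid("GHOST", 0.3, 0.5, 0.3)
  set.seed(608)
  rmse <- vapply(c(150, 600, 2400), function(n) {
    errs <- replicate(3, {
      fit <- msci_fit(simulate_triples(truth, n), "GHOST", n_restarts = 3,
                      seed = 608)
      c(fit$model$gamma - 0.3, fit$model$tau_R - truth$tau_R)
    })
    sqrt(mean(errs^2))
  }, 0)
  expect_lt(rmse[3], rmse[1])
})

test_that("fit methods expose the usual modelling surface", {
  truth <- msci_from_grid("GHOST", 0.3, 0.5, 0.3)
  tr <- simulate_triples(truth, 300, seed = 609)
  fit <- msci_fit(tr, "GHOST", n_restarts = 2, seed = 609)
  expect_output(print(fit), "GHOST")
  expect_output(summary(fit), "C_T")
  sims <- simulate(fit, nsim = 50, seed = 1)
  expect_s3_class(sims, "data.frame")
  expect_equal(nrow(sims), 50L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_warning(msci_fit(tr[1:20, ], "GHOST", n_restarts = 1, seed = 1),
                 "fewer than 50")
})
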
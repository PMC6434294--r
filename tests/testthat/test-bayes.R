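test_that("prior gradients have their closed forms", {
  expect_equal(unname(prior_gradient("noninformative", c(1, 2, 3))),
               c(-1, -0.5, -1 / 3))
  g <- prior_gradient("gamma_scale", c(1, 2, 3), a = 2, b = 1)
  expect_equal(unname(g[2]), (2 - 1) / 2 - 1)  # = -0.5
  expect_equal(unname(g[c(1, 3)]), c(-1, -1 / 3))
  # a = 1, b -> 0 is flat in lambda
  g0 <- prior_gradient("gamma_scale", c(1, 2, 3), a = 1, b = 1e-12)
  expect_equal(unname(g0[2]), 0, tolerance = 1e-10)
  expect_error(prior_gradient("noninformative", c(1, 2, 0)), "degenerate")
  expect_error(prior_gradient("gamma_scale", c(1, 2, 3)), "hyperparameters")
})

test_that("Lindley contractions equal a brute-force triple loop", {
  set.seed(51)
  cs <- random_case(n = 60)
  fit <- frechet_fit(cs$x, methods = "ML")
  sigma <- fit$fisher$sigma
  lt <- lindley_contractions(fit$par, cs$x, sigma)
  for (k in 1:3) {
    brute <- 0
    for (i in 1:3) for (j in 1:3) brute <- brute + lt$L3[i, j, k] * sigma[i, j]
    expect_equal(unname(lt$Lambda[k]), brute, tolerance = 1e-12)
  }
  rho <- prior_gradient("noninformative", fit$par)
  b <- lt$bfun(rho)
  for (i in 1:3) {
    brute <- sum(rho * sigma[i, ])
    expect_equal(unname(b[i]), brute)
  }
  # linear contraction: zero gradient gives zero weights
  expect_equal(unname(lt$bfun(c(0, 0, 0))), c(0, 0, 0))
})

test_that("derived LINEX at k -> 0 and GE at k = -1 both give the Lindley posterior mean", {
  set.seed(52)
  x <- rfrechet(80, 1, 2, 3)
  fit <- frechet_fit(x, methods = "ML")
  sigma <- fit$fisher$sigma
  lt <- lindley_contractions(fit$par, x, sigma)
  rho <- prior_gradient("noninformative", fit$par)
  b <- lt$bfun(rho)
  pmean <- vapply(1:3, function(p) {
    fit$par[p] + b[p] + 0.5 * sum(lt$Lambda * sigma[, p])
  }, numeric(1))
  tiny_k <- frechet_fit(x, k = 1e-7, variant = "derived",
                        methods = c("ML", "BLNP"))
  expect_equal(unname(tiny_k$estimates["BLNP", ]), pmean, tolerance = 1e-5)
  ge_m1 <- frechet_fit(x, k = -1, variant = "derived",
                       methods = c("ML", "BGENP"))
  expect_equal(unname(ge_m1$estimates["BGENP", ]), pmean, tolerance = 1e-10)
})

test_that("derived-variant estimators agree with direct posterior integration", {
  # exact posterior expectations by 3-D Gauss-Legendre quadrature of
  # likelihood x noninformative prior; the Lindley error is O(1/n) so
  # the n = 200 discrepancy must undercut the n = 50 one
  set.seed(101)
  diffs <- sapply(c(50, 200), function(n) {
    x <- rfrechet(n, 1, 2, 3)
    fit <- frechet_fit(x, k = 1, variant = "derived",
                       methods = c("ML", "BLNP", "BGENP"))
    E <- posterior_expecter(x, fit$par, fit$fisher$sigma)
    d <- numeric(0)
    for (p in 1:3) {
      blnp_ex <- -log(E(function(a, l, e)
        exp(-switch(p, a, l, e))))
      bgenp_ex <- 1 / E(function(a, l, e) 1 / switch(p, a, l, e))
      d <- c(d, abs(fit$estimates["BLNP", p] - blnp_ex),
                abs(fit$estimates["BGENP", p] - bgenp_ex))
    }
    d
  })
  # agreement at both sizes (tolerance calibrated at 3x the discrepancy
  # scale observed for this generator) and shrinkage with n
  expect_lt(max(diffs[, 1]), 0.65)
  expect_lt(max(diffs[, 2]), 0.05)
  expect_lt(max(diffs[, 2]), max(diffs[, 1]))
})

test_that("LINEX estimates are monotone nonincreasing in k (derived variant)", {
  set.seed(53)
  x <- rfrechet(100, 1, 2, 3)
  ks <- c(0.25, 0.5, 1, 2)
  al <- vapply(ks, function(k) {
    frechet_fit(x, k = k, variant = "derived",
                methods = c("ML", "BLNP"))$estimates["BLNP", "alpha"]
  }, numeric(1))
  expect_true(all(diff(al) <= 1e-10))
})

test_that("all five estimators coincide asymptotically", {
  set.seed(54)
  x <- rfrechet(1e4, 1, 2, 3)
  fit <- frechet_fit(x)
  est <- fit$estimates
  for (m in rownames(est)[-1]) {
    expect_lt(max(abs(est[m, ] / est["ML", ] - 1)), 0.01)
  }
})

test_that("the posterior-mean correction shrinks like 1/n", {
  set.seed(55)
  corr <- sapply(c(200, 400, 800), function(n) {
    x <- rfrechet(n, 1, 2, 3)
    fit <- frechet_fit(x, methods = "ML")
    sigma <- fit$fisher$sigma
    lt <- lindley_contractions(fit$par, x, sigma)
    b <- lt$bfun(prior_gradient("noninformative", fit$par))
    max(abs(vapply(1:3, function(p)
      b[p] + 0.5 * sum(lt$Lambda * sigma[, p]), numeric(1))))
  })
  # roughly halves when n doubles: allow a generous band around 1/n decay
  expect_lt(corr[2], corr[1])
  expect_lt(corr[3], corr[2])
  expect_lt(corr[3], corr[1] / 2)
})

test_that("failed Bayes brackets degrade to flagged NA estimates, never abort", {
  # the head-and-neck data with default hyperparameters drives several
  # printed-variant brackets negative; the batch must still return
  x <- headneck()
  fit <- frechet_fit(x)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["ML", ]), unname(fit$par))
  expect_true(length(fit$flags) > 0)
  expect_true(any(is.na(fit$estimates)))
  expect_match(paste(unlist(fit$flags), collapse = " "), "nonpositive")
})
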
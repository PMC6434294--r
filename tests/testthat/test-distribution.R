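test_that("density has the closed form on the support and vanishes below it", {
  # at x = eta + lambda the standardized value is 1, so f = (alpha/lambda)/e
  for (p in list(c(1, 1, 0), c(1.5, 2, 3), c(0.5, 1.5, -2))) {
    expect_equal(dfrechet(p[3] + p[2], p[1], p[2], p[3]),
                 p[1] / p[2] * exp(-1))
  }
  expect_identical(dfrechet(3, shape = 1.5, scale = 2, loc = 3), 0)
  expect_identical(dfrechet(-5, shape = 1.5, scale = 2, loc = 3), 0)
  # extreme exponents underflow cleanly instead of erroring
  expect_identical(dfrechet(3 + 1e-300, shape = 2, scale = 1, loc = 3), 0)
  expect_equal(pfrechet(3 + 1e-300, shape = 2, scale = 1, loc = 3), 0)
})

test_that("density integrates to one and matches the cdf by quadrature", {
  p <- c(1.5, 2, 3)
  total <- integrate(dfrechet, lower = p[3], upper = Inf, shape = p[1],
                     scale = p[2], loc = p[3], rel.tol = 1e-10)
  expect_equal(total$value, 1, tolerance = 1e-6)
  set.seed(5)
  for (rep in 1:5) {
    a <- runif(1, 0.5, 3); l <- runif(1, 0.5, 3); e <- runif(1, -2, 4)
    total <- integrate(dfrechet, lower = e, upper = Inf, shape = a,
                       scale = l, loc = e, rel.tol = 1e-10)
    expect_equal(total$value, 1, tolerance = 1e-6)
    for (q in e + l * (-log(runif(4)))^(-1 / a)) {
      num <- integrate(dfrechet, lower = e, upper = q, shape = a,
                       scale = l, loc = e, rel.tol = 1e-10)$value
      expect_equal(pfrechet(q, a, l, e), num, tolerance = 1e-6)
    }
  }
})

test_that("cdf is monotone with the documented boundary values", {
  expect_equal(pfrechet(3 + 2, shape = 1.7, scale = 2, loc = 3), exp(-1))
  expect_identical(pfrechet(3, shape = 1.7, scale = 2, loc = 3), 0)
  xs <- seq(3.01, 30, length.out = 200)
  Fx <- pfrechet(xs, shape = 1.7, scale = 2, loc = 3)
  expect_true(all(diff(Fx) >= 0))
  expect_true(all(Fx >= 0 & Fx <= 1))
  # upper tail complements
  expect_equal(pfrechet(5, 1.7, 2, 3, lower.tail = FALSE),
               1 - pfrechet(5, 1.7, 2, 3))
})

test_that("quantile function inverts the cdf", {
  expect_equal(qfrechet(exp(-1), shape = 1.2, scale = 2, loc = 3), 5)
  expect_equal(qfrechet(0.5, shape = 1, scale = 2, loc = 3),
               3 + 2 / log(2))
  u <- seq(0.01, 0.99, by = 0.07)
  q <- qfrechet(u, shape = 0.8, scale = 1.5, loc = -1)
  expect_equal(pfrechet(q, 0.8, 1.5, -1), u, tolerance = 1e-12)
  expect_error(qfrechet(0, shape = 1), "inside")
  expect_error(qfrechet(1, shape = 1), "inside")
})

test_that("parameter domain is enforced", {
  expect_error(dfrechet(1, shape = -1), "shape")
  expect_error(pfrechet(1, shape = 1, scale = 0), "scale")
  expect_error(rfrechet(0, shape = 1), "n")
})

test_that("sampling is seeded, supported above eta, and consistent with the cdf", {
  set.seed(31); s1 <- rfrechet(500, 1.3, 2, 3)
  set.seed(31); s2 <- rfrechet(500, 1.3, 2, 3)
  expect_identical(s1, s2)
  expect_true(min(s1) > 3)
  # large-sample KS distance against the true cdf below the 1% critical
  # value 1.63 / sqrt(n)
  set.seed(99)
  x <- rfrechet(1e5, 1, 2, 3)
  D <- frechet_ks(x, c(1, 2, 3))$D
  expect_lt(D, 1.63 / sqrt(1e5))
})

test_that("log-likelihood equals the sum of log densities", {
  # single observation at eta + lambda with alpha = lambda = 1:
  # log 1 - log 1 - 1 = -1
  expect_equal(frechet_loglik(c(1, 1, 2), 3), -1)
  set.seed(17)
  for (rep in 1:10) {
    cs <- random_case()
    expect_equal(frechet_loglik(cs$par, cs$x),
                 sum(dfrechet(cs$x, cs$par[1], cs$par[2], cs$par[3],
                              log = TRUE)),
                 tolerance = 1e-10)
    expect_equal(frechet_loglik(cs$par, cs$x),
                 frechet_loglik(cs$par, rev(cs$x)))
  }
})

test_that("support violations raise a distinct error from bad parameters", {
  expect_error(frechet_loglik(c(1, 1, 5), c(4, 6)), "support violation")
  expect_error(frechet_loglik(c(-1, 1, 0), c(4, 6)), "invalid Frechet")
  expect_error(frechet_score(c(1, 1, 5), c(4, 6)), "support violation")
})

test_that("the sample reader handles comments, blanks and CSV headers", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "1.5", "", "2.5, 3.5", "  4.5 "), f)
  expect_equal(read_sample(f), c(1.5, 2.5, 3.5, 4.5))
  g <- tempfile(fileext = ".csv")
  writeLines(c("time", "1", "2"), g)
  expect_equal(read_sample(g), c(1, 2))
  expect_error(read_sample(tempfile()), "not found")
  h <- tempfile()
  writeLines(c("1", "abc", "2"), h)
  expect_error(read_sample(h), "parse")
  expect_length(headneck(), 44)
})
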
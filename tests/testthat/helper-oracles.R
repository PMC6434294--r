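# Independent oracles used across the suite.  Everything here is written
# directly from the model definition, not by calling the code paths under
# test.

# log density written out independently of dfrechet()
ref_logpdf <- function(x, a, l, e) {
  ifelse(x > e,
         log(a / l) - (a + 1) * log((x - e) / l) - ((x - e) / l)^(-a),
         -Inf)
}

ref_loglik <- function(par, x) sum(ref_logpdf(x, par[1], par[2], par[3]))

# central finite differences of an R^3 -> R function
fd_grad <- function(f, p, h = 1e-6) {
  vapply(1:3, function(i) {
    hi <- h * max(1, abs(p[i]))
    pp <- p; pp[i] <- pp[i] + hi
    pm <- p; pm[i] <- pm[i] - hi
    (f(pp) - f(pm)) / (2 * hi)
  }, numeric(1))
}

fd_jacobian <- function(g, p, h = 1e-6) {
  # g: R^3 -> R^3; returns 3x3 matrix of dg_j / dp_i in column i
  sapply(1:3, function(i) {
    hi <- h * max(1, abs(p[i]))
    pp <- p; pp[i] <- pp[i] + hi
    pm <- p; pm[i] <- pm[i] - hi
    (g(pp) - g(pm)) / (2 * hi)
  })
}

# draw a random admissible (parameters, data) configuration
random_case <- function(n = 40) {
  a <- runif(1, 0.6, 2.5)
  l <- runif(1, 0.5, 3)
  e <- runif(1, -2, 4)
  x <- e + l * (-log(runif(n)))^(-1 / a)
  # evaluate derivatives at a point near, but not at, the truth
  par <- c(a * runif(1, 0.8, 1.25), l * runif(1, 0.8, 1.25),
           e - runif(1, 0.05, 0.5))
  list(par = par, x = x)
}

# Posterior-expectation oracle: tensor-product Gauss-Legendre quadrature
# of the exact posterior (likelihood x noninformative prior) over a box
# of +/- 6 posterior standard deviations around the MLE.  Returns a
# closure evaluating E[g(alpha, lambda, eta) | x] for any g.
posterior_expecter <- function(x, mle, sigma, nq = 40) {
  se <- sqrt(diag(sigma))
  lo <- c(max(mle[1] - 6 * se[1], 1e-3),
          max(mle[2] - 6 * se[2], 1e-3),
          mle[3] - 6 * se[3])
  hi <- c(mle[1] + 6 * se[1], mle[2] + 6 * se[2],
          min(mle[3] + 6 * se[3], min(x) - 1e-9))
  gq <- lapply(1:3, function(i) pracma::gaussLegendre(nq, lo[i], hi[i]))
  grid <- expand.grid(a = gq[[1]]$x, l = gq[[2]]$x, e = gq[[3]]$x)
  w3 <- expand.grid(a = gq[[1]]$w, l = gq[[2]]$w, e = gq[[3]]$w)
  w3 <- w3$a * w3$l * w3$e
  lp <- mapply(function(a, l, e) {
    ref_loglik(c(a, l, e), x) - log(a) - log(l) - log(abs(e))
  }, grid$a, grid$l, grid$e)
  lp <- lp - max(lp)
  base <- w3 * exp(lp)
  den <- sum(base)
  function(g) sum(base * g(grid$a, grid$l, grid$e)) / den
}

headneck <- function() {
  read_sample(system.file("extdata", "headneck_survival.txt",
                          package = "frechet3"))
}
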
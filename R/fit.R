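#' Optimizer settings for Frechet model fitting
#'
#' @param tol convergence tolerance on the scaled score: the fit is
#'   declared converged when the gradient of the log-likelihood in the
#'   elasticity coordinates (log alpha, log lambda, log(min(x) - eta)) has
#'   max-norm below \code{tol}.
#' @param maxit maximum BFGS iterations per start.
#' @param restarts number of additional deterministic jittered starting
#'   points tried when a start fails to converge.
#' @param newton_steps maximum Newton polishing steps applied after BFGS.
#' @return a list of class \code{frechet_control}.
#' @export
frechet_control <- function(tol = 1e-8, maxit = 500, restarts = 5,
                            newton_steps = 30) {
  stopifnot(tol > 0, maxit >= 1, restarts >= 0)
  structure(list(tol = tol, maxit = maxit, restarts = restarts,
                 newton_steps = newton_steps),
            class = "frechet_control")
}

#' Deterministic starting values for the Frechet fit
#'
#' Places the location just below the sample minimum
#' (\code{eta0 = min(x) - 0.1 * (median(x) - min(x))}), then solves the
#' two-quantile system of the Frechet quantile function at probabilities
#' 0.25 and 0.75 on the shifted data for the shape and scale.
#'
#' @param x data vector with at least 4 distinct values.
#' @return named triple \code{c(alpha, lambda, eta)} with
#'   \code{eta < min(x)}.
#' @export
frechet_init <- function(x) {
  if (length(x) < 4L)
    stop("need at least 4 observations to fit three parameters",
         call. = FALSE)
  spread <- stats::median(x) - min(x)
  if (spread <= 0)
    stop("data have no spread above the minimum; ",
         "the three-parameter Frechet model is unidentifiable",
         call. = FALSE)
  eta0 <- min(x) - 0.1 * spread
  y <- x - eta0
  q <- stats::quantile(y, c(0.25, 0.75), names = FALSE, type = 7)
  c25 <- -base::log(0.25)  # 1.386...
  c75 <- -base::log(0.75)  # 0.2877...
  # q75/q25 = (c25/c75)^(1/alpha)
  alpha0 <- base::log(c25 / c75) / base::log(q[2L] / q[1L])
  if (!is.finite(alpha0) || alpha0 <= 0) alpha0 <- 1
  lambda0 <- q[1L] * c25^(1 / alpha0)
  c(alpha = alpha0, lambda = lambda0, eta = eta0)
}

## scaled (elasticity) gradient used as the convergence measure; the three
## components are d l / d log(alpha), d l / d log(lambda) and
## -d l / d phi with eta = min(x) - exp(phi), so all are scale-free
scaled_score <- function(par, x, m) {
  g <- frechet_score(par, x)
  c(par[1L] * g[1L], par[2L] * g[2L], (m - par[3L]) * g[3L])
}

## single BFGS run in unconstrained coordinates
## th = (log alpha, log lambda, phi), eta = m - exp(phi)
bfgs_once <- function(th0, x, m, control) {
  to_par <- function(th) c(exp(th[1L]), exp(th[2L]), m - exp(th[3L]))
  negll <- function(th) {
    p <- to_par(th)
    if (any(!is.finite(p))) return(.Machine$double.xmax)
    ll <- tryCatch(frechet_loglik(p, x), error = function(e) -Inf)
    if (!is.finite(ll)) .Machine$double.xmax else -ll
  }
  neggr <- function(th) {
    p <- to_par(th)
    g <- tryCatch(frechet_score(p, x), error = function(e) rep(0, 3))
    -c(p[1L] * g[1L], p[2L] * g[2L], -exp(th[3L]) * g[3L])
  }
  opt <- stats::optim(th0, negll, neggr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = 1e-14))
  list(par = to_par(opt$par), value = -opt$value,
       counts = opt$counts[["function"]], code = opt$convergence)
}

## Newton polish on the score in original coordinates, with step halving
## keeping (alpha, lambda) positive and eta below min(x)
newton_polish <- function(par, x, m, control) {
  iter <- 0L
  repeat {
    s <- scaled_score(par, x, m)
    if (max(abs(s)) < control$tol || iter >= control$newton_steps) break
    H <- frechet_hessian(par, x)
    g <- frechet_score(par, x)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    fac <- 1
    ll0 <- frechet_loglik(par, x)
    repeat {
      cand <- par + fac * step
      ok <- cand[1L] > 0 && cand[2L] > 0 && cand[3L] < m
      if (ok) {
        llc <- tryCatch(frechet_loglik(cand, x), error = function(e) -Inf)
        if (is.finite(llc) && llc >= ll0 - 1e-10) break
      }
      fac <- fac / 2
      if (fac < 1e-10) { cand <- par; break }
    }
    if (identical(cand, par)) break
    par <- cand
    iter <- iter + 1L
  }
  par
}

## full ML driver: BFGS from the default (or supplied) start, Newton
## polish, deterministic jittered restarts on failure
fit_ml <- function(x, init = NULL, control = frechet_control()) {
  m <- min(x)
  start <- if (is.null(init)) frechet_init(x) else as_frechet_par(init)
  if (start[3L] >= m)
    stop("initial eta must lie below min(x)", call. = FALSE)
  th0 <- c(base::log(start[1L]), base::log(start[2L]),
           base::log(m - start[3L]))
  # fixed jitter pattern so restarts never consume RNG state
  jit <- rbind(c(0, 0, 0),
               c(0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5),
               c(1, -1, 1), c(-1, 1, -1), c(0.25, -0.75, 2))
  best <- NULL
  tried <- 0L
  for (r in seq_len(min(nrow(jit), control$restarts + 1L))) {
    tried <- tried + 1L
    res <- tryCatch(bfgs_once(th0 + jit[r, ], x, m, control),
                    error = function(e) NULL)
    if (is.null(res)) next
    par <- tryCatch(newton_polish(res$par, x, m, control),
                    error = function(e) res$par)
    gnorm <- max(abs(scaled_score(par, x, m)))
    cand <- list(par = par, loglik = frechet_loglik(par, x),
                 grad_norm = gnorm, iterations = res$counts,
                 converged = gnorm < control$tol)
    if (is.null(best) || cand$loglik > best$loglik ||
        (cand$converged && !best$converged)) best <- cand
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best))
    stop("maximum likelihood optimization failed from all starting points",
         call. = FALSE)
  best$restarts_used <- tried - 1L
  names(best$par) <- c("alpha", "lambda", "eta")
  best
}

#' Fit the three-parameter Frechet distribution by ML and Lindley-Bayes
#'
#' Fits a three-parameter Frechet distribution to a positive, right-skewed
#' sample.  The maximum likelihood estimate is found by BFGS quasi-Newton
#' ascent of the log-likelihood in transformed coordinates
#' \code{(log alpha, log lambda, phi)} with
#' \code{eta = min(x) - exp(phi)}, which keeps every iterate inside the
#' constraint set \code{alpha > 0, lambda > 0, eta < min(x)}, followed by
#' Newton polishing of the score.  Around that MLE, four approximate Bayes
#' estimators are computed by Lindley's second-order expansion of the
#' posterior:
#' \describe{
#'   \item{BLNP}{LINEX loss, noninformative prior
#'     \eqn{\pi \propto 1/(\alpha\lambda\eta)}}
#'   \item{BGENP}{general entropy loss, noninformative prior}
#'   \item{BLGP}{LINEX loss, gamma prior on the scale
#'     \eqn{\pi(\lambda) \propto \lambda^{a-1} e^{-b\lambda}}}
#'   \item{BGEGP}{general entropy loss, gamma prior on the scale}
#' }
#' The LINEX Bayes estimator of a parameter \eqn{\theta} is
#' \eqn{-(1/k)\log E[e^{-k\theta}\,|\,x]} and the general entropy (GE)
#' estimator is \eqn{(E[\theta^{-k}\,|\,x])^{-1/k}}; both posterior
#' expectations are approximated via the inverse observed information, the
#' log-prior gradient and the third log-likelihood derivatives.  See
#' \code{vignette("frechet3-methods")} for the expansion and the meaning
#' of the \code{variant} switch.
#'
#' @param x numeric data vector (at least 4 distinct values).
#' @param k loss-function constant, nonzero.  For LINEX, \code{k > 0}
#'   penalizes overestimation more than underestimation; for GE,
#'   \code{k = -1} reduces to the posterior mean.
#' @param a,b shape and rate hyperparameters (> 0) of the gamma prior on
#'   the scale parameter, used by the BLGP/BGEGP estimators.
#' @param variant \code{"printed"} (default) evaluates the published
#'   closed-form Lindley brackets literally; \code{"derived"} uses the
#'   expansion re-derived from \eqn{E[e^{-k\theta}]} and
#'   \eqn{E[\theta^{-k}]}, which is the form validated against direct
#'   numerical posterior integration.
#' @param methods subset of \code{c("ML","BLNP","BGENP","BLGP","BGEGP")}
#'   to compute.  \code{"ML"} is always computed.
#' @param init optional starting triple \code{c(alpha, lambda, eta)}.
#' @param control a \code{\link{frechet_control}} list.
#' @return an object of class \code{"frechet_fit"} with components
#'   \code{estimates} (methods x parameters matrix; entries are \code{NA}
#'   with a recorded flag where a Bayes bracket left the domain of its
#'   loss transform), \code{par} (the MLE), \code{fisher} (observed
#'   information and its inverse), \code{loglik}, \code{converged},
#'   \code{grad_norm}, \code{iterations}, \code{hyper}, \code{flags}, and
#'   the data.  Standard methods \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{logLik}, \code{plot},
#'   \code{simulate} and \code{residuals} apply; \code{summary} appends
#'   a Kolmogorov-Smirnov goodness-of-fit column per estimator.
#' @examples
#' x <- read_sample(system.file("extdata", "headneck_survival.txt",
#'                              package = "frechet3"))
#' fit <- frechet_fit(x)
#' fit
#' summary(fit)
#' @seealso \code{\link{frechet_ks}}, \code{\link{frechet_sim_cell}}
#' @export
frechet_fit <- function(x, k = 1, a = 1, b = 1,
                        variant = c("printed", "derived"),
                        methods = c("ML", "BLNP", "BGENP", "BLGP", "BGEGP"),
                        init = NULL, control = frechet_control()) {
  variant <- match.arg(variant)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.numeric(k) || length(k) != 1L || k == 0)
    stop("loss constant 'k' must be a single nonzero number", call. = FALSE)
  if (a <= 0 || b <= 0)
    stop("gamma prior hyperparameters 'a' and 'b' must be > 0",
         call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite and free of missing values", call. = FALSE)

  ml <- fit_ml(x, init = init, control = control)
  fisher <- frechet_info(ml$par, x)

  mnames <- c("ML", "BLNP", "BGENP", "BLGP", "BGEGP")
  methods <- unique(c("ML", methods))
  est <- matrix(NA_real_, length(mnames), 3,
                dimnames = list(mnames, c("alpha", "lambda", "eta")))
  est["ML", ] <- ml$par
  flags <- list()
  if (!ml$converged)
    flags$ML <- sprintf("not converged (scaled score %.2e)", ml$grad_norm)

  bayes_wanted <- setdiff(methods, "ML")
  if (length(bayes_wanted) > 0) {
    lt <- lindley_contractions(ml$par, x, fisher$sigma)
    for (mth in bayes_wanted) {
      prior <- if (mth %in% c("BLNP", "BGENP")) "noninformative"
               else "gamma_scale"
      rho <- prior_gradient(prior, ml$par, a = a, b = b)
      r <- if (mth %in% c("BLNP", "BLGP"))
        linex_lindley(ml$par, fisher$sigma, lt$Lambda, rho, k, variant)
      else
        gentropy_lindley(ml$par, fisher$sigma, lt$Lambda, rho, k, variant)
      est[mth, ] <- r$est
      if (length(r$flags)) flags[[mth]] <- r$flags
    }
  }
  est <- est[mnames %in% methods, , drop = FALSE]

  structure(list(estimates = est, par = ml$par, fisher = fisher,
                 loglik = ml$loglik, converged = ml$converged,
                 grad_norm = ml$grad_norm, iterations = ml$iterations,
                 restarts_used = ml$restarts_used,
                 hyper = list(k = k, a = a, b = b, variant = variant),
                 flags = flags, x = x, n = length(x),
                 call = match.call()),
            class = "frechet_fit")
}

#' @export
print.frechet_fit <- function(x, digits = 4, ...) {
  cat("Three-parameter Frechet fit (n =", x$n, "observations)\n")
  cat(sprintf("ML by BFGS + Newton polish: logLik = %.*f, %s\n",
              digits, x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("Bayes hyperparameters: k = %g, a = %g, b = %g, variant = %s\n\n",
              x$hyper$k, x$hyper$a, x$hyper$b, x$hyper$variant))
  print(round(x$estimates, digits))
  if (length(x$flags)) {
    cat("\nFlags:\n")
    for (nm in names(x$flags))
      cat("  ", nm, ": ", paste(x$flags[[nm]], collapse = "; "), "\n",
          sep = "")
  }
  invisible(x)
}

#' @export
coef.frechet_fit <- function(object, method = "ML", ...) {
  if (identical(method, "all")) return(object$estimates)
  drop(object$estimates[method, ])
}

#' @export
vcov.frechet_fit <- function(object, ...) object$fisher$sigma

#' @export
logLik.frechet_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' @export
simulate.frechet_fit <- function(object, nsim = 1, seed = NULL,
                                 method = "ML", ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$estimates[method, ]
  out <- replicate(nsim,
                   rfrechet(object$n, shape = p[1], scale = p[2],
                            loc = p[3]),
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.frechet_fit <- function(object, type = c("quantile", "uniform"),
                                  method = "ML", ...) {
  type <- match.arg(type)
  p <- object$estimates[method, ]
  u <- pfrechet(object$x, shape = p[1], scale = p[2], loc = p[3])
  if (type == "uniform") u else stats::qnorm(u)
}

#' @export
summary.frechet_fit <- function(object, ...) {
  est <- object$estimates
  gof <- t(vapply(rownames(est), function(m) {
    p <- est[m, ]
    if (anyNA(p)) return(c(D = NA_real_, p.value = NA_real_))
    r <- frechet_ks(object$x, p)
    c(D = r$D, p.value = r$p.value)
  }, numeric(2)))
  se <- sqrt(diag(object$fisher$sigma))
  structure(list(fit = object, table = cbind(est, gof), ml_se = se),
            class = "summary.frechet_fit")
}

#' @export
print.summary.frechet_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Three-parameter Frechet fit with goodness of fit (n =", f$n, ")\n")
  cat(sprintf("hyperparameters: k = %g, a = %g, b = %g, variant = %s\n",
              f$hyper$k, f$hyper$a, f$hyper$b, f$hyper$variant))
  cat(sprintf("ML standard errors (observed information): %s\n\n",
              paste(names(f$par), "=", signif(x$ml_se, digits),
                    collapse = ", ")))
  print(round(x$table, digits))
  cat("\nKS p-values use the asymptotic Kolmogorov distribution and do not\n")
  cat("account for parameter estimation.\n")
  if (length(f$flags)) {
    cat("Flags:\n")
    for (nm in names(f$flags))
      cat("  ", nm, ": ", paste(f$flags[[nm]], collapse = "; "), "\n",
          sep = "")
  }
  invisible(x)
}

#' Density-overlay plot of fitted Frechet curves
#'
#' Draws a probability histogram of the data with the fitted density of
#' each estimation method overlaid.
#'
#' @param x a \code{frechet_fit} object.
#' @param breaks passed to \code{\link[graphics]{hist}}.
#' @param ... further arguments passed to \code{hist}.
#' @export
plot.frechet_fit <- function(x, breaks = "Sturges", ...) {
  est <- x$estimates[!apply(is.na(x$estimates), 1, any), , drop = FALSE]
  h <- graphics::hist(x$x, breaks = breaks, freq = FALSE,
                      main = "Fitted three-parameter Frechet densities",
                      xlab = "x", border = "grey60", col = "grey90", ...)
  xs <- seq(min(x$x), max(x$x), length.out = 512)
  cols <- seq_len(nrow(est)) + 1L
  for (i in seq_len(nrow(est))) {
    p <- est[i, ]
    graphics::lines(xs, dfrechet(xs, p[1], p[2], p[3]), col = cols[i],
                    lwd = 2)
  }
  graphics::legend("topright", legend = rownames(est), col = cols, lwd = 2,
                   bty = "n")
  invisible(h)
}
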
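#' Log-prior gradient for the Lindley expansion
#'
#' Evaluates \eqn{\rho = \nabla \log \pi} at a parameter triple for the
#' two priors used by the approximate Bayes estimators:
#' \itemize{
#'   \item \code{"noninformative"}: \eqn{\pi \propto 1/(\alpha\lambda\eta)},
#'     giving \eqn{\rho = (-1/\alpha, -1/\lambda, -1/\eta)};
#'   \item \code{"gamma_scale"}: independent \eqn{\pi(\alpha) \propto
#'     1/\alpha}, \eqn{\pi(\eta) \propto 1/\eta} and a gamma prior
#'     \eqn{\pi(\lambda) \propto \lambda^{a-1} e^{-b\lambda}}, giving
#'     \eqn{\rho = (-1/\alpha, (a-1)/\lambda - b, -1/\eta)}.
#' }
#' The priors are written for positive parameters; when the plugged-in
#' location estimate is negative the gradient is still evaluated as
#' written (\eqn{1/\eta} is finite for \eqn{\eta \ne 0}) and the caller
#' attaches a warning flag.
#'
#' @param prior \code{"noninformative"} or \code{"gamma_scale"}.
#' @param par parameter triple \code{c(alpha, lambda, eta)}.
#' @param a,b gamma hyperparameters, required for \code{"gamma_scale"}.
#' @return named length-3 numeric vector \eqn{(\rho_1,\rho_2,\rho_3)}.
#' @export
prior_gradient <- function(prior = c("noninformative", "gamma_scale"),
                           par, a = NULL, b = NULL) {
  prior <- match.arg(prior)
  par <- as_frechet_par(par)
  if (par[3L] == 0)
    stop("degenerate prior: eta = 0 makes the 1/eta prior factor singular",
         call. = FALSE)
  rho <- c(-1 / par[1L], -1 / par[2L], -1 / par[3L])
  if (prior == "gamma_scale") {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
      stop("gamma_scale prior requires hyperparameters a > 0 and b > 0",
           call. = FALSE)
    rho[2L] <- (a - 1) / par[2L] - b
  }
  names(rho) <- c("alpha", "lambda", "eta")
  rho
}

#' Lindley expansion ingredients at the MLE
#'
#' Computes the pieces of Lindley's second-order posterior expansion that
#' depend only on the likelihood: the third-derivative tensor
#' \eqn{L_{ijk}} of the log-likelihood and its contractions
#' \eqn{\Lambda_k = \sum_{i,j} L_{ijk}\,\sigma_{ij}} with the inverse
#' observed information \eqn{\sigma}.  Given a log-prior gradient
#' \eqn{\rho}, the prior-dependent weights are
#' \eqn{b_i = \sum_j \rho_j \sigma_{ij}}.
#'
#' @param par the MLE triple.
#' @param x data vector.
#' @param sigma inverse observed information at \code{par}
#'   (see \code{\link{frechet_info}}).
#' @return list with the tensor \code{L3}, the triple \code{Lambda}, and
#'   \code{bfun}, a function mapping a prior gradient \code{rho} to the
#'   weight triple \code{b}.
#' @export
lindley_contractions <- function(par, x, sigma) {
  L3 <- frechet_third_deriv(par, x)
  Lambda <- vapply(1:3, function(k) sum(L3[, , k] * sigma), numeric(1))
  names(Lambda) <- c("alpha", "lambda", "eta")
  list(L3 = L3, Lambda = Lambda,
       bfun = function(rho) drop(sigma %*% rho))
}

## LINEX-loss Lindley estimator for all three parameters.
## For each parameter p with MLE th_p, the estimator is
##   th_p - log(A_p)/k
## where, writing b_p = (sigma rho)_p and c_p = sum_m Lambda_m sigma[m,p]:
##   derived: A_p = 1 - k b_p + (k^2/2) sigma_pp - (k/2) c_p
##            (the expansion of E[exp(-k th_p)] about the MLE)
##   printed: A_p = 1 - k b_p - (k^2/2) sigma_pp + c_p/2
##            (the published closed form evaluated literally)
linex_lindley <- function(par, sigma, Lambda, rho, k, variant) {
  b <- drop(sigma %*% rho)
  est <- rep(NA_real_, 3)
  flags <- character(0)
  for (p in 1:3) {
    cp <- sum(Lambda * sigma[, p])
    A <- if (variant == "derived")
      1 - k * b[p] + k^2 / 2 * sigma[p, p] - k / 2 * cp
    else
      1 - k * b[p] - k^2 / 2 * sigma[p, p] + cp / 2
    if (!is.finite(A) || A <= 0) {
      flags <- c(flags, sprintf(
        "LINEX bracket for %s nonpositive (%.4g); estimate undefined",
        c("alpha", "lambda", "eta")[p], A))
    } else {
      est[p] <- par[p] - base::log(A) / k
    }
  }
  names(est) <- c("alpha", "lambda", "eta")
  list(est = est, flags = flags)
}

## General-entropy-loss Lindley estimator; th_p * B_p^(-1/k) with
##   derived: B_p = 1 - (k/th_p) b_p + k(k+1)/(2 th_p^2) sigma_pp
##                - (k/(2 th_p)) c_p   (expansion of E[th_p^-k])
##   printed: B_p = 1 - (k/th_p) b_p - k(k+1)/(2 th_p^2) sigma_pp + c_p/2
gentropy_lindley <- function(par, sigma, Lambda, rho, k, variant) {
  b <- drop(sigma %*% rho)
  est <- rep(NA_real_, 3)
  flags <- character(0)
  for (p in 1:3) {
    th <- par[p]
    if (th == 0) {
      flags <- c(flags, sprintf("GE estimator undefined at %s = 0",
                                c("alpha", "lambda", "eta")[p]))
      next
    }
    if (th < 0 && variant == "derived")
      flags <- c(flags, sprintf(
        "GE loss assumes a positive parameter; %s estimate %.4g <= 0",
        c("alpha", "lambda", "eta")[p], th))
    cp <- sum(Lambda * sigma[, p])
    B <- if (variant == "derived")
      1 - (k / th) * b[p] + k * (k + 1) / (2 * th^2) * sigma[p, p] -
        k / (2 * th) * cp
    else
      1 - (k / th) * b[p] - k * (k + 1) / (2 * th^2) * sigma[p, p] +
        cp / 2
    if (!is.finite(B) || B <= 0) {
      flags <- c(flags, sprintf(
        "GE bracket for %s nonpositive (%.4g); estimate undefined",
        c("alpha", "lambda", "eta")[p], B))
    } else {
      est[p] <- th * B^(-1 / k)
    }
  }
  names(est) <- c("alpha", "lambda", "eta")
  list(est = est, flags = flags)
}
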
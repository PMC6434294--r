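#' The three-parameter Frechet distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Frechet (extreme value type-II) distribution with shape
#' \code{shape} (\eqn{\alpha > 0}), scale \code{scale} (\eqn{\lambda > 0})
#' and location \code{loc} (\eqn{\eta}, any real).  The support is the open
#' ray \eqn{x > \eta}:
#' \deqn{F(x) = \exp\{-((x-\eta)/\lambda)^{-\alpha}\}, \quad x > \eta,}
#' \deqn{f(x) = (\alpha/\lambda)\,((x-\eta)/\lambda)^{-\alpha-1}
#'              \exp\{-((x-\eta)/\lambda)^{-\alpha}\}.}
#' Setting \code{loc = 0} gives the two-parameter Frechet; \code{shape = 1}
#' is the inverse exponential and \code{shape = 2} the inverse Rayleigh
#' distribution.
#'
#' Both density and distribution function return 0 at and below the
#' location parameter.  Extreme exponents are guarded: where
#' \eqn{((x-\eta)/\lambda)^{-\alpha}} would overflow, the density and
#' distribution function underflow cleanly to 0 rather than erroring.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities, strictly inside (0, 1).
#' @param n number of draws.
#' @param shape shape parameter \eqn{\alpha > 0}.
#' @param scale scale parameter \eqn{\lambda > 0}, same units as the data.
#' @param loc location (threshold) parameter \eqn{\eta}.
#' @param log,log.p logical; if TRUE, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#' @return \code{dfrechet} gives the density, \code{pfrechet} the
#'   distribution function, \code{qfrechet} the quantile function and
#'   \code{rfrechet} a vector of random deviates, all of length matching
#'   the usual recycling rules.
#' @examples
#' dfrechet(4, shape = 1.5, scale = 2, loc = 3)   # density just above eta
#' pfrechet(5, shape = 1.5, scale = 2, loc = 3)
#' qfrechet(exp(-1), shape = 1.5, scale = 2, loc = 3)  # equals loc + scale
#' set.seed(1); rfrechet(5, shape = 1.5, scale = 2, loc = 3)
#' @name Frechet
NULL

check_frechet_par <- function(shape, scale) {
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop("invalid Frechet parameters: 'shape' must be finite and > 0",
         call. = FALSE)
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("invalid Frechet parameters: 'scale' must be finite and > 0",
         call. = FALSE)
  invisible(TRUE)
}

#' @rdname Frechet
#' @export
dfrechet <- function(x, shape, scale = 1, loc = 0, log = FALSE) {
  check_frechet_par(shape, scale)
  z <- (x - loc) / scale
  logd <- rep(-Inf, length(z))
  pos <- is.finite(z) & z > 0
  # log f = log(shape/scale) - (shape+1) log z - z^(-shape)
  lz <- base::log(z[pos])
  logd[pos] <- base::log(shape / scale) - (shape + 1) * lz - exp(-shape * lz)
  logd[is.na(z)] <- NA_real_
  if (log) logd else exp(logd)
}

#' @rdname Frechet
#' @export
pfrechet <- function(q, shape, scale = 1, loc = 0,
                     lower.tail = TRUE, log.p = FALSE) {
  check_frechet_par(shape, scale)
  z <- (q - loc) / scale
  logF <- rep(-Inf, length(z))
  pos <- is.finite(z) & z > 0
  logF[pos] <- -exp(-shape * base::log(z[pos]))
  logF[is.na(z)] <- NA_real_
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    p <- -expm1(logF)
    if (log.p) base::log(p) else p
  }
}

#' @rdname Frechet
#' @export
qfrechet <- function(p, shape, scale = 1, loc = 0,
                     lower.tail = TRUE, log.p = FALSE) {
  check_frechet_par(shape, scale)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  loc + scale * (-base::log(p))^(-1 / shape)
}

#' @rdname Frechet
#' @export
rfrechet <- function(n, shape, scale = 1, loc = 0) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  check_frechet_par(shape, scale)
  # inverse transform: X = loc + scale * (-log U)^(-1/shape)
  u <- stats::runif(n)
  loc + scale * (-base::log(u))^(-1 / shape)
}

#' Read a univariate sample from a text or CSV file
#'
#' Reads positive reals, one value per row (a single-column CSV header row
#' is tolerated).  Blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path path to a plain-text or single-column CSV file.
#' @return numeric vector of the values read, in file order.
#' @examples
#' f <- system.file("extdata", "headneck_survival.txt", package = "frechet3")
#' x <- read_sample(f)
#' length(x)  # 44
#' @export
read_sample <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  # tolerate comma/whitespace separated tokens
  toks <- unlist(strsplit(lines, "[,[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    # allow a single non-numeric header token
    if (is.na(vals[1L]) && !anyNA(vals[-1L])) {
      vals <- vals[-1L]
    } else {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("could not parse token %d ('%s') in %s",
                   bad, toks[bad], path), call. = FALSE)
    }
  }
  if (length(vals) == 0L)
    stop("no data values found in ", path, call. = FALSE)
  vals
}
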
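## Internal exponential-polynomial algebra.
##
## Signals are represented as sums of terms c * tau^p * exp(-r * tau) on
## tau >= 0, stored as a 3-column matrix (coef, pow, rate). Convolution with
## an exponential kernel, cumulative integration and pointwise evaluation are
## all closed-form, so compartment-model TACs and their exact per-frame
## integrals carry no quadrature or ODE-solver error. Rates closer than
## .EP_TOL are treated as equal (the confluent limit), which avoids
## catastrophic cancellation in the 1/(rate difference) coefficients.

.EP_TOL <- 1e-9

.epTerms <- function(coef, pow, rate) {
  cbind(coef = coef, pow = pow, rate = rate)
}

.epEmpty <- matrix(numeric(0), ncol = 3L,
                   dimnames = list(NULL, c("coef", "pow", "rate")))

.epMerge <- function(terms) {
  if (is.null(terms) || nrow(terms) == 0L) return(.epEmpty)
  key <- paste(terms[, 2L], signif(terms[, 3L], 12))
  agg <- rowsum(terms[, 1L], key, reorder = FALSE)
  first <- terms[!duplicated(key), , drop = FALSE]
  first[, 1L] <- agg[, 1L]
  first[abs(first[, 1L]) > 0, , drop = FALSE]
}

## I_p(tau) = int_0^tau u^p exp(-mu u) du, expanded as ep terms in tau
## (constants appear with rate 0).
.epIp <- function(p, mu) {
  if (abs(mu) < .EP_TOL) return(.epTerms(1 / (p + 1), p + 1, 0))
  if (p == 0) return(.epTerms(c(1, -1) / mu, c(0, 0), c(0, mu)))
  prev <- .epIp(p - 1, mu)
  prev[, 1L] <- prev[, 1L] * p / mu
  rbind(prev, .epTerms(-1 / mu, p, mu))
}

## Convolution (f * g)(tau) with g(tau) = exp(-a tau).
.epConvExp <- function(terms, a) {
  pieces <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    c0 <- terms[i, 1L]; p <- terms[i, 2L]; l <- terms[i, 3L]
    mu <- l - a
    if (abs(mu) < .EP_TOL) {
      pieces[[i]] <- .epTerms(c0 / (p + 1), p + 1, l)
    } else {
      ip <- .epIp(p, mu)
      ip[, 3L] <- ip[, 3L] + a   # multiply by exp(-a tau)
      ip[, 1L] <- ip[, 1L] * c0
      pieces[[i]] <- ip
    }
  }
  .epMerge(do.call(rbind, pieces))
}

## Cumulative integral int_0^tau f.
.epCum <- function(terms) {
  pieces <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    ip <- .epIp(terms[i, 2L], terms[i, 3L])
    ip[, 1L] <- ip[, 1L] * terms[i, 1L]
    pieces[[i]] <- ip
  }
  .epMerge(do.call(rbind, pieces))
}

.epEval <- function(terms, tau) {
  out <- numeric(length(tau))
  for (i in seq_len(nrow(terms)))
    out <- out + terms[i, 1L] * tau^terms[i, 2L] * exp(-terms[i, 3L] * tau)
  unname(out)
}

.epScale <- function(terms, s) { terms[, 1L] <- terms[, 1L] * s; terms }

## Plasma-input term set on tau = t - delay (Feng bolus, continuous at 0).
.epPlasma <- function(input) {
  .epMerge(.epTerms(
    coef = c(-input@A2 - input@A3, input@A1, input@A2, input@A3),
    pow = c(0, 1, 0, 0),
    rate = c(input@lambda1, input@lambda1, input@lambda2, input@lambda3)))
}

## Exact frame averages of an ep signal delayed by `delay` (all times in the
## same unit as the rates' inverse).
.epFrameAverage <- function(terms, starts, ends, delay) {
  cum <- .epCum(terms)
  at <- function(t) .epEval(cum, pmax(t - delay, 0))
  (at(ends) - at(starts)) / (ends - starts)
}
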
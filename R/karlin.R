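#' Karlin-Altschul parameters for an ungapped match/mismatch score system
#'
#' `lambda` is the unique positive solution of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1`, found by bisection to 1e-9.
#' `K` uses the closed form for score systems whose gcd-reduced maximum score
#' equals +1 (the case of all match/mismatch systems with positive match
#' score): `K = (1 - exp(-lambda')) * E[S' * exp(lambda' * S')]` on the
#' gcd-reduced lattice, which reproduces the published ungapped BLASTN
#' constants (e.g. +1/-2: lambda 1.33, K 0.62; +1/-1: lambda 1.10, K 1/3).
#' For other systems a conservative `K = 0.3` is used with a warning.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param background_freqs nucleotide background frequencies (length 4,
#'   summing to 1).
#' @return list with `lambda`, `K` and the relative entropy `H` (nats).
#' @export
karlin_altschul_params <- function(match = 1L, mismatch = -2L,
                                   background_freqs = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0,
            length(background_freqs) == 4,
            abs(sum(background_freqs) - 1) < 1e-8)
  p_match <- sum(background_freqs^2)
  p_mis <- 1 - p_match
  escore <- p_match * match + p_mis * mismatch
  if (escore >= 0)
    stop("expected score per aligned pair must be negative")
  f <- function(l) p_match * exp(l * match) + p_mis * exp(l * mismatch) - 1
  lo <- 1e-9
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  d <- .gcd2(abs(match), abs(mismatch))
  m2 <- match / d; mm2 <- mismatch / d; l2 <- lambda * d
  if (m2 == 1) {
    av <- p_match * m2 * exp(l2 * m2) + p_mis * mm2 * exp(l2 * mm2)
    K <- (1 - exp(-l2)) * av
  } else {
    warning("no closed form K for this score system; using K = 0.3")
    K <- 0.3
  }
  H <- lambda * (p_match * match * exp(lambda * match) +
                   p_mis * mismatch * exp(lambda * mismatch))
  list(lambda = lambda, K = K, H = H)
}

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)

#' E-value of an ungapped local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score alignment score(s).
#' @param m query length.
#' @param n total searched (subject) length.
#' @param ka list from [karlin_altschul_params()].
#' @return numeric E-value(s).
#' @export
evalue <- function(score, m, n, ka) {
  ka$K * as.numeric(m) * as.numeric(n) * exp(-ka$lambda * score)
}

#' Bit score corresponding to a raw score
#' @inheritParams evalue
#' @return numeric bit score(s).
#' @export
bitscore <- function(score, ka) {
  (ka$lambda * score - log(ka$K)) / log(2)
}
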
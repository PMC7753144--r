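#' Blink-count probability model
#'
#' A photoconverted emitter produces a train of fluorescent "appearances":
#' after each appearance it bleaches with probability `p` or returns for
#' another appearance with probability `1 - p`, so the number of
#' appearances of one emitter is geometric on 1, 2, ... with parameter `p`.
#' For a nanocluster containing `m` detected emitters the total appearance
#' count is the sum of `m` independent geometrics — a shifted negative
#' binomial:
#'
#'   P(n | m, p) = choose(n - 1, m - 1) p^m (1 - p)^(n - m),  n >= m.
#'
#' `pmf_appearances()` evaluates this pmf; it is the building block of the
#' monomer and dimer fit functions.
#'
#' @param n appearance count(s), integer >= m.
#' @param m number of detected emitters, integer >= 1.
#' @param p bleaching probability per appearance, in (0, 1].
#' @return probability vector of `length(n)`.
#' @export
pmf_appearances <- function(n, m = 1L, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    qp_param_error("p must be a probability in (0, 1]")
  if (!is_count(m) || m < 1) qp_param_error("m must be an integer >= 1")
  if (any(n != round(n)) || any(n < m))
    qp_stop("qp_domain_error", "n must be integer >= m = %d", m)
  stats::dnbinom(n - m, size = m, prob = p)
}

#' Dimeric blink-count fit function
#'
#' Observed appearance-count distribution of a dimer, conditioned on the
#' cluster being detected at all: with probability `q` only one of the two
#' protomers is ever detected (one geometric train), with probability
#' `1 - q` both are (two-emitter negative binomial).
#'
#' @inheritParams pmf_appearances
#' @param q probability that a detected dimer shows only one emitter,
#'   in \[0, 1).
#' @return probability vector of `length(n)`.
#' @export
pmf_dimer <- function(n, p, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q >= 1)
    qp_param_error("q must be a probability in [0, 1)")
  if (any(n != round(n)) || any(n < 1))
    qp_stop("qp_domain_error", "n must be integer >= 1")
  mono <- pmf_appearances(n, 1L, p)
  di <- ifelse(n >= 2, stats::dnbinom(pmax(n - 2, 0), size = 2, prob = p), 0)
  q * mono + (1 - q) * di
}

#' Convert between the dimeric q-value and detection efficiency
#'
#' If each protomer of a dimer is detected independently with probability
#' `d`, then conditional on at least one detection the probability that
#' exactly one is detected is `q = 2 d (1 - d) / (1 - (1 - d)^2)
#' = 2 (1 - d) / (2 - d)`. `q_to_d()` inverts this: `d = 2 (1 - q) / (2 - q)`.
#' A fitted q-value of 0.35 corresponds to a detection efficiency of 79%.
#'
#' @param q probability a detected dimer shows one emitter, in \[0, 1).
#' @param d per-protomer detection efficiency, in (0, 1].
#' @return `q_to_d`: d; `d_to_q`: q.
#' @export
q_to_d <- function(q) {
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0) || any(q >= 1))
    qp_param_error("q must be in [0, 1)")
  2 * (1 - q) / (2 - q)
}

#' @rdname q_to_d
#' @export
d_to_q <- function(d) {
  if (!is.numeric(d) || any(is.na(d)) || any(d <= 0) || any(d > 1))
    qp_param_error("d must be in (0, 1]")
  2 * (1 - d) / (2 - d)
}

#' Absolute detection efficiency
#'
#' Combines the photophysical per-protomer detection efficiency with the
#' labeling efficiency (the fraction of receptors actually carrying a tag,
#' e.g. 0.81 from western-blot band quantification) into the absolute
#' detection efficiency `d_abs = d * L` that corrects for all undetected
#' receptors. No rounding is applied here; round only when reporting.
#'
#' @param d per-protomer detection efficiency in (0, 1].
#' @param L labeling efficiency in (0, 1].
#' @return `d * L`.
#' @export
absolute_detection <- function(d, L) {
  if (!is.numeric(d) || any(d <= 0) || any(d > 1))
    qp_param_error("d must be in (0, 1]")
  if (!is.numeric(L) || any(L <= 0) || any(L > 1))
    qp_param_error("L must be in (0, 1]")
  d * L
}

#' Photophysics parameter set
#'
#' Bundles the counting parameters: bleaching probability `p`, dimeric
#' `q`-value, per-protomer detection efficiency `d`, labeling efficiency
#' `L` and absolute detection efficiency `d_abs = d * L`. If only one of
#' `q` / `d` is given the other is filled in via [q_to_d()] / [d_to_q()];
#' if both are given they must agree.
#'
#' @param p bleaching probability per appearance, (0, 1].
#' @param q,d see [q_to_d()]; give at least one.
#' @param L labeling efficiency, (0, 1].
#' @return object of class `photophysics` (a named list).
#' @export
photophysics_params <- function(p, q = NULL, d = NULL, L = 1) {
  if (!is.numeric(p) || p <= 0 || p > 1) qp_param_error("p must be in (0, 1]")
  if (is.null(q) && is.null(d)) qp_param_error("give q or d")
  if (is.null(d)) d <- q_to_d(q)
  if (is.null(q)) q <- d_to_q(d)
  if (abs(q - d_to_q(d)) > 1e-9)
    qp_param_error("inconsistent q (%.4f) and d (%.4f): q must equal 2(1-d)/(2-d)",
                   q, d)
  structure(list(p = p, q = q, d = d, L = L,
                 d_abs = absolute_detection(d, L)),
            class = "photophysics")
}

#' @export
print.photophysics <- function(x, ...) {
  cat(sprintf("<photophysics> p = %.3f, q = %.3f, d = %.3f, L = %.2f, d_abs = %.3f\n",
              x$p, x$q, x$d, x$L, x$d_abs))
  invisible(x)
}
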
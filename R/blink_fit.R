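#' Fit the bleaching probability from a monomeric reference
#'
#' Maximum likelihood fit of the geometric appearance-count model to a
#' blink histogram of a monomeric reference protein (e.g. CD86). The MLE
#' has the closed form `p_hat = 1 / mean(n)`.
#'
#' @param hist a [blink_histogram()].
#' @param B bootstrap replicates for the confidence interval (>= 100), or 0
#'   to skip the interval.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `blink_fit`: `p`, `ci` (see [bootstrap_ci()]),
#'   `n_clusters`, `mean_n`.
#' @export
fit_p <- function(hist, B = 1000, seed = 1) {
  hist <- as_blink_histogram(hist)
  if (hist$total_clusters <= 0) qp_data_error("empty histogram")
  est <- function(h) h$total_clusters / sum(seq_len(h$n_max) * h$counts)
  p_hat <- est(hist)
  ci <- if (B > 0) bootstrap_ci(hist, est, B = B, seed = seed) else NULL
  structure(list(p = p_hat, ci = ci, n_clusters = hist$total_clusters,
                 mean_n = 1 / p_hat),
            class = "blink_fit")
}

# Multinomial log-likelihood of a pmf over the histogram bins; counts above
# n_max are censored into the top bin, so the top bin uses the tail mass.
.hist_loglik <- function(hist, pmf_fun) {
  n <- seq_len(hist$n_max)
  pr <- pmf_fun(n)
  pr[hist$n_max] <- pr[hist$n_max] + max(0, 1 - sum(pr))
  pr <- pmax(pr, 1e-300)
  sum(hist$counts * log(pr))
}

#' Fit the dimeric q-value from a dimeric reference
#'
#' With the bleaching probability `p` fixed from a monomeric reference,
#' fits the one-parameter dimeric model [pmf_dimer()] to the blink
#' histogram of a dimeric reference protein (e.g. CTLA4) by maximum
#' likelihood. The fitted `q` converts to a per-protomer detection
#' efficiency via [q_to_d()].
#'
#' @inheritParams fit_p
#' @param p bleaching probability, fixed.
#' @param objective `"ml"` (multinomial maximum likelihood, default) or
#'   `"ls"` (least squares on the normalized histogram).
#' @return list of class `blink_fit`: `q`, `d` (= [q_to_d()]), `ci`,
#'   `loglik`, `converged` (FALSE when the estimate sits on the q -> 1
#'   boundary, e.g. when no cluster blinks more than expected of monomers).
#' @export
fit_q <- function(hist, p, B = 1000, seed = 1, objective = c("ml", "ls")) {
  hist <- as_blink_histogram(hist)
  objective <- match.arg(objective)
  if (hist$total_clusters <= 0) qp_data_error("empty histogram")
  est <- function(h) .optimize_q(h, p, objective)
  q_hat <- est(hist)
  boundary <- q_hat > 1 - 1e-4
  ci <- if (B > 0) bootstrap_ci(hist, est, B = B, seed = seed) else NULL
  structure(list(q = q_hat, d = q_to_d(min(q_hat, 1 - 1e-12)), ci = ci,
                 loglik = .hist_loglik(hist, function(n) pmf_dimer(n, p, q_hat)),
                 converged = !boundary, n_clusters = hist$total_clusters),
            class = "blink_fit")
}

.optimize_q <- function(hist, p, objective) {
  obj <- if (objective == "ml") {
    function(q) -.hist_loglik(hist, function(n) pmf_dimer(n, p, q))
  } else {
    n <- seq_len(hist$n_max)
    f_obs <- hist$counts / hist$total_clusters
    function(q) sum((f_obs - pmf_dimer(n, p, q))^2)
  }
  stats::optimize(obj, c(0, 1 - 1e-9), tol = 1e-10)$minimum
}

#' Fit the monomer/dimer mixture of a receptor population
#'
#' Fits the observed blink histogram with a two-component mixture of the
#' monomer pmf ([pmf_appearances()] with m = 1) and the dimer pmf
#' ([pmf_dimer()] with q derived from `d_abs`), maximising the multinomial
#' likelihood over the observed dimer weight `f_obs`. Because monomers and
#' dimers are not equally detectable (a cluster is only seen if at least
#' one protomer is labeled and detected: probability `d_abs` for a monomer,
#' `1 - (1 - d_abs)^2` for a dimer), the observed weight is converted to
#' the true population fraction
#'
#'   f_true = (f_obs / Pdet2) / (f_obs / Pdet2 + (1 - f_obs) / Pdet1),
#'
#' which is the headline reported number.
#'
#' @inheritParams fit_q
#' @param d_abs absolute detection efficiency (detection x labeling).
#' @return object of class `mixture_fit`: `fractions` (named true-population
#'   monomer/dimer fractions, summing to 1), `fractions_observed`, `ci`
#'   (bootstrap intervals for the true and observed dimer fraction),
#'   `loglik`, `converged`, `settings`.
#' @export
fit_mixture <- function(hist, p, d_abs, B = 1000, seed = 1,
                        objective = c("ml", "ls")) {
  hist <- as_blink_histogram(hist)
  objective <- match.arg(objective)
  if (hist$total_clusters <= 0) qp_data_error("empty histogram")
  q <- d_to_q(d_abs)
  n <- seq_len(hist$n_max)
  mono <- pmf_appearances(n, 1L, p)
  dim2 <- pmf_dimer(n, p, q)
  # censor tail mass into the top bin for both components
  mono[hist$n_max] <- mono[hist$n_max] + max(0, 1 - sum(mono))
  dim2[hist$n_max] <- dim2[hist$n_max] + max(0, 1 - sum(dim2))
  est_obs <- function(h) {
    obj <- if (objective == "ml") {
      function(f) -sum(h$counts * log(pmax(f * dim2 + (1 - f) * mono, 1e-300)))
    } else {
      fr <- h$counts / h$total_clusters
      function(f) sum((fr - (f * dim2 + (1 - f) * mono))^2)
    }
    stats::optimize(obj, c(0, 1), tol = 1e-10)$minimum
  }
  f_obs <- est_obs(hist)
  f_true <- observed_to_true_fraction(f_obs, d_abs)
  ci <- NULL
  if (B > 0) {
    ci_obs <- bootstrap_ci(hist, est_obs, B = B, seed = seed)
    ci_true <- bootstrap_ci(hist, function(h)
      observed_to_true_fraction(est_obs(h), d_abs), B = B, seed = seed)
    ci <- list(dimer_observed = ci_obs, dimer_true = ci_true)
  }
  ll <- sum(hist$counts * log(pmax(f_obs * dim2 + (1 - f_obs) * mono, 1e-300)))
  structure(list(
    fractions = c(monomer = 1 - f_true, dimer = f_true),
    fractions_observed = c(monomer = 1 - f_obs, dimer = f_obs),
    ci = ci, loglik = ll,
    converged = f_obs > 1e-6 && f_obs < 1 - 1e-6,
    n_clusters = hist$total_clusters,
    settings = list(p = p, d_abs = d_abs, q = q, n_max = hist$n_max,
                    objective = objective, B = B, seed = seed)),
    class = "mixture_fit")
}

#' Detectability correction between observed and true dimer fractions
#'
#' A monomer is observed with probability `Pdet1 = d_abs`; a dimer with
#' probability `Pdet2 = 1 - (1 - d_abs)^2`. These reweight the observed
#' mixture relative to the true population.
#'
#' @param f_obs observed (detected-population) dimer fraction in \[0, 1\].
#' @param f_true true population dimer fraction in \[0, 1\].
#' @param d_abs absolute detection efficiency in (0, 1].
#' @return the corresponding fraction.
#' @export
observed_to_true_fraction <- function(f_obs, d_abs) {
  p1 <- d_abs; p2 <- 1 - (1 - d_abs)^2
  (f_obs / p2) / (f_obs / p2 + (1 - f_obs) / p1)
}

#' @rdname observed_to_true_fraction
#' @export
true_to_observed_fraction <- function(f_true, d_abs) {
  p1 <- d_abs; p2 <- 1 - (1 - d_abs)^2
  (f_true * p2) / (f_true * p2 + (1 - f_true) * p1)
}

#' Cluster-level bootstrap interval for a histogram estimator
#'
#' Resamples the blink histogram at the cluster level (multinomial over
#' bins with the total cluster count fixed), applies `estimator` to each
#' resample and reports the 2.5/97.5 percentile interval and the bootstrap
#' standard deviation. Deterministic for a fixed seed.
#'
#' @param hist a [blink_histogram()].
#' @param estimator function taking a `blink_histogram` and returning one
#'   number.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @return list of class `boot_ci`: `lower`, `upper`, `sd`, `B`, `seed`.
#' @export
bootstrap_ci <- function(hist, estimator, B = 1000, seed = 1) {
  hist <- as_blink_histogram(hist)
  if (!is_count(B) || B < 100) qp_param_error("B must be an integer >= 100")
  tot <- round(hist$total_clusters)
  if (tot <= 0) qp_data_error("empty histogram")
  prob <- hist$counts / hist$total_clusters
  vals <- with_seed(seed, {
    draws <- stats::rmultinom(B, size = tot, prob = prob)
    apply(draws, 2, function(cts) estimator(as_blink_histogram(cts)))
  })
  qs <- unname(stats::quantile(vals, c(0.025, 0.975), type = 7))
  structure(list(lower = qs[1], upper = qs[2], sd = stats::sd(vals),
                 B = B, seed = seed),
            class = "boot_ci")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d clusters: dimer fraction %.3f (observed %.3f)\n",
              x$n_clusters, x$fractions[["dimer"]],
              x$fractions_observed[["dimer"]]))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI (true dimer): [%.3f, %.3f], sd %.3f\n",
                x$ci$dimer_true$lower, x$ci$dimer_true$upper,
                x$ci$dimer_true$sd))
  invisible(x)
}

#' @export
print.blink_fit <- function(x, ...) {
  lab <- if (!is.null(x$p)) sprintf("p = %.4f", x$p) else
    sprintf("q = %.4f (d = %.4f)", x$q, x$d)
  cat(sprintf("<blink_fit> %s from %d clusters", lab, x$n_clusters))
  if (!is.null(x$ci))
    cat(sprintf("; 95%% CI [%.4f, %.4f]", x$ci$lower, x$ci$upper))
  cat("\n")
  invisible(x)
}
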
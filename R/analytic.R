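# Exact steady-state theory of the reduced bursty expression model:
# stationary protein distribution, noise decomposition, and the limits of
# noise suppression by negative feedback.

new_protein_distribution <- function(probs, truncation_mass, source) {
  structure(list(n = seq_along(probs) - 1L, probs = probs,
                 truncation_mass = truncation_mass, source = source),
            class = "protein_distribution")
}

#' @export
print.protein_distribution <- function(x, ...) {
  m <- distribution_moments(x)
  cat(sprintf("Protein copy-number distribution (%s): support 0..%d\n",
              x$source, max(x$n)))
  cat(sprintf("  mean = %.4g, var = %.4g, noise eta = %.4g, truncation mass = %.3g\n",
              m$mean_n, m$var_n, m$var_n / m$mean_n^2, x$truncation_mass))
  invisible(x)
}

#' Stationary protein distribution of the bursty feedback model
#'
#' Computes the exact steady-state distribution of the protein copy number
#' for the reduced model with geometric translational bursts (burst
#' probability `p`) and effective transcription rate \eqn{c_n}:
#' \deqn{p_n = A \frac{p^n}{n!} \frac{c_0}{d}
#'       \left(\frac{c_1}{d}+1\right)\cdots\left(\frac{c_{n-1}}{d}+n-1\right).}
#' Weights are accumulated in log space via
#' \eqn{\log w_{n+1} = \log w_n + \log p + \log(c_n/d + n) - \log(n+1)}
#' and the support is extended until a conservative geometric bound on the
#' remaining mass drops below `tail_tol`: the term ratio is bounded by
#' \eqn{p (n + c_{max}/d)/(n+1)}, which is decreasing in `n`, so once it
#' falls below one the remaining mass is at most
#' \eqn{w_N \rho/(1-\rho)} with \eqn{\rho} that bound at the current `N`.
#'
#' @param rf A [regulatory_function()] (or any function of `n`; it is then
#'   wrapped with unknown topology).
#' @param p Burst probability, in (0, 1).
#' @param d Protein degradation rate, `> 0`.
#' @param tail_tol Upper bound on the truncated probability mass.
#' @param n_max Hard cap on the support (error if the tail bound is not
#'   reached by then).
#' @return A `protein_distribution` with fields `n`, `probs`,
#'   `truncation_mass`, `source = "analytic"`;
#'   `sum(probs) + truncation_mass == 1`.
#' @export
steady_state_distribution <- function(rf, p, d, tail_tol = 1e-12,
                                      n_max = 1e6) {
  if (is.function(rf)) rf <- regulatory_function(rf)
  stopifnot(inherits(rf, "regulatory_function"),
            is.numeric(p), length(p) == 1L, p > 0, p < 1,
            is.numeric(d), length(d) == 1L, d > 0)
  c_fn <- rf$c_fn
  logp <- log(p)
  cmax <- max(rf$s, rf$r, 0, na.rm = TRUE)
  chunk <- 1024L
  lw <- numeric(0)
  last_lw <- 0                       # log w_0 = 0
  n0 <- 0L
  log_bound <- Inf
  repeat {
    nn <- n0:(n0 + chunk - 1L)
    cn <- c_fn(nn)
    if (any(!is.finite(cn)) || any(cn < 0))
      stop("regulatory function returned a negative or non-finite rate")
    cmax <- max(cmax, cn)
    inc <- logp + log(cn / d + nn) - log(nn + 1)
    lw_chunk <- last_lw + c(0, cumsum(inc[-chunk]))
    lw <- c(lw, lw_chunk)
    last_lw <- lw_chunk[chunk] + inc[chunk]
    n0 <- n0 + chunk
    if (!is.finite(last_lw)) {       # absorbed: all later weights are zero
      log_bound <- -Inf
      break
    }
    # conservative geometric bound on the mass beyond the current support
    rho <- p * (n0 + cmax / d) / (n0 + 1)
    if (rho < 1) {
      log_bound <- last_lw + log(rho) - log1p(-rho)
      log_tot <- logsumexp(lw)
      if (log_bound - log_tot < log(tail_tol)) break
    }
    if (n0 >= n_max) {
      ach <- if (is.finite(log_bound)) exp(log_bound - logsumexp(lw)) else NA
      stop(sprintf(paste0("steady_state_distribution: tail bound %g not ",
                          "reached within n_max = %g (achieved %.3g); ",
                          "increase n_max or tail_tol"),
                   tail_tol, n_max, ach))
    }
  }
  keep <- which(is.finite(lw))
  if (!length(keep)) stop("degenerate distribution: all weights are zero")
  # trim trailing -Inf but keep the contiguous finite head
  n_keep <- max(keep)
  lw <- lw[seq_len(n_keep)]
  log_tot <- logsumexp(c(lw, log_bound))
  probs <- exp(lw - log_tot)
  probs[!is.finite(lw)] <- 0
  tm <- if (is.finite(log_bound)) exp(log_bound - log_tot) else 0
  new_protein_distribution(probs, tm, "analytic")
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Negative-binomial stationary distribution (no feedback)
#'
#' Closed form of the stationary protein distribution when the effective
#' transcription rate is a constant `c`:
#' \deqn{p_n = \frac{p^n}{n!}\frac{\Gamma(c/d+n)}{\Gamma(c/d)} q^{c/d},}
#' i.e. a negative binomial with size \eqn{c/d} and success probability
#' \eqn{q = 1-p}. Evaluated via log-gamma and truncated at `tail_tol`.
#'
#' @param c Constant transcription rate, `>= 0` (`c = 0` gives a point
#'   mass at zero).
#' @param d Protein degradation rate, `> 0`.
#' @param p Burst probability in (0, 1).
#' @param tail_tol Truncated tail mass.
#' @return A `protein_distribution` with `source = "analytic"`.
#' @export
negative_binomial_pmf <- function(c, d, p, tail_tol = 1e-12) {
  stopifnot(c >= 0, d > 0, p > 0, p < 1)
  if (c == 0) return(new_protein_distribution(1, 0, "analytic"))
  size <- c / d
  nmax <- stats::qnbinom(tail_tol, size = size, prob = 1 - p,
                         lower.tail = FALSE) + 10L
  probs <- stats::dnbinom(0:nmax, size = size, prob = 1 - p)
  new_protein_distribution(probs, max(0, 1 - sum(probs)), "analytic")
}

#' Empirical protein distribution from samples or occupancy weights
#'
#' @param x Non-negative integer observations (when `weights` is `NULL`)
#'   or the integers `0..N` implicitly indexed by `weights`.
#' @param weights Optional non-negative occupancy weights over `0..N`
#'   (e.g. time spent in each state).
#' @param source Provenance tag stored on the object.
#' @return A `protein_distribution`.
#' @export
empirical_distribution <- function(x = NULL, weights = NULL,
                                   source = "empirical_data") {
  if (is.null(weights)) {
    stopifnot(length(x) > 0, all(x >= 0))
    x <- as.integer(round(x))
    weights <- tabulate(x + 1L, nbins = max(x) + 1L)
  }
  stopifnot(all(weights >= 0), sum(weights) > 0)
  new_protein_distribution(weights / sum(weights), 0, source)
}

#' Mean and variance of a protein distribution
#'
#' Exact truncated-sum moments (the distribution is renormalized over its
#' stored support, so the tiny truncated mass is ignored).
#'
#' @param dist A `protein_distribution`.
#' @return List with `mean_n` and `var_n`.
#' @export
distribution_moments <- function(dist) {
  stopifnot(inherits(dist, "protein_distribution"))
  w <- dist$probs
  tot <- sum(w)
  if (tot <= 0) stop("degenerate distribution: zero total mass")
  w <- w / tot
  m1 <- sum(w * dist$n)
  var_n <- sum(w * (dist$n - m1)^2)
  list(mean_n = m1, var_n = var_n)
}

#' Exact feedback coefficient
#'
#' The relative covariance between the protein copy number and the
#' effective transcription rate,
#' \eqn{\eta_f = \mathrm{Cov}(n, c_n)/(\langle n\rangle\langle c_n\rangle)},
#' evaluated under `dist`. Its sign equals the monotonicity sign of
#' \eqn{c_n}: zero for no feedback, positive for positive feedback,
#' negative for negative feedback.
#'
#' @param dist A `protein_distribution`.
#' @param rf A [regulatory_function()].
#' @return The (signed, dimensionless) feedback coefficient.
#' @export
feedback_coefficient_exact <- function(dist, rf) {
  stopifnot(inherits(dist, "protein_distribution"),
            inherits(rf, "regulatory_function"))
  w <- dist$probs / sum(dist$probs)
  n <- dist$n
  cn <- rf$c_fn(n)
  En <- sum(w * n)
  Ec <- sum(w * cn)
  if (En <= 0 || Ec <= 0)
    stop("feedback coefficient undefined: zero mean protein or rate")
  (sum(w * n * cn) - En * Ec) / (En * Ec)
}

#' Decompose the protein noise by biophysical origin
#'
#' Splits the squared coefficient of variation
#' \eqn{\eta = \sigma^2/\langle n\rangle^2} into the Poisson term
#' \eqn{1/\langle n\rangle} (protein birth-death), the mRNA fluctuation
#' term \eqn{d/(v\langle m\rangle)}, and the feedback coefficient
#' \eqn{\eta_f}; equivalently into the feedback-free noise
#' \eqn{1/(q\langle n\rangle)} plus \eqn{\eta_f}. Under fast promoter
#' switching both identities are exact for the analytic stationary law.
#' For empirical distributions (finite switching rates) the residual
#' \eqn{\eta - 1/(q\langle n\rangle) - \eta_f} is reported as the
#' promoter-switching noise `eta_s`.
#'
#' The mRNA mean of the reduced model is taken as
#' \eqn{\langle m\rangle = \langle c_n\rangle/v}, which is consistent with
#' the stationary flux balance \eqn{d\langle n\rangle = (p/q)\langle
#' c_n\rangle}.
#'
#' @param dist A `protein_distribution`.
#' @param rf The [regulatory_function()] that generated it.
#' @param bursts [burst_parameters()] (or a list with `p`, `q`).
#' @param d Protein degradation rate.
#' @param v mRNA degradation rate; defaults to `bursts$lam * d`.
#' @return An object of class `noise_decomposition` with fields `eta`,
#'   `poisson_term`, `mrna_term`, `feedback_free`, `eta_f`, `eta_s`,
#'   `mean_n`, `var_n`, `mrna_mean`.
#' @export
decompose_noise <- function(dist, rf, bursts, d, v = NULL) {
  stopifnot(inherits(dist, "protein_distribution"),
            inherits(rf, "regulatory_function"))
  if (is.null(v)) v <- bursts$lam * d
  stopifnot(v > 0, d > 0)
  mom <- distribution_moments(dist)
  if (mom$mean_n <= 0) stop("noise undefined: zero mean protein level")
  w <- dist$probs / sum(dist$probs)
  mean_c <- sum(w * rf$c_fn(dist$n))
  if (mean_c <= 0) stop("noise decomposition undefined: zero mean rate")
  eta <- mom$var_n / mom$mean_n^2
  feedback_free <- 1 / (bursts$q * mom$mean_n)
  eta_f <- feedback_coefficient_exact(dist, rf)
  eta_s <- if (identical(dist$source, "analytic")) NA_real_
           else eta - feedback_free - eta_f
  structure(list(eta = eta,
                 poisson_term = 1 / mom$mean_n,
                 mrna_term = d / mean_c,
                 feedback_free = feedback_free,
                 eta_f = eta_f,
                 eta_s = eta_s,
                 mean_n = mom$mean_n,
                 var_n = mom$var_n,
                 mrna_mean = mean_c / v),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("Noise decomposition\n")
  cat(sprintf("  mean <n> = %.5g, var = %.5g, eta = %.5g\n",
              x$mean_n, x$var_n, x$eta))
  cat(sprintf("  Poisson 1/<n> = %.5g, mRNA d/(v<m>) = %.5g\n",
              x$poisson_term, x$mrna_term))
  cat(sprintf("  feedback-free 1/(q<n>) = %.5g, feedback eta_f = %+.5g\n",
              x$feedback_free, x$eta_f))
  if (!is.na(x$eta_s))
    cat(sprintf("  promoter-switching residual eta_s = %+.5g\n", x$eta_s))
  invisible(x)
}

#' Flat-list report of a noise decomposition (for JSON serialization)
#' @param x A `noise_decomposition`.
#' @return A plain named list of numbers.
#' @export
decomposition_report <- function(x) {
  stopifnot(inherits(x, "noise_decomposition"))
  unclass(x)
}

#' Noise bounds for a negative-feedback circuit
#'
#' The total noise of a negative-feedback circuit is squeezed between
#' \deqn{\frac{1}{q\langle n\rangle}\frac{1}{1+\alpha p/(dq)} \le \eta <
#'       \frac{1}{q\langle n\rangle},}
#' where \eqn{\alpha} is the steepness of the regulatory function. The
#' corresponding cap on the noise-filtering efficiency is
#' \eqn{\gamma \le 1/(1 + dq/(\alpha p))}.
#'
#' @param q mRNA death probability in (0, 1).
#' @param mean_n Stationary protein mean, `> 0`.
#' @param alpha Steepness \eqn{\sup_x |c'(x)|}, `>= 0`.
#' @param p Burst probability in (0, 1).
#' @param d Protein degradation rate, `> 0`.
#' @return An object of class `noise_bounds`: list with `lower`, `upper`,
#'   `alpha`, `efficiency_cap`.
#' @export
noise_bounds_negative <- function(q, mean_n, alpha, p, d) {
  stopifnot(q > 0, q < 1, mean_n > 0, alpha >= 0, p > 0, p < 1, d > 0)
  if (alpha == 0)
    warning("alpha = 0: bounds collapse to the no-feedback value")
  upper <- 1 / (q * mean_n)
  lower <- upper / (1 + alpha * p / (d * q))
  cap <- if (alpha == 0) 0 else 1 / (1 + d * q / (alpha * p))
  structure(list(lower = lower, upper = upper, alpha = alpha,
                 efficiency_cap = cap),
            class = "noise_bounds")
}

#' @export
print.noise_bounds <- function(x, ...) {
  cat(sprintf("Noise bounds (negative feedback): %.5g <= eta < %.5g; efficiency cap %.4g\n",
              x$lower, x$upper, x$efficiency_cap))
  invisible(x)
}

#' Noise-filtering efficiency of negative feedback
#'
#' The fraction of the feedback-free noise removed by the loop,
#' \eqn{\gamma = -\eta_f/(\eta - \eta_f) \in (0, 1)}. Defined only for
#' negative feedback (`eta_f < 0`).
#'
#' @param eta Total noise, `> 0`.
#' @param eta_f Feedback coefficient, `< 0`.
#' @return Efficiency \eqn{\gamma} in (0, 1).
#' @export
efficiency <- function(eta, eta_f) {
  stopifnot(is.numeric(eta), is.numeric(eta_f))
  if (eta <= 0) stop("efficiency requires eta > 0")
  if (eta_f >= 0)
    stop("efficiency is defined only for negative feedback (eta_f < 0)")
  -eta_f / (eta - eta_f)
}

#' Exponential tail-decay diagnostic
#'
#' Verifies the asymptotic tail law
#' \eqn{p_{n+1}/p_n = p\,(n + c_n/d)/(n+1) \to p}: over the support beyond
#' the 99th percentile it computes
#' \eqn{\max_n |\log(p_{n+1}/p_n) - \log p|}. Small values confirm that
#' `q` (via \eqn{-\log p \approx q} for \eqn{q \ll p}) is the decay rate
#' of the distribution's tail.
#'
#' @param dist An analytic `protein_distribution`.
#' @param q mRNA death probability (its complement `p = 1 - q` sets the
#'   limiting ratio). A warning is issued outside the bursty regime
#'   `p/q >= 10`.
#' @return Maximal absolute deviation of the log tail ratio from
#'   \eqn{\log p}, with the examined range in attribute `"window"`.
#' @export
tail_decay_check <- function(dist, q) {
  stopifnot(inherits(dist, "protein_distribution"), q > 0, q < 1)
  p <- 1 - q
  if (p / q < 10)
    warning("p/q < 10: exponential tail approximation e^{-q} is crude here")
  probs <- dist$probs / sum(dist$probs)
  cdf <- cumsum(probs)
  i99 <- which(cdf >= 0.99)[1]
  tail_idx <- i99:length(probs)
  pos <- tail_idx[probs[tail_idx] > 0]
  if (length(pos) < 6)
    stop("tail too short beyond the 99th percentile for a decay check")
  pos <- pos[-length(pos)]
  ratios <- log(probs[pos + 1]) - log(probs[pos])
  dev <- max(abs(ratios - log(p)))
  attr(dev, "window") <- range(dist$n[pos])
  dev
}

#' Total-variation distance between two protein distributions
#'
#' @param d1,d2 `protein_distribution` objects (supports are aligned by
#'   zero-padding).
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "protein_distribution"),
            inherits(d2, "protein_distribution"))
  len <- max(length(d1$probs), length(d2$probs))
  p1 <- c(d1$probs, numeric(len - length(d1$probs))) / sum(d1$probs)
  p2 <- c(d2$probs, numeric(len - length(d2$probs))) / sum(d2$probs)
  sum(abs(p1 - p2)) / 2
}

#' Write a protein distribution as a two-column TSV (n, probability)
#' @param dist A `protein_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "protein_distribution"))
  utils::write.table(data.frame(n = dist$n, probability = dist$probs),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
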
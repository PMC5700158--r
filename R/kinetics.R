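# Circuit kinetics: the three-stage expression model and its effective
# regulation under fast promoter switching.

#' Promoter switching-rate specification
#'
#' Builds the pair of promoter switching-rate functions \eqn{a_n} (inactive
#' to active) and \eqn{b_n} (active to inactive) from one of the standard
#' parametric families used for autoregulatory circuits.
#'
#' Supported forms:
#' \describe{
#'   \item{`constant`}{\eqn{a_n = a}, \eqn{b_n = b}: no feedback.}
#'   \item{`linear_activation`}{\eqn{a_n = a + k n}, \eqn{b_n = b}: protein
#'     promotes activation (positive feedback when `s > r`).}
#'   \item{`linear_inactivation`}{\eqn{a_n = a}, \eqn{b_n = b + k n}: protein
#'     promotes inactivation (negative feedback when `s > r`).}
#'   \item{`hill`}{\eqn{a_n = a}, \eqn{b_n = n^h}: yields the generalized
#'     Hill regulatory function \eqn{c(x) = (as + x^h r)/(a + x^h)}.}
#' }
#'
#' @param form One of `"constant"`, `"linear_activation"`,
#'   `"linear_inactivation"`, `"hill"`.
#' @param a Baseline activation rate (scale parameter for `"hill"`), `> 0`
#'   unless a linear slope makes the sum positive.
#' @param b Baseline inactivation rate (ignored for `"hill"`).
#' @param k Feedback slope for the linear forms, `>= 0`.
#' @param h Hill coefficient, `>= 1` (only for `"hill"`).
#' @return An object of class `switching_spec` with vectorized rate
#'   functions `a_fn(n)` and `b_fn(n)`.
#' @examples
#' sw <- switching_spec("linear_inactivation", a = 100, b = 1, k = 2)
#' sw$a_fn(0:3); sw$b_fn(0:3)
#' @export
switching_spec <- function(form = c("constant", "linear_activation",
                                    "linear_inactivation", "hill"),
                           a = 1, b = 1, k = 0, h = 1) {
  form <- match.arg(form)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a >= 0,
            is.numeric(b), length(b) == 1L, is.finite(b), b >= 0,
            is.numeric(k), length(k) == 1L, is.finite(k), k >= 0,
            is.numeric(h), length(h) == 1L, is.finite(h))
  if (form == "hill") {
    if (a <= 0) stop("hill switching form requires a > 0")
    if (h < 1) stop("Hill coefficient h must be >= 1")
  }
  fns <- switch(form,
    constant = list(a_fn = function(n) rep_len(a, length(n)),
                    b_fn = function(n) rep_len(b, length(n))),
    linear_activation = list(a_fn = function(n) a + k * n,
                             b_fn = function(n) rep_len(b, length(n))),
    linear_inactivation = list(a_fn = function(n) rep_len(a, length(n)),
                               b_fn = function(n) b + k * n),
    hill = list(a_fn = function(n) rep_len(a, length(n)),
                b_fn = function(n) n^h)
  )
  structure(list(form = form, params = list(a = a, b = b, k = k, h = h),
                 a_fn = fns$a_fn, b_fn = fns$b_fn),
            class = "switching_spec")
}

#' Gene circuit with autoregulatory promoter switching
#'
#' Full kinetic parameterization of the three-stage expression model: a
#' promoter that switches between an active form (transcription rate `s`)
#' and an inactive form (basal rate `r`), mRNA translated at rate `u` per
#' transcript and degraded at rate `v`, protein degraded at rate `d`.
#' Feedback enters through the protein-copy-number dependence of the
#' promoter switching rates \eqn{a_n} (on) and \eqn{b_n} (off).
#'
#' @param s Transcription rate of the active promoter (molecules/time),
#'   `>= 0`.
#' @param r Basal transcription rate of the inactive promoter, `>= 0`.
#' @param u Translation rate per mRNA (1/time), `> 0`.
#' @param v mRNA degradation rate (1/time), `> 0`.
#' @param d Protein degradation rate (1/time), `> 0`.
#' @param switching A [switching_spec()], or a list with elements `a_fn`
#'   and `b_fn`, vectorized non-negative rate functions of the protein
#'   copy number `n`.
#' @return An object of class `gene_circuit`.
#' @examples
#' cir <- gene_circuit(s = 100, r = 5, u = 70, v = 30, d = 1,
#'                     switching = switching_spec("hill", a = 200, h = 2))
#' burst_parameters(cir)
#' @export
gene_circuit <- function(s, r, u, v, d,
                         switching = switching_spec("constant")) {
  # u = 0 (translation off) is tolerated for simulation diagnostics even
  # though burst parameters are then undefined
  stopifnot(is.numeric(s), s >= 0, is.numeric(r), r >= 0,
            is.numeric(u), u >= 0, is.numeric(v), v > 0,
            is.numeric(d), d > 0)
  if (!is.list(switching) || is.null(switching$a_fn) ||
      is.null(switching$b_fn))
    stop("'switching' must be a switching_spec or a list with a_fn and b_fn")
  structure(list(s = s, r = r, u = u, v = v, d = d,
                 a_fn = switching$a_fn, b_fn = switching$b_fn,
                 switching = if (inherits(switching, "switching_spec"))
                   switching else NULL),
            class = "gene_circuit")
}

#' @export
print.gene_circuit <- function(x, ...) {
  cat("Gene circuit (three-stage model)\n")
  cat(sprintf("  transcription: s = %g (active), r = %g (inactive)\n",
              x$s, x$r))
  cat(sprintf("  translation u = %g, mRNA decay v = %g, protein decay d = %g\n",
              x$u, x$v, x$d))
  bp <- burst_parameters(x)
  cat(sprintf("  burst parameters: p = %.4g, q = %.4g, lambda = v/d = %.4g\n",
              bp$p, bp$q, bp$lam))
  if (!is.null(x$switching))
    cat(sprintf("  switching form: %s\n", x$switching$form))
  invisible(x)
}

#' Translational burst parameters
#'
#' The probability that a given mRNA molecule produces one more protein
#' before being degraded is \eqn{p = u/(u+v)}; with probability
#' \eqn{q = v/(u+v)} it dies first. The resulting burst sizes are geometric
#' with mean \eqn{p/q = u/v}. The lifetime ratio \eqn{\lambda = v/d}
#' controls the validity of the reduced bursty model (requires
#' \eqn{\lambda \gg 1}).
#'
#' @param u Translation rate per mRNA, or a [gene_circuit()].
#' @param v mRNA degradation rate (ignored when `u` is a circuit).
#' @param d Protein degradation rate (ignored when `u` is a circuit).
#' @return An object of class `burst_parameters`: list with `p`, `q`,
#'   `lam`; `p + q == 1` exactly.
#' @export
burst_parameters <- function(u, v = NULL, d = NULL) {
  if (inherits(u, "gene_circuit")) {
    cir <- u; u <- cir$u; v <- cir$v; d <- cir$d
  }
  stopifnot(is.numeric(u), length(u) == 1L, is.numeric(v), length(v) == 1L,
            is.numeric(d), length(d) == 1L)
  if (u <= 0 || v <= 0 || d <= 0)
    stop("burst parameters require positive rates u, v, d")
  p <- u / (u + v)
  structure(list(p = p, q = 1 - p, lam = v / d), class = "burst_parameters")
}

#' @export
print.burst_parameters <- function(x, ...) {
  cat(sprintf("Burst parameters: p = %.6g, q = %.6g, lambda = %.6g (mean burst size p/q = %.4g)\n",
              x$p, x$q, x$lam, x$p / x$q))
  invisible(x)
}

#' Effective transcription rate under fast promoter switching
#'
#' When promoter switching is fast compared with protein turnover, the
#' promoter equilibrates at each protein level and transcription proceeds
#' at the switching-averaged rate
#' \deqn{c_n = \frac{a_n s + b_n r}{a_n + b_n},}
#' which always lies between the basal and active rates. The monotonicity
#' of \eqn{c_n} in `n` encodes the feedback sign.
#'
#' @param circuit A [gene_circuit()].
#' @param n Protein copy number(s), non-negative.
#' @return Numeric vector of effective rates, one per element of `n`.
#' @export
effective_transcription_rate <- function(circuit, n) {
  stopifnot(inherits(circuit, "gene_circuit"), all(n >= 0))
  a <- circuit$a_fn(n)
  b <- circuit$b_fn(n)
  if (any(a < 0) || any(b < 0))
    stop("switching rates must be non-negative")
  bad <- which(a + b <= 0)
  if (length(bad))
    stop(sprintf("invalid kinetics: a_n + b_n = 0 at n = %s",
                 paste(n[bad[seq_len(min(5, length(bad)))]], collapse = ", ")))
  (a * circuit$s + b * circuit$r) / (a + b)
}

#' Regulatory function c(x)
#'
#' Wraps an effective transcription-rate function, defined on real
#' \eqn{x \ge 0} (the integer version \eqn{c_n} is the same function
#' evaluated at \eqn{x = n}), together with its declared feedback topology.
#'
#' @param c_fn Vectorized non-negative function of `x >= 0`.
#' @param topology One of `"positive"`, `"negative"`, `"none"`,
#'   `"unknown"`.
#' @param s,r Optional active/basal rates bracketing the range of `c_fn`
#'   (used for tolerance scaling and tail bounds).
#' @return An object of class `regulatory_function`, callable via `$c_fn`.
#' @seealso [hill_regulatory_function()], [as_regulatory_function()]
#' @export
regulatory_function <- function(c_fn, topology = "unknown",
                                s = NA_real_, r = NA_real_) {
  stopifnot(is.function(c_fn),
            topology %in% c("positive", "negative", "none", "unknown"))
  structure(list(c_fn = c_fn, declared_topology = topology, s = s, r = r),
            class = "regulatory_function")
}

#' @export
print.regulatory_function <- function(x, ...) {
  cat(sprintf("Regulatory function c(x); declared topology: %s\n",
              x$declared_topology))
  cat(sprintf("  c(0) = %g, c(10) = %g, c(100) = %g\n",
              x$c_fn(0), x$c_fn(10), x$c_fn(100)))
  invisible(x)
}

#' Regulatory function of a gene circuit
#'
#' Builds the fast-switching effective transcription rate
#' \eqn{c(x) = (a(x) s + b(x) r)/(a(x)+b(x))} of a circuit as a
#' [regulatory_function()], with the topology declared from the switching
#' form when known (and `"unknown"` otherwise).
#'
#' @param circuit A [gene_circuit()].
#' @return A [regulatory_function()].
#' @export
as_regulatory_function <- function(circuit) {
  stopifnot(inherits(circuit, "gene_circuit"))
  s <- circuit$s; r <- circuit$r
  a_fn <- circuit$a_fn; b_fn <- circuit$b_fn
  c_fn <- function(x) {
    a <- a_fn(x); b <- b_fn(x)
    (a * s + b * r) / (a + b)
  }
  topo <- "unknown"
  if (!is.null(circuit$switching)) {
    form <- circuit$switching$form
    k <- circuit$switching$params$k
    ds <- sign(s - r)
    topo <- switch(form,
      constant = "none",
      # growing a_n pushes c toward s
      linear_activation = if (k == 0 || ds == 0) "none"
                          else if (ds > 0) "positive" else "negative",
      # growing b_n pushes c toward r
      linear_inactivation = if (k == 0 || ds == 0) "none"
                            else if (ds > 0) "negative" else "positive",
      hill = if (ds == 0) "none" else if (ds > 0) "negative" else "positive")
  }
  regulatory_function(c_fn, topology = topo, s = s, r = r)
}

#' Generalized Hill regulatory function
#'
#' The effective transcription rate
#' \deqn{c(x) = \frac{a s + x^h r}{a + x^h}}
#' interpolating from `c(0) = s` to `r` as \eqn{x \to \infty}; decreasing
#' (negative feedback) when `s > r`, increasing (positive feedback) when
#' `s < r`.
#'
#' @param a Scale parameter, `> 0` (half-saturation at \eqn{x = a^{1/h}}).
#' @param s Rate at `x = 0`, `>= 0`.
#' @param r Asymptotic rate, `>= 0`.
#' @param h Hill coefficient, `>= 1`.
#' @return A [regulatory_function()].
#' @export
hill_regulatory_function <- function(a, s, r, h = 1) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(h), length(h) == 1L)
  if (!is.finite(a) || a <= 0) stop("Hill scale 'a' must be > 0")
  if (h < 1) stop("Hill coefficient h must be >= 1")
  if (s < 0 || r < 0) stop("rates s, r must be >= 0")
  topo <- if (s > r) "negative" else if (s < r) "positive" else "none"
  c_fn <- function(x) (a * s + x^h * r) / (a + x^h)
  regulatory_function(c_fn, topology = topo, s = s, r = r)
}

#' Maximal steepness of the generalized Hill function
#'
#' Closed-form supremum of \eqn{|c'(x)|} over \eqn{x > 0} for the
#' generalized Hill regulatory function:
#' \deqn{\alpha = \frac{(h-1)^{1-1/h}(h+1)^{1+1/h}}{4h}\,
#'       \frac{s-r}{a^{1/h}}.}
#' At `h = 1` the factor \eqn{(h-1)^{1-1/h}} is a removable \eqn{0^0} and
#' is evaluated as its limit 1, reproducing the direct derivative bound
#' \eqn{(s-r)/a}.
#'
#' @inheritParams hill_regulatory_function
#' @return The steepness \eqn{\alpha \ge 0} (rate per copy number).
#' @export
hill_steepness <- function(a, s, r, h = 1) {
  stopifnot(a > 0, h >= 1, s >= r)
  if (s == r) return(0)
  fac <- if (h == 1) 1 else (h - 1)^(1 - 1 / h)
  fac * (h + 1)^(1 + 1 / h) / (4 * h) * (s - r) / a^(1 / h)
}

#' Classify the feedback topology of a regulatory function
#'
#' Evaluates `c` on the integers `0..n_max` and reports `"positive"` if it
#' is increasing, `"negative"` if decreasing, `"none"` if constant, and
#' `"non-monotone"` otherwise. Differences smaller than
#' `1e-12 * max(|s|, |r|, 1)` (or the range of the evaluated values when
#' `s`, `r` are unknown) are treated as zero so that floating-point noise
#' cannot turn "none" into a feedback call.
#'
#' @param rf A [regulatory_function()].
#' @param n_max Largest copy number examined, `>= 2`.
#' @return One of `"positive"`, `"negative"`, `"none"`, `"non-monotone"`.
#' @export
classify_topology <- function(rf, n_max = 200L) {
  stopifnot(inherits(rf, "regulatory_function"), n_max >= 2)
  cn <- rf$c_fn(0:n_max)
  scale <- max(abs(rf$s), abs(rf$r), abs(cn), 1, na.rm = TRUE)
  tol <- 1e-12 * scale
  dn <- diff(cn)
  up <- any(dn > tol)
  down <- any(dn < -tol)
  if (up && down) "non-monotone"
  else if (up) "positive"
  else if (down) "negative"
  else "none"
}

# ---- configuration -------------------------------------------------------

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' Build a gene circuit from a configuration block
#'
#' Accepts a list (or a path to a JSON/YAML file) with named numeric
#' fields `s`, `r`, `u`, `v`, `d` and a `switching` block
#' `list(form = ..., a = , b = , k = , h = )` as in [switching_spec()].
#' Unknown keys are rejected.
#'
#' @param config A named list or a file path.
#' @return A [gene_circuit()].
#' @export
circuit_from_config <- function(config) {
  if (is.character(config)) config <- read_config_file(config)
  if (!is.list(config)) stop("config must be a list or a file path")
  allowed <- c("s", "r", "u", "v", "d", "switching")
  extra <- setdiff(names(config), allowed)
  if (length(extra))
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  need <- setdiff(c("s", "r", "u", "v", "d"), names(config))
  if (length(need))
    stop(sprintf("missing config key(s): %s", paste(need, collapse = ", ")))
  sw <- config$switching
  if (is.null(sw)) {
    spec <- switching_spec("constant")
  } else {
    if (is.null(sw$form)) stop("switching block must name a 'form'")
    sw_allowed <- c("form", "a", "b", "k", "h")
    sw_extra <- setdiff(names(sw), sw_allowed)
    if (length(sw_extra))
      stop(sprintf("unknown switching key(s): %s",
                   paste(sw_extra, collapse = ", ")))
    args <- sw[setdiff(names(sw), "form")]
    spec <- do.call(switching_spec, c(list(form = sw$form), args))
  }
  gene_circuit(s = config$s, r = config$r, u = config$u, v = config$v,
               d = config$d, switching = spec)
}
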
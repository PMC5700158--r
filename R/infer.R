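# Feedback-sign inference from single-cell protein measurements: moment
# estimation, exponential tail-decay fitting, and the bootstrapped
# feedback-coefficient estimator eta_f = sigma^2/<n>^2 - 1/(q<n>).

#' Single-cell dataset
#'
#' @param values Non-negative measurements: protein copy numbers
#'   (integers) or fluorescence/concentration values (reals).
#' @param is_concentration `TRUE` when the values are on an arbitrary
#'   continuous scale (tail bins are then chosen by the Freedman-Diaconis
#'   rule instead of unit bins).
#' @param label Free-text condition label.
#' @return An object of class `sc_dataset`.
#' @export
single_cell_dataset <- function(values, is_concentration = FALSE,
                                label = "") {
  values <- as.numeric(values)
  if (!length(values)) stop("empty dataset")
  if (anyNA(values) || any(values < 0))
    stop("values must be non-negative and non-missing")
  structure(list(values = values,
                 is_concentration = isTRUE(is_concentration),
                 label = as.character(label)),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("Single-cell dataset '%s': %d cells (%s)\n", x$label,
              length(x$values),
              if (x$is_concentration) "concentrations" else "copy numbers"))
  cat(sprintf("  mean = %.4g, sd = %.4g, range = [%.4g, %.4g]\n",
              mean(x$values), stats::sd(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Sample moments of a single-cell dataset
#'
#' @param data An `sc_dataset` (or a numeric vector).
#' @return List with `mean_hat` (sample mean) and `var_hat` (unbiased
#'   sample variance).
#' @export
estimate_moments <- function(data) {
  x <- if (inherits(data, "sc_dataset")) data$values else as.numeric(data)
  if (length(x) < 2) stop("at least two cells are needed for moments")
  list(mean_hat = mean(x), var_hat = stats::var(x))
}

# Core tail fit on a numeric vector. Integer data use unit bins; for
# concentrations the bin width follows the Freedman-Diaconis rule on the
# window.
#
# method "curved" (default): Poisson log-linear regression of the bin
# counts on (center, log center). The stationary law of the bursty model
# has log p_n = const + n log(p) + (C - 1) log(n) + O(1/n) whenever the
# regulatory function saturates in the tail (C = c_tail/d), so the log
# term absorbs the polynomial prefactor that would otherwise bias the
# slope at accessible copy numbers; all bins in the window enter (zeros
# included), avoiding the selection bias of count thresholds.
#
# method "ols": unweighted least squares of log relative frequency
# against bin center over bins with >= min_bin_count cells.
#
# Both return q_hat = -slope; the slope coefficient rescales exactly
# under x -> x/V (the log term changes only by an additive constant), so
# q_hat * mean is scale invariant.
tail_fit_values <- function(x, window = c(0.60, 0.9995), min_bin_count = 5,
                            integer_mode = TRUE,
                            method = c("curved", "ols")) {
  method <- match.arg(method)
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] > 0, window[2] < 1)
  qs <- stats::quantile(x, window, names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  sel <- x[x >= lo & x <= hi]
  if (length(sel) < 8 * min_bin_count)
    stop("too few cells in the tail window; widen the window or add cells")
  delta <- NA_real_  # lattice spacing of quantized data, if any
  if (integer_mode) {
    width <- 1
    delta <- 1
    lo <- floor(lo)
    nb <- as.integer(round(hi)) - as.integer(lo) + 1L
    idx <- as.integer(round(sel)) - as.integer(lo)
    counts <- tabulate(idx + 1L, nbins = nb)
    centers <- lo + seq_along(counts) - 1  # integer bin at its value
  } else {
    iqr <- stats::IQR(sel)
    if (iqr <= 0) stop("degenerate tail window (zero spread)")
    width <- 2 * iqr / length(sel)^(1 / 3)
    # quantized measurements (e.g. rescaled counts, digitized fluorescence)
    # alias badly into bins of arbitrary width: snap the width to a
    # multiple of the value lattice and align the edges, so every bin
    # covers the same number of lattice sites
    ux <- unique(sort(sel))
    gaps <- diff(ux)
    gaps <- gaps[gaps > 0]
    if (length(gaps)) {
      gap <- min(gaps)
      if (gap > 1e-9 * max(sel) && width > 1.5 * gap &&
          width / gap < 1e4) {
        delta <- gap
        width <- max(1, round(width / gap)) * gap
        lo <- ux[1] - gap / 2
      }
    }
    nb <- as.integer(floor((hi - lo) / width)) + 1L
    idx <- pmin(as.integer(floor((sel - lo) / width)), nb - 1L)
    counts <- tabulate(idx + 1L, nbins = nb)
    centers <- lo + (seq_along(counts) - 0.5) * width
  }
  ok <- centers > 0
  counts <- counts[ok]; centers <- centers[ok]
  if (method == "curved") {
    if (length(counts) < 8)
      stop("fewer than 8 tail bins; widen the window or add cells")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, centers, log(centers)), counts,
                     family = stats::poisson()))
    if (!fit$converged) stop("tail fit did not converge")
    slope <- fit$coefficients[[2]]
    n_bins <- length(counts)
  } else {
    use <- counts >= min_bin_count
    if (sum(use) < 8)
      stop(sprintf("only %d usable tail bins (need >= 8); widen the window or add cells",
                   sum(use)))
    xc <- centers[use]
    y <- log(counts[use] / (length(x) * width))
    sx <- xc - mean(xc)
    slope <- sum(sx * (y - mean(y))) / sum(sx * sx)
    n_bins <- sum(use)
  }
  # diagnostic R^2 of log counts vs the fitted linear predictor, over
  # well-populated bins
  use <- counts >= max(min_bin_count, 1)
  yobs <- log(counts[use])
  yfit <- if (method == "curved")
    fit$coefficients[[1]] + slope * centers[use] +
      fit$coefficients[[3]] * log(centers[use])
  else
    slope * centers[use]
  r2 <- if (stats::var(yobs) > 0) stats::cor(yobs, yfit)^2 else 0
  # For copy numbers (and lattice-quantized concentrations) the exact tail
  # ratio is p_{n+1}/p_n -> p, so the per-step log ratio converts to the
  # death probability via q = 1 - e^{slope * delta}; for genuinely
  # continuous data the decay rate is the negated slope itself. The two
  # agree to O(q^2) in the bursty regime q << p.
  q_hat <- if (is.finite(delta) && slope * delta > -30)
    (1 - exp(slope * delta)) / delta else -slope
  list(q_hat = q_hat, slope = slope, r_squared = r2,
       window = c(lo, hi), n_bins = n_bins, bin_width = width,
       method = method, decreasing = slope < 0)
}

#' Estimate the exponential decay rate of the distribution tail
#'
#' Histograms the upper tail of the data (sample-quantile window,
#' default the 60th to 99.95th percentiles) and fits its log frequencies
#' against the bin centers. The negated linear slope estimates the
#' tail-decay rate: for copy numbers this approximates the mRNA death
#' probability `q` (per copy); for concentrations `x = n/V` it estimates
#' `q V` (per concentration unit), so the product `q_hat * mean_hat` is
#' scale invariant.
#'
#' The default `method = "curved"` is a Poisson log-linear regression of
#' the bin counts on `(center, log center)`: the stationary law of the
#' bursty model decays as \eqn{n^{C-1} e^{n \log p}} when the regulatory
#' function saturates in the tail, and the `log` term absorbs the
#' polynomial prefactor that would otherwise bias the slope at the copy
#' numbers a realistic window reaches. `method = "ols"` is the plain
#' unweighted least-squares fit of log relative frequency against bin
#' center over bins with at least `min_bin_count` cells; it is unbiased
#' only when the window sits deep in the purely exponential regime.
#'
#' @param data An `sc_dataset`.
#' @param window Quantile pair defining the fitted tail.
#' @param min_bin_count Minimum cells per usable bin (`"ols"` method and
#'   diagnostics).
#' @param method `"curved"` (default) or `"ols"`.
#' @return List with `q_hat` and tail-fit diagnostics (`r_squared`,
#'   `window`, `n_bins`, `bin_width`, `method`, `decreasing`). A warning
#'   is issued when the fitted tail is not decreasing.
#' @export
estimate_decay_rate <- function(data, window = c(0.60, 0.9995),
                                min_bin_count = 5,
                                method = c("curved", "ols")) {
  stopifnot(inherits(data, "sc_dataset"))
  fit <- tail_fit_values(data$values, window, min_bin_count,
                         integer_mode = !data$is_concentration,
                         method = method)
  if (!fit$decreasing)
    warning("tail is not decreasing over the fit window; q_hat <= 0")
  fit
}

#' Infer the feedback sign from a single-cell dataset
#'
#' Plug-in estimate of the feedback coefficient,
#' \deqn{\hat\eta_f = \frac{\hat\sigma^2}{\hat{\langle n\rangle}^2} -
#'       \frac{1}{\hat q\,\hat{\langle n\rangle}},}
#' with uncertainty from a seeded nonparametric bootstrap (cells resampled
#' with replacement, the full moment + tail-fit pipeline re-run per
#' resample). The topology call compares \eqn{z = \hat\eta_f /
#' \mathrm{se}(\hat\eta_f)} with `z_threshold`: positive feedback when `z`
#' exceeds it, negative when below its negative, none otherwise.
#'
#' @param data An `sc_dataset` with at least `min_cells` cells.
#' @param window Tail-fit quantile window.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param z_threshold Two-sided z cutoff for the call.
#' @param min_bin_count Minimum cells per usable tail bin.
#' @param min_cells Minimum number of cells required.
#' @param method Tail-fit method, see [estimate_decay_rate()].
#' @return An object of class `feedback_inference`: estimates
#'   (`mean_hat`, `var_hat`, `q_hat`, `eta_hat`, `feedback_free_hat`,
#'   `eta_f_hat`), `se_eta_f`, `z`, `call`
#'   (`"positive"`/`"negative"`/`"none"`), `unreliable` (more than 10% of
#'   bootstrap replicates failed), and `tail_fit` diagnostics.
#' @export
infer_feedback <- function(data, window = c(0.60, 0.9995), B = 200,
                           seed = 1, z_threshold = 1.96,
                           min_bin_count = 5, min_cells = 500,
                           method = c("curved", "ols")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "sc_dataset"))
  x <- data$values
  n <- length(x)
  if (n < min_cells)
    stop(sprintf("inference requires at least %d cells (got %d)",
                 min_cells, n))
  integer_mode <- !data$is_concentration
  mom <- estimate_moments(data)
  if (mom$mean_hat <= 0) stop("zero mean expression; inference undefined")
  if (mom$var_hat <= 0) stop("constant data; inference undefined")
  fit <- tail_fit_values(x, window, min_bin_count, integer_mode, method)
  if (!fit$decreasing)
    warning("tail not decreasing; the decay-rate estimate is unusable")
  point <- function(m, v, qh) v / m^2 - 1 / (qh * m)
  eta_hat <- mom$var_hat / mom$mean_hat^2
  ff_hat <- 1 / (fit$q_hat * mom$mean_hat)
  eta_f_hat <- eta_hat - ff_hat
  set.seed(seed)
  boot <- numeric(B)
  failed <- 0L
  for (b in seq_len(B)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    est <- tryCatch({
      fb <- tail_fit_values(xb, window, min_bin_count, integer_mode, method)
      if (fb$q_hat <= 0) stop("non-decreasing tail")
      point(mean(xb), stats::var(xb), fb$q_hat)
    }, error = function(e) NA_real_)
    if (is.na(est)) failed <- failed + 1L
    boot[b] <- est
  }
  se <- stats::sd(boot[!is.na(boot)])
  z <- eta_f_hat / se
  call <- if (z > z_threshold) "positive"
          else if (z < -z_threshold) "negative"
          else "none"
  structure(list(label = data$label, n_cells = n,
                 mean_hat = mom$mean_hat, var_hat = mom$var_hat,
                 q_hat = fit$q_hat, eta_hat = eta_hat,
                 feedback_free_hat = ff_hat, eta_f_hat = eta_f_hat,
                 se_eta_f = se, z = z, call = call,
                 z_threshold = z_threshold, B = B,
                 boot_failed = failed, unreliable = failed > 0.1 * B,
                 tail_fit = fit),
            class = "feedback_inference")
}

#' @export
print.feedback_inference <- function(x, ...) {
  cat(sprintf("Feedback inference%s (%d cells)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n_cells))
  cat(sprintf("  mean = %.5g, var = %.5g, eta = %.5g\n",
              x$mean_hat, x$var_hat, x$eta_hat))
  cat(sprintf("  q_hat = %.5g (tail R^2 = %.3f, %d bins)\n",
              x$q_hat, x$tail_fit$r_squared, x$tail_fit$n_bins))
  cat(sprintf("  feedback-free 1/(q<n>) = %.5g\n", x$feedback_free_hat))
  cat(sprintf("  eta_f = %+.5g +/- %.3g (z = %.2f) -> call: %s%s\n",
              x$eta_f_hat, x$se_eta_f, x$z, toupper(x$call),
              if (x$unreliable) " [UNRELIABLE]" else ""))
  invisible(x)
}

#' Analyze a panel of single-cell datasets
#'
#' Runs [infer_feedback()] on each dataset (per-dataset failures are
#' isolated, not fatal) and assembles a condition-by-condition table of
#' the total noise, feedback-free noise, and feedback coefficient with
#' bootstrap standard errors — the quantities needed for a dose-response
#' plot of the decomposition.
#'
#' @param datasets A list of `sc_dataset` objects (or a single one).
#' @param ... Passed to [infer_feedback()] (`window`, `B`, `z_threshold`,
#'   ...).
#' @param seed Base seed; dataset `i` uses `seed + i - 1`.
#' @return A data.frame of class `panel_result` with one row per
#'   condition; failed conditions carry `NA` estimates and the error
#'   message.
#' @export
analyze_panel <- function(datasets, ..., seed = 1) {
  if (inherits(datasets, "sc_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  rows <- lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    res <- tryCatch(infer_feedback(ds, seed = seed + i - 1, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(label = ds$label, n_cells = length(ds$values),
                 mean_hat = NA_real_, var_hat = NA_real_,
                 eta_hat = NA_real_, q_hat = NA_real_,
                 feedback_free_hat = NA_real_, eta_f_hat = NA_real_,
                 se_eta_f = NA_real_, z = NA_real_, call = NA_character_,
                 unreliable = NA, r_squared = NA_real_,
                 error = conditionMessage(res))
    } else {
      data.frame(label = res$label, n_cells = res$n_cells,
                 mean_hat = res$mean_hat, var_hat = res$var_hat,
                 eta_hat = res$eta_hat, q_hat = res$q_hat,
                 feedback_free_hat = res$feedback_free_hat,
                 eta_f_hat = res$eta_f_hat, se_eta_f = res$se_eta_f,
                 z = res$z, call = res$call, unreliable = res$unreliable,
                 r_squared = res$tail_fit$r_squared, error = "")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("panel_result", class(out))
  out
}

#' Read single-cell datasets from a delimited file
#'
#' Accepts either a one-column table of values (header optional) or a
#' two-column long-format table `(condition, value)`; the delimiter is
#' inferred from the extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path File path.
#' @param is_concentration Passed to [single_cell_dataset()].
#' @return A list of `sc_dataset` objects (length 1 for one-column input).
#' @export
read_datasets <- function(path, is_concentration = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- utils::read.table(path, sep = sep, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- !all(vapply(first, is.numeric, logical(1)))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 1) {
    list(single_cell_dataset(df[[1]], is_concentration,
                             label = sub("\\.[^.]+$", "", basename(path))))
  } else if (ncol(df) == 2) {
    groups <- split(df[[2]], factor(df[[1]], levels = unique(df[[1]])))
    unname(Map(function(v, lab)
      single_cell_dataset(v, is_concentration, label = lab),
      groups, names(groups)))
  } else {
    stop("expected a one-column or two-column (condition, value) table")
  }
}
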
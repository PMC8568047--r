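#' Z-score a fluorescence trace
#'
#' Standardizes a trace to zero mean and unit sd over the full record using
#' the sample sd (n - 1 denominator). Constant traces cannot be standardized
#' and are returned as all-NA with a warning so that downstream selection
#' drops them.
#'
#' @param x Numeric trace.
#' @return Standardized numeric vector.
#' @export
zscore_trace <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant trace: flagged degenerate (all NA)")
    return(rep(NA_real_, length(x)))
  }
  (x - mean(x)) / s
}

#' Z-score every trace in a matrix
#'
#' Row-wise \code{\link{zscore_trace}} over an ROIs x samples matrix.
#' Standardization is per ROI over the full recording; "pooling" refers to
#' assembling all ROIs of all fish into one matrix before thresholding, not
#' to sharing a scale across ROIs (a cohort-wide scale would leave
#' ROI-specific offsets that break regression comparability). A pooled
#' cohort-wide standardization is available behind \code{pooled = TRUE}.
#'
#' @param traces ROIs x samples matrix.
#' @param pooled If TRUE, standardize with the grand mean/sd of the whole
#'   matrix instead of per ROI.
#' @return Matrix of the same shape.
#' @export
zscore_traces <- function(traces, pooled = FALSE) {
  if (pooled) {
    s <- stats::sd(as.vector(traces))
    if (s == 0) stop("constant trace matrix")
    return((traces - mean(traces)) / s)
  }
  mu <- rowMeans(traces)
  s <- sqrt(rowSums((traces - mu)^2) / (ncol(traces) - 1))
  bad <- !is.finite(s) | s == 0
  s[bad] <- NA_real_
  out <- (traces - mu) / s
  if (any(bad)) warning(sum(bad), " constant trace(s) flagged degenerate")
  out
}

#' Coefficient of determination of a trace against a stimulus regressor
#'
#' Ordinary least squares of the (z-scored) trace on the regressor with an
#' intercept, restricted to \code{fit_range}; returns r-squared. For this
#' simple regression r-squared equals the squared Pearson correlation.
#'
#' @param z Numeric trace (same clock as the regressor).
#' @param regressor A \code{"regressor"} or numeric vector.
#' @param fit_range Integer sample indices to fit over (default: all).
#' @return r-squared in [0, 1].
#' @export
regress_roi <- function(z, regressor, fit_range = NULL) {
  r <- if (inherits(regressor, "regressor")) regressor$samples else regressor
  if (is.null(fit_range)) fit_range <- seq_along(r)
  zf <- z[fit_range]; rf <- r[fit_range]
  if (stats::sd(rf) == 0) stop("zero-variance regressor on fit_range")
  fit <- stats::lm(zf ~ rf)
  summary(fit)$r.squared
}

# Vectorized multiple-regression r2 of every row of `traces` on the columns
# of `R` (with intercept) over `fit_range`. Used when a protocol mixes
# stimulus kinds: a single combined regressor structurally penalizes ROIs
# responding to only one component, so each kind gets its own regressor.
.r2_rows_multi <- function(traces, R, fit_range = NULL) {
  if (is.null(fit_range)) fit_range <- seq_len(nrow(R))
  X <- R[fit_range, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  qrx <- qr(Xc)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  Z <- traces[, fit_range, drop = FALSE]
  Zc <- Z - rowMeans(Z)
  expl <- rowSums((Zc %*% Q)^2)
  drop(expl / rowSums(Zc^2))
}

# Vectorized squared correlation of every row of `traces` with `r` over
# `fit_range`; algebraically identical to regress_roi per row.
.r2_rows <- function(traces, r, fit_range = NULL) {
  if (inherits(r, "regressor")) r <- r$samples
  if (is.null(fit_range)) fit_range <- seq_along(r)
  X <- traces[, fit_range, drop = FALSE]
  rf <- r[fit_range] - mean(r[fit_range])
  Xc <- X - rowMeans(X)
  num <- (Xc %*% rf)^2
  den <- rowSums(Xc^2) * sum(rf^2)
  drop(num / den)
}

#' Select responsive ROIs by the median + 2 SD r-squared rule
#'
#' The responsiveness threshold is computed over the pooled per-ROI
#' r-squared values of the whole cohort: tau = median(r2) + 2 * sd(r2)
#' (sample sd). An ROI is responsive iff its r-squared strictly exceeds tau.
#'
#' @param r2 Numeric vector of per-ROI r-squared values (length >= 2; NAs
#'   are treated as non-responsive and excluded from the threshold).
#' @return A list of class \code{"responsiveness"}: \code{r2},
#'   \code{threshold}, \code{responsive} (logical).
#' @export
select_responsive <- function(r2) {
  ok <- is.finite(r2)
  if (sum(ok) < 2) stop("need at least 2 ROIs with finite r-squared")
  tau <- stats::median(r2[ok]) + 2 * stats::sd(r2[ok])
  structure(list(r2 = r2, threshold = tau,
                 responsive = ok & r2 > tau),
            class = "responsiveness")
}

#' @export
print.responsiveness <- function(x, ...) {
  cat(sprintf(
    "Responsiveness: %d / %d ROIs above threshold %s (median + 2 SD)\n",
    sum(x$responsive), length(x$responsive),
    paste(sprintf("%.4f", x$threshold), collapse = "/")))
  invisible(x)
}

#' Baseline-subtracted maximum response to one stimulus
#'
#' Maximum z value within the stimulus window (onset to the end of the fade
#' by default) minus the mean z over the \code{baseline_s} seconds preceding
#' onset. A baseline extending before the start of the record is truncated
#' with a warning.
#'
#' @param z Numeric z-scored trace.
#' @param event A \code{\link{stim_event}}.
#' @param rate_hz Sampling rate of the trace.
#' @param baseline_s Baseline length in seconds (> 0, default 5).
#' @param window \code{"full"} (expansion + fade), \code{"expansion"}
#'   (expansion period only), or \code{"peak"} (1 s around the end of the
#'   expansion, where the kernel-convolved response peaks; the tight window
#'   minimizes the extreme-value bias of the max statistic).
#' @return The maximum response in z units.
#' @export
max_response <- function(z, event, rate_hz = 2, baseline_s = 5,
                         window = c("full", "expansion", "peak")) {
  stopifnot(inherits(event, "stim_event"))
  if (baseline_s <= 0) stop("baseline_s must be > 0")
  window <- match.arg(window)
  w <- .response_window(event$onset_s, event$expand_s, event$fade_s,
                        rate_hz, window, length(z))
  i0 <- w[1]; i1 <- w[2]
  b0 <- floor((event$onset_s - baseline_s) * rate_hz) + 1L
  if (b0 < 1L) {
    warning("baseline window truncated at record start")
    b0 <- 1L
  }
  b1 <- floor(event$onset_s * rate_hz)
  base <- if (b1 >= b0) mean(z[b0:b1]) else 0
  max(z[i0:i1]) - base
}

# start/end sample indices of the response window for one event
.response_window <- function(onset_s, expand_s, fade_s, rate_hz, window,
                             n_samples) {
  if (window == "peak") {
    i0 <- floor((onset_s + expand_s - 1) * rate_hz) + 1L
    i1 <- ceiling((onset_s + expand_s + 1) * rate_hz)
  } else {
    win_len <- if (window == "full") expand_s + fade_s else expand_s
    i0 <- floor(onset_s * rate_hz) + 1L
    i1 <- ceiling((onset_s + win_len) * rate_hz)
  }
  c(max(1L, i0), min(n_samples, i1))
}

# ROIs x events matrix of baseline-subtracted maximum responses; the
# vectorized counterpart of max_response.
.max_response_matrix <- function(traces, train, rate_hz = 2, baseline_s = 5,
                                 window = "full") {
  ev <- train$events
  n_ev <- nrow(ev)
  out <- matrix(NA_real_, nrow(traces), n_ev)
  for (k in seq_len(n_ev)) {
    w <- .response_window(ev$onset_s[k], ev$expand_s[k], ev$fade_s[k],
                          rate_hz, window, ncol(traces))
    i0 <- w[1]; i1 <- w[2]
    b0 <- max(1L, floor((ev$onset_s[k] - baseline_s) * rate_hz) + 1L)
    b1 <- floor(ev$onset_s[k] * rate_hz)
    sub <- traces[, i0:i1, drop = FALSE]
    mx <- sub[, 1]
    for (j in seq_len(ncol(sub))[-1]) mx <- pmax(mx, sub[, j])
    base <- if (b1 >= b0)
      rowMeans(traces[, b0:b1, drop = FALSE]) else 0
    out[, k] <- mx - base
  }
  rownames(out) <- rownames(traces)
  out
}

#' Two-stage group means of maximum responses
#'
#' Averages per-stimulus maximum responses first across the ROIs of each
#' fish, then across fish (so every fish carries equal weight regardless of
#' its ROI count). Fish contributing no ROIs are omitted with a warning.
#'
#' @param M ROIs x stimuli matrix of maximum responses.
#' @param fish_ids Fish id per ROI (length nrow(M)).
#' @return List with \code{fish_means} (fish x stimuli) and
#'   \code{group_mean} (per-stimulus vector).
#' @export
group_mean_responses <- function(M, fish_ids) {
  if (nrow(M) == 0) stop("no responsive ROIs")
  stopifnot(length(fish_ids) == nrow(M))
  fish <- sort(unique(fish_ids))
  fm <- t(vapply(fish, function(f)
    colMeans(M[fish_ids == f, , drop = FALSE]), numeric(ncol(M))))
  rownames(fm) <- fish
  list(fish_means = fm, group_mean = colMeans(fm))
}

#' Responsiveness analysis of a cohort (first-block regression)
#'
#' Dataset-1-style pipeline: z-score all traces, regress every ROI on the
#' regressor built from the first \code{n_first} stimuli (fit restricted to
#' that span), select responsive ROIs with the median + 2 SD rule, compute
#' per-stimulus maximum responses for them, and average per fish then per
#' group.
#'
#' @param cohort A \code{"synthetic_cohort"} (or compatible list with
#'   \code{traces}, \code{rois}, \code{train}).
#' @param n_first Number of initial stimuli driving the selection
#'   regression (default 10).
#' @param rate_hz,kernel_tau_s,baseline_s Analysis parameters.
#' @return List with \code{selection} (\code{"responsiveness"}), \code{M}
#'   (responsive ROIs x stimuli max responses), \code{group}
#'   (\code{\link{group_mean_responses}} output), \code{z} (z-scored
#'   traces), \code{fit_range}.
#' @export
analyze_responsiveness <- function(cohort, n_first = 10, rate_hz = 2,
                                   kernel_tau_s = 3.5, baseline_s = 5) {
  train <- cohort$train
  z <- zscore_traces(cohort$traces)
  ev <- train$events[seq_len(min(n_first, nrow(train$events))), ]
  reg <- build_regressor(train, unique(ev$kind), kernel_tau_s, rate_hz)
  lo <- max(1L, floor((ev$onset_s[1] - baseline_s) * rate_hz) + 1L)
  hi <- min(length(reg$samples),
            ceiling((ev$onset_s[nrow(ev)] + ev$expand_s[nrow(ev)] +
                       ev$fade_s[nrow(ev)]) * rate_hz))
  fit_range <- lo:hi
  r2 <- .r2_rows(z, reg, fit_range)
  sel <- select_responsive(r2)
  keep <- which(sel$responsive)
  M <- .max_response_matrix(z[keep, , drop = FALSE], train, rate_hz,
                            baseline_s)
  grp <- if (length(keep))
    group_mean_responses(M, cohort$rois$fish_id[keep]) else NULL
  list(selection = sel, M = M, group = grp, z = z, fit_range = fit_range)
}
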
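#' Classify a tracking bin by speed
#'
#' Speed groups follow the standard tracking convention for larval zebrafish:
#' drift below 0.5 mm/s, scoots between 0.5 and 30 mm/s (closed interval),
#' escapes above 30 mm/s. With 1 s bins, distance moved (mm) equals speed
#' (mm/s).
#'
#' @param speed Numeric vector of non-negative speeds (mm/s).
#' @return Factor with levels drift, scoot, escape.
#' @examples
#' classify_movement(c(0.3, 12, 45, 30))
#' @export
classify_movement <- function(speed) {
  stopifnot(is.numeric(speed))
  if (any(speed < 0)) stop("speed must be >= 0")
  factor(ifelse(speed < 0.5, "drift",
                ifelse(speed <= 30, "scoot", "escape")),
         levels = c("drift", "scoot", "escape"))
}

#' Exclude fish that never escaped
#'
#' Fish with no escape-classified bin (> 30 mm/s) anywhere in their record
#' are dropped, mirroring the exclusion of untrackable or never-escaping
#' fish.
#'
#' @param records Behavior data.frame (fish_id, second, distance_mm).
#' @return The filtered data.frame. If no fish survive, a zero-row
#'   data.frame is returned with a warning.
#' @export
filter_fish <- function(records) {
  if (nrow(records) == 0) stop("empty behavior records")
  esc <- tapply(records$distance_mm > 30, records$fish_id, any)
  keep <- names(esc)[esc]
  out <- records[as.character(records$fish_id) %in% keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no fish retained after escape filtering")
  out
}

# fish x stimulus logical matrix: did the fish escape within the response
# window of each stimulus?
.escape_matrix <- function(records, train, window_s = 5) {
  if (window_s <= 0) stop("window_s must be > 0")
  fish <- sort(unique(records$fish_id))
  ev <- train$events
  n_ev <- nrow(ev)
  if (n_ev > 1) {
    gaps <- diff(ev$onset_s)
    if (any(window_s > gaps))
      warning("response window overlaps the next stimulus onset; truncating")
  }
  m <- matrix(FALSE, length(fish), n_ev,
              dimnames = list(fish, NULL))
  esc <- records[records$distance_mm > 30, , drop = FALSE]
  for (k in seq_len(n_ev)) {
    lo <- ev$onset_s[k]
    hi <- lo + window_s
    if (k < n_ev) hi <- min(hi, ev$onset_s[k + 1])
    in_win <- esc$second >= lo & esc$second < hi
    if (any(in_win))
      m[match(unique(esc$fish_id[in_win]), fish), k] <- TRUE
  }
  m
}

#' Per-stimulus escape probability
#'
#' For each stimulus, the proportion of fish with at least one escape bin
#' (> 30 mm/s) within \code{window_s} seconds of onset (default: the 5 s
#' expansion period). Windows that would overlap the next onset are
#' truncated with a warning.
#'
#' @param records Behavior data.frame (fish_id, second, distance_mm).
#' @param train The \code{"stimulus_train"} that was presented.
#' @param window_s Attribution window in seconds (> 0).
#' @return A data.frame of class \code{"escape_curve"} with columns
#'   \code{stimulus_index}, \code{kind}, \code{p}, \code{n}; the fish x
#'   stimulus escape matrix is attached as attribute \code{"escapes"}.
#' @export
escape_probability <- function(records, train, window_s = 5) {
  stopifnot(inherits(train, "stimulus_train"))
  m <- .escape_matrix(records, train, window_s)
  out <- data.frame(stimulus_index = seq_len(ncol(m)),
                    kind = train$events$kind,
                    p = colMeans(m), n = nrow(m))
  attr(out, "escapes") <- m
  class(out) <- c("escape_curve", "data.frame")
  out
}

#' Rank-based habituation test (ANOVA-type statistic)
#'
#' One-group longitudinal design over repeated time points (typically the
#' first and last stimuli of the initial block and the first loom of the
#' probe block): Brunner-Langer ANOVA-type statistic (ATS) on mid-ranks.
#' All observations are ranked jointly, the time contrast is tested with
#' the ATS, and the statistic is referred to an F distribution with
#' box-type adjusted numerator degrees of freedom f and denominator
#' degrees of freedom f * (n - 1), a finite-sample reference that holds
#' the nominal 5% level to within half a point in simulation for binary
#' and continuous responses alike at n >= 10 (the infinite-denominator
#' reference is liberal by 1-2 points at these sizes).
#'
#' @param x Either an n x T matrix (fish x time points), or the first of
#'   three per-fish vectors.
#' @param last,probe When \code{x} is a vector: per-fish responses at the
#'   last stimulus of the block and at the probe stimulus; the same fish in
#'   the same order.
#' @return A list of class \code{"htest"} with \code{statistic} (ATS),
#'   \code{parameter} (adjusted df), \code{p.value}.
#' @examples
#' set.seed(1)
#' test_habituation(rbinom(20, 1, 0.9), rbinom(20, 1, 0.3), rbinom(20, 1, 0.3))
#' @export
test_habituation <- function(x, last = NULL, probe = NULL) {
  if (!is.matrix(x)) {
    stopifnot(length(x) == length(last), length(x) == length(probe))
    x <- cbind(x, last, probe)
  }
  if (nrow(x) < 2) stop("need at least 2 fish")
  n <- nrow(x); tt <- ncol(x)
  R <- matrix(rank(x), n, tt)  # joint mid-ranks
  Rbar <- colMeans(R)
  P <- diag(tt) - 1 / tt
  S <- stats::cov(R)
  TS <- P %*% S
  den <- sum(diag(TS))
  num <- n * drop(crossprod(Rbar, P %*% Rbar))
  scale_r <- sum(Rbar^2) + 1
  if (den < 1e-10 * scale_r) {
    # degenerate rank covariance: constant data (no effect, p = 1 by
    # convention) vs perfectly consistent time effect (p -> 0)
    if (num < 1e-8 * n * scale_r) {
      stat <- 0; df <- NA_real_; p <- 1
    } else {
      stat <- Inf; df <- NA_real_; p <- 0
    }
  } else {
    stat <- num / den
    df <- den^2 / sum(TS * t(TS))
    p <- stats::pf(stat, df, df * (n - 1), lower.tail = FALSE)
  }
  structure(list(statistic = c(ATS = stat),
                 parameter = c(df1 = df, df2 = df * (n - 1)),
                 p.value = p,
                 method = "ANOVA-type statistic (rank-based longitudinal test)",
                 data.name = sprintf("%d fish x %d time points", n, tt),
                 rel_effects = (Rbar - 0.5) / (n * tt)),
            class = "htest")
}

#' Mann-Whitney U test with Bonferroni correction
#'
#' Two-sided Mann-Whitney U test: exact enumeration of all rank assignments
#' when the combined sample size is at most 20 (correct under ties),
#' otherwise a tie-corrected normal approximation with continuity
#' correction. The Bonferroni-corrected p multiplies the raw p by the number
#' of comparisons in the family (capped at 1).
#'
#' @param x,y Non-empty numeric samples.
#' @param n_comparisons Size of the comparison family (default 1).
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return A list of class \code{"htest"} with \code{statistic} (U for the
#'   first sample), \code{p.value} (raw), and \code{p.bonferroni}.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value  # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, n_comparisons = 1, exact_max = 20) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    # enumerate all assignments of n1 of the pooled ranks to sample x
    combs <- utils::combn(n, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), p.value = p,
                 p.bonferroni = min(1, p * n_comparisons),
                 method = method,
                 data.name = paste(deparse(substitute(x)), "vs",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Fit the behavioral habituation curve
#'
#' Least-squares fit of a one-phase exponential decay with plateau fixed at
#' zero, \eqn{p_k = Y_0 e^{-K k}}, to escape probabilities at stimulus
#' indices 1-20 (multi-start over K), and an ordinary linear regression to
#' indices 21-30 (the probe block), when present.
#'
#' @param curve An \code{\link{escape_probability}} result, or a numeric
#'   vector of per-stimulus probabilities.
#' @param decay_range Stimulus indices for the exponential fit.
#' @param linear_range Stimulus indices for the linear fit.
#' @param starts Multi-start values for K.
#' @return A list of class \code{"escape_decay_fit"} with \code{Y0},
#'   \code{K}, \code{identifiable}, \code{slope}, \code{intercept}, and the
#'   fitted ranges.
#' @export
fit_escape_decay <- function(curve, decay_range = 1:20,
                             linear_range = 21:30,
                             starts = c(0.01, 0.1, 0.5, 1)) {
  p <- if (is.data.frame(curve)) curve$p else as.numeric(curve)
  decay_range <- decay_range[decay_range <= length(p)]
  if (length(decay_range) < 4) stop("need at least 4 points in the decay range")
  k <- decay_range
  y <- p[decay_range]
  if (all(y == 0)) {
    fit <- list(Y0 = 0, K = NA_real_, identifiable = FALSE)
  } else {
    # profile SSE: for fixed K the optimal Y0 is closed-form
    sse_k <- function(K) {
      e <- exp(-K * k)
      y0 <- sum(y * e) / sum(e * e)
      sum((y - y0 * e)^2)
    }
    best <- NULL
    for (K0 in starts) {
      o <- stats::optim(K0, sse_k, method = "L-BFGS-B",
                        lower = 0, upper = 50)
      if (is.null(best) || o$value < best$value) best <- o
    }
    ref <- stats::optimize(sse_k, c(max(0, best$par - 0.05),
                                    best$par + 0.05), tol = 1e-10)
    K <- if (ref$objective < best$value) ref$minimum else best$par
    e <- exp(-K * k)
    fit <- list(Y0 = sum(y * e) / sum(e * e), K = K,
                identifiable = TRUE)
  }
  lin <- NULL
  linear_range <- linear_range[linear_range <= length(p)]
  if (length(linear_range) >= 4) {
    lm_fit <- stats::lm(p[linear_range] ~ linear_range)
    lin <- list(intercept = unname(stats::coef(lm_fit)[1]),
                slope = unname(stats::coef(lm_fit)[2]))
  }
  structure(c(fit, list(slope = lin$slope, intercept = lin$intercept,
                        decay_range = decay_range,
                        linear_range = linear_range, p = p)),
            class = "escape_decay_fit")
}

#' @export
print.escape_decay_fit <- function(x, ...) {
  cat("One-phase escape-probability decay (plateau 0):\n")
  if (x$identifiable)
    cat(sprintf("  Y0 = %.4f, K = %.4f per stimulus\n", x$Y0, x$K))
  else
    cat("  Y0 = 0; K not identifiable (all-zero curve)\n")
  if (!is.null(x$slope))
    cat(sprintf("  probe block linear fit: intercept %.4f, slope %.5f\n",
                x$intercept, x$slope))
  invisible(x)
}

#' @export
coef.escape_decay_fit <- function(object, ...) {
  c(Y0 = object$Y0, K = object$K,
    intercept = if (is.null(object$intercept)) NA_real_ else object$intercept,
    slope = if (is.null(object$slope)) NA_real_ else object$slope)
}

#' @export
plot.escape_decay_fit <- function(x, ...) {
  idx <- seq_along(x$p)
  graphics::plot(idx, x$p, xlab = "stimulus", ylab = "escape probability",
                 ylim = c(0, 1), pch = 19, ...)
  if (x$identifiable) {
    kk <- seq(min(x$decay_range), max(x$decay_range), length.out = 100)
    graphics::lines(kk, x$Y0 * exp(-x$K * kk), col = 2)
  }
  if (!is.null(x$slope))
    graphics::abline(a = x$intercept, b = x$slope, col = 4, lty = 2)
  invisible(x)
}

#' Behavioral habituation analysis of one stimulus train
#'
#' Convenience wrapper: filters never-escaping fish, computes the escape
#' curve, runs the ATS habituation test on (first stimulus of the block,
#' last stimulus of the block, first probe stimulus), and fits the
#' habituation curves.
#'
#' @param records Behavior data.frame.
#' @param train The presented \code{"stimulus_train"}.
#' @param window_s Escape-attribution window (s).
#' @param block_len Length of the initial stimulus block (default 20).
#' @return List with \code{curve}, \code{habituation} (htest), \code{fit}.
#' @export
analyze_behavior <- function(records, train, window_s = 5, block_len = 20) {
  records <- filter_fish(records)
  curve <- escape_probability(records, train, window_s)
  esc <- attr(curve, "escapes")
  probe <- min(block_len + 1L, ncol(esc))
  hab <- test_habituation(esc[, 1L], esc[, block_len], esc[, probe])
  list(curve = curve, habituation = hab, fit = fit_escape_decay(curve))
}
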
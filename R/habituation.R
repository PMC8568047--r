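#' Classify component sensitivity from response evidence
#'
#' Single-threshold rule on the dim and checkerboard response evidence (mean
#' response amplitude in z units): dim-sensitive iff the dim evidence
#' exceeds \code{theta}, checkerboard-sensitive iff the checkerboard
#' evidence exceeds \code{theta}, \code{both} iff both, otherwise
#' \code{none}.
#'
#' @param evidence_dim,evidence_checker Numeric vectors of response
#'   evidence (z units), same length.
#' @param theta Threshold in z units (default 1).
#' @return Character vector of labels dim / checker / both / none.
#' @examples
#' classify_components(c(2.5, 2.5, 0.2), c(0.2, 2.5, 0.4))
#' @export
classify_components <- function(evidence_dim, evidence_checker, theta = 1) {
  stopifnot(length(evidence_dim) == length(evidence_checker))
  if (any(!is.finite(evidence_dim)) || any(!is.finite(evidence_checker)))
    stop("missing stimulus responses")
  d <- evidence_dim > theta
  k <- evidence_checker > theta
  ifelse(d & k, "both", ifelse(d, "dim", ifelse(k, "checker", "none")))
}

#' Component response evidence for sensitivity classification
#'
#' Estimates each ROI's naive response amplitude (z units) to the dim and
#' checkerboard components. The default \code{"beta"} method regresses the
#' trace on one peak-normalized calcium-kernel regressor per component
#' presentation (so each coefficient estimates that presentation's peak
#' response) and averages the coefficients of the first-block presentations
#' of each kind: using only the pre-loom presentations keeps the evidence a
#' measure of inherent sensitivity rather than of habituation state, and
#' the regression estimator carries no extreme-value noise bias, so a fixed
#' threshold in z units stays meaningful. The \code{"eta"} method instead
#' averages the trace over all matching presentations (event-triggered
#' average) and takes the baseline-subtracted maximum over the expansion
#' period.
#'
#' @param z ROIs x samples z-scored trace matrix.
#' @param train The \code{"stimulus_train"}.
#' @param rate_hz Sampling rate.
#' @param baseline_s Baseline seconds before onset.
#' @param method \code{"beta"} (per-event regression amplitudes, default)
#'   or \code{"eta"} (trial-averaged maximum response).
#' @param kernel_tau_s Calcium kernel decay constant for the regression
#'   design.
#' @return Matrix (ROIs x 2) with columns \code{dim}, \code{checker}.
#' @export
component_evidence <- function(z, train, rate_hz = 2, baseline_s = 5,
                               method = c("beta", "eta"),
                               kernel_tau_s = 3.5) {
  method <- match.arg(method)
  ev <- train$events
  out <- matrix(NA_real_, nrow(z), 2, dimnames = list(rownames(z),
                                                      c("dim", "checker")))
  if (method == "beta") {
    comp_idx <- which(ev$kind != "loom")
    lobes <- .event_lobes(train, rate_hz, kernel_tau_s,
                          normalize = "peak")[, comp_idx, drop = FALSE]
    fit_range <- sort(unique(unlist(lapply(comp_idx, function(i) {
      lo <- max(1L, floor((ev$onset_s[i] - baseline_s) * rate_hz) + 1L)
      hi <- min(ncol(z), ceiling((ev$onset_s[i] + ev$expand_s[i] +
                                    ev$fade_s[i]) * rate_hz))
      lo:hi
    }))))
    X <- lobes[fit_range, , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    Z <- z[, fit_range, drop = FALSE]
    B <- (Z - rowMeans(Z)) %*% Xc %*% solve(crossprod(Xc))
    kinds <- ev$kind[comp_idx]
    half <- seq_len(length(comp_idx) / 2)  # first flanking block
    for (j in 1:2) {
      g <- c("dim", "checkerboard")[j]
      cols <- intersect(which(kinds == g), half)
      if (length(cols))
        out[, j] <- rowMeans(B[, cols, drop = FALSE])
    }
    return(out)
  }
  nb <- round(baseline_s * rate_hz)
  for (j in 1:2) {
    g <- c("dim", "checkerboard")[j]
    idx <- which(ev$kind == g)
    if (!length(idx)) next
    nw <- round(ev$expand_s[idx[1]] * rate_hz)
    acc <- 0
    for (i in idx) {
      i0 <- floor(ev$onset_s[i] * rate_hz) + 1L
      acc <- acc + z[, (i0 - nb):(i0 + nw - 1L), drop = FALSE]
    }
    eta <- acc / length(idx)
    base <- rowMeans(eta[, seq_len(nb), drop = FALSE])
    win <- eta[, (nb + 1L):(nb + nw), drop = FALSE]
    mx <- win[, 1]
    for (cc in seq_len(ncol(win))[-1]) mx <- pmax(mx, win[, cc])
    out[, j] <- mx - base
  }
  out
}

# --- robust exponential decay fitting ---------------------------------------

# L1 (least-absolute-residual) linear solve of y ~ 1 + e by IRLS with
# weights 1/max(|r|, delta); `e` is exp(-c*x) for the current c.
.lar_linear <- function(y, e, delta = 1e-6, max_iter = 200, tol = 1e-9) {
  a <- b <- 0
  w <- rep(1, length(y))
  for (it in seq_len(max_iter)) {
    s1 <- sum(w); se <- sum(w * e); see <- sum(w * e * e)
    sy <- sum(w * y); sye <- sum(w * e * y)
    det <- s1 * see - se * se
    if (abs(det) < 1e-300) break
    a_new <- (see * sy - se * sye) / det
    b_new <- (s1 * sye - se * sy) / det
    conv <- max(abs(a_new - a), abs(b_new - b)) < tol
    a <- a_new; b <- b_new
    r <- y - a - b * e
    w <- 1 / pmax(abs(r), delta)
    if (conv) break
  }
  r <- y - a - b * e
  list(a = a, b = b, obj = sum(abs(r)), resid = r)
}

.ls_linear <- function(y, e) {
  s1 <- length(y); se <- sum(e); see <- sum(e * e)
  sy <- sum(y); sye <- sum(e * y)
  det <- s1 * see - se * se
  if (abs(det) < 1e-300) {
    a <- mean(y); b <- 0
  } else {
    a <- (see * sy - se * sye) / det
    b <- (s1 * sye - se * sy) / det
  }
  r <- y - a - b * e
  list(a = a, b = b, obj = sum(r * r), resid = r)
}

.decay_obj <- function(cc, y, x, method, delta) {
  e <- exp(-cc * x)
  if (method == "lar") .lar_linear(y, e, delta)$obj
  else .ls_linear(y, e)$obj
}

.decay_grid <- function(starts, c_bounds) {
  g <- sort(unique(c(c_bounds[1], starts,
                     exp(seq(log(0.01), log(max(c_bounds[2], 0.02)),
                             length.out = 40)))))
  g[g >= c_bounds[1] & g <= c_bounds[2]]
}

#' Fit an exponential habituation decay to per-presentation responses
#'
#' Fits \eqn{f(x) = a + b e^{-c x}} to the maximum responses at loom indices
#' x = 1..n by robust least-absolute-residual (LAR) regression: for each
#' candidate decay constant the linear parameters (a, b) solve the L1
#' problem by iteratively reweighted least squares with weights
#' \eqn{1/\max(|r|, 10^{-6})}, and c is found by a multi-start grid over
#' [0, 10] followed by local refinement. \code{method = "ls"} gives the
#' plain least-squares fit for comparison. Goodness of fit is summarized by
#' the raw SSE against the fitted curve and the adjusted r-squared with
#' p = 3 parameters; the fit is accepted iff adjusted r-squared > 0.5 and
#' SSE < 20.
#'
#' @param y Numeric vector of maximum responses (z units), one per loom.
#' @param x Presentation indices (default \code{1:length(y)}).
#' @param method \code{"lar"} (robust, default) or \code{"ls"}.
#' @param c_bounds Bounds for c (default c(0, 10)).
#' @param starts Multi-start values for c, augmented by an internal grid.
#' @param delta IRLS residual floor.
#' @return An object of class \code{"decay_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{fitted}, \code{residuals}, \code{plot}. Fields: coefficients
#'   (a, b, c), \code{adj_r2}, \code{sse}, \code{accepted}, \code{method}.
#' @examples
#' x <- 1:10
#' f <- fit_decay(0.5 + 2 * exp(-0.7 * x))
#' coef(f)
#' @export
fit_decay <- function(y, x = seq_along(y), method = c("lar", "ls"),
                      c_bounds = c(0, 10), starts = c(0.05, 0.3, 0.7, 1.5),
                      delta = 1e-6) {
  method <- match.arg(method)
  if (any(!is.finite(y))) stop("responses must be finite")
  n <- length(y)
  grid <- .decay_grid(starts, c_bounds)
  objs <- vapply(grid, .decay_obj, numeric(1), y = y, x = x,
                 method = method, delta = delta)
  i <- which.min(objs)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  cc <- if (hi > lo) {
    stats::optimize(.decay_obj, c(lo, hi), y = y, x = x, method = method,
                    delta = delta, tol = 1e-8)$minimum
  } else grid[i]
  if (.decay_obj(grid[i], y, x, method, delta) <
      .decay_obj(cc, y, x, method, delta)) cc <- grid[i]
  e <- exp(-cc * x)
  sol <- if (method == "lar") .lar_linear(y, e, delta) else .ls_linear(y, e)
  fitted <- sol$a + sol$b * e
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  p <- 3
  adj_r2 <- if (sst > 0) 1 - (sse / (n - p)) / (sst / (n - 1)) else NA_real_
  structure(list(coefficients = c(a = sol$a, b = sol$b, c = cc),
                 x = x, y = y, fitted.values = fitted,
                 residuals = y - fitted,
                 adj_r2 = adj_r2, sse = sse,
                 accepted = isTRUE(adj_r2 > 0.5 && sse < 20),
                 objective = sol$obj, method = method),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Exponential decay fit (%s): f(x) = %.4f + %.4f * exp(-%.4f x)\n",
              if (x$method == "lar") "robust LAR" else "least squares",
              co["a"], co["b"], co["c"]))
  cat(sprintf("  adj r2 = %s, SSE = %.4f, %s\n",
              if (is.na(x$adj_r2)) "NA" else sprintf("%.4f", x$adj_r2),
              x$sse, if (x$accepted) "accepted" else "not accepted"))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat("  residuals:\n")
  print(summary(object$residuals))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  co <- object$coefficients
  co["a"] + co["b"] * exp(-co["c"] * x)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "presentation", ylab = "max response (z)",
                 pch = 19, ...)
  xx <- seq(min(x$x), max(x$x), length.out = 100)
  graphics::lines(xx, predict(x, xx), col = 2)
  invisible(x)
}

#' Fit habituation decays for a matrix of ROIs
#'
#' Vectorized version of \code{\link{fit_decay}} for many ROIs at once: the
#' c grid search runs all ROIs simultaneously (the IRLS linear solves are
#' closed-form and vectorized across ROIs), followed by per-ROI local
#' refinement of c.
#'
#' @param M ROIs x presentations matrix of maximum responses.
#' @param x Presentation indices.
#' @param method \code{"lar"} or \code{"ls"}.
#' @inheritParams fit_decay
#' @param refine Per-ROI local refinement of c (default TRUE).
#' @return A data.frame (one row per ROI): a, b, c, adj_r2, sse, accepted.
#' @export
fit_decay_all <- function(M, x = seq_len(ncol(M)), method = c("lar", "ls"),
                          c_bounds = c(0, 10),
                          starts = c(0.05, 0.3, 0.7, 1.5),
                          delta = 1e-6, refine = TRUE) {
  method <- match.arg(method)
  n_roi <- nrow(M); n <- ncol(M)
  Y <- t(M)  # presentations x ROIs
  grid <- .decay_grid(starts, c_bounds)
  best_obj <- rep(Inf, n_roi)
  best_i <- rep(1L, n_roi)
  for (gi in seq_along(grid)) {
    e <- exp(-grid[gi] * x)
    obj <- .batch_linear_obj(Y, e, method, delta)
    obj[!is.finite(obj)] <- Inf
    better <- obj < best_obj
    best_obj[better] <- obj[better]
    best_i[better] <- gi
  }
  cc <- grid[best_i]
  if (refine) {
    for (r in seq_len(n_roi)) {
      i <- best_i[r]
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      if (hi > lo) {
        o <- stats::optimize(.decay_obj, c(lo, hi), y = Y[, r], x = x,
                             method = method, delta = delta, tol = 1e-7)
        if (o$objective < best_obj[r]) cc[r] <- o$minimum
      }
    }
  }
  out <- data.frame(a = numeric(n_roi), b = numeric(n_roi), c = cc,
                    adj_r2 = NA_real_, sse = NA_real_, accepted = FALSE)
  for (r in seq_len(n_roi)) {
    e <- exp(-cc[r] * x)
    sol <- if (method == "lar") .lar_linear(Y[, r], e, delta)
           else .ls_linear(Y[, r], e)
    fitted <- sol$a + sol$b * e
    sse <- sum((Y[, r] - fitted)^2)
    sst <- sum((Y[, r] - mean(Y[, r]))^2)
    adj <- if (sst > 0) 1 - (sse / (n - 3)) / (sst / (n - 1)) else NA_real_
    out$a[r] <- sol$a; out$b[r] <- sol$b
    out$sse[r] <- sse; out$adj_r2[r] <- adj
    out$accepted[r] <- isTRUE(adj > 0.5 && sse < 20)
  }
  rownames(out) <- rownames(M)
  out
}

# objective of the (a, b) linear solve for a fixed c, vectorized across the
# columns (ROIs) of Y
.batch_linear_obj <- function(Y, e, method, delta, max_iter = 30,
                              tol = 1e-8) {
  n <- nrow(Y); m <- ncol(Y)
  if (method == "ls") {
    s1 <- n; se <- sum(e); see <- sum(e * e)
    sy <- colSums(Y); sye <- drop(crossprod(Y, e))
    det <- s1 * see - se * se
    if (abs(det) < 1e-12) {   # constant design: intercept-only fit
      a <- sy / n; b <- rep(0, m)
    } else {
      a <- (see * sy - se * sye) / det
      b <- (s1 * sye - se * sy) / det
    }
    R <- Y - rep(a, each = n) - outer(e, b)
    return(colSums(R * R))
  }
  W <- matrix(1, n, m)
  a <- b <- rep(0, m)
  for (it in seq_len(max_iter)) {
    s1 <- colSums(W); se <- colSums(W * e); see <- colSums(W * e * e)
    sy <- colSums(W * Y); sye <- colSums(W * e * Y)
    det <- s1 * see - se * se
    det[abs(det) < 1e-300] <- NA
    a_new <- (see * sy - se * sye) / det
    b_new <- (s1 * sye - se * sy) / det
    a_new[is.na(a_new)] <- a[is.na(a_new)]
    b_new[is.na(b_new)] <- b[is.na(b_new)]
    done <- max(abs(a_new - a), abs(b_new - b)) < tol
    a <- a_new; b <- b_new
    R <- Y - rep(a, each = n) - outer(e, b)
    W <- 1 / pmax(abs(R), delta)
    if (done) break
  }
  colSums(abs(R))
}

# --- Friedman test ----------------------------------------------------------

.perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Friedman rank test across complete blocks
#'
#' Within-block mid-ranks with tie correction. For at most \code{exact_max}
#' blocks the p-value is exact, by enumeration of all within-block rank
#' permutations (dynamic programming over the distribution of column rank
#' sums); otherwise the chi-squared approximation with k - 1 degrees of
#' freedom is used.
#'
#' @param mat Blocks x treatments matrix (e.g. fish x sensitivity class
#'   median decay constants); must be complete (no NA).
#' @param exact_max Largest block count for exact enumeration (default 8).
#' @return A list of class \code{"htest"} with \code{statistic}
#'   (tie-corrected Friedman chi-squared), \code{parameter} (df),
#'   \code{p.value}, and \code{exact} flag.
#' @examples
#' friedman_rank_test(matrix(rep(c(1, 2, 3), 4), 4, byrow = TRUE))
#' @export
friedman_rank_test <- function(mat, exact_max = 8) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("blocks must be complete (no NA)")
  b <- nrow(mat); k <- ncol(mat)
  if (b < 2) stop("need at least 2 blocks")
  R <- t(apply(mat, 1, rank))
  stat_from_sums <- function(Rj, A) {
    C <- b * k * (k + 1)^2 / 4
    den <- A - C
    if (den <= 1e-12) return(0)
    (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / den
  }
  A <- sum(R^2)  # invariant under within-block permutation
  stat <- stat_from_sums(colSums(R), A)
  if (b <= exact_max) {
    P <- .perms(k)
    n_perm <- nrow(P)
    # DP over blocks: distribution of the column rank-sum vector
    states <- matrix(0, 1, k)
    counts <- 1
    for (i in seq_len(b)) {
      r <- R[i, ]
      add <- matrix(r[P], n_perm, k)
      new_states <- states[rep(seq_len(nrow(states)), each = n_perm), ,
                           drop = FALSE] +
        add[rep(seq_len(n_perm), nrow(states)), , drop = FALSE]
      new_counts <- rep(counts, each = n_perm)
      key <- apply(new_states, 1, paste, collapse = ",")
      agg <- rowsum(new_counts, key)
      states <- do.call(rbind, lapply(strsplit(rownames(agg), ","),
                                      as.numeric))
      counts <- agg[, 1]
    }
    stats_all <- apply(states, 1, stat_from_sums, A = A)
    p <- sum(counts[stats_all >= stat - 1e-9]) / sum(counts)
    exact <- TRUE
  } else {
    p <- if (stat == 0) 1 else
      stats::pchisq(stat, k - 1, lower.tail = FALSE)
    exact <- FALSE
  }
  structure(list(statistic = c("Friedman chi-squared" = stat),
                 parameter = c(df = k - 1), p.value = p, exact = exact,
                 method = paste0("Friedman rank test (",
                                 if (exact) "exact permutation"
                                 else "chi-squared approximation", ")"),
                 data.name = deparse(substitute(mat))),
            class = "htest")
}

#' Component-sensitivity habituation analysis (flanked-loom protocol)
#'
#' Dataset-3-style pipeline on an \code{imaging3_component} cohort:
#' \enumerate{
#'   \item z-score traces and select responsive ROIs by regression against
#'     the component regressor over the first and last four (component)
#'     stimuli, median + 2 SD threshold;
#'   \item classify responsive ROIs as dim / checker / both / none from
#'     their component response evidence at threshold \code{theta};
#'   \item fit the robust exponential decay to each classified ROI's
#'     maximum responses over the 10-loom block and keep accepted fits
#'     (adjusted r-squared > 0.5, SSE < 20);
#'   \item compare per-fish medians of c across the three classes with the
#'     Friedman test (fish lacking any class are dropped with a warning).
#' }
#'
#' @param cohort A \code{"synthetic_cohort"} (or compatible list) following
#'   the \code{imaging3_component} protocol.
#' @param theta Component classification threshold (z units).
#' @param rate_hz,kernel_tau_s,baseline_s Analysis parameters.
#' @param response_baseline_s Baseline length (s) for the per-loom maximum
#'   responses (default 15; the 20 s loom ISI leaves a long stimulus-free
#'   pre-onset stretch, and a longer baseline reduces the noise of the
#'   baseline estimate entering every maximum response).
#' @param response_window Window for the per-loom maximum responses fed to
#'   the decay fit: \code{"expansion"} (default; the kernel-convolved
#'   response peaks at the end of the expansion, and the shorter window
#'   halves the extreme-value bias of the max statistic) or \code{"full"}.
#' @return A list of class \code{"experiment3"}: \code{selection},
#'   \code{classes} (data.frame roi_id, label, evidence), \code{fits}
#'   (per-ROI decay parameters with accepted flags), \code{medians}
#'   (fish x class matrix of median c), \code{friedman} (htest),
#'   \code{dropped_fish}.
#' @export
run_experiment3 <- function(cohort, theta = 1, rate_hz = 2,
                            kernel_tau_s = 3.5, baseline_s = 5,
                            response_window = "peak",
                            response_baseline_s = 15) {
  train <- cohort$train
  ev <- train$events
  comp_idx <- which(ev$kind != "loom")
  loom_idx <- which(ev$kind == "loom")
  if (length(comp_idx) < 8 || length(loom_idx) < 2)
    stop("cohort does not follow the flanked-loom component protocol")
  z <- zscore_traces(cohort$traces)
  ok <- stats::complete.cases(z)
  z <- z[ok, , drop = FALSE]
  rois <- cohort$rois[ok, , drop = FALSE]
  sel_idx <- c(utils::head(comp_idx, 4), utils::tail(comp_idx, 4))
  # one regressor per flanking component presentation: responses habituate,
  # so an event-wise design captures any decay profile and keeps
  # single-component and fast-habituating ROIs on the same footing as ROIs
  # responding strongly to every presentation
  lobes <- .event_lobes(train, rate_hz, kernel_tau_s)
  n_s <- nrow(lobes)
  fit_range <- sort(unique(unlist(lapply(sel_idx, function(i) {
    lo <- max(1L, floor((ev$onset_s[i] - baseline_s) * rate_hz) + 1L)
    hi <- min(n_s, ceiling((ev$onset_s[i] + ev$expand_s[i] +
                              ev$fade_s[i]) * rate_hz))
    lo:hi
  }))))
  r2 <- .r2_rows_multi(z, lobes[, sel_idx, drop = FALSE], fit_range)
  sel <- select_responsive(r2)
  keep <- which(sel$responsive)
  if (!length(keep)) stop("responsiveness stage: zero ROIs selected")
  evd <- component_evidence(z[keep, , drop = FALSE], train, rate_hz,
                            baseline_s)
  label <- classify_components(evd[, "dim"], evd[, "checker"], theta)
  classes <- data.frame(roi_id = rois$roi_id[keep], label = label,
                        evidence_dim = evd[, "dim"],
                        evidence_checker = evd[, "checker"],
                        fish_id = rois$fish_id[keep],
                        stringsAsFactors = FALSE)
  cls_keep <- which(label != "none")
  if (!length(cls_keep)) stop("classification stage: zero ROIs classified")
  M <- .max_response_matrix(z[keep[cls_keep], , drop = FALSE], train,
                            rate_hz, response_baseline_s,
                            response_window)[, loom_idx, drop = FALSE]
  fits <- fit_decay_all(M)
  fits <- cbind(classes[cls_keep, c("roi_id", "label", "fish_id")], fits)
  acc <- fits[fits$accepted, , drop = FALSE]
  if (!nrow(acc)) stop("decay-fit stage: zero accepted fits")
  fish <- sort(unique(acc$fish_id))
  cls <- c("dim", "checker", "both")
  med <- matrix(NA_real_, length(fish), 3, dimnames = list(fish, cls))
  for (f in seq_along(fish)) for (j in seq_along(cls)) {
    v <- acc$c[acc$fish_id == fish[f] & acc$label == cls[j]]
    if (length(v)) med[f, j] <- stats::median(v)
  }
  complete <- stats::complete.cases(med)
  dropped <- rownames(med)[!complete]
  if (length(dropped))
    warning("fish dropped from the Friedman design (incomplete classes): ",
            paste(dropped, collapse = ", "))
  med_c <- med[complete, , drop = FALSE]
  if (nrow(med_c) < 2) stop("Friedman stage: fewer than 2 complete fish")
  fr <- friedman_rank_test(med_c)
  structure(list(selection = sel, classes = classes, fits = fits,
                 medians = med_c, friedman = fr, dropped_fish = dropped),
            class = "experiment3")
}

#' @export
print.experiment3 <- function(x, ...) {
  cat("Component-sensitivity habituation analysis\n")
  print(x$selection)
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$classes$label)),
                                  as.integer(table(x$classes$label))),
                          collapse = ", "), "\n")
  cat(sprintf("  accepted decay fits: %d / %d\n",
              sum(x$fits$accepted), nrow(x$fits)))
  cat(sprintf("  Friedman chi-squared = %.3f, p = %.4f (%d fish)\n",
              x$friedman$statistic, x$friedman$p.value, nrow(x$medians)))
  invisible(x)
}
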
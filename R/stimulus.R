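#' Construct a single visual stimulus event
#'
#' A stimulus event is one presentation of a loom, checkerboard loom, or
#' whole-field dim. Events expand hyperbolically from onset to their maximum
#' state over \code{expand_s} seconds and then fade linearly back to the
#' background over \code{fade_s} seconds.
#'
#' @param kind One of \code{"loom"}, \code{"checkerboard"}, \code{"dim"}.
#' @param onset_s Onset time in seconds from the start of the experiment
#'   (non-negative).
#' @param expand_s Seconds from onset to maximum state (default 5).
#' @param fade_s Seconds of linear return to background (default 15).
#' @return A list of class \code{"stim_event"}.
#' @examples
#' ev <- stim_event("loom", onset_s = 30)
#' stimulus_profile(ev, c(30, 35, 42.5))
#' @export
stim_event <- function(kind = c("loom", "checkerboard", "dim"),
                       onset_s, expand_s = 5, fade_s = 15) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(onset_s), length(onset_s) == 1L)
  if (onset_s < 0) stop("onset_s must be >= 0")
  if (expand_s <= 0) stop("expand_s must be > 0")
  if (fade_s < 0) stop("fade_s must be >= 0")
  structure(list(kind = kind, onset_s = onset_s,
                 expand_s = expand_s, fade_s = fade_s),
            class = "stim_event")
}

# Geometry of the hyperbolic-approach profile.  The visual angle of an object
# of half-size r approaching at speed v is theta(t) = 2*atan(r / (v*(t_c - t)))
# with t_c the (virtual) collision time.  We anchor the curve so that theta
# rises from 1% to 99% of theta_max = pi across the expansion period and then
# normalize to [0, 1]; this pins both free constants (r/v and the virtual
# collision offset) and makes the profile exactly 0 at onset and exactly 1 at
# onset + expand_s.
.loom_geometry <- function(expand_s) {
  c1 <- tan(0.495 * pi)   # theta/2 at end of expansion: 0.99 * pi / 2
  c0 <- tan(0.005 * pi)   # theta/2 at onset: 0.01 * pi / 2
  delta <- expand_s * c0 / (c1 - c0)  # virtual collision offset past expansion
  list(rho = c1 * delta, delta = delta,
       theta0 = 0.01 * pi, theta1 = 0.99 * pi)
}

#' Time-intensity profile of a stimulus event
#'
#' Returns the normalized stimulus magnitude in [0, 1]: zero before onset, a
#' hyperbolic looming-angle rise (theta(t) = 2 atan(r / (v (t_c - t)))) from 0
#' at onset to 1 at \code{onset_s + expand_s}, then a linear fade back to 0
#' over \code{fade_s}, and zero afterwards.
#'
#' @param event A \code{\link{stim_event}}.
#' @param t Numeric vector of times in seconds (non-negative).
#' @return Numeric vector of the same length as \code{t}, values in [0, 1].
#' @export
stimulus_profile <- function(event, t) {
  stopifnot(inherits(event, "stim_event"), is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  E <- event$expand_s
  geo <- .loom_geometry(E)
  s <- t - event$onset_s
  out <- numeric(length(t))
  rising <- s >= 0 & s <= E
  if (any(rising)) {
    theta <- 2 * atan(geo$rho / (E + geo$delta - s[rising]))
    out[rising] <- (theta - geo$theta0) / (geo$theta1 - geo$theta0)
  }
  if (event$fade_s > 0) {
    fading <- s > E & s < E + event$fade_s
    out[fading] <- 1 - (s[fading] - E) / event$fade_s
  }
  pmin(pmax(out, 0), 1)
}

.protocols <- c("behavior_loom", "behavior_checker", "behavior_dim",
                "imaging1_loom", "imaging1_checker", "imaging1_dim",
                "imaging2_sequence", "imaging3_component")

#' Build a stimulus train for a named protocol
#'
#' Protocols mirror the experimental designs: behavioral trains present 20
#' stimuli of one kind followed by 10 looms (a pure-loom train presents 30
#' looms) with inter-stimulus intervals drawn uniformly from
#' \code{isi_choices} (20, 25, 30, 35 s); imaging protocol 1 presents 10
#' stimuli of one kind then 5 looms at a fixed 20 s ISI; imaging protocol 2 is
#' dim, checkerboard, loom spaced 1 min apart, repeated after a 5 min break;
#' imaging protocol 3 is a dim/checkerboard/dim/checkerboard block, 10 looms,
#' and a repeat of the initial block, at 20 s ISI. Behavioral trains start
#' after a 5 min stimulus-free baseline, imaging trains after 30 s.
#'
#' @param protocol One of \code{behavior_loom}, \code{behavior_checker},
#'   \code{behavior_dim}, \code{imaging1_loom}, \code{imaging1_checker},
#'   \code{imaging1_dim}, \code{imaging2_sequence}, \code{imaging3_component}.
#' @param seed Integer seed for the ISI draw (behavioral protocols only; the
#'   imaging schedules are fixed). A fixed seed gives an identical train.
#' @param isi_choices Allowed behavioral ISIs in seconds.
#' @param expand_s,fade_s Expansion and fade durations passed to every event.
#' @return A \code{"stimulus_train"}: list with \code{protocol}, \code{seed},
#'   \code{events} (data.frame: kind, onset_s, expand_s, fade_s),
#'   \code{isi_s}, \code{baseline_s}, \code{total_duration_s}.
#' @examples
#' tr <- build_train("imaging1_dim")
#' table(tr$events$kind)
#' @export
build_train <- function(protocol, seed = 1L,
                        isi_choices = c(20, 25, 30, 35),
                        expand_s = 5, fade_s = 15) {
  if (!protocol %in% .protocols)
    stop("unknown protocol: ", protocol)
  event_len <- expand_s + fade_s
  kinds <- switch(protocol,
    behavior_loom      = rep("loom", 30),
    behavior_checker   = c(rep("checkerboard", 20), rep("loom", 10)),
    behavior_dim       = c(rep("dim", 20), rep("loom", 10)),
    imaging1_loom      = rep("loom", 15),
    imaging1_checker   = c(rep("checkerboard", 10), rep("loom", 5)),
    imaging1_dim       = c(rep("dim", 10), rep("loom", 5)),
    imaging2_sequence  = rep(c("dim", "checkerboard", "loom"), 2),
    imaging3_component = c("dim", "checkerboard", "dim", "checkerboard",
                           rep("loom", 10),
                           "dim", "checkerboard", "dim", "checkerboard"))
  n <- length(kinds)
  behavioral <- grepl("^behavior", protocol)
  baseline_s <- if (behavioral) 300 else 30
  if (behavioral) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    isi <- sample(isi_choices, n - 1L, replace = TRUE)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  } else if (protocol == "imaging2_sequence") {
    # 1 min between onsets within a block; 5 min break between blocks.
    isi <- rep(60 - event_len, n - 1L)
    isi[3L] <- 300
  } else {
    isi <- rep(20, n - 1L)
  }
  onsets <- baseline_s + c(0, cumsum(event_len + isi))
  events <- data.frame(kind = kinds, onset_s = onsets,
                       expand_s = expand_s, fade_s = fade_s,
                       stringsAsFactors = FALSE)
  structure(list(protocol = protocol, seed = as.integer(seed),
                 events = events, isi_s = isi, baseline_s = baseline_s,
                 total_duration_s = onsets[n] + event_len),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat("Stimulus train:", x$protocol, "(seed", paste0(x$seed, ")"), "\n")
  cat(" ", nrow(x$events), "events:",
      paste(sprintf("%s x%d", names(table(x$events$kind)),
                    as.integer(table(x$events$kind))), collapse = ", "), "\n")
  cat("  duration", x$total_duration_s, "s,",
      "first onset", x$events$onset_s[1], "s\n")
  invisible(x)
}

.event_row <- function(train, i) {
  e <- train$events[i, ]
  stim_event(e$kind, e$onset_s, e$expand_s, e$fade_s)
}

#' @keywords internal
.train_grid <- function(train, rate_hz) {
  n <- ceiling(train$total_duration_s * rate_hz)
  (seq_len(n) - 1) / rate_hz
}

# One column per event: the event's expansion-period indicator convolved with
# a causal exponential calcium kernel exp(-t/tau).  `normalize = "peak"`
# rescales so a single lobe peaks at 1 (used by the synthetic generator so
# that ground-truth amplitudes are peak response sizes); the regressor uses
# the raw convolution.
.event_lobes <- function(train, rate_hz, kernel_tau_s, normalize = "none") {
  t <- .train_grid(train, rate_hz)
  n <- length(t)
  dt <- 1 / rate_hz
  nk <- max(2L, ceiling(10 * kernel_tau_s * rate_hz))
  kern <- exp(-(0:(nk - 1L)) * dt / kernel_tau_s)
  ev <- train$events
  lobes <- matrix(0, n, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    u <- as.numeric(t >= ev$onset_s[i] & t < ev$onset_s[i] + ev$expand_s[i])
    idx <- which(u > 0)
    if (!length(idx)) next
    col <- numeric(n)
    for (j in idx) {
      hi <- min(n, j + nk - 1L)
      col[j:hi] <- col[j:hi] + kern[seq_len(hi - j + 1L)]
    }
    lobes[, i] <- col
  }
  if (normalize == "peak") {
    # peak of a single lobe; identical for events sharing expand_s
    pk <- apply(lobes, 2, max)
    pk[pk == 0] <- 1
    lobes <- sweep(lobes, 2, pk, "/")
  }
  lobes
}

#' Build a calcium-kernel stimulus regressor
#'
#' The regressor is the linear superposition, over every event whose kind is
#' in \code{kinds}, of the event's expansion-period indicator convolved with a
#' causal single-exponential calcium kernel \eqn{e^{-t/\tau}}, sampled on the
#' imaging clock. A first-order kernel matches the autoregressive order used
#' for nuclear GCaMP6s trace extraction; the default \eqn{\tau} of 3.5 s
#' emulates the indicator's decay.
#'
#' @param train A \code{\link{build_train}} result.
#' @param kinds Character vector of event kinds to include (non-empty).
#' @param kernel_tau_s Kernel decay time constant in seconds (> 0).
#' @param rate_hz Sampling rate (default 2 Hz, the imaging frame rate).
#' @return A \code{"regressor"}: list with \code{samples}, \code{rate_hz},
#'   \code{kernel_tau_s}, \code{kinds}. \code{length(samples)} equals
#'   \code{ceiling(total_duration_s * rate_hz)}.
#' @export
build_regressor <- function(train, kinds, kernel_tau_s = 3.5, rate_hz = 2) {
  stopifnot(inherits(train, "stimulus_train"))
  if (length(kinds) == 0) stop("kinds must be non-empty")
  if (kernel_tau_s <= 0) stop("kernel_tau_s must be > 0")
  keep <- train$events$kind %in% kinds
  lobes <- .event_lobes(train, rate_hz, kernel_tau_s)
  samples <- if (any(keep)) rowSums(lobes[, keep, drop = FALSE])
             else numeric(nrow(lobes))
  structure(list(samples = samples, rate_hz = rate_hz,
                 kernel_tau_s = kernel_tau_s, kinds = kinds),
            class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  cat("Stimulus regressor:", length(x$samples), "samples at", x$rate_hz,
      "Hz, kernel tau", x$kernel_tau_s, "s, kinds:",
      paste(x$kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a stimulus train to JSON
#'
#' @param train A \code{"stimulus_train"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "stimulus_train"))
  obj <- list(protocol = train$protocol, seed = train$seed,
              baseline_s = train$baseline_s,
              events = train$events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stimulus train from JSON
#'
#' @param path Path to a file written by \code{\link{write_train}}.
#' @return A \code{"stimulus_train"}.
#' @export
read_train <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  n <- nrow(ev)
  structure(list(protocol = obj$protocol, seed = as.integer(obj$seed),
                 events = ev,
                 isi_s = if (n > 1)
                   diff(ev$onset_s) - (ev$expand_s[-n] + ev$fade_s[-n])
                 else numeric(0),
                 baseline_s = obj$baseline_s,
                 total_duration_s = ev$onset_s[n] + ev$expand_s[n] + ev$fade_s[n]),
            class = "stimulus_train")
}
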
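.regions <- c("pallium", "subpallium", "thalamus", "habenula", "pretectum",
              "tectum", "tegmentum", "cerebellum", "hindbrain")

# Per-class region priors. Qualitative anatomy encoded as configurable
# priors: ROIs responsive to both components concentrate in the tectum;
# dim-sensitive ROIs sit mostly in habenula/thalamus/tectum; checkerboard
# (motion) responses are broad; non-responsive ROIs follow rough region size.
.region_priors <- function() {
  m <- rbind(
    none    = c(.10, .05, .08, .03, .06, .25, .08, .12, .23),
    checker = c(.10, .05, .10, .04, .08, .25, .08, .10, .20),
    dim     = c(.08, .02, .22, .20, .08, .30, .02, .03, .05),
    both    = c(.04, .01, .08, .04, .08, .60, .03, .04, .08))
  colnames(m) <- .regions
  m
}

# Nominal region centroid coordinates in arbitrary atlas units (x lateral,
# y rostro-caudal, z dorso-ventral); only used to give ROIs plausible
# positions, never analyzed quantitatively.
.region_centers <- function() {
  m <- rbind(
    pallium    = c(250, 120, 180), subpallium = c(250, 150, 120),
    thalamus   = c(250, 300, 130), habenula   = c(230, 260, 200),
    pretectum  = c(250, 320, 170), tectum     = c(250, 400, 190),
    tegmentum  = c(250, 420, 110), cerebellum = c(250, 520, 170),
    hindbrain  = c(250, 650, 120))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Default synthetic-cohort configuration
#'
#' Returns the configuration list consumed by \code{\link{generate_cohort}}.
#' Defaults emulate the component-sensitivity imaging experiment: 11 fish,
#' 500 ROIs per fish, a small visually-responsive minority (2\% dim-, 5\%
#' checkerboard-, 3\% both-sensitive, 90\% non-responsive -- visually
#' responsive neurons are a minority brain-wide and motion responses
#' outnumber luminance responses), peak response amplitude 3 z-units, trace
#' noise sd 1, habituation decay constants drawn uniformly from [0.2, 1.2]
#' per presentation, and a 3.5 s calcium kernel sampled at 2 Hz.
#'
#' @param protocol Stimulus-train protocol name (see \code{\link{build_train}}).
#' @param n_fish Number of fish.
#' @param rois_per_fish ROIs per fish.
#' @param class_mix Named probabilities for classes dim/checker/both/none;
#'   must sum to 1.
#' @param amplitude Peak transient amplitude in z-score units.
#' @param decay_range Range of the per-presentation habituation decay
#'   constant c (uniform draw), or use \code{decay_by_class}.
#' @param decay_by_class Optional named vector (dim, checker, both) of fixed
#'   class-specific decay constants; overrides \code{decay_range}.
#' @param noise_sd Gaussian trace noise sd in z-score units (> 0).
#' @param rate_hz Imaging rate.
#' @param kernel_tau_s Calcium kernel decay constant in seconds.
#' @param region_priors Class x region probability matrix.
#' @return A configuration list.
#' @export
cohort_config <- function(protocol = "imaging3_component",
                          n_fish = 11, rois_per_fish = 500,
                          class_mix = c(dim = 0.02, checker = 0.05,
                                        both = 0.03, none = 0.90),
                          amplitude = 3,
                          decay_range = c(0.2, 1.2),
                          decay_by_class = NULL,
                          noise_sd = 1,
                          rate_hz = 2, kernel_tau_s = 3.5,
                          region_priors = .region_priors()) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix probabilities must sum to 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  list(protocol = protocol, n_fish = n_fish, rois_per_fish = rois_per_fish,
       class_mix = class_mix, amplitude = amplitude,
       decay_range = decay_range, decay_by_class = decay_by_class,
       noise_sd = noise_sd, rate_hz = rate_hz, kernel_tau_s = kernel_tau_s,
       region_priors = region_priors)
}

# Which ground-truth classes respond to each event kind. A full loom drives
# both the luminance and the motion channel, so its response weight is the
# sum of the ROI's component amplitudes (linear summation of components).
.roi_event_weights <- function(class, amplitude, decay_c, kinds) {
  amp_dim <- if (class %in% c("dim", "both")) amplitude else 0
  amp_chk <- if (class %in% c("checker", "both")) amplitude else 0
  base <- c(dim = amp_dim, checkerboard = amp_chk, loom = amp_dim + amp_chk)
  w <- base[kinds]
  for (g in unique(kinds)) {
    idx <- which(kinds == g)
    w[idx] <- w[idx] * exp(-decay_c * (seq_along(idx) - 1))
  }
  unname(w)
}

#' Simulate one ROI's fluorescence trace
#'
#' Each stimulus event whose kind matches the ROI's ground-truth class adds a
#' calcium transient: the event's expansion-period indicator convolved with a
#' single-exponential kernel, peak-normalized, and scaled by
#' \eqn{A_k = \mathrm{amplitude} \cdot e^{-c (k-1)}} where k is the 1-based
#' index of the event among same-kind events (per-kind habituation). Looms
#' drive the sum of the ROI's dim and checkerboard component amplitudes, so a
#' both-class ROI's noiseless trace is exactly the sum of the corresponding
#' dim-only and checker-only traces. I.i.d. Gaussian noise of sd
#' \code{roi$noise_sd} is added (use 0 for the noiseless limit).
#'
#' @param roi A list or one-row data.frame with fields \code{class}
#'   (dim/checker/both/none), \code{amplitude}, \code{decay_c},
#'   \code{noise_sd}.
#' @param train A \code{"stimulus_train"}.
#' @param rate_hz,kernel_tau_s Imaging clock and calcium kernel.
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric trace of length \code{ceiling(total_duration_s * rate_hz)}.
#' @export
generate_trace <- function(roi, train, rate_hz = 2, kernel_tau_s = 3.5,
                           seed = NULL) {
  stopifnot(inherits(train, "stimulus_train"))
  lobes <- .event_lobes(train, rate_hz, kernel_tau_s, normalize = "peak")
  w <- .roi_event_weights(as.character(roi$class), roi$amplitude,
                          roi$decay_c, train$events$kind)
  mu <- drop(lobes %*% w)
  if (roi$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    mu <- mu + stats::rnorm(length(mu), 0, roi$noise_sd)
  }
  mu
}

#' Generate a seeded synthetic cohort with known ground truth
#'
#' Draws per-ROI ground truth (fish, class, region, centroid, amplitude,
#' decay constant, noise sd) from the configuration, simulates every trace
#' (see \code{\link{generate_trace}}), and returns the cohort. Deterministic
#' for a fixed seed.
#'
#' @param config A \code{\link{cohort_config}} list.
#' @param seed Integer seed.
#' @return A \code{"synthetic_cohort"}: list with \code{rois} (ground-truth
#'   data.frame), \code{traces} (ROIs x samples matrix, rownames = roi_id),
#'   \code{train}, \code{config}, \code{seed}.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (abs(sum(config$class_mix) - 1) > 1e-8)
    stop("class_mix probabilities must sum to 1")
  set.seed(seed)
  train <- build_train(config$protocol, seed = seed)
  n_roi <- config$n_fish * config$rois_per_fish
  fish_id <- rep(seq_len(config$n_fish), each = config$rois_per_fish)
  cls <- sample(names(config$class_mix), n_roi, replace = TRUE,
                prob = config$class_mix)
  pri <- config$region_priors
  region <- character(n_roi)
  for (cl in rownames(pri)) {
    idx <- which(cls == cl)
    if (length(idx))
      region[idx] <- sample(colnames(pri), length(idx), replace = TRUE,
                            prob = pri[cl, ])
  }
  centers <- .region_centers()[region, , drop = FALSE]
  coords <- centers + matrix(stats::rnorm(3L * n_roi, 0, 30), ncol = 3L)
  decay_c <- if (!is.null(config$decay_by_class)) {
    dc <- c(config$decay_by_class, none = 0)
    unname(dc[cls])
  } else {
    stats::runif(n_roi, config$decay_range[1], config$decay_range[2])
  }
  decay_c[cls == "none"] <- 0
  rois <- data.frame(
    roi_id = sprintf("roi_%05d", seq_len(n_roi)),
    fish_id = fish_id, region = region,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    class = cls,
    amplitude = ifelse(cls == "none", 0, config$amplitude),
    decay_c = decay_c, noise_sd = config$noise_sd,
    stringsAsFactors = FALSE)
  lobes <- .event_lobes(train, config$rate_hz, config$kernel_tau_s,
                        normalize = "peak")
  W <- vapply(seq_len(n_roi), function(i)
    .roi_event_weights(cls[i], rois$amplitude[i], rois$decay_c[i],
                       train$events$kind),
    numeric(nrow(train$events)))
  traces <- t(lobes %*% W)
  traces <- traces + matrix(stats::rnorm(length(traces), 0, config$noise_sd),
                            nrow = n_roi)
  rownames(traces) <- rois$roi_id
  structure(list(rois = rois, traces = traces, train = train,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$rois), "ROIs,",
      length(unique(x$rois$fish_id)), "fish, protocol",
      x$train$protocol, "(seed", paste0(x$seed, ")\n"))
  print(table(x$rois$class))
  invisible(x)
}

#' Default behavioral response model
#'
#' Escape probability per stimulus: looms habituate as
#' \eqn{p_k = p_0 e^{-\lambda (k-1)} + \mathrm{floor}}, checkerboards elicit
#' escapes at a constant lower rate, dims almost never.
#'
#' @param loom_p0,loom_lambda,loom_floor Loom decay parameters.
#' @param checker_p,dim_p Constant per-stimulus escape probabilities.
#' @return A response-model list for \code{\link{generate_behavior}}.
#' @export
response_model <- function(loom_p0 = 0.8, loom_lambda = 0.25, loom_floor = 0,
                           checker_p = 0.3, dim_p = 0.02) {
  list(loom = list(p0 = loom_p0, lambda = loom_lambda, floor = loom_floor),
       checkerboard = list(p = checker_p), dim = list(p = dim_p))
}

.event_escape_probs <- function(train, model) {
  kinds <- train$events$kind
  p <- numeric(length(kinds))
  for (g in unique(kinds)) {
    idx <- which(kinds == g)
    m <- model[[g]]
    p[idx] <- if (!is.null(m$p0))
      m$p0 * exp(-m$lambda * (seq_along(idx) - 1)) + m$floor
    else m$p
  }
  if (any(p < 0 | p > 1)) stop("escape probabilities must lie in [0, 1]")
  p
}

#' Simulate ViewPoint-style behavioral tracking records
#'
#' Produces per-fish, per-second distance-moved bins. Baseline bins are a
#' drift/scoot mixture (80\% drift, |N(0.1, 0.1)| mm; 20\% scoot, U(0.5, 5)
#' mm). For each stimulus, each fish escapes independently with the
#' model-specified probability; an escape places one bin of 35-80 mm within
#' the response window after onset.
#'
#' @param n_fish Number of fish.
#' @param train A \code{"stimulus_train"}.
#' @param model A \code{\link{response_model}} list.
#' @param seed Integer seed.
#' @param window_s Escape-attribution window in seconds after onset
#'   (default: the 5 s expansion period).
#' @return A data.frame (fish_id, second, distance_mm); the per-stimulus
#'   ground-truth probabilities are attached as attribute \code{"p_true"}.
#' @export
generate_behavior <- function(n_fish, train, model = response_model(),
                              seed = 1L, window_s = 5) {
  stopifnot(inherits(train, "stimulus_train"), n_fish >= 1)
  set.seed(seed)
  p <- .event_escape_probs(train, model)
  dur <- ceiling(train$total_duration_s)
  n <- n_fish * dur
  scoot <- stats::runif(n) < 0.2
  dist <- abs(stats::rnorm(n, 0.1, 0.1))
  dist[scoot] <- stats::runif(sum(scoot), 0.5, 5)
  out <- data.frame(fish_id = rep(seq_len(n_fish), each = dur),
                    second = rep(0:(dur - 1L), n_fish),
                    distance_mm = dist)
  onsets <- floor(train$events$onset_s)
  for (i in seq_along(p)) {
    esc <- stats::runif(n_fish) < p[i]
    if (!any(esc)) next
    bins <- onsets[i] + sample.int(window_s, sum(esc), replace = TRUE) - 1L
    rows <- (which(esc) - 1L) * dur + bins + 1L
    out$distance_mm[rows] <- stats::runif(sum(esc), 35, 80)
  }
  attr(out, "p_true") <- data.frame(stimulus_index = seq_along(p),
                                    kind = train$events$kind, p = p)
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes \code{traces.csv} (long: roi_id, fish_id, sample_index, value),
#' \code{rois.csv} (ground truth), \code{train.json}, and, if supplied,
#' \code{behavior.csv} (fish_id, second, distance_mm).
#'
#' @param cohort A \code{"synthetic_cohort"}.
#' @param dir Output directory (created if needed).
#' @param behavior Optional behavior data.frame.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, behavior = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_s <- ncol(cohort$traces)
  long <- data.frame(
    roi_id = rep(cohort$rois$roi_id, each = n_s),
    fish_id = rep(cohort$rois$fish_id, each = n_s),
    sample_index = rep(seq_len(n_s), nrow(cohort$traces)),
    value = as.vector(t(cohort$traces)))
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(cohort$rois, file.path(dir, "rois.csv"), row.names = FALSE)
  write_train(cohort$train, file.path(dir, "train.json"))
  if (!is.null(behavior))
    utils::write.csv(behavior, file.path(dir, "behavior.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir Directory containing \code{traces.csv}, \code{rois.csv},
#'   \code{train.json}.
#' @return A \code{"synthetic_cohort"} (config and seed are not recoverable
#'   from disk and are set to NULL/NA).
#' @export
read_cohort <- function(dir) {
  rois <- utils::read.csv(file.path(dir, "rois.csv"),
                          stringsAsFactors = FALSE)
  long <- utils::read.csv(file.path(dir, "traces.csv"),
                          stringsAsFactors = FALSE)
  train <- read_train(file.path(dir, "train.json"))
  ids <- unique(long$roi_id)
  n_s <- max(long$sample_index)
  traces <- matrix(NA_real_, length(ids), n_s, dimnames = list(ids, NULL))
  traces[cbind(match(long$roi_id, ids), long$sample_index)] <- long$value
  traces <- traces[match(rois$roi_id, ids), , drop = FALSE]
  structure(list(rois = rois, traces = traces, train = train,
                 config = NULL, seed = NA_integer_),
            class = "synthetic_cohort")
}
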
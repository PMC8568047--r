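#' Read an analysis configuration file
#'
#' Reads a YAML or JSON configuration (rate_hz, kernel_tau_s, protocol,
#' seed, cohort settings, ...) into a plain list. The format is chosen by
#' file extension.
#'
#' @param path Path to a .yaml/.yml or .json file.
#' @return A named list.
#' @examples
#' cfg <- read_config(system.file("extdata", "example_config.yaml",
#'                                package = "habitrace"))
#' cfg$protocol
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write behavioral analysis outputs
#'
#' Writes \code{escape_curve.csv} (stimulus_index, kind, p, n) and
#' \code{stats.json} (habituation test and curve-fit parameters) for an
#' \code{\link{analyze_behavior}} result.
#'
#' @param res An \code{\link{analyze_behavior}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_behavior_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res$curve),
                   file.path(dir, "escape_curve.csv"), row.names = FALSE)
  stats_out <- list(
    habituation = list(test = res$habituation$method,
                       statistic = unname(res$habituation$statistic),
                       df = unname(res$habituation$parameter),
                       p = res$habituation$p.value),
    fit = list(Y0 = res$fit$Y0, K = res$fit$K,
               slope = res$fit$slope, intercept = res$fit$intercept))
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write responsiveness analysis outputs
#'
#' Writes \code{responsiveness.csv} (roi_id, r2, responsive),
#' \code{max_responses.csv} (long: roi_id, stimulus_index, value) and
#' \code{group_curves.csv} for an \code{\link{analyze_responsiveness}}
#' result.
#'
#' @param res An \code{\link{analyze_responsiveness}} result.
#' @param roi_ids ROI ids in the order of the analyzed trace matrix.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
save_responsiveness <- function(res, roi_ids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(roi_id = roi_ids, r2 = res$selection$r2,
                              responsive = res$selection$responsive),
                   file.path(dir, "responsiveness.csv"), row.names = FALSE)
  M <- res$M
  long <- data.frame(roi_id = rep(rownames(M), ncol(M)),
                     stimulus_index = rep(seq_len(ncol(M)), each = nrow(M)),
                     value = as.vector(M))
  utils::write.csv(long, file.path(dir, "max_responses.csv"),
                   row.names = FALSE)
  if (!is.null(res$group))
    utils::write.csv(data.frame(stimulus_index = seq_along(res$group$group_mean),
                                mean_response = res$group$group_mean),
                     file.path(dir, "group_curves.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write component-habituation analysis outputs
#'
#' Writes \code{classes.csv}, \code{decay_fits.csv} and
#' \code{group_stats.json} for a \code{\link{run_experiment3}} result.
#'
#' @param res A \code{\link{run_experiment3}} result.
#' @param dir Output directory.
#' @return \code{dir}, invisibly.
#' @export
save_experiment3 <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$classes, file.path(dir, "classes.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fits, file.path(dir, "decay_fits.csv"),
                   row.names = FALSE)
  out <- list(median_c = as.list(as.data.frame(res$medians)),
              friedman = list(statistic = unname(res$friedman$statistic),
                              df = unname(res$friedman$parameter),
                              p = res$friedman$p.value,
                              exact = res$friedman$exact))
  jsonlite::write_json(out, file.path(dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write clustering analysis outputs
#'
#' Writes \code{clusters.csv} (roi_id, cluster, merged_cluster),
#' \code{cluster_means.csv} (retained cluster means, one row per cluster),
#' \code{validity.json} (per-criterion booleans), and, when supplied,
#' \code{region_composition.csv} for an \code{\link{analyze_clusters}}
#' result.
#'
#' @param res An \code{\link{analyze_clusters}} result.
#' @param dir Output directory (created if needed).
#' @param composition Optional \code{\link{region_composition}} result.
#' @return \code{dir}, invisibly.
#' @export
save_clusters <- function(res, dir, composition = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$assignments, file.path(dir, "clusters.csv"),
                   row.names = FALSE)
  if (!is.null(res$validity$means)) {
    means <- data.frame(cluster = rownames(res$validity$means),
                        res$validity$means, check.names = FALSE)
    utils::write.csv(means, file.path(dir, "cluster_means.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$validity$criteria, file.path(dir, "validity.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(composition)) {
    comp <- data.frame(region = names(composition$prop_responsive),
                       prop_responsive = unname(composition$prop_responsive),
                       composition$composition, check.names = FALSE)
    utils::write.csv(comp, file.path(dir, "region_composition.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
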
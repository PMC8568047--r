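#' K-means clustering of responsive z-scored traces
#'
#' Euclidean k-means over ROIs x samples z traces, deliberately
#' over-clustered (default k = 10) so that uncommon response profiles can be
#' removed by validation. The best of \code{replicates} random
#' initializations (by total within-cluster sum of squares) is kept;
#' deterministic for a fixed seed.
#'
#' @param z ROIs x samples matrix (responsive ROIs only).
#' @param k Number of clusters (>= 2).
#' @param replicates Number of random starts (>= 1).
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd iterations per start.
#' @return A list of class \code{"cluster_result"}: \code{cluster}
#'   (assignment per ROI, named by rownames), \code{centers} (k x samples),
#'   \code{withinss}, \code{k}, \code{seed}.
#' @export
kmeans_traces <- function(z, k = 10, replicates = 20, seed = 1L,
                          iter_max = 100) {
  if (k < 2) stop("k must be >= 2")
  if (replicates < 1) stop("replicates must be >= 1")
  if (nrow(z) < k) stop("fewer ROIs than clusters")
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = replicates,
                      iter.max = iter_max)
  structure(list(cluster = stats::setNames(km$cluster, rownames(z)),
                 centers = km$centers, withinss = km$tot.withinss,
                 k = k, seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("K-means clustering: k =", x$k, "over", length(x$cluster), "ROIs\n")
  print(table(x$cluster))
  invisible(x)
}

#' Validate clusters for cross-animal consistency
#'
#' A cluster is retained iff it satisfies all four criteria: (1) every
#' member ROI correlates with the cluster mean above \code{min_corr}; (2) at
#' least \code{min_size} member ROIs; (3) members from at least
#' \code{min_fish_frac} of the cohort's fish; (4) no single fish contributes
#' more than \code{max_fish_share} of the members. By default criterion 1 is
#' applied by pruning low-correlation members (against the original cluster
#' mean) before evaluating criteria 2-4; \code{prune = FALSE} instead
#' rejects outright any cluster containing a low-correlation member.
#'
#' @param result A \code{"cluster_result"}.
#' @param z The ROIs x samples matrix that was clustered (same row order).
#' @param fish_ids Fish id per ROI.
#' @param n_fish Total number of fish in the cohort (defaults to the number
#'   of distinct \code{fish_ids}).
#' @param min_corr,min_size,min_fish_frac,max_fish_share Criterion
#'   parameters (defaults 0.5, 100, 0.75, 0.33).
#' @param prune Prune low-correlation members (default) or strictly reject.
#' @return A list of class \code{"cluster_validity"}: \code{criteria}
#'   (per-cluster data.frame of booleans and the overall \code{retained}
#'   flag), \code{members} (per-cluster member indices after any pruning),
#'   \code{retained} (retained cluster ids), \code{means} (retained cluster
#'   means recomputed over surviving members).
#' @export
validate_clusters <- function(result, z, fish_ids,
                              n_fish = length(unique(fish_ids)),
                              min_corr = 0.5, min_size = 100,
                              min_fish_frac = 0.75, max_fish_share = 0.33,
                              prune = TRUE) {
  stopifnot(inherits(result, "cluster_result"),
            length(fish_ids) == nrow(z))
  ids <- sort(unique(result$cluster))
  crit <- data.frame(cluster = ids, corr_ok = NA, size_ok = NA,
                     fish_coverage_ok = NA, fish_share_ok = NA,
                     retained = NA)
  members <- list()
  means <- list()
  for (i in seq_along(ids)) {
    idx <- which(result$cluster == ids[i])
    mu <- colMeans(z[idx, , drop = FALSE])
    cors <- as.vector(stats::cor(t(z[idx, , drop = FALSE]), mu))
    if (prune) {
      keep <- idx[cors > min_corr]
      corr_ok <- length(keep) > 0
    } else {
      keep <- idx
      corr_ok <- all(cors > min_corr)
    }
    size_ok <- length(keep) >= min_size
    f <- fish_ids[keep]
    coverage <- length(unique(f)) / n_fish
    share <- if (length(f)) max(table(f)) / length(f) else 1
    fish_coverage_ok <- coverage >= min_fish_frac
    fish_share_ok <- share <= max_fish_share
    crit[i, 2:6] <- c(corr_ok, size_ok, fish_coverage_ok, fish_share_ok,
                      corr_ok && size_ok && fish_coverage_ok && fish_share_ok)
    members[[as.character(ids[i])]] <- keep
    means[[as.character(ids[i])]] <-
      if (length(keep)) colMeans(z[keep, , drop = FALSE]) else mu
  }
  retained <- crit$cluster[crit$retained]
  structure(list(criteria = crit, members = members,
                 retained = retained,
                 means = do.call(rbind, means[as.character(retained)]),
                 sizes = vapply(members, length, integer(1))),
            class = "cluster_validity")
}

#' @export
print.cluster_validity <- function(x, ...) {
  cat("Cluster validation:", length(x$retained), "of",
      nrow(x$criteria), "clusters retained\n")
  print(x$criteria, row.names = FALSE)
  invisible(x)
}

#' Merge retained clusters with similar mean profiles
#'
#' Agglomerative merging by transitive closure: clusters whose mean traces
#' have pairwise Pearson correlation above \code{threshold} are joined into
#' one merged cluster (connected components of the correlation graph), the
#' automated counterpart of manually combining clusters with similar
#' response profiles. Merged means are member-count-weighted averages.
#'
#' @param means Retained-cluster means (clusters x samples matrix, rownames
#'   = cluster ids), e.g. from \code{\link{validate_clusters}}.
#' @param sizes Member counts per retained cluster (same order).
#' @param threshold Correlation threshold (default 0.8).
#' @return A list of class \code{"cluster_merge"}: \code{map} (named vector
#'   original cluster id -> merged cluster id), \code{means} (merged means),
#'   \code{sizes}.
#' @export
merge_clusters <- function(means, sizes = rep(1L, nrow(means)),
                           threshold = 0.8) {
  if (is.null(means) || nrow(means) == 0) stop("no retained clusters")
  ids <- rownames(means)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(means)))
  n <- nrow(means)
  adj <- if (n > 1) stats::cor(t(means)) > threshold else matrix(TRUE, 1, 1)
  diag(adj) <- TRUE
  # connected components by label propagation (transitive closure)
  comp <- seq_len(n)
  repeat {
    prev <- comp
    for (i in seq_len(n)) comp[adj[i, ]] <- min(comp[adj[i, ]])
    if (identical(prev, comp)) break
  }
  comp <- match(comp, sort(unique(comp)))
  merged_ids <- paste0("M", comp)
  map <- stats::setNames(merged_ids, ids)
  mm <- t(vapply(sort(unique(merged_ids)), function(g) {
    rows <- which(merged_ids == g)
    colSums(means[rows, , drop = FALSE] * sizes[rows]) / sum(sizes[rows])
  }, numeric(ncol(means))))
  ms <- tapply(sizes, merged_ids, sum)
  structure(list(map = map, means = mm, sizes = ms[rownames(mm)]),
            class = "cluster_merge")
}

#' @export
print.cluster_merge <- function(x, ...) {
  cat("Cluster merge:", length(x$map), "->", nrow(x$means),
      "clusters\n")
  print(x$map)
  invisible(x)
}

#' Per-region responsive proportions and class composition
#'
#' For each fish and brain region: the fraction of that region's ROIs that
#' are responsive, averaged across fish (fish with no ROIs in a region are
#' omitted from that region's average); and, analogously, the per-region
#' composition of responsive classes (dim / checker / both), normalized to
#' sum to 1 within each region.
#'
#' @param responsive Logical per ROI.
#' @param class Class label per ROI (dim/checker/both/none; only responsive
#'   ROIs enter the composition).
#' @param region Region label per ROI.
#' @param fish_ids Fish id per ROI.
#' @return A list of class \code{"region_composition"}:
#'   \code{prop_responsive} (named per-region vector) and
#'   \code{composition} (regions x classes matrix, rows summing to 1 where
#'   defined).
#' @export
region_composition <- function(responsive, class, region, fish_ids) {
  stopifnot(length(responsive) == length(class),
            length(class) == length(region),
            length(region) == length(fish_ids))
  regions <- sort(unique(region))
  fish <- sort(unique(fish_ids))
  classes <- c("dim", "checker", "both")
  prop <- stats::setNames(numeric(length(regions)), regions)
  comp <- matrix(NA_real_, length(regions), length(classes),
                 dimnames = list(regions, classes))
  for (rg in regions) {
    in_rg <- region == rg
    per_fish <- vapply(fish, function(f) {
      n <- sum(in_rg & fish_ids == f)
      if (n == 0) NA_real_ else sum(responsive & in_rg & fish_ids == f) / n
    }, numeric(1))
    prop[rg] <- mean(per_fish, na.rm = TRUE)
    cls_fish <- vapply(classes, function(cl) {
      per <- vapply(fish, function(f) {
        n <- sum(in_rg & fish_ids == f)
        if (n == 0) NA_real_
        else sum(responsive & in_rg & fish_ids == f & class == cl) / n
      }, numeric(1))
      mean(per, na.rm = TRUE)
    }, numeric(1))
    tot <- sum(cls_fish)
    comp[rg, ] <- if (is.finite(tot) && tot > 0) cls_fish / tot else NA_real_
  }
  structure(list(prop_responsive = prop, composition = comp),
            class = "region_composition")
}

#' @export
print.region_composition <- function(x, ...) {
  cat("Per-region responsive proportion:\n")
  print(round(x$prop_responsive, 3))
  cat("Normalized class composition:\n")
  print(round(x$composition, 3))
  invisible(x)
}

#' Functional clustering analysis of a cohort (paired-stimulus protocol)
#'
#' Dataset-2-style pipeline: z-score, select responsive ROIs by regression
#' against the all-stimulus regressor, over-cluster with k-means, validate,
#' and merge similar clusters.
#'
#' @param cohort A \code{"synthetic_cohort"} (imaging2_sequence protocol).
#' @param k,replicates,seed K-means parameters.
#' @param merge_threshold Mean-trace correlation threshold for merging
#'   (pipeline default 0.9: under additive loom responses the mean profiles
#'   of *different* classes correlate up to ~0.87, so the pipeline threshold
#'   sits above that; \code{\link{merge_clusters}} keeps 0.8 as its
#'   operation-level default).
#' @param min_size Minimum validated cluster size (scale to cohort size).
#' @param rate_hz,kernel_tau_s Analysis parameters.
#' @return List with \code{selection}, \code{kmeans}, \code{validity},
#'   \code{merge}, and \code{assignments} (data.frame roi_id, cluster,
#'   merged_cluster for responsive ROIs).
#' @export
analyze_clusters <- function(cohort, k = 10, replicates = 20, seed = 1L,
                             merge_threshold = 0.9, min_size = 100,
                             rate_hz = 2, kernel_tau_s = 3.5) {
  train <- cohort$train
  z <- zscore_traces(cohort$traces)
  # one regression per stimulus kind (each presented as a pair in this
  # protocol); an ROI is responsive if it passes the median + 2 SD rule for
  # any kind, so single-component ROIs are not diluted by a combined
  # regressor
  kinds <- unique(train$events$kind)
  sel_by_kind <- lapply(kinds, function(g) {
    reg <- build_regressor(train, g, kernel_tau_s, rate_hz)
    select_responsive(.r2_rows(z, reg))
  })
  names(sel_by_kind) <- kinds
  responsive <- Reduce(`|`, lapply(sel_by_kind, `[[`, "responsive"))
  sel <- structure(list(r2 = sapply(sel_by_kind, `[[`, "r2"),
                        threshold = vapply(sel_by_kind, `[[`, numeric(1),
                                           "threshold"),
                        responsive = responsive, by_kind = sel_by_kind),
                   class = "responsiveness")
  keep <- which(sel$responsive)
  if (length(keep) < k) stop("fewer responsive ROIs than clusters")
  zr <- z[keep, , drop = FALSE]
  fish <- cohort$rois$fish_id[keep]
  km <- kmeans_traces(zr, k, replicates, seed)
  val <- validate_clusters(km, zr, fish,
                           n_fish = length(unique(cohort$rois$fish_id)),
                           min_size = min_size)
  mg <- if (length(val$retained))
    merge_clusters(val$means, val$sizes[as.character(val$retained)],
                   merge_threshold) else NULL
  assignments <- data.frame(roi_id = rownames(zr),
                            cluster = unname(km$cluster),
                            merged_cluster = NA_character_,
                            stringsAsFactors = FALSE)
  if (!is.null(mg)) {
    for (cl in names(mg$map)) {
      rows <- val$members[[cl]]
      assignments$merged_cluster[rows] <- mg$map[[cl]]
    }
  }
  list(selection = sel, kmeans = km, validity = val, merge = mg,
       assignments = assignments)
}
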
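# Builds a synthetic "cluster" of traces around a base profile, tagged with
# fish ids, for exercising the validation criteria in isolation.
mk_cluster_z <- function(profile, n, fish, jitter = 0.01, seed = 1) {
  set.seed(seed)
  z <- matrix(rep(profile, each = n), n) +
    matrix(rnorm(n * length(profile), 0, jitter), n)
  list(z = z, fish = fish)
}

as_cluster_result <- function(assignments, z) {
  structure(list(cluster = assignments,
                 centers = NULL, withinss = NA, k = length(unique(assignments)),
                 seed = 1L),
            class = "cluster_result")
}

profile_a <- sin(2 * pi * (1:80) / 16)
profile_b <- cos(2 * pi * (1:80) / 10)

test_that("k-means recovers well-separated profiles deterministically", {
  za <- mk_cluster_z(profile_a, 30, rep(1:3, 10), jitter = 0.2, seed = 2)$z
  zb <- mk_cluster_z(profile_b, 25, rep(1:3, length.out = 25), jitter = 0.2,
                     seed = 3)$z
  z <- rbind(za, zb)
  rownames(z) <- sprintf("r%02d", seq_len(nrow(z)))
  km <- kmeans_traces(z, k = 2, replicates = 5, seed = 7)
  truth <- rep(1:2, c(30, 25))
  tab <- table(km$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), 55)  # perfect up to label swap
  km2 <- kmeans_traces(z, k = 2, replicates = 5, seed = 7)
  expect_identical(km$cluster, km2$cluster)
  expect_error(kmeans_traces(z, k = 60), "fewer ROIs")
  expect_error(kmeans_traces(z, k = 1), "k must be")
})

test_that("cluster size criterion: 99 rejected, 100 retained", {
  for (n in c(99, 100)) {
    cl <- mk_cluster_z(profile_a, n, rep(1:11, length.out = n), seed = 4)
    val <- validate_clusters(as_cluster_result(rep(1, n), cl$z), cl$z,
                             cl$fish, n_fish = 11)
    expect_equal(val$criteria$retained, n >= 100)
    expect_equal(val$criteria$size_ok, n >= 100)
  }
})

test_that("fish coverage criterion: 8 of 11 rejected, 9 of 11 retained", {
  for (nf in c(8, 9)) {
    cl <- mk_cluster_z(profile_a, 150, rep(seq_len(nf), length.out = 150),
                       seed = 5)
    val <- validate_clusters(as_cluster_result(rep(1, 150), cl$z), cl$z,
                             cl$fish, n_fish = 11)
    expect_equal(val$criteria$fish_coverage_ok, nf >= 9)
    expect_equal(val$criteria$retained, nf >= 9)
  }
})

test_that("single-fish share criterion: 33% retained, 34% rejected", {
  for (n1 in c(33, 34)) {
    fish <- c(rep(1, n1), rep(2:11, length.out = 100 - n1))
    cl <- mk_cluster_z(profile_a, 100, fish, seed = 6)
    val <- validate_clusters(as_cluster_result(rep(1, 100), cl$z), cl$z,
                             cl$fish, n_fish = 11)
    expect_equal(val$criteria$fish_share_ok, n1 <= 33)
    expect_equal(val$criteria$retained, n1 <= 33)
  }
})

test_that("member correlation criterion prunes at the 0.5 boundary", {
  # integer-valued construction: profile p, orthogonal q, and a member pair
  # (m, 2p - m) whose inclusion leaves the cluster mean exactly at p, with
  # cor(m, p) = 0.5 exactly and cor(2p - m, p) = sqrt(3)/2
  p <- rep(c(1, 1, -1, -1, 1, 1, -1, -1), 10)
  m <- rep(c(1, 1, -1, -1, -1, 1, 1, -1), 10)
  m2 <- 2 * p - m
  core <- matrix(rep(p, each = 120), 120)
  z <- rbind(core, m, m2)
  fish <- rep(1:11, length.out = nrow(z))
  val <- validate_clusters(as_cluster_result(rep(1, nrow(z)), z), z, fish,
                           n_fish = 11)
  pruned <- setdiff(seq_len(nrow(z)), val$members[["1"]])
  expect_equal(pruned, 121)                   # cor exactly 0.5 -> pruned
  expect_true(122 %in% val$members[["1"]])    # cor ~0.87 -> kept
  expect_true(val$criteria$retained)
  # strict mode rejects the whole cluster instead of pruning
  val_strict <- validate_clusters(as_cluster_result(rep(1, nrow(z)), z), z,
                                  fish, n_fish = 11, prune = FALSE)
  expect_false(val_strict$criteria$retained)
  expect_false(val_strict$criteria$corr_ok)
})

test_that("all four criteria hold together for a healthy cluster", {
  cl <- mk_cluster_z(profile_a, 150, rep(1:10, each = 15), seed = 8)
  val <- validate_clusters(as_cluster_result(rep(1, 150), cl$z), cl$z,
                           cl$fish, n_fish = 11)
  expect_true(all(unlist(val$criteria[, 2:6])))
})

test_that("cluster merging joins correlated means transitively", {
  means <- rbind(A = profile_a, B = profile_b)
  mg <- merge_clusters(means, c(10, 20), threshold = 0.8)
  expect_equal(length(unique(mg$map)), 2)  # identity map when uncorrelated
  # three noisy copies of one profile collapse into one merged cluster
  set.seed(9)
  noisy <- rbind(A = profile_a + rnorm(80, 0, 0.05),
                 B = profile_a + rnorm(80, 0, 0.05),
                 C = profile_a + rnorm(80, 0, 0.05),
                 D = profile_b)
  mg2 <- merge_clusters(noisy, c(5, 5, 5, 5), threshold = 0.8)
  expect_equal(length(unique(mg2$map[c("A", "B", "C")])), 1)
  expect_false(mg2$map[["D"]] %in% mg2$map[c("A", "B", "C")])
  # order independence: permuting input rows gives the same partition
  perm <- c(3, 1, 4, 2)
  mg3 <- merge_clusters(noisy[perm, ], c(5, 5, 5, 5)[perm], threshold = 0.8)
  same <- function(m, i, j) m$map[[i]] == m$map[[j]]
  for (i in c("A", "B", "C", "D")) for (j in c("A", "B", "C", "D"))
    expect_equal(same(mg2, i, j), same(mg3, i, j))
  # merged means are member-weighted
  mgw <- merge_clusters(rbind(A = profile_a, B = 3 * profile_a),
                        sizes = c(3, 1), threshold = 0.8)
  expect_equal(unname(mgw$means[1, ]), (3 * profile_a + 3 * profile_a) / 4,
               tolerance = 1e-12)
  expect_error(merge_clusters(matrix(0, 0, 10)), "no retained")
})

test_that("region composition averages per fish and normalizes classes", {
  n <- 6
  responsive <- rep(TRUE, n)
  region <- rep("tectum", n)
  fish <- rep(1, n)
  cls <- c("dim", "dim", rep("checker", 3), "both")
  rc <- region_composition(responsive, cls, region, fish)
  expect_equal(unname(rc$prop_responsive["tectum"]), 1)
  rc2 <- region_composition(rep(TRUE, 12),
                            c(rep("dim", 2), rep("checker", 6),
                              rep("both", 4)),
                            rep("tectum", 12), rep(1, 12))
  expect_equal(unname(rc2$composition["tectum", ]), c(1/6, 1/2, 1/3))
  # fish with zero ROIs in a region are omitted from that region's average
  rc3 <- region_composition(c(TRUE, FALSE, TRUE),
                            c("dim", "none", "dim"),
                            c("tectum", "tectum", "habenula"),
                            c(1, 1, 2))
  expect_equal(unname(rc3$prop_responsive), c(1, 0.5))  # habenula, tectum
})

test_that("the clustering pipeline finds the three generating classes", {
  # dataset-2-like regime: the paired-stimulus protocol retained only
  # strongly responsive ROIs (its r-squared threshold implies member-to-mean
  # correlations well above 0.5), so the test cohort uses amplitude 5
  # the paired-stimulus protocol spaces presentations a minute apart with a
  # long mid-train break precisely to minimize habituation, so its cohort is
  # generated with near-zero per-presentation decay
  cfg <- cohort_config(n_fish = 8, rois_per_fish = 150,
                       protocol = "imaging2_sequence", amplitude = 5,
                       decay_range = c(0, 0.1),
                       class_mix = c(dim = 0.08, checker = 0.22,
                                     both = 0.10, none = 0.60))
  ends_at_three <- 0
  for (seed in 1:3) {
    co <- generate_cohort(cfg, seed = seed)
    res <- analyze_clusters(co, k = 10, replicates = 5, seed = seed,
                            min_size = 20)
    expect_lte(length(res$validity$retained), 10)
    expect_lte(nrow(res$merge$means), length(res$validity$retained))
    # over-clustering still recovers the generating response profiles
    tmpl <- vapply(c("dim", "checker", "both"), function(cl)
      generate_trace(list(class = cl, amplitude = 5, decay_c = 0,
                          noise_sd = 0), co$train),
      numeric(ncol(co$traces)))
    cors <- cor(t(res$validity$means), tmpl)
    hit <- apply(cors, 2, max) > 0.9
    expect_gte(sum(hit), 3)
    if (nrow(res$merge$means) == 3) ends_at_three <- ends_at_three + 1
    # no loom-specific cluster: every validated cluster's loom response is
    # the sum of its dim and checkerboard responses
    M <- habitrace:::.max_response_matrix(res$validity$means, co$train,
                                          window = "peak")
    kinds <- co$train$events$kind
    loom_resp <- rowMeans(M[, kinds == "loom", drop = FALSE])
    dim_resp <- rowMeans(M[, kinds == "dim", drop = FALSE])
    chk_resp <- rowMeans(M[, kinds == "checkerboard", drop = FALSE])
    expect_lt(max(abs(loom_resp - (dim_resp + chk_resp)) / loom_resp), 0.25)
  }
  expect_gte(ends_at_three, 2)
})

test_that("clustering outputs round-trip through the interchange files", {
  cfg <- cohort_config(n_fish = 6, rois_per_fish = 100,
                       protocol = "imaging2_sequence", amplitude = 5,
                       decay_range = c(0, 0.1),
                       class_mix = c(dim = 0.08, checker = 0.22,
                                     both = 0.10, none = 0.60))
  co <- generate_cohort(cfg, seed = 4)
  res <- analyze_clusters(co, k = 6, replicates = 3, seed = 4, min_size = 15)
  keep <- res$selection$responsive
  rc <- region_composition(res$selection$responsive, co$rois$class,
                           co$rois$region, co$rois$fish_id)
  dir <- tempfile()
  save_clusters(res, dir, composition = rc)
  back <- read.csv(file.path(dir, "clusters.csv"))
  expect_equal(nrow(back), sum(keep))
  expect_true(file.exists(file.path(dir, "validity.json")))
  comp <- read.csv(file.path(dir, "region_composition.csv"))
  expect_equal(comp$prop_responsive,
               unname(rc$prop_responsive[comp$region]))
  unlink(dir, recursive = TRUE)
})
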
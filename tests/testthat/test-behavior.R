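test_that("movement classification partitions speeds at the stated bounds", {
  expect_equal(as.character(classify_movement(c(0.3, 12, 45))),
               c("drift", "scoot", "escape"))
  # closed scoot interval: both bounds are scoots, drift bound is strict
  expect_equal(as.character(classify_movement(c(0.5, 30))),
               c("scoot", "scoot"))
  expect_equal(as.character(classify_movement(0.499999)), "drift")
  expect_equal(as.character(classify_movement(30.00001)), "escape")
  set.seed(1)
  speeds <- c(0, runif(500, 0, 60))
  cls <- classify_movement(speeds)
  expect_false(anyNA(cls))  # every speed maps to exactly one class
  expect_error(classify_movement(-1), ">= 0")
})

test_that("never-escaping fish are excluded", {
  rec <- data.frame(fish_id = rep(1:3, each = 4), second = rep(0:3, 3),
                    distance_mm = c(rep(1, 4), c(1, 40, 1, 1), rep(29, 4)))
  out <- filter_fish(rec)
  expect_equal(sort(unique(out$fish_id)), 2)
  expect_warning(empty <- filter_fish(rec[rec$fish_id != 2, ]),
                 "no fish retained")
  expect_equal(nrow(empty), 0)
  expect_error(filter_fish(rec[0, ]), "empty")
})

test_that("escape probability counts fish with escapes in the window", {
  tr <- build_train("imaging1_loom")  # onsets 30, 70, ...
  mk <- function(fish, sec) data.frame(fish_id = fish, second = sec,
                                       distance_mm = 50)
  base <- expand.grid(fish_id = 1:12, second = 0:629)
  base$distance_mm <- 0.1
  esc <- mk(1:6, 31)  # 6 of 12 fish escape to stimulus 1
  rec <- rbind(base, esc)
  curve <- escape_probability(rec, tr)
  expect_equal(curve$p[1], 0.5)
  expect_equal(curve$p[-1], rep(0, 14))
  expect_equal(curve$n[1], 12)
  # invariant to fish ordering and to bins outside response windows
  rec2 <- rbind(esc, base[sample(nrow(base)), ])
  rec2$distance_mm[rec2$second == 55] <- 60  # escape bin between stimuli
  curve2 <- escape_probability(rec2, tr)
  expect_equal(curve2$p, curve$p)
  expect_error(escape_probability(rec, tr, window_s = 0), "window_s")
  expect_warning(escape_probability(rec, tr, window_s = 100), "overlap")
})

test_that("the ATS habituation test behaves at its degenerate corners", {
  # identical responses at all time points for every fish
  set.seed(4)
  v <- rbinom(15, 1, 0.5)
  res <- test_habituation(cbind(v, v, v))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  # all-constant data
  res0 <- test_habituation(matrix(1, 10, 3))
  expect_equal(res0$p.value, 1)
  expect_error(test_habituation(matrix(1, 1, 3)), "at least 2")
})

test_that("ATS detects complete habituation, agreeing with permutation", {
  x <- cbind(rep(1, 20), rep(0, 20), rep(0, 20))
  res <- test_habituation(x[, 1], x[, 2], x[, 3])
  expect_lt(res$p.value, 0.01)
  expect_lt(ats_perm_oracle(x, B = 500), 0.01)
  # partial effect: F-approximate p tracks the permutation p
  set.seed(7)
  y <- cbind(rbinom(25, 1, 0.9), rbinom(25, 1, 0.45), rbinom(25, 1, 0.45))
  p_f <- test_habituation(y)$p.value
  p_perm <- ats_perm_oracle(y, B = 4000)
  expect_lt(abs(p_f - p_perm), 0.03)
})

test_that("Mann-Whitney U matches enumeration and wilcox.test", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p.value, 0.1)  # 2 of the 20 rank assignments as extreme
  expect_equal(mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))$p.value, 1)
  expect_equal(mann_whitney_u(c(5, 7), c(5, 7), n_comparisons = 8)$p.value, 1)
  # exact path vs independent enumeration oracle, with and without ties
  set.seed(11)
  for (rep in 1:5) {
    x <- sample(1:6, 4, replace = TRUE)
    y <- sample(1:6, 5, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p.value, mw_enum_oracle(x, y))
  }
  # tie-free exact agrees with wilcox.test's exact p
  x <- c(1.2, 3.4, 5.1, 8.3); y <- c(2.2, 4.9, 9.1, 10.2, 11.5)
  expect_equal(mann_whitney_u(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  # large samples: tie-corrected normal approximation matches wilcox.test
  set.seed(2)
  xl <- sample(1:10, 30, replace = TRUE); yl <- sample(2:11, 25, replace = TRUE)
  expect_equal(mann_whitney_u(xl, yl)$p.value,
               wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # Bonferroni: multiplication capped at 1
  m <- mann_whitney_u(c(1, 2, 3, 4, 10), c(5, 6, 7, 8, 9), n_comparisons = 8)
  expect_equal(m$p.bonferroni, min(1, m$p.value * 8))
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("escape decay fit recovers exact and degenerate curves", {
  k <- 1:20
  fit <- fit_escape_decay(0.9 * exp(-0.2 * k))
  expect_equal(fit$Y0, 0.9, tolerance = 1e-6)
  expect_equal(fit$K, 0.2, tolerance = 1e-6)
  z <- fit_escape_decay(rep(0, 20))
  expect_equal(z$Y0, 0)
  expect_false(z$identifiable)
  # linear probe-block fit on indices 21-30 only
  p <- c(0.9 * exp(-0.2 * k), seq(0.8, 0.8 - 9 * 0.01, by = -0.01))
  f2 <- fit_escape_decay(p)
  expect_equal(f2$slope, -0.01, tolerance = 1e-8)
  expect_equal(unname(coef(f2)["K"]), f2$K)
  expect_error(fit_escape_decay(c(0.5, 0.4)), "at least 4")
})

test_that("noisy binomial escape curves recover the decay rate", {
  set.seed(21)
  k <- 1:20
  truth <- 0.85 * exp(-0.3 * k)
  p_obs <- rbinom(20, 100, truth) / 100
  fit <- fit_escape_decay(p_obs)
  expect_lt(abs(fit$K - 0.3) / 0.3, 0.25)
})

test_that("behavior analysis writes its interchange files", {
  tr <- build_train("behavior_loom", seed = 3)
  beh <- generate_behavior(12, tr, seed = 3)
  res <- analyze_behavior(beh, tr)
  dir <- tempfile()
  save_behavior_analysis(res, dir)
  curve <- read.csv(file.path(dir, "escape_curve.csv"))
  expect_equal(curve$p, res$curve$p)
  stats <- jsonlite::read_json(file.path(dir, "stats.json"),
                               simplifyVector = TRUE)
  expect_equal(stats$fit$K, res$fit$K)
  unlink(dir, recursive = TRUE)
})
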
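test_that("listwise exclusion drops exactly the records with missing items", {
  # 518 raw records, 15 of them incomplete
  set.seed(4)
  raw <- matrix(sample(0:3, 518 * 5, replace = TRUE), 518, 5,
                dimnames = list(NULL, paste0("q", 1:5)))
  raw[sample(518, 15), 3] <- NA
  out <- exclude_incomplete(raw)
  expect_equal(nrow(out$responses), 503)
  expect_equal(out$n_excluded, 15)
  expect_equal(out$pct_excluded, 2.9)

  complete <- matrix(rep(1:0, 25), 10, 5, dimnames = list(NULL, paste0("q", 1:5)))
  out2 <- exclude_incomplete(complete)
  expect_equal(out2$n_excluded, 0)
  expect_equal(out2$pct_excluded, 0.0)

  # one record missing a single item, one missing everything
  part <- rbind(c(0, 1), c(NA, 2), c(NA, NA), c(3, 3))
  colnames(part) <- c("a", "b")
  out3 <- exclude_incomplete(part)
  expect_equal(nrow(out3$responses), 2)
  expect_equal(out3$pct_excluded, 50.0)

  expect_error(exclude_incomplete(matrix(NA_real_, 3, 2)),
               class = "empty_dataset")
  expect_error(exclude_incomplete(matrix(c(0, 5), 1, 2)),
               class = "validation_error")
})

test_that("prevalence counts scores >= 1 and rounds half away from zero", {
  m <- matrix(0L, 503, 2, dimnames = list(NULL, c("weak", "zero")))
  m[1:358, "weak"] <- 1L
  p <- item_prevalence(m, "weak")
  expect_equal(p$count, 358)
  expect_equal(p$pct, 71.2)
  expect_equal(item_prevalence(m, "zero"), list(count = 0L, pct = 0))
  expect_error(item_prevalence(m, "nope"), class = "missing_item")

  # half-away-from-zero, not banker's rounding
  expect_equal(round_half_away(0.25, 1), 0.3)
  expect_equal(round_half_away(-0.25, 1), -0.3)
  expect_equal(prevalence_pct(1, 8), 12.5)
  # printed-percentage fixtures: count/N pairs reproduce the published table
  pairs <- list(c(358, 503, 71.2), c(330, 503, 65.6), c(322, 503, 64.0),
                c(298, 503, 59.2), c(382, 503, 75.9), c(351, 503, 69.8),
                c(231, 503, 45.9), c(15, 518, 2.9), c(393, 431, 91.2),
                c(498, 503, 99.0), c(463, 503, 92.0), c(54, 503, 10.7))
  for (p in pairs) expect_equal(prevalence_pct(p[1], p[2]), p[3])
})

test_that("severity uses the sample (N-1) standard deviation", {
  m <- cbind(const = rep(2L, 6), two = c(0L, 3L, 0L, 3L, 0L, 3L),
             toy = c(0L, 1L, 1L, 2L, 3L, 3L))
  s <- item_severity(m, "const")
  expect_equal(s$mean, 2.0)
  expect_equal(s$sd, 0.0)
  s2 <- item_severity(m[1:2, ], "two")
  expect_equal(s2$mean, 1.5)
  expect_equal(s2$sd, sqrt((1.5^2 + 1.5^2) / 1))  # two-point closed form
  # 6-value toy column against hand-computed moments
  x <- c(0, 1, 1, 2, 3, 3)
  s3 <- item_severity(m, "toy")
  expect_equal(s3$mean, sum(x) / 6)
  expect_equal(s3$sd, sqrt(sum((x - mean(x))^2) / 5))
  expect_error(item_severity(m[1, , drop = FALSE], "toy"),
               class = "insufficient_data")
})

test_that("cluster composites are sums with any-member prevalence", {
  inst <- toy_instrument()
  m <- toy_responses(n = 6, seed = 2)
  comp <- cluster_score(m, inst, "alpha")
  expect_equal(comp, as.integer(m[, "q1"] + m[, "q2"] + m[, "q3"]))
  zero <- matrix(0L, 3, 6, dimnames = list(NULL, paste0("q", 1:6)))
  zero[1, ] <- 1L  # keep one prevalent row
  expect_equal(cluster_score(zero, inst, "alpha"), c(3L, 0L, 0L))
  # all scores 3 on a 3-item cluster -> composite 9 = 3k
  all3 <- matrix(3L, 2, 6, dimnames = list(NULL, paste0("q", 1:6)))
  expect_equal(cluster_score(all3, inst, "alpha"), c(9L, 9L))
  expect_error(cluster_score(m, inst, "gamma"), class = "invalid_config")

  cp <- cluster_prevalence(zero, inst, "alpha")
  expect_equal(cp$count, 1)
  expect_equal(cp$pct, 33.3)
  # singleton-style reduction: a cluster member alone
  single <- instrument_config(
    data.frame(id = c("a", "b"), label = c("A", "B")),
    clusters = list(solo = "a"), standalone = "b")
  m2 <- cbind(a = c(0L, 1L, 2L, 0L), b = c(1L, 0L, 3L, 2L))
  expect_equal(cluster_prevalence(m2, single, "solo"),
               item_prevalence(m2, "a"))
})

test_that("cluster prevalence dominates member-item prevalence", {
  inst <- toy_instrument()
  for (seed in 1:5) {
    m <- toy_responses(n = 40, seed = seed)
    for (cl in names(inst$clusters)) {
      cp <- cluster_prevalence(m, inst, cl)$pct
      for (it in inst$clusters[[cl]]) {
        expect_gte(cp, item_prevalence(m, it)$pct)
      }
    }
    # mean bounded by prevalence share: scores >= 1 exactly for prevalent rows
    for (it in colnames(m)) {
      pr <- item_prevalence(m, it)$pct / 100
      mu <- item_severity(m, it)$mean
      expect_lte(mu, 3 * pr + 1e-12)
      expect_gte(mu, pr - 1e-12)
    }
  }
})

test_that("cronbach alpha matches a from-scratch variance decomposition", {
  inst <- toy_instrument()
  # 5 participants x 3 items, alpha recomputed independently
  m <- cbind(q1 = c(0L, 1L, 2L, 3L, 1L), q2 = c(1L, 1L, 3L, 2L, 0L),
             q3 = c(0L, 2L, 2L, 3L, 2L), q4 = c(1L, 0L, 2L, 1L, 3L),
             q5 = c(0L, 3L, 1L, 2L, 2L), q6 = c(2L, 1L, 0L, 3L, 1L))
  a <- cronbach_alpha(m, inst, "alpha")
  svar <- function(v) sum((v - mean(v))^2) / (length(v) - 1)
  tot <- m[, "q1"] + m[, "q2"] + m[, "q3"]
  a_oracle <- 3 / 2 * (1 - (svar(m[, "q1"]) + svar(m[, "q2"]) + svar(m[, "q3"])) / svar(tot))
  expect_equal(a, a_oracle, tolerance = 1e-12)

  # identical nonconstant items -> exactly 1
  dup <- cbind(q1 = c(0L, 1L, 2L, 3L), q2 = c(0L, 1L, 2L, 3L),
               q3 = c(0L, 1L, 2L, 3L), q4 = 0:3, q5 = 0:3, q6 = 0:3)
  expect_equal(cronbach_alpha(dup, inst, "alpha"), 1.0)

  # pairwise-independent items with equal variances -> alpha near 0
  set.seed(9)
  big <- matrix(sample(0L:3L, 3 * 20000, replace = TRUE), 20000, 3,
                dimnames = list(NULL, c("q1", "q2", "q3")))
  big <- cbind(big, q4 = 0L, q5 = 0L, q6 = 0L)
  big[1:2, 4:6] <- 1L
  expect_lt(abs(cronbach_alpha(big, inst, "alpha")), 0.05)

  # invariant under adding a constant to every item
  expect_equal(cronbach_alpha(m + 2L, inst, "alpha"),
               cronbach_alpha(m, inst, "alpha"))

  const <- matrix(1L, 5, 6, dimnames = list(NULL, paste0("q", 1:6)))
  expect_error(cronbach_alpha(const, inst, "alpha"), class = "undefined_alpha")
})

test_that("score_responses assembles the published-table shape", {
  inst <- toy_instrument()
  m <- toy_responses(n = 25, seed = 3)
  tab <- score_responses(m, inst)
  expect_equal(sum(tab$type == "item"), 6)
  expect_equal(sum(tab$type == "cluster"), 2)
  expect_true(all(tab$pct >= 0 & tab$pct <= 100))
  expect_true(all(is.na(tab$alpha[tab$type == "item"])))
  a_row <- tab[tab$node == "alpha", ]
  expect_equal(a_row$mean, mean(cluster_score(m, inst, "alpha")))
  expect_equal(a_row$count, cluster_prevalence(m, inst, "alpha")$count)
})
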
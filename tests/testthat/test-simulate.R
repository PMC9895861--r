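test_that("latent thresholds are normal quantiles of cumulative marginals", {
  cuts <- thresholds_from_marginals(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(cuts[2], 0)            # symmetry of the normal
  expect_equal(cuts[1], -cuts[3])
  expect_equal(thresholds_from_marginals(c(1, 0, 0, 0)), rep(Inf, 3))
  # frozen high-precision quantile oracle values
  expect_equal(thresholds_from_marginals(c(0.288, 0.312, 0.25, 0.15)),
               c(-0.559236977611907, 0.253347103135800, 1.036433389493789),
               tolerance = 1e-12)
  # zero-probability middle category -> coincident cutpoints
  cuts0 <- thresholds_from_marginals(c(0.3, 0, 0.4, 0.3))
  expect_equal(cuts0[1], cuts0[2])
  expect_error(thresholds_from_marginals(c(0.5, 0.6, 0, 0)),
               class = "invalid_marginal")
  expect_error(thresholds_from_marginals(c(-0.1, 0.6, 0.3, 0.2)),
               class = "invalid_marginal")
})

test_that("marginal inversion satisfies both moment constraints", {
  expect_equal(marginal_to_categories(0, 0), c(1, 0, 0, 0))
  expect_equal(marginal_to_categories(100, 3), c(0, 0, 0, 1))
  # published-style target: prevalence 64.0%, mean 1.07
  p <- marginal_to_categories(64.0, 1.07)
  expect_equal(100 * (1 - p[1]), 64.0, tolerance = 1e-9)
  expect_equal(sum(p * 0:3), 1.07, tolerance = 1e-9)
  # frozen geometric-allocation solution, verified at build time against a
  # grid-search oracle over (p1, p2, p3)
  expect_equal(p, c(0.36, 0.327127890120235, 0.195744219759530,
                    0.117127890120235), tolerance = 1e-9)
  # property over a target grid: probabilities valid, moments matched
  for (prev in c(5, 23.9, 50, 78.5, 99)) {
    for (ratio in c(1.01, 1.5, 2.4, 2.95)) {
      mean_sev <- ratio * prev / 100
      q <- marginal_to_categories(prev, mean_sev)
      expect_true(all(q >= 0) && abs(sum(q) - 1) < 1e-9)
      expect_equal(100 * (1 - q[1]), prev, tolerance = 1e-7)
      expect_equal(sum(q * 0:3), mean_sev, tolerance = 1e-7)
    }
  }
  expect_error(marginal_to_categories(10, 0.9), class = "infeasible_marginal")
  expect_error(marginal_to_categories(50, 0.2), class = "infeasible_marginal")
  expect_error(marginal_to_categories(120, 1), class = "infeasible_marginal")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- copula_spec(200, diag(4), c(0.4, 0.3, 0.2, 0.1), seed = 7)
  set.seed(123)
  before <- .Random.seed
  r1 <- generate_responses(spec)
  expect_identical(.Random.seed, before)
  r2 <- generate_responses(spec)
  expect_identical(r1, r2)
  expect_true(all(r1 %in% 0:3))
  # degenerate marginal: every score 0
  spec0 <- copula_spec(50, diag(2), c(1, 0, 0, 0), seed = 1)
  expect_true(all(generate_responses(spec0) == 0))
})

test_that("copula spec validates its matrix and marginals", {
  bad_sym <- matrix(c(1, 0.2, 0.3, 1), 2, 2)
  expect_error(copula_spec(10, bad_sym, c(0.25, 0.25, 0.25, 0.25), 1),
               class = "invalid_spec")
  not_psd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(copula_spec(10, not_psd, c(0.25, 0.25, 0.25, 0.25), 1),
               class = "not_psd")
  expect_warning(
    sp <- copula_spec(10, not_psd, c(0.25, 0.25, 0.25, 0.25), 1, repair = TRUE),
    "repaired"
  )
  ev <- eigen(sp$latent_corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(sp$latent_corr), rep(1, 3), ignore_attr = TRUE)
})

test_that("column marginals converge to the specified category probabilities", {
  spec <- calibrate_spec(n_participants = 50000, seed = 31)
  resp <- generate_responses(spec)
  for (j in seq_len(ncol(resp))) {
    freq <- tabulate(resp[, j] + 1L, nbins = 4) / nrow(resp)
    expect_lt(max(abs(freq - spec$category_probs[j, ])), 0.01)
  }
})

test_that("empirical Spearman rho is monotone in the latent correlation", {
  rhos <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(latent) {
    m <- matrix(c(1, latent, latent, 1), 2, 2)
    spec <- copula_spec(20000, m, c(0.25, 0.25, 0.25, 0.25), seed = 5)
    r <- generate_responses(spec)
    spearman_rho(r[, 1], r[, 2])
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_lt(abs(rhos[1]), 0.05)  # independence
})

test_that("copula association matches an independent Monte-Carlo oracle", {
  # oracle: direct bivariate-normal thresholding, 1e6 draws, written from
  # first principles (no copula_spec machinery)
  set.seed(2024)
  n_mc <- 1e6
  cuts <- qnorm(c(0.25, 0.5, 0.75))
  z1 <- rnorm(n_mc)
  z2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * rnorm(n_mc)
  rho_oracle <- cor(findInterval(z1, cuts), findInterval(z2, cuts),
                    method = "spearman")

  m <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  spec <- copula_spec(50000, m, c(0.25, 0.25, 0.25, 0.25), seed = 17)
  r <- generate_responses(spec)
  expect_equal(spearman_rho(r[, 1], r[, 2]), rho_oracle, tolerance = 0.03)
})

test_that("a pair with the largest latent correlation has the largest empirical rho", {
  corr <- diag(6)
  corr[1, 2] <- corr[2, 1] <- 0.95
  spec <- copula_spec(10000, corr, c(0.25, 0.25, 0.25, 0.25), seed = 3)
  r <- generate_responses(spec)
  rho <- cor(r, method = "spearman")
  off <- abs(rho[upper.tri(rho)])
  expect_equal(max(off), abs(rho[1, 2]))
  # the independent pairs stay near zero
  expect_lt(sort(off, decreasing = TRUE)[2], 0.05)
})

test_that("plant_hub rewires the latent matrix and validates its design", {
  spec <- copula_spec(100, diag(5), c(0.25, 0.25, 0.25, 0.25), seed = 1)
  hub <- plant_hub(spec, 2, hub_corr = 0.6, background_corr = 0.2)
  expect_equal(unname(hub$latent_corr[2, -2]), rep(0.6, 4))
  expect_equal(unname(hub$latent_corr[1, 3]), 0.2)
  expect_error(plant_hub(spec, 1, 0.3, 0.3), class = "invalid_design")
  expect_error(plant_hub(spec, 1, 0.3, -0.1), class = "invalid_design")
  expect_error(plant_hub(spec, "nope", 0.5, 0.1), class = "missing_item")
})

test_that("a hub at zero background has ~4x the strength of spokes (5 items)", {
  spec <- copula_spec(50000, diag(5), c(0.25, 0.25, 0.25, 0.25), seed = 23)
  hub <- suppressWarnings(plant_hub(spec, 3, hub_corr = 0.5, background_corr = 0))
  net <- symptom_network(generate_responses(hub))
  s <- node_strength(net)
  ratio <- s[3] / mean(s[-3])
  expect_equal(unname(ratio), 4, tolerance = 0.08)
})

test_that("the planted hub is the top-strength node in >= 18 of 20 replicates", {
  hits <- 0
  for (seed in 1:20) {
    spec <- copula_spec(2000, diag(10), c(0.25, 0.25, 0.25, 0.25), seed = seed)
    # hub 0.7 over background 0.2 is slightly indefinite by design; the
    # documented nearest-PSD repair applies
    hub <- suppressWarnings(plant_hub(spec, 4, hub_corr = 0.7,
                                      background_corr = 0.2))
    net <- symptom_network(generate_responses(hub))
    s <- node_strength(net)
    hits <- hits + (which.max(s) == 4)
  }
  expect_gte(hits, 18)
})

test_that("copula specs round-trip through JSON and YAML", {
  spec <- calibrate_spec(n_participants = 41, seed = 9)
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    write_copula_spec(spec, path)
    back <- read_copula_spec(path)
    expect_equal(back$latent_corr, spec$latent_corr)
    expect_equal(back$category_probs, spec$category_probs)
    expect_identical(generate_responses(back), generate_responses(spec))
  }
})
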
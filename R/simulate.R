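# Gaussian-copula generator for correlated 0-3 ordinal questionnaire data.
#
# A latent multivariate normal vector with unit variances and a specified
# correlation matrix is thresholded item-by-item at the standard-normal
# quantiles of the cumulative category probabilities. Marginals and
# association structure are therefore controlled independently: the
# thresholds fix each item's category distribution, the latent correlation
# fixes the (monotone) inter-item association.

#' Copula specification for synthetic ordinal responses
#'
#' @param n_participants Positive integer, number of records to generate.
#' @param latent_corr Symmetric correlation matrix over items: unit diagonal,
#'   positive semidefinite (eigenvalues >= -1e-10 tolerated). Column names,
#'   if present, become the item IDs.
#' @param category_probs Numeric matrix (items x 4) or a single length-4
#'   vector recycled to all items; each row gives the probabilities of
#'   scores 0, 1, 2, 3 and must sum to 1.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#' @param repair If `TRUE`, a latent matrix with slightly negative
#'   eigenvalues is projected to the nearest positive-semidefinite
#'   correlation matrix (with a warning); if `FALSE`, such input is an error.
#' @return An object of class `copula_spec`.
#' @export
#' @examples
#' spec <- copula_spec(100, diag(3), c(0.4, 0.3, 0.2, 0.1), seed = 1)
#' head(generate_responses(spec))
copula_spec <- function(n_participants, latent_corr, category_probs, seed,
                        repair = FALSE) {
  n_participants <- as.integer(n_participants)
  stopifnot(n_participants >= 1L)
  latent_corr <- as.matrix(latent_corr)
  p <- ncol(latent_corr)
  if (nrow(latent_corr) != p) {
    stop_symptomnet("latent_corr must be square", "invalid_spec")
  }
  if (max(abs(latent_corr - t(latent_corr))) > 1e-12) {
    stop_symptomnet("latent_corr must be symmetric", "invalid_spec")
  }
  if (max(abs(diag(latent_corr) - 1)) > 1e-12) {
    stop_symptomnet("latent_corr must have unit diagonal", "invalid_spec")
  }
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    if (!repair) {
      stop_symptomnet(
        sprintf("latent_corr is not positive semidefinite (min eigenvalue %.3g)",
                min(ev)),
        "not_psd"
      )
    }
    latent_corr <- nearest_psd_corr(latent_corr)
  }
  if (is.null(colnames(latent_corr))) {
    colnames(latent_corr) <- rownames(latent_corr) <- paste0("item", seq_len(p))
  }
  if (is.vector(category_probs)) {
    category_probs <- matrix(category_probs, nrow = p, ncol = 4, byrow = TRUE)
  }
  category_probs <- as.matrix(category_probs)
  if (ncol(category_probs) != 4 || nrow(category_probs) != p) {
    stop_symptomnet("category_probs must be items x 4", "invalid_marginal")
  }
  apply(category_probs, 1, validate_marginal)
  rownames(category_probs) <- colnames(latent_corr)
  structure(
    list(n_participants = n_participants,
         latent_corr = latent_corr,
         category_probs = category_probs,
         seed = as.integer(seed)),
    class = "copula_spec"
  )
}

validate_marginal <- function(probs) {
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop_symptomnet("category probabilities must be nonnegative and sum to 1",
                    "invalid_marginal")
  }
  invisible(probs)
}

#' Latent thresholds from category probabilities
#'
#' The three latent cutpoints of an item are the standard-normal quantiles
#' of the cumulative probabilities `p0`, `p0+p1`, `p0+p1+p2`. A
#' zero-probability category yields coincident cutpoints; a degenerate
#' marginal yields infinite ones.
#'
#' @param probs Length-4 probabilities of scores 0-3, summing to 1.
#' @return Nondecreasing numeric vector of 3 cutpoints.
#' @export
#' @examples
#' thresholds_from_marginals(c(0.25, 0.25, 0.25, 0.25))[2] # exactly 0
thresholds_from_marginals <- function(probs) {
  validate_marginal(probs)
  stats::qnorm(pmin(cumsum(probs)[1:3], 1))
}

#' Category probabilities from prevalence and mean severity
#'
#' Inverts a (prevalence, mean) marginal target into four category
#' probabilities: `p0` is fixed by prevalence (share of scores >= 1) and the
#' mean pins one more moment. The remaining degree of freedom is resolved by
#' allocating the positive-score mass in geometric proportion
#' `p1 : p2 : p3 = w : w^2 : w^3`, with `w > 0` solved from the mean
#' constraint; when no finite `w` applies (mean at either feasibility
#' boundary, or numerically unreachable) the mass falls back to a two-point
#' split over scores {1, 3}.
#'
#' @param prevalence_pct Percentage of participants scoring >= 1, in
#'   `[0, 100]`.
#' @param mean_severity Target item mean in `[0, 3]`. Feasibility requires
#'   `prevalence/100 <= mean <= 3 * prevalence/100`.
#' @return Length-4 probability vector over scores 0-3.
#' @export
#' @examples
#' marginal_to_categories(64.0, 1.07)
marginal_to_categories <- function(prevalence_pct, mean_severity) {
  if (prevalence_pct < 0 || prevalence_pct > 100 ||
      mean_severity < 0 || mean_severity > 3) {
    stop_symptomnet("marginal target out of range", "infeasible_marginal")
  }
  m <- prevalence_pct / 100
  tol <- 1e-9
  if (mean_severity > 3 * m + tol || mean_severity < m - tol) {
    stop_symptomnet(
      "mean severity incompatible with prevalence (needs prev/100 <= mean <= 3*prev/100)",
      "infeasible_marginal"
    )
  }
  if (m < tol) return(c(1, 0, 0, 0))
  ratio <- min(max(mean_severity / m, 1), 3)
  if (ratio <= 1 + tol) return(c(1 - m, m, 0, 0))
  if (ratio >= 3 - tol) return(c(1 - m, 0, 0, m))
  # (1 + 2w + 3w^2) / (1 + w + w^2) is increasing from 1 to 3 on w > 0
  w <- tryCatch(
    stats::uniroot(function(w) (1 + 2 * w + 3 * w^2) / (1 + w + w^2) - ratio,
                   c(1e-12, 1e8), tol = 1e-12)$root,
    error = function(e) NA_real_
  )
  if (is.na(w)) {
    p3 <- (mean_severity - m) / 2
    p <- c(1 - m, m - p3, 0, p3)
  } else {
    pos <- m * w^(1:3) / sum(w^(1:3))
    p <- c(1 - m, pos)
  }
  validate_marginal(p)
  p
}

# Nearest positive-semidefinite correlation matrix: clip negative
# eigenvalues at zero, then rescale to unit diagonal. Warns with the
# Frobenius distance moved.
nearest_psd_corr <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  warning(sprintf("latent matrix repaired to nearest PSD (Frobenius distance %.3g)",
                  sqrt(sum((out - m)^2))))
  out
}

#' Generate synthetic ordinal responses
#'
#' Draws from the Gaussian copula defined by a [copula_spec()]: latent
#' multivariate-normal rows are thresholded per item at the cutpoints from
#' [thresholds_from_marginals()]. Byte-identical output for identical specs;
#' the caller's RNG state is left untouched.
#'
#' @param spec A `copula_spec`.
#' @return Integer matrix (`n_participants` x items) with entries in 0-3 and
#'   item IDs as column names.
#' @export
generate_responses <- function(spec) {
  stopifnot(inherits(spec, "copula_spec"))
  p <- ncol(spec$latent_corr)
  e <- eigen(spec$latent_corr, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- with_local_seed(spec$seed,
    matrix(stats::rnorm(spec$n_participants * p), spec$n_participants, p)
  )
  x <- z %*% root
  scores <- vapply(seq_len(p), function(j) {
    cuts <- thresholds_from_marginals(spec$category_probs[j, ])
    findInterval(x[, j], cuts)
  }, integer(spec$n_participants))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- colnames(spec$latent_corr)
  scores
}

#' Plant a hub item in a copula specification
#'
#' Returns a spec whose latent correlation is exchangeable at
#' `background_corr` except that the hub item correlates at `hub_corr` with
#' every other item. Used for centrality-recovery experiments: the hub
#' should surface as the most central node of the estimated network.
#'
#' @param spec A `copula_spec` (its marginals, n and seed are kept).
#' @param hub_item Item ID or index of the hub.
#' @param hub_corr Latent correlation between the hub and every other item.
#' @param background_corr Latent correlation between all non-hub pairs;
#'   must be strictly below `hub_corr` and nonnegative.
#' @return A new `copula_spec` (repaired to nearest PSD if needed).
#' @export
plant_hub <- function(spec, hub_item, hub_corr, background_corr) {
  stopifnot(inherits(spec, "copula_spec"))
  if (!(hub_corr > background_corr) || background_corr < 0) {
    stop_symptomnet("need hub_corr > background_corr >= 0", "invalid_design")
  }
  items <- colnames(spec$latent_corr)
  idx <- if (is.character(hub_item)) match(hub_item, items) else as.integer(hub_item)
  if (is.na(idx) || idx < 1 || idx > length(items)) {
    stop_symptomnet("unknown hub item", "missing_item")
  }
  p <- length(items)
  m <- matrix(background_corr, p, p)
  m[idx, ] <- m[, idx] <- hub_corr
  diag(m) <- 1
  dimnames(m) <- dimnames(spec$latent_corr)
  copula_spec(spec$n_participants, m, spec$category_probs, spec$seed,
              repair = TRUE)
}

#' Calibrate a copula specification to published marginals
#'
#' Builds a generator spec whose item marginals match given prevalence /
#' mean-severity targets (via [marginal_to_categories()]) and whose latent
#' correlation has a dense positive block structure: `within` correlation
#' for item pairs sharing a cluster, `between` for all other pairs. The
#' defaults emulate the high internal consistency (alpha > 0.85 per
#' subscale) and large overall network density characteristic of mental
#' health symptom data.
#'
#' @param targets data.frame with columns `id`, `prevalence_pct`,
#'   `severity_mean` (defaults to the packaged [reference_marginals()]).
#' @param instrument An [instrument_config()] supplying the cluster blocks;
#'   default [mh_instrument()].
#' @param n_participants Number of records (default 503).
#' @param seed Integer seed.
#' @param within,between Latent correlations inside and across cluster
#'   blocks (defaults 0.65 and 0.35). Standalone items use `between` with
#'   every other item.
#' @return A `copula_spec`.
#' @export
calibrate_spec <- function(targets = reference_marginals(),
                           instrument = mh_instrument(),
                           n_participants = 503, seed = 1,
                           within = 0.65, between = 0.35) {
  ids <- instrument$items$id
  targets <- targets[match(ids, targets$id), ]
  if (anyNA(targets$id)) {
    stop_symptomnet("targets must cover every instrument item", "invalid_config")
  }
  probs <- t(vapply(seq_len(nrow(targets)), function(i) {
    marginal_to_categories(targets$prevalence_pct[i], targets$severity_mean[i])
  }, numeric(4)))
  block <- rep("", length(ids))
  for (cl in names(instrument$clusters)) {
    block[ids %in% instrument$clusters[[cl]]] <- cl
  }
  same <- outer(block, block, "==") & block != ""
  corr <- matrix(between, length(ids), length(ids))
  corr[same] <- within
  diag(corr) <- 1
  dimnames(corr) <- list(ids, ids)
  copula_spec(n_participants, corr, probs, seed)
}

#' Read or write a copula specification
#'
#' JSON (or YAML, by extension) serialization of the full generative spec:
#' sample size, latent correlation matrix, per-item category probabilities
#' and seed.
#'
#' @param spec A `copula_spec` (for writing).
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_copula_spec()` returns a `copula_spec`; `write_copula_spec()`
#'   returns `path` invisibly.
#' @export
write_copula_spec <- function(spec, path) {
  obj <- list(
    n_participants = spec$n_participants,
    items = colnames(spec$latent_corr),
    latent_corr = unname(apply(spec$latent_corr, 1, as.numeric, simplify = FALSE)),
    category_probs = unname(apply(spec$category_probs, 1, as.numeric, simplify = FALSE)),
    seed = spec$seed
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 15)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_copula_spec
#' @export
read_copula_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  corr <- as_mat(obj$latent_corr)
  items <- as.character(unlist(obj$items))
  dimnames(corr) <- list(items, items)
  probs <- as_mat(obj$category_probs)
  copula_spec(obj$n_participants, corr, probs, obj$seed)
}

#' @export
print.copula_spec <- function(x, ...) {
  cat("Gaussian copula spec:", x$n_participants, "participants x",
      ncol(x$latent_corr), "items, seed", x$seed, "\n")
  off <- x$latent_corr[upper.tri(x$latent_corr)]
  cat(sprintf("latent correlations: min %.2f, mean %.2f, max %.2f\n",
              min(off), mean(off), max(off)))
  invisible(x)
}
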
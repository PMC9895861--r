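# Independent brute-force oracles. Deliberately naive implementations --
# explicit loops and first-principles formulas -- so they share no code path
# with the package.

# Mid-rank Spearman: ranks computed by counting, Pearson by raw sum formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  a <- midrank(x); b <- midrank(y); n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  num / den
}

# Floyd-Warshall all-pairs shortest paths on distances d = 1/|w|.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w == 0, Inf, 1 / abs(w))
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Enumerate every simple path between two nodes; return list of
# (length, intermediate nodes) for geodesics only.
oracle_geodesics <- function(w, s, t, tol = 1e-9) {
  n <- nrow(w)
  best <- list(len = Inf, paths = list())
  walk <- function(v, visited, len) {
    if (len > best$len * (1 + tol)) return()
    if (v == t) {
      if (len < best$len * (1 - tol)) {
        best$len <<- len
        best$paths <<- list(setdiff(visited, c(s, t)))
      } else if (len <= best$len * (1 + tol)) {
        best$len <<- min(best$len, len)
        best$paths <<- c(best$paths, list(setdiff(visited, c(s, t))))
      }
      return()
    }
    for (u in seq_len(n)) {
      if (w[v, u] != 0 && !(u %in% visited)) {
        walk(u, c(visited, u), len + 1 / abs(w[v, u]))
      }
    }
  }
  walk(s, s, 0)
  best
}

# Betweenness, closeness and strength from exhaustive enumeration.
oracle_centrality <- function(w) {
  n <- nrow(w)
  strength <- sapply(seq_len(n), function(i) sum(abs(w[i, -i])))
  d <- oracle_distances(w)
  closeness <- sapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    nr <- sum(reach)
    (nr / sum(di[reach])) * (nr / (n - 1))
  })
  btw <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        geo <- oracle_geodesics(w, s, t)
        if (!is.finite(geo$len) || length(geo$paths) == 0) next
        sigma <- length(geo$paths)
        for (v in seq_len(n)) {
          if (v == s || v == t) next
          through <- sum(vapply(geo$paths, function(p) v %in% p, logical(1)))
          btw[v] <- btw[v] + through / sigma
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  list(strength = strength, closeness = closeness, betweenness = btw)
}

# Wrap an arbitrary symmetric weight matrix as a fitted network object so
# centrality/layout functions can be exercised on hand-built graphs.
make_net <- function(rho, level = "symptom", n = 100) {
  if (is.null(rownames(rho))) {
    dimnames(rho) <- list(letters[seq_len(ncol(rho))],
                          letters[seq_len(ncol(rho))])
  }
  diag(rho) <- 1
  structure(
    list(rho = rho, nodes = rownames(rho), labels = rownames(rho),
         level = level, n = n, dropped = character(),
         min_abs_weight = 0, category_freq = NULL, call = NULL),
    class = "symptom_network"
  )
}

# Seeded random weighted graph on up to max_n nodes: some edges absent,
# weights in [-1, 1] \ {0}.
random_graph <- function(seed, max_n = 8) {
  set.seed(seed)
  n <- sample(4:max_n, 1)
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < 0.7) {
        sign <- if (runif(1) < 0.85) 1 else -1
        w[i, j] <- w[j, i] <- sign * runif(1, 0.1, 1)
      }
    }
  }
  w
}

# Small toy instrument: 2 clusters (3 + 2 items) and 1 standalone item.
toy_instrument <- function() {
  instrument_config(
    items = data.frame(id = paste0("q", 1:6), label = paste("Item", 1:6)),
    clusters = list(alpha = c("q1", "q2", "q3"), beta = c("q4", "q5")),
    standalone = "q6"
  )
}

toy_responses <- function(n = 30, seed = 11, items = paste0("q", 1:6)) {
  set.seed(seed)
  m <- matrix(sample(0:3, n * length(items), replace = TRUE), n,
              dimnames = list(NULL, items))
  # guarantee nonconstant columns
  m[1, ] <- 0L
  m[2, ] <- 3L
  m
}
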
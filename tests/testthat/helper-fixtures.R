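# shared fixtures and independent oracles

# three-formula toy network used across modules
tiny_edges <- function() {
  data.frame(
    target_id = c("f1", "f1", "f2"),
    attribute_type = c("herb", "symptom", "herb"),
    attribute_id = c("h1", "s1", "h1"),
    weight = c(1, 2, 1),
    stringsAsFactors = FALSE
  )
}

tiny_net <- function() star_network(tiny_edges())

expect_distribution <- function(probs, tol = 1e-9) {
  expect_true(all(probs >= 0))
  expect_lt(abs(sum(probs) - 1), tol)
}

# dense-eigendecomposition oracle for the dominant eigenvector of a
# non-negative matrix, L1-normalized with non-negative sign
dense_principal_eigvec <- function(M) {
  e <- eigen(M)
  v <- Re(e$vectors[, which.max(abs(Re(e$values)))])
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sum(v)
}

# plain alternating Rule-1 iteration (Eqs 1-4 with L1 normalization),
# independent of power_iteration
plain_rule1_rank <- function(W, tol = 1e-12, max_iter = 10000) {
  s <- rep(1 / ncol(W), ncol(W))
  f <- rep(1 / nrow(W), nrow(W))
  for (i in seq_len(max_iter)) {
    f_new <- as.vector(W %*% s); f_new <- f_new / sum(f_new)
    s_new <- as.vector(t(W) %*% f_new); s_new <- s_new / sum(s_new)
    if (sum(abs(s_new - s)) + sum(abs(f_new - f)) < tol) {
      return(list(target = f_new, attribute = s_new))
    }
    s <- s_new; f <- f_new
  }
  list(target = f, attribute = s)
}

# brute-force FVIC: explicit set intersections, no tabulation shortcuts
brute_fvic <- function(found, known) {
  N <- length(unlist(known))
  total <- 0
  for (cl in found) {
    best <- 0
    for (cs in known) {
      ol <- length(intersect(cl, cs))
      if (ol > best) best <- ol
    }
    total <- total + best
  }
  total / N
}

# all set partitions of seq_len(n) (Bell-number enumeration)
all_set_partitions <- function(n) {
  if (n == 0) return(list(list()))
  sub <- all_set_partitions(n - 1)
  out <- list()
  for (p in sub) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

# random non-negative bipartite relation with guaranteed positive mass
random_relation <- function(m, n, density = 0.6) {
  W <- matrix(stats::runif(m * n) * (stats::runif(m * n) < density), m, n)
  if (sum(W) == 0) W[1, 1] <- 1
  dimnames(W) <- list(paste0("x", seq_len(m)), paste0("y", seq_len(n)))
  W
}

# random valid cluster_model for EM tests
random_cluster_model <- function(m, n, K) {
  px <- matrix(stats::runif(m * K) + 0.05, m, K)
  py <- matrix(stats::runif(n * K) + 0.05, n, K)
  px <- sweep(px, 2, colSums(px), `/`)
  py <- sweep(py, 2, colSums(py), `/`)
  cluster_model(px, py)
}

# small planted benchmark for loop-level tests (kept light; the acceptance
# tests use the full study conditions)
small_benchmark <- function(noise = 0.05, rng_seed = 1, K = 3,
                            targets_per_cluster = 15, attrs_per_cluster = 8,
                            links_per_type = 4) {
  simulate_star_network(K = K, targets_per_cluster = targets_per_cluster,
                        attrs_per_cluster = attrs_per_cluster,
                        links_per_type = links_per_type, noise = noise,
                        rng_seed = rng_seed)
}

# deterministic draw of a fraction of targets to use as soft seeds
with_seed_select <- function(sim, s, frac = 0.1) {
  set.seed(s)
  sample(names(sim$labels), max(1L, round(frac * length(sim$labels))))
}

run_fvic <- function(sim, K = 3, rng_seed = 1, ...) {
  res <- cluster_star_network(sim$network, K = K, rng_seed = rng_seed, ...)
  fvic(as_partition(res$assignment), sim$truth)
}
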
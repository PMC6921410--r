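test_that("initial partitions are uniform, non-empty, and seed-deterministic", {
  net <- small_benchmark(rng_seed = 1)$network
  a1 <- initialize_partition(net, 1)
  expect_true(all(a1 == 1L))
  m <- length(net$targets)
  amax <- initialize_partition(net, m, rng_seed = 5)
  expect_equal(sort(unname(amax)), seq_len(m))   # perfect matching
  a <- initialize_partition(net, 3, rng_seed = 9)
  b <- initialize_partition(net, 3, rng_seed = 9)
  expect_identical(a, b)
  expect_equal(length(unique(a)), 3)
  expect_error(initialize_partition(net, m + 1), "exceeds")
})

test_that("target embeddings concatenate posterior blocks in schema order", {
  th1 <- matrix(c(0.5, 0.9, 0.5, 0.1), 2, 2,
                dimnames = list(c("f1", "f2"), NULL))
  expect_equal(unname(embed_targets(list(a = th1))), unname(th1))
  th2 <- matrix(c(0.2, 0.3, 0.8, 0.7), 2, 2,
                dimnames = list(c("f1", "f2"), NULL))
  emb <- embed_targets(list(a = th1, b = th2))
  expect_equal(unname(emb["f1", ]), c(0.5, 0.5, 0.2, 0.8))
  bad <- matrix(1, 2, 1, dimnames = list(c("f1", "f2"), NULL))
  expect_error(embed_targets(list(a = th1, b = bad)), "K mismatch")
  # uniform posteriors collapse every embedding to the same point
  u <- matrix(0.5, 2, 2, dimnames = list(c("f1", "f2"), NULL))
  eu <- embed_targets(list(a = u, b = u))
  expect_equal(eu["f1", ], eu["f2", ])
})

test_that("centers are arithmetic means of member embeddings", {
  emb <- rbind(c(1, 0), c(0, 1), c(1, 0))
  rownames(emb) <- c("f1", "f2", "f3")
  a <- stats::setNames(c(1L, 1L, 2L), rownames(emb))
  ctr <- compute_centers(emb, a)
  expect_equal(unname(ctr[1, ]), c(0.5, 0.5))
  expect_equal(unname(ctr[2, ]), c(1, 0))        # singleton
  same <- stats::setNames(c(1L, 2L, 1L), rownames(emb))
  expect_equal(unname(compute_centers(emb, same)[1, ]), c(1, 0))
  expect_error(compute_centers(emb, stats::setNames(c(1L, 1L, 1L),
                                                    rownames(emb)), K = 2),
               "empty")
})

test_that("cosine distance follows its closed form", {
  expect_equal(cosine_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2))
  expect_error(cosine_distance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("assignment picks the nearest center with lowest-index tie-breaking", {
  centers <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  emb <- rbind(f1 = c(0, 0, 1), f2 = c(1, 1, 0))  # f2 equidistant from 1 and 2
  got <- assign_clusters(emb, centers)
  expect_equal(unname(got), c(3L, 1L))
  # planted-block embeddings against planted centers recover the labels
  set.seed(2)
  lab <- rep(1:3, each = 5)
  emb <- t(vapply(lab, function(k) {
    v <- stats::runif(3) * 0.05; v[k] <- 1; v
  }, numeric(3)))
  rownames(emb) <- paste0("f", seq_along(lab))
  got <- assign_clusters(emb, diag(3))
  expect_equal(unname(got), lab)
})

test_that("K = 1 terminates immediately with global rankings", {
  sim <- small_benchmark(rng_seed = 6)
  res <- cluster_star_network(sim$network, K = 1, rng_seed = 1)
  expect_equal(res$diagnostics$outer_iterations, 1L)
  expect_true(all(res$assignment == 1L))
  glob <- res$global_rankings
  for (a in names(glob)) {
    expect_equal(res$cluster_rankings[[1]][[a]]$probs,
                 glob[[a]]$attribute$probs, tolerance = 1e-7)
  }
})

test_that("a noise-free planted network is recovered exactly", {
  sim <- small_benchmark(noise = 0, rng_seed = 3)
  res <- cluster_star_network(sim$network, K = 3, rng_seed = 3)
  expect_equal(fvic(as_partition(res$assignment), sim$truth), 1.0)
  expect_true(res$diagnostics$converged)
  expect_equal(utils::tail(res$diagnostics$assignment_changes, 1), 0L)
  sizes <- tabulate(res$assignment, nbins = 3)
  expect_true(all(sizes > 0))
})

test_that("identical inputs and seed give identical results", {
  sim <- small_benchmark(rng_seed = 10)
  r1 <- cluster_star_network(sim$network, K = 3, rng_seed = 4)
  r2 <- cluster_star_network(sim$network, K = 3, rng_seed = 4)
  expect_identical(r1$assignment, r2$assignment)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$diagnostics$assignment_changes,
                   r2$diagnostics$assignment_changes)
})

test_that("relabeling objects permutes the result without changing accuracy", {
  sim <- small_benchmark(rng_seed = 12)
  base_fvic <- run_fvic(sim, rng_seed = 2)
  # permute edge rows and rename every object id
  e <- sim$network$edges
  set.seed(1)
  e <- e[sample.int(nrow(e)), , drop = FALSE]
  rename_t <- stats::setNames(paste0("T", seq_along(sim$network$targets)),
                              sim$network$targets)
  e$target_id <- unname(rename_t[e$target_id])
  e$attribute_id <- paste0("A_", e$attribute_id)
  net2 <- star_network(e, schema = sim$network$schema,
                       targets = unname(rename_t[sim$network$targets]))
  truth2 <- lapply(sim$truth, function(cl) unname(rename_t[cl]))
  res2 <- cluster_star_network(net2, K = 3, rng_seed = 2)
  expect_equal(fvic(as_partition(res2$assignment), truth2), base_fvic)
})

test_that("degenerate inputs are rejected", {
  net <- tiny_net()
  expect_error(cluster_star_network(net, K = 5), "between 1 and")
  empty <- induced_subnetwork(net, character(0))
  expect_error(cluster_star_network(empty, K = 1), "no edges")
})
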
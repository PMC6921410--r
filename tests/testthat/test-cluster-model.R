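make_dist <- function(probs, ids = paste0("o", seq_along(probs)),
                      type = "t") {
  ranking_distribution(type, ids, probs)
}

test_that("smoothing is the stated convex combination with boundary cases", {
  cond <- make_dist(c(0.5, 0.5))
  glob <- make_dist(c(0.9, 0.1))
  expect_equal(smooth_rank(cond, glob, 1)$probs, glob$probs)
  expect_equal(smooth_rank(cond, glob, 0)$probs, cond$probs)
  expect_equal(unname(smooth_rank(cond, glob, 0.2)$probs), c(0.58, 0.42))
  mism <- make_dist(c(1, 0), ids = c("a", "b"))
  expect_error(smooth_rank(cond, mism, 0.2), "registry mismatch")
  # smoothing floor: smoothed(x) >= lam * global(x)
  set.seed(1)
  for (i in 1:10) {
    p <- stats::runif(6); q <- stats::runif(6)
    cond <- make_dist(p / sum(p)); glob <- make_dist(q / sum(q))
    lam <- stats::runif(1)
    expect_true(all(smooth_rank(cond, glob, lam)$probs >=
                      lam * glob$probs - 1e-12))
  }
})

test_that("K = 1 conditional rankings equal the global rankings", {
  sim <- small_benchmark(rng_seed = 2)
  net <- sim$network
  assign1 <- stats::setNames(rep(1L, length(net$targets)), net$targets)
  cond <- conditional_rankings(net, assign1, 1)
  glob <- rank_network(net)
  for (a in names(cond)) {
    expect_equal(cond[[a]]$attribute$probs, glob[[a]]$attribute$probs,
                 tolerance = 1e-7)
    expect_equal(cond[[a]]$target$probs, glob[[a]]$target$probs,
                 tolerance = 1e-7)
  }
})

test_that("planted-block conditional attribute ranks match manual block extraction", {
  sim <- small_benchmark(noise = 0, rng_seed = 4, K = 2)
  net <- sim$network
  cond <- conditional_rankings(net, sim$labels, 1)
  Ws <- decompose_bipartite(net)
  for (a in names(Ws)) {
    W <- Ws[[a]]
    members <- names(sim$labels)[sim$labels == 1]
    Wk <- W[members, , drop = FALSE]
    Wk <- Wk[, colSums(Wk) > 0, drop = FALSE]
    oracle <- authority_rank(Wk, tol = 1e-12)$attribute$probs
    got <- cond[[a]]$attribute$probs
    expect_lt(sum(abs(got[names(oracle)] - oracle)), 1e-6)
    # attributes outside the block keep rank 0
    expect_equal(unname(got[setdiff(names(got), names(oracle))]),
                 rep(0, sum(!names(got) %in% names(oracle))))
    expect_distribution(got)
    expect_distribution(cond[[a]]$target$probs)
  }
})

test_that("E-step responsibilities normalize and match hand-computed products", {
  W <- matrix(c(1, 0, 2, 1), 2, 2)
  m1 <- cluster_model(matrix(c(0.4, 0.6), 2, 1), matrix(c(0.3, 0.7), 2, 1))
  r1 <- e_step(W, m1)
  expect_true(all(r1[, , 1] == 1))

  px <- matrix(c(0.4, 0.6), 2, 2)  # identical clusters
  py <- matrix(c(0.3, 0.7), 2, 2)
  r2 <- e_step(W, cluster_model(px, py))
  expect_true(all(abs(r2 - 0.5) < 1e-12))

  # p(x|1)=0.6, p(y|1)=0.5, p(z)=0.5 each vs p(x|2)=0.2, p(y|2)=0.25:
  # products 0.15 vs 0.025 -> 6/7 and 1/7
  px <- cbind(c(0.6, 0.4), c(0.2, 0.8))
  py <- cbind(c(0.5, 0.5), c(0.25, 0.75))
  r3 <- e_step(matrix(1, 2, 2), cluster_model(px, py))
  expect_equal(r3[1, 1, 1], 0.857142857, tolerance = 1e-9)
  expect_equal(r3[1, 1, 2], 0.142857143, tolerance = 1e-9)
  expect_equal(unname(apply(r3, c(1, 2), sum)), matrix(1, 2, 2))
})

test_that("M-step is the weight-weighted mean responsibility", {
  W1 <- matrix(1, 1, 1)
  resp <- array(c(0.3, 0.7), dim = c(1, 1, 2))
  expect_equal(m_step(W1, resp), c(0.3, 0.7))

  W <- matrix(c(1, 3, 2, 0), 2, 2)   # [[1,2],[3,0]]
  set.seed(8)
  r <- array(stats::runif(8), dim = c(2, 2, 2))
  tot <- r[, , 1] + r[, , 2]
  r[, , 1] <- r[, , 1] / tot; r[, , 2] <- r[, , 2] / tot
  got <- m_step(W, r)
  # brute-force summation oracle
  num <- c(0, 0)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    num[k] <- num[k] + W[i, j] * r[i, j, k]
  }
  expect_equal(got, num / sum(W))
  expect_equal(sum(got), 1)
  expect_error(m_step(matrix(0, 2, 2), r), "degenerate")

  unif <- array(0.5, dim = c(2, 2, 2))
  expect_equal(m_step(W, unif), c(0.5, 0.5))
})

test_that("EM converges, keeps the likelihood non-decreasing, and honours symmetry", {
  W1 <- matrix(c(1, 2, 0, 3), 2, 2)
  m1 <- cluster_model(matrix(c(0.4, 0.6), 2, 1), matrix(c(0.3, 0.7), 2, 1))
  em1 <- em_estimate(W1, m1)
  expect_equal(em1$prior, 1)
  expect_equal(em1$iterations, 1L)
  expect_equal(unname(em1$theta[, 1]), c(1, 1))

  # two-block symmetric relation and mirror-symmetric model -> even priors
  W <- rbind(cbind(matrix(2, 2, 2), matrix(0, 2, 2)),
             cbind(matrix(0, 2, 2), matrix(2, 2, 2)))
  px <- cbind(c(0.4, 0.4, 0.1, 0.1), c(0.1, 0.1, 0.4, 0.4))
  py <- px
  em <- em_estimate(W, cluster_model(px, py))
  expect_equal(em$prior, c(0.5, 0.5), tolerance = 1e-9)

  set.seed(21)
  for (i in 1:10) {
    W <- random_relation(5, 6)
    model <- random_cluster_model(5, 6, 2)
    em <- em_estimate(W, model, max_iter = 50)
    expect_true(all(diff(em$loglik) >= -1e-9))
    expect_distribution(em$prior)
    expect_true(all(abs(rowSums(em$theta) - 1) < 1e-9))
  }
})

test_that("posterior rows follow Bayes rule with uniform fallback for isolates", {
  expect_equal(unname(posterior_update(matrix(c(0.2, 0.8), 2, 1), 1)),
               matrix(1, 2, 1))
  px <- cbind(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(unname(posterior_update(px, c(0.5, 0.5))),
               matrix(0.5, 2, 2))
  px <- cbind(c(0.3, 0.7), c(0.1, 0.9))
  th <- posterior_update(px, c(0.5, 0.5))
  expect_equal(unname(th[1, ]), c(0.75, 0.25))
  iso <- rbind(c(0, 0), c(0.5, 0.2))
  expect_message(th2 <- posterior_update(iso, c(0.5, 0.5)), "isolated")
  expect_equal(unname(th2[1, ]), c(0.5, 0.5))
})

test_that("seed guidance blends rows toward the seeded basis vector", {
  theta <- matrix(c(0.5, 0.2, 0.5, 0.8), 2, 2,
                  dimnames = list(c("f1", "f2"), NULL))
  expect_equal(apply_seed_prior(theta, seed_spec(c(f1 = 1), lambda_d = 0)),
               theta)
  big <- apply_seed_prior(theta, seed_spec(c(f1 = 1), lambda_d = 1e6))
  expect_equal(unname(big["f1", ]), c(1, 0), tolerance = 1e-5)
  one <- apply_seed_prior(theta, seed_spec(c(f2 = 1), lambda_d = 1))
  expect_equal(unname(one["f2", ]), c(0.6, 0.4))     # (0.2+1)/2, 0.8/2
  expect_equal(one["f1", ], theta["f1", ])
  expect_true(all(abs(rowSums(one) - 1) < 1e-12))
  expect_error(apply_seed_prior(theta, seed_spec(c(f1 = 3))), "exceeds")
  expect_error(apply_seed_prior(theta, seed_spec(c(zz = 1))), "unknown")
  # seeded-argmax consistency at high confidence
  set.seed(3)
  th <- matrix(stats::runif(20), 10, 2)
  th <- th / rowSums(th)
  rownames(th) <- paste0("f", 1:10)
  labs <- stats::setNames(sample(1:2, 4, replace = TRUE), paste0("f", 1:4))
  out <- apply_seed_prior(th, seed_spec(labs, lambda_d = 100))
  expect_equal(unname(apply(out[names(labs), ], 1, which.max)),
               unname(labs))
})

test_that("Q-function grid search finds no prior better than the M-step update", {
  set.seed(17)
  W <- matrix(stats::runif(9), 3, 3)
  model <- random_cluster_model(3, 3, 2)
  resp <- e_step(W, model)
  est <- m_step(W, resp)
  # expected complete log-likelihood as a function of the prior alone
  q_of <- function(p) {
    sum(W * (resp[, , 1] * log(p[1]) + resp[, , 2] * log(p[2])))
  }
  grid <- seq(0.001, 0.999, by = 0.001)
  q_best <- max(vapply(grid, function(g) q_of(c(g, 1 - g)), numeric(1)))
  expect_gte(q_of(est) + 1e-12, q_best)
})
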
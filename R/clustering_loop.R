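#' Random initial partition of the target objects
#'
#' Assigns each target uniformly at random to one of `K` clusters, redrawing
#' (up to 100 times) until no cluster is empty.  When rejection cannot
#' plausibly succeed (e.g. `K` close to the number of targets, where the only
#' admissible partitions are near-matchings) the partition is built
#' constructively: one random target per cluster, the rest uniform, then
#' shuffled.  Deterministic given `rng_seed`; the caller's RNG state is left
#' untouched.  With `K` equal to the number of targets this yields a perfect
#' matching.
#'
#' @param net A [star_network()].
#' @param K Number of clusters, `1 <= K <=` number of targets.
#' @param rng_seed Integer seed.
#' @return Named integer vector target id -> cluster index in `1..K`.
#' @export
initialize_partition <- function(net, K, rng_seed = 1L) {
  stopifnot(inherits(net, "star_network"))
  m <- length(net$targets)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > m) stop("K = ", K, " exceeds the number of targets (", m, ")")
  with_local_seed(rng_seed, {
    for (try in seq_len(100L)) {
      a <- sample.int(K, m, replace = TRUE)
      if (length(unique(a)) == K) {
        return(stats::setNames(a, net$targets))
      }
    }
    # guarantee every cluster one member, fill the rest uniformly
    a <- sample(c(seq_len(K), sample.int(K, m - K, replace = TRUE)))
    stats::setNames(as.integer(a), net$targets)
  })
}

#' Concatenate per-network posteriors into target embeddings
#'
#' Each target is represented by the concatenation of its K-dimensional
#' posterior membership rows, one block per attribute-type bipartite network
#' in schema order, giving an `A * K`-dimensional vector per target.
#'
#' @param posteriors Named list (schema order) of m x K posterior matrices
#'   sharing rownames and K.
#' @return m x (A*K) numeric matrix; rows are targets.
#' @export
embed_targets <- function(posteriors) {
  stopifnot(is.list(posteriors), length(posteriors) >= 1L)
  Ks <- vapply(posteriors, ncol, integer(1))
  if (length(unique(Ks)) != 1L) {
    stop("K mismatch across bipartite networks: ",
         paste(Ks, collapse = ", "))
  }
  ids <- rownames(posteriors[[1]])
  for (p in posteriors) {
    if (!identical(rownames(p), ids)) {
      stop("posterior matrices must share the same target registry")
    }
  }
  emb <- do.call(cbind, posteriors)
  rownames(emb) <- ids
  colnames(emb) <- unlist(lapply(names(posteriors) %||%
                                   seq_along(posteriors), function(a) {
    paste0(a, ".k", seq_len(Ks[[1]]))
  }))
  emb
}

#' Cluster centers as arithmetic means of member embeddings
#'
#' @param emb Embedding matrix from [embed_targets()].
#' @param assignment Named integer vector target -> cluster in `1..K`.
#' @param K Number of clusters (defaults to `max(assignment)`).
#' @return K x (A*K) matrix of centers.
#' @export
compute_centers <- function(emb, assignment, K = max(assignment)) {
  stopifnot(is.matrix(emb), !is.null(rownames(emb)),
            setequal(names(assignment), rownames(emb)))
  assignment <- assignment[rownames(emb)]
  sizes <- tabulate(assignment, nbins = K)
  if (any(sizes == 0L)) {
    stop("empty cluster(s): ", paste(which(sizes == 0L), collapse = ", "))
  }
  centers <- matrix(0, nrow = K, ncol = ncol(emb))
  for (k in seq_len(K)) {
    centers[k, ] <- colMeans(emb[assignment == k, , drop = FALSE])
  }
  colnames(centers) <- colnames(emb)
  centers
}

#' Cosine distance between two vectors
#'
#' `1 - (v . c) / (||v||_2 ||c||_2)`; lies in `[0, 1]` for non-negative
#' vectors.
#'
#' @param v,c_ Numeric vectors of equal length, neither all-zero.
#' @return A single number.
#' @examples
#' cosine_distance(c(1, 1, 0), c(1, 0, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(v, c_) {
  stopifnot(is.numeric(v), is.numeric(c_), length(v) == length(c_))
  nv <- sqrt(sum(v^2))
  nc <- sqrt(sum(c_^2))
  if (nv == 0 || nc == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(v * c_) / (nv * nc)
}

#' Assign each target to the nearest cluster center
#'
#' Nearest by cosine distance; ties are broken toward the lowest cluster
#' index, so the result is deterministic.
#'
#' @param emb Embedding matrix (rows = targets).
#' @param centers K x (A*K) center matrix.
#' @return Named integer vector target -> cluster.
#' @export
assign_clusters <- function(emb, centers) {
  stopifnot(is.matrix(emb), is.matrix(centers),
            ncol(emb) == ncol(centers))
  en <- emb / sqrt(rowSums(emb^2))
  cn <- centers / sqrt(rowSums(centers^2))
  sim <- en %*% t(cn)
  a <- apply(sim, 1L, which.max)   # first (lowest) index wins ties
  stats::setNames(as.integer(a), rownames(emb))
}

# Move the globally farthest-from-its-center target into each empty cluster
# so K never shrinks. Deterministic: ties resolve to the first target in
# registry order.
repair_empty_clusters <- function(assignment, emb, centers, K,
                                  locked = character(0)) {
  repeat {
    sizes <- tabulate(assignment, nbins = K)
    empty <- which(sizes == 0L)
    if (length(empty) == 0L) return(assignment)
    k <- empty[[1]]
    movable <- sizes[assignment] >= 2L &   # don't empty a singleton cluster
      !(names(assignment) %in% locked)
    if (!any(movable)) stop("cannot repair empty cluster ", k)
    d <- vapply(which(movable), function(i) {
      cosine_distance(emb[i, ], centers[assignment[[i]], ])
    }, numeric(1))
    pick <- which(movable)[which.max(d)]
    assignment[[pick]] <- k
  }
}

#' Ranking-based clustering of a star network
#'
#' The full algorithm: (0) randomly partition the targets and decompose the
#' network into one bipartite relation per attribute type; then iterate
#' (1) within each cluster, compute conditional authority rankings per
#' bipartite network and smooth them against the global rankings; (2) per
#' bipartite network, estimate cluster priors by EM and target posteriors by
#' Bayes rule, optionally blending in soft seed guidance; (3) embed every
#' target as the concatenation of its per-network posterior rows, compute
#' cluster centers, and reassign each target to the center with the smallest
#' cosine distance; (4) stop when no target changes cluster or `max_outer`
#' is reached.  Clusters emptied by a reassignment are repaired by moving in
#' the target farthest from its own center.
#'
#' @param net A [star_network()] with at least one edge.
#' @param K Number of clusters.
#' @param alpha Meta-path weight of the ranking function, in `[0, 1]`.
#' @param lambda Smoothing weight for attribute-type rankings: a scalar, or
#'   a named vector with one entry per attribute type.
#' @param lambda_target Smoothing weight for the target-type rankings.
#' @param em_max_iter,em_tol EM controls per bipartite network.
#' @param max_outer Cap on outer iterations.
#' @param seeds Optional [seed_spec()] of soft target labels.
#' @param rng_seed Integer seed controlling the initial partitions (the only
#'   randomness); identical inputs and seed give identical results.
#' @param n_restarts Number of random initial partitions to try (restart r
#'   uses seed `rng_seed + r - 1`); the run whose final per-cluster models
#'   give the highest summed observed log-likelihood over the bipartite
#'   networks is returned.  Restarts are the standard guard against the
#'   merged-cluster local optima of center-based partitioning.
#' @param rank_tol,rank_max_iter Power-method controls.
#' @param rule2 Attribute-attribute relation variant, see [authority_rank()].
#' @param warm_start If `TRUE`, each outer iteration starts EM from the
#'   previous iteration's priors instead of uniform.
#' @return An object of class `star_clustering`: `assignment` (named 1-based
#'   integer vector), `theta` and `priors` per attribute type, `embedding`,
#'   `centers`, `global_rankings`, `cluster_rankings` (per cluster, per type,
#'   smoothed; the target-type ranking is the normalized mean over the
#'   per-network conditionals), `diagnostics` (outer iteration count,
#'   assignment-change history, per-network EM iteration counts and final
#'   log-likelihood traces) and `params`.
#' @examples
#' sim <- simulate_star_network(K = 2, targets_per_cluster = 8,
#'                              attrs_per_cluster = 5, links_per_type = 3,
#'                              noise = 0, rng_seed = 7)
#' res <- cluster_star_network(sim$network, K = 2, rng_seed = 7)
#' fvic(as_partition(res$assignment), sim$truth)
#' @export
cluster_star_network <- function(net, K, alpha = 0.8, lambda = 0.2,
                                 lambda_target = 0.2, em_max_iter = 100L,
                                 em_tol = 1e-6, max_outer = 20L,
                                 seeds = NULL, rng_seed = 1L,
                                 n_restarts = 5L,
                                 rank_tol = 1e-8, rank_max_iter = 1000L,
                                 rule2 = c("literal", "stochastic"),
                                 warm_start = FALSE) {
  stopifnot(inherits(net, "star_network"))
  rule2 <- match.arg(rule2)
  if (nrow(net$edges) == 0L) stop("degenerate network: no edges")
  m <- length(net$targets)
  K <- as.integer(K)
  if (K < 1L || K > m) stop("K must be between 1 and the number of targets")
  if (!is.null(seeds)) {
    stopifnot(inherits(seeds, "seed_spec"))
    if (any(seeds$labels > K)) stop("seed label exceeds K")
  }
  types <- net$schema$attribute_types
  A <- length(types)
  lam <- resolve_lambda(lambda, types)
  stopifnot(lambda_target >= 0, lambda_target <= 1)

  Ws <- decompose_bipartite(net)
  usable <- vapply(Ws, function(W) ncol(W) > 0 && sum(W) > 0, logical(1))
  if (!any(usable)) stop("degenerate network: no usable bipartite relation")
  if (!all(usable)) {
    message("attribute type(s) with no edges skipped: ",
            paste(types[!usable], collapse = ", "))
    types <- types[usable]
    Ws <- Ws[usable]
    lam <- lam[usable]
  }

  global <- lapply(types, function(a) {
    authority_rank(Ws[[a]], alpha = alpha, tol = rank_tol,
                   max_iter = rank_max_iter, rule2 = rule2,
                   target_type = net$schema$target_type, attribute_type = a)
  })
  names(global) <- types

  n_restarts <- as.integer(n_restarts)
  stopifnot(n_restarts >= 1L)
  if (K == 1L) n_restarts <- 1L   # every initialization is identical

  run_once <- function(seed_r, init = NULL) {
    assignment <- if (is.null(init)) initialize_partition(net, K, seed_r)
                  else init
    if (!is.null(seeds) && seeds$lambda_d > 0) {
      # user guidance anchors the cluster indices: seeded targets start in
      # their seeded cluster, so the labels the guidance refers to and the
      # cluster indices the algorithm optimizes stay aligned
      assignment[names(seeds$labels)] <- seeds$labels
      sizes <- tabulate(assignment, nbins = K)
      for (k in which(sizes == 0L)) {
        donor <- which.max(tabulate(assignment, nbins = K))
        movable <- setdiff(names(assignment)[assignment == donor],
                           names(seeds$labels))
        assignment[[movable[[1]]]] <- k
      }
    }
    changes_hist <- integer(0)
    em_iter_hist <- list()
    prev_priors <- NULL
    thetas <- priors <- loglik_traces <- NULL
    emb <- NULL

    for (outer in seq_len(max_outer)) {
      models <- build_cluster_models(Ws, types, assignment, K, global,
                                     alpha, lam, lambda_target,
                                     rank_tol, rank_max_iter, rule2)
      thetas <- list(); thetas_raw <- list(); priors <- list()
      loglik_traces <- list()
      em_iters <- integer(0)
      for (a in types) {
        init <- if (warm_start && !is.null(prev_priors)) prev_priors[[a]]
                else NULL
        em <- em_estimate(Ws[[a]], models[[a]], max_iter = em_max_iter,
                          tol = em_tol, init_prior = init)
        thetas_raw[[a]] <- em$theta
        thetas[[a]] <- if (is.null(seeds)) em$theta else
          apply_seed_prior(em$theta, seeds)
        priors[[a]] <- em$prior
        loglik_traces[[a]] <- em$loglik
        em_iters[[a]] <- em$iterations
      }
      prev_priors <- priors
      em_iter_hist[[outer]] <- em_iters

      # the geometric step runs on the unblended posteriors: seed guidance
      # acts through the seeded targets' own membership below, never by
      # distorting centers with near-basis-vector rows
      emb <- embed_targets(thetas_raw)
      centers <- compute_centers(emb, assignment, K)
      new_assignment <- assign_clusters(emb, centers)
      if (!is.null(seeds) && seeds$lambda_d > 0) {
        blend <- embed_targets(thetas)
        for (id in names(seeds$labels)) {
          block_sum <- rowSums(matrix(blend[id, ], nrow = K))
          new_assignment[[id]] <- which.max(block_sum)
        }
      }
      locked <- if (is.null(seeds)) character(0) else names(seeds$labels)
      new_assignment <- repair_empty_clusters(new_assignment, emb, centers,
                                              K, locked = locked)
      changes <- sum(new_assignment != assignment[names(new_assignment)])
      assignment <- new_assignment
      changes_hist <- c(changes_hist, changes)
      if (changes == 0L) break
    }

    # internal objective: total model fit of the final per-cluster models -
    # the summed observed log-likelihood of the bipartite networks
    final_centers <- compute_centers(emb, assignment, K)
    objective <- sum(vapply(loglik_traces, function(x) x[[length(x)]],
                            numeric(1)))

    list(assignment = assignment, thetas = thetas, priors = priors,
         loglik_traces = loglik_traces, emb = emb,
         centers = final_centers, changes_hist = changes_hist,
         em_iter_hist = em_iter_hist, objective = objective,
         seed = seed_r)
  }

  restart_seeds <- rng_seed + seq_len(n_restarts) - 1L
  runs <- lapply(restart_seeds, run_once)
  if (!is.null(seeds) && seeds$lambda_d > 0) {
    guided <- guided_partition(net, Ws, types, seeds, K, global, alpha, lam,
                               lambda_target, rank_tol, rank_max_iter, rule2)
    if (!is.null(guided)) {
      runs <- c(runs, list(run_once(rng_seed, init = guided)))
      restart_seeds <- c(restart_seeds, NA_integer_)   # guided, seed-free
    }
  }
  objectives <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.max(objectives)]]

  cluster_rankings <- final_cluster_rankings(net, Ws, types,
                                             best$assignment, K,
                                             global, alpha, lam,
                                             lambda_target, rank_tol,
                                             rank_max_iter, rule2)
  structure(list(
    assignment = best$assignment,
    theta = best$thetas,
    priors = best$priors,
    embedding = best$emb,
    centers = best$centers,
    global_rankings = global,
    cluster_rankings = cluster_rankings,
    diagnostics = list(
      outer_iterations = length(best$changes_hist),
      converged = utils::tail(best$changes_hist, 1) == 0L,
      assignment_changes = best$changes_hist,
      em_iterations = best$em_iter_hist,
      loglik_traces = best$loglik_traces,
      restart_seeds = restart_seeds,
      restart_objectives = objectives,
      chosen_restart = which.max(objectives)
    ),
    params = list(K = K, alpha = alpha, lambda = lam,
                  lambda_target = lambda_target, em_max_iter = em_max_iter,
                  em_tol = em_tol, max_outer = max_outer,
                  rng_seed = rng_seed, n_restarts = n_restarts,
                  rule2 = rule2, warm_start = warm_start,
                  lambda_d = if (is.null(seeds)) NULL else seeds$lambda_d)
  ), class = "star_clustering")
}

# scalar or per-type named smoothing weights -> named vector over `types`
resolve_lambda <- function(lambda, types) {
  if (length(lambda) == 1L && is.null(names(lambda))) {
    lam <- stats::setNames(rep(as.numeric(lambda), length(types)), types)
  } else {
    if (is.null(names(lambda)) || !all(types %in% names(lambda))) {
      stop("per-type lambda must be named with every attribute type")
    }
    lam <- stats::setNames(as.numeric(lambda[types]), types)
  }
  if (any(lam < 0) || any(lam > 1)) stop("lambda must lie in [0, 1]")
  lam
}

# Deterministic guidance-driven initial partition: per-cluster ranking
# profiles are built from the seed groups alone and every target joins the
# cluster whose seed profile it links into most strongly (summed over
# networks).  NULL when some cluster has no seed.
guided_partition <- function(net, Ws, types, seeds, K, global, alpha, lam,
                             lambda_target, rank_tol, rank_max_iter, rule2) {
  groups <- split(names(seeds$labels), seeds$labels)
  if (length(groups) < K) return(NULL)
  score <- matrix(0, nrow = length(net$targets), ncol = K,
                  dimnames = list(net$targets, NULL))
  for (a in types) {
    for (k in seq_len(K)) {
      cr <- conditional_rank_matrix(Ws[[a]], groups[[as.character(k)]],
                                    alpha = alpha, tol = rank_tol,
                                    max_iter = rank_max_iter, rule2 = rule2)
      cond <- if (cr$degenerate) global[[a]]$target$probs else cr$target
      score[, k] <- score[, k] + (1 - lambda_target) * cond +
        lambda_target * global[[a]]$target$probs
    }
  }
  assignment <- stats::setNames(apply(score, 1L, which.max), net$targets)
  assignment[names(seeds$labels)] <- seeds$labels
  sizes <- tabulate(assignment, nbins = K)
  if (any(sizes == 0L)) return(NULL)   # degenerate guidance; fall back
  stats::setNames(as.integer(assignment), net$targets)
}

# Smoothed per-cluster generative models for every usable bipartite network.
build_cluster_models <- function(Ws, types, assignment, K, global, alpha,
                                 lam, lambda_target, rank_tol, rank_max_iter,
                                 rule2) {
  models <- list()
  for (a in types) {
    W <- Ws[[a]]
    g_t <- global[[a]]$target$probs
    g_a <- global[[a]]$attribute$probs
    px <- matrix(0, nrow = nrow(W), ncol = K,
                 dimnames = list(rownames(W), NULL))
    py <- matrix(0, nrow = ncol(W), ncol = K,
                 dimnames = list(colnames(W), NULL))
    for (k in seq_len(K)) {
      members <- names(assignment)[assignment == k]
      cr <- conditional_rank_matrix(W, members, alpha = alpha,
                                    tol = rank_tol,
                                    max_iter = rank_max_iter, rule2 = rule2)
      if (cr$degenerate) {
        # no within-cluster signal for this type: fall back to the global
        # ranking, which the smoothing blend then returns unchanged
        cond_t <- g_t
        cond_a <- g_a
      } else {
        cond_t <- cr$target
        cond_a <- cr$attribute
      }
      px[, k] <- (1 - lambda_target) * cond_t + lambda_target * g_t
      py[, k] <- (1 - lam[[a]]) * cond_a + lam[[a]] * g_a
    }
    models[[a]] <- cluster_model(px, py)
  }
  models
}

# Per-cluster smoothed rankings for reporting, computed on the final
# assignment: attribute types directly, the target type as the L1-normalized
# mean of its per-network smoothed conditionals.
final_cluster_rankings <- function(net, Ws, types, assignment, K, global,
                                   alpha, lam, lambda_target, rank_tol,
                                   rank_max_iter, rule2) {
  out <- vector("list", K)
  for (k in seq_len(K)) {
    members <- names(assignment)[assignment == k]
    per_type <- list()
    t_acc <- stats::setNames(numeric(length(net$targets)), net$targets)
    for (a in types) {
      cr <- conditional_rank_matrix(Ws[[a]], members, alpha = alpha,
                                    tol = rank_tol,
                                    max_iter = rank_max_iter, rule2 = rule2)
      g_t <- global[[a]]$target$probs
      g_a <- global[[a]]$attribute$probs
      cond_t <- if (cr$degenerate) g_t else cr$target
      cond_a <- if (cr$degenerate) g_a else cr$attribute
      sm_a <- (1 - lam[[a]]) * cond_a + lam[[a]] * g_a
      sm_t <- (1 - lambda_target) * cond_t + lambda_target * g_t
      per_type[[a]] <- ranking_distribution(a, names(sm_a), as.vector(sm_a),
                                            degenerate = cr$degenerate)
      t_acc <- t_acc + sm_t
    }
    per_type[[net$schema$target_type]] <-
      ranking_distribution(net$schema$target_type, names(t_acc),
                           as.vector(t_acc / sum(t_acc)))
    out[[k]] <- per_type
  }
  out
}

#' @export
print.star_clustering <- function(x, ...) {
  sizes <- tabulate(x$assignment, nbins = x$params$K)
  cat("<star_clustering> K =", x$params$K,
      "| cluster sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  outer iterations:", x$diagnostics$outer_iterations,
      "| converged:", x$diagnostics$converged, "\n")
  cat("  assignment changes:",
      paste(x$diagnostics$assignment_changes, collapse = " "), "\n")
  invisible(x)
}
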
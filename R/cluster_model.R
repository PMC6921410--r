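#' Jelinek-Mercer smoothing of a conditional ranking with the global ranking
#'
#' Within-cluster (conditional) rankings assign rank 0 to every object absent
#' from the cluster's induced subnetwork, which would zero out the generative
#' probability of links touching those objects.  Blending with the global
#' ranking, `smoothed = (1 - lam) * conditional + lam * global`, keeps every
#' observed object visible: `smoothed(x) >= lam * global(x)` for all x.
#'
#' @param conditional,global_ Two [ranking_distribution()]s over the same
#'   object registry.
#' @param lam Smoothing weight in `[0, 1]`: the portion of global ranking.
#' @return A [ranking_distribution()] over the same registry.
#' @examples
#' g <- ranking_distribution("t", c("a", "b"), c(0.9, 0.1))
#' c_ <- ranking_distribution("t", c("a", "b"), c(0.5, 0.5))
#' smooth_rank(c_, g, 0.2)$probs  # 0.58, 0.42
#' @export
smooth_rank <- function(conditional, global_, lam) {
  stopifnot(inherits(conditional, "ranking_distribution"),
            inherits(global_, "ranking_distribution"),
            is.numeric(lam), length(lam) == 1L, lam >= 0, lam <= 1)
  if (!identical(conditional$object_ids, global_$object_ids)) {
    stop("registry mismatch: conditional and global rankings must cover the ",
         "same objects in the same order")
  }
  p <- (1 - lam) * conditional$probs + lam * global_$probs
  ranking_distribution(conditional$type_name, conditional$object_ids,
                       as.vector(p),
                       degenerate = conditional$degenerate && global_$degenerate)
}

# Conditional (within-cluster) ranking straight from a relation matrix.
# Attribute side: authority ranking of the block restricted to the cluster's
# members, with attribute columns that lose all their links dropped (their
# conditional rank is 0 by convention) and the result re-expanded over the
# full registry.  Target side: the ranking rule propagates the cluster's
# attribute ranks through EVERY target's full link row,
# cond(x) = sum_j W(x, j) p(y_j | k) (L1-normalized), so each target -
# member or not - is scored by how strongly it links into the cluster's
# attribute profile; targets with no links into that profile get rank 0.
# This cross-cluster visibility is what lets the outer reassignment loop
# move targets between clusters.
conditional_rank_matrix <- function(W, members, alpha = 0.8, tol = 1e-8,
                                    max_iter = 1000L,
                                    rule2 = "literal") {
  stopifnot(all(members %in% rownames(W)))
  if (length(members) == 0L) {
    return(list(target = NULL, attribute = NULL, degenerate = TRUE))
  }
  Wk <- W[rownames(W) %in% members, , drop = FALSE]
  keep <- colSums(Wk) > 0
  target_full <- stats::setNames(numeric(nrow(W)), rownames(W))
  attr_full <- stats::setNames(numeric(ncol(W)), colnames(W))
  if (!any(keep) || all(Wk == 0)) {
    # cluster has no links of this type: no within-cluster signal
    return(list(target = target_full, attribute = attr_full,
                degenerate = TRUE))
  }
  ar <- authority_rank(Wk[, keep, drop = FALSE], alpha = alpha, tol = tol,
                       max_iter = max_iter, rule2 = rule2)
  attr_full[names(ar$attribute$probs)] <- ar$attribute$probs
  t_raw <- as.vector(W %*% attr_full)
  if (sum(t_raw) > 0) target_full[] <- t_raw / sum(t_raw)
  list(target = target_full, attribute = attr_full, degenerate = FALSE)
}

#' Within-cluster rankings over the full object registries
#'
#' Ranks attributes inside the subnetwork induced by one cluster of a
#' partition, and ranks every target by propagating those within-cluster
#' attribute ranks through its link row (the same mutual-reinforcement rule
#' used globally).  The returned distributions span the FULL registries of
#' `net`: attribute objects absent from the cluster, and targets with no
#' links into the cluster's attribute profile, get rank 0 (pre-smoothing).
#'
#' @param net A [star_network()].
#' @param assignment Named integer vector mapping every target id to a
#'   cluster index in `1..K`.
#' @param k Cluster index to rank.
#' @param alpha,tol,max_iter,rule2 Passed to [authority_rank()].
#' @return Named list per attribute type; each element has `target` and
#'   `attribute` [ranking_distribution()]s over the full registries and a
#'   `degenerate` flag (empty cluster or no links of that type).
#' @export
conditional_rankings <- function(net, assignment, k, alpha = 0.8, tol = 1e-8,
                                 max_iter = 1000L,
                                 rule2 = c("literal", "stochastic")) {
  stopifnot(inherits(net, "star_network"))
  rule2 <- match.arg(rule2)
  if (is.null(names(assignment)) ||
      !setequal(names(assignment), net$targets)) {
    stop("assignment must be a named vector covering every target id")
  }
  members <- names(assignment)[assignment == k]
  Ws <- decompose_bipartite(net)
  out <- lapply(names(Ws), function(a) {
    cr <- conditional_rank_matrix(Ws[[a]], members, alpha = alpha, tol = tol,
                                  max_iter = max_iter, rule2 = rule2)
    if (is.null(cr$target)) {
      return(list(target = NULL, attribute = NULL, degenerate = TRUE))
    }
    tp <- if (sum(cr$target) > 0) cr$target else
      rep(1 / length(cr$target), length(cr$target))
    ap <- if (sum(cr$attribute) > 0) cr$attribute else
      rep(1 / length(cr$attribute), length(cr$attribute))
    list(
      target = ranking_distribution(net$schema$target_type, net$targets,
                                    as.vector(tp), degenerate = cr$degenerate),
      attribute = ranking_distribution(a, net$attributes[[a]], as.vector(ap),
                                       degenerate = cr$degenerate),
      degenerate = cr$degenerate
    )
  })
  names(out) <- names(Ws)
  out
}

#' Per-cluster conditional generative model for one bipartite network
#'
#' Bundles, for one bipartite relation, the smoothed within-cluster ranking
#' distributions of the target side (`px`, m x K) and attribute side
#' (`py`, n x K) together with the cluster priors `prior` (length K).  Each
#' column of `px`/`py` and the prior vector sum to 1.
#'
#' @param px Numeric matrix, one column per cluster, rows = target objects;
#'   each column a probability distribution.
#' @param py Numeric matrix, one column per cluster, rows = attribute
#'   objects; each column a probability distribution.
#' @param prior Numeric vector of cluster priors `p(z = k)`, summing to 1.
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(px, py, prior = NULL) {
  stopifnot(is.matrix(px), is.matrix(py), ncol(px) == ncol(py))
  K <- ncol(px)
  if (is.null(prior)) prior <- rep(1 / K, K)
  stopifnot(length(prior) == K)
  if (any(px < 0) || any(py < 0) || any(prior < 0)) {
    stop("model probabilities must be non-negative")
  }
  bad <- c(abs(colSums(px) - 1), abs(colSums(py) - 1), abs(sum(prior) - 1))
  if (any(bad > 1e-9)) {
    stop("cluster_model columns and prior must each sum to 1 within 1e-9")
  }
  structure(list(px = px, py = py, prior = as.numeric(prior), K = K),
            class = "cluster_model")
}

#' E-step: link-to-cluster responsibilities
#'
#' For every cell (i, j) computes
#' `P(z = k | x_i, y_j) \propto p(x_i | k) p(y_j | k) p(z = k)`.  Values are
#' meaningful where `W[i, j] > 0`; links whose K products are all zero get a
#' uniform `1/K` responsibility (reported via a message).
#'
#' @param W Non-negative relation matrix (m x n).
#' @param model A [cluster_model()] with current priors.
#' @return An m x n x K array of responsibilities; for every (i, j) the
#'   K-slice sums to 1.
#' @export
e_step <- function(W, model) {
  stopifnot(inherits(model, "cluster_model"),
            is.matrix(W), nrow(W) == nrow(model$px),
            ncol(W) == nrow(model$py))
  K <- model$K
  m <- nrow(W); n <- ncol(W)
  slices <- lapply(seq_len(K), function(k) {
    tcrossprod(model$px[, k], model$py[, k]) * model$prior[k]
  })
  denom <- Reduce(`+`, slices)
  zero <- denom == 0
  if (any(zero & W > 0)) {
    message("e_step: ", sum(zero & W > 0),
            " link(s) with all-zero cluster products; using uniform 1/K")
  }
  denom[zero] <- 1
  resp <- array(0, dim = c(m, n, K),
                dimnames = list(rownames(W), colnames(W), NULL))
  for (k in seq_len(K)) {
    slice <- slices[[k]] / denom
    slice[zero] <- 1 / K
    resp[, , k] <- slice
  }
  resp
}

#' M-step: re-estimate cluster priors from responsibilities
#'
#' `p(z = k) = sum_ij W(i,j) P(z = k | x_i, y_j) / sum_ij W(i,j)` - the
#' weight-weighted mean responsibility, which maximizes the expected complete
#' log-likelihood over the prior simplex.
#'
#' @param W Non-negative relation matrix.
#' @param responsibilities Array from [e_step()].
#' @return Numeric vector of K priors summing to 1.
#' @export
m_step <- function(W, responsibilities) {
  stopifnot(is.matrix(W), length(dim(responsibilities)) == 3L,
            all(dim(responsibilities)[1:2] == dim(W)))
  tw <- sum(W)
  if (tw <= 0) stop("degenerate bipartite network: total edge weight is 0")
  K <- dim(responsibilities)[3]
  vapply(seq_len(K),
         function(k) sum(W * responsibilities[, , k]) / tw,
         numeric(1))
}

# observed-data log-likelihood sum_ij W_ij log sum_k p(x_i|k) p(y_j|k) p(z=k)
observed_loglik <- function(W, model) {
  K <- model$K
  denom <- matrix(0, nrow(W), ncol(W))
  for (k in seq_len(K)) {
    denom <- denom + tcrossprod(model$px[, k], model$py[, k]) * model$prior[k]
  }
  nz <- W > 0
  sum(W[nz] * log(pmax(denom[nz], 1e-300)))
}

#' Estimate cluster priors for one bipartite network by EM
#'
#' Holds the smoothed per-cluster ranking distributions fixed and alternates
#' [e_step()] / [m_step()] on the cluster priors, starting from even values,
#' until the largest absolute prior change falls below `tol` or `max_iter` is
#' hit.  The observed log-likelihood is recorded at every iteration and is
#' non-decreasing.  The final target posteriors are computed with
#' [posterior_update()].
#'
#' @param W Non-negative relation matrix with at least one positive entry.
#' @param model A [cluster_model()]; its `prior` slot is ignored in favour of
#'   `init_prior`.
#' @param max_iter,tol EM stopping controls.
#' @param init_prior Optional starting prior (defaults to uniform `1/K`).
#' @return List with `prior`, `theta` (m x K posterior matrix), `loglik`
#'   (trace, one value per iteration), `iterations`, `converged`.
#' @export
em_estimate <- function(W, model, max_iter = 100L, tol = 1e-6,
                        init_prior = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (sum(W) <= 0) stop("degenerate bipartite network: total edge weight is 0")
  K <- model$K
  prior <- init_prior %||% rep(1 / K, K)
  stopifnot(length(prior) == K, all(prior >= 0), sums_to_one(prior, 1e-6))
  prior <- prior / sum(prior)
  ll <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    cur <- cluster_model(model$px, model$py, prior)
    ll <- c(ll, observed_loglik(W, cur))
    resp <- e_step(W, cur)
    new_prior <- m_step(W, resp)
    delta <- max(abs(new_prior - prior))
    prior <- new_prior
    if (delta <= tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  final <- cluster_model(model$px, model$py, prior)
  ll <- c(ll, observed_loglik(W, final))
  theta <- posterior_update(model$px, prior)
  list(prior = prior, theta = theta, loglik = ll, iterations = iter,
       converged = converged)
}

#' Posterior cluster membership of each target object
#'
#' Bayes rule on the smoothed conditional target rankings:
#' `Theta[i, k] = p(x_i | G_k) p(z = k) / sum_l p(x_i | G_l) p(z = l)`.
#' Targets with all-zero numerators (fully isolated) get a uniform `1/K` row.
#'
#' @param px m x K matrix of smoothed per-cluster target ranking
#'   distributions (columns sum to 1).
#' @param prior Cluster priors, length K, summing to 1.
#' @return m x K row-stochastic matrix (rows sum to 1), rownames preserved.
#' @export
posterior_update <- function(px, prior) {
  stopifnot(is.matrix(px), length(prior) == ncol(px))
  num <- sweep(px, 2L, prior, `*`)
  rs <- rowSums(num)
  zero <- rs == 0
  if (any(zero)) {
    message("posterior_update: ", sum(zero),
            " isolated target(s) assigned uniform posterior")
    num[zero, ] <- 1 / ncol(px)
    rs[zero] <- 1
  }
  num / rs
}

#' Specify soft seed labels for user-guided clustering
#'
#' Seeds express prior knowledge that particular targets belong to particular
#' clusters.  They are soft: each seeded target's posterior row is drawn
#' toward the basis vector of its seeded cluster with confidence `lambda_d`
#' (a Dirichlet prior with parameter `lambda_d * e_k + 1`), never hard-fixed.
#'
#' @param labels Named integer vector: target id -> cluster index (1-based).
#' @param lambda_d Non-negative confidence; 0 leaves posteriors untouched,
#'   large values pin seeded rows to their label.
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(labels, lambda_d = 10) {
  stopifnot(is.numeric(labels), !is.null(names(labels)),
            all(nzchar(names(labels))),
            is.numeric(lambda_d), length(lambda_d) == 1L, lambda_d >= 0)
  nm <- names(labels)
  labels <- as.integer(labels)
  names(labels) <- nm
  if (anyNA(labels) || any(labels < 1L)) {
    stop("seed labels must be positive cluster indices")
  }
  if (anyDuplicated(nm)) stop("duplicated target ids in seed labels")
  structure(list(labels = labels, lambda_d = lambda_d), class = "seed_spec")
}

#' Blend seed guidance into a posterior matrix
#'
#' For each seeded target i with label k*, the row becomes
#' `(row + lambda_d * e_{k*}) / (1 + lambda_d)` (posterior-mean update under
#' the Dirichlet seed prior); unseeded rows are unchanged.  Rows remain on
#' the simplex.
#'
#' @param theta m x K row-stochastic posterior matrix with target rownames.
#' @param seeds A [seed_spec()].
#' @return Updated posterior matrix.
#' @export
apply_seed_prior <- function(theta, seeds) {
  stopifnot(is.matrix(theta), inherits(seeds, "seed_spec"))
  if (seeds$lambda_d == 0 || length(seeds$labels) == 0L) return(theta)
  K <- ncol(theta)
  if (any(seeds$labels > K)) {
    stop("seed label exceeds the number of clusters K = ", K)
  }
  unknown <- setdiff(names(seeds$labels), rownames(theta))
  if (length(unknown) > 0) {
    stop("seed(s) reference unknown target id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ld <- seeds$lambda_d
  for (id in names(seeds$labels)) {
    e <- numeric(K)
    e[seeds$labels[[id]]] <- 1
    theta[id, ] <- (theta[id, ] + ld * e) / (1 + ld)
  }
  theta
}
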
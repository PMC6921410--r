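#' Construct a ranking distribution
#'
#' A ranking distribution is a discrete probability distribution over the
#' objects of one type: non-negative values summing to 1.  A distribution
#' computed from an all-zero relation (no information) is uniform and flagged
#' `degenerate`.
#'
#' @param type_name Object type the distribution ranks.
#' @param object_ids Character vector of object identifiers (registry order).
#' @param probs Non-negative numeric vector, same length as `object_ids`,
#'   summing to 1 within 1e-9.
#' @param degenerate Logical flag for all-zero-input distributions.
#' @return An object of class `ranking_distribution` with fields `type_name`,
#'   `object_ids`, `probs` (named) and `degenerate`.
#' @export
ranking_distribution <- function(type_name, object_ids, probs,
                                 degenerate = FALSE) {
  stopifnot(is.character(type_name), length(type_name) == 1L,
            is.character(object_ids),
            is.numeric(probs), length(probs) == length(object_ids))
  if (any(probs < 0)) stop("ranking probabilities must be non-negative")
  if (!sums_to_one(probs)) {
    stop("ranking distribution must sum to 1 within 1e-9 (got ",
         format(sum(probs), digits = 15), ")")
  }
  names(probs) <- object_ids
  structure(list(type_name = type_name, object_ids = object_ids,
                 probs = probs, degenerate = isTRUE(degenerate)),
            class = "ranking_distribution")
}

#' @export
print.ranking_distribution <- function(x, n = 5, ...) {
  cat("<ranking_distribution> type:", x$type_name,
      "|", length(x$probs), "object(s)",
      if (x$degenerate) "| DEGENERATE (uniform)" else "", "\n")
  top <- sort(x$probs, decreasing = TRUE)
  print(utils::head(top, n))
  invisible(x)
}

#' Principal eigenvector of a non-negative matrix by power iteration
#'
#' Iterates `v <- M v / ||M v||_1` from a uniform start vector until both the
#' L1 change between successive iterates and the relative fixed-point residual
#' `||M v - ||M v||_1 v||_1 / ||M v||_1` fall below `tol`.  For the symmetric
#' non-negative products used by [authority_rank()] this converges to the
#' Perron (dominant) eigenvector.
#'
#' @param M Square non-negative numeric matrix.
#' @param tol Convergence tolerance (L1 change and relative residual).
#' @param max_iter Iteration cap; non-convergence raises a warning and
#'   returns the last iterate.
#' @return List with `vector` (non-negative, L1-normalized, named if `M` has
#'   dimnames), `iterations`, `converged` and `degenerate` (TRUE when `M` has
#'   no usable mass and a uniform vector is returned).
#' @examples
#' power_iteration(diag(3))$vector        # uniform by symmetry
#' power_iteration(matrix(c(2, 0, 0, 1), 2))$vector  # dominant axis
#' @export
power_iteration <- function(M, tol = 1e-8, max_iter = 1000L) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), nrow(M) >= 1L)
  if (any(M < 0)) stop("M must be non-negative")
  stopifnot(is.numeric(tol), tol > 0, max_iter >= 1L)
  n <- nrow(M)
  ids <- rownames(M)
  uniform <- function() {
    v <- rep(1 / n, n)
    if (!is.null(ids)) names(v) <- ids
    v
  }
  if (all(M == 0)) {
    return(list(vector = uniform(), iterations = 0L,
                converged = TRUE, degenerate = TRUE))
  }
  v <- rep(1 / n, n)
  mv <- as.vector(M %*% v)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- sum(mv)
    if (s <= 0) {
      # nilpotent action on the non-negative cone: no principal direction
      return(list(vector = uniform(), iterations = iter,
                  converged = TRUE, degenerate = TRUE))
    }
    v_new <- mv / s
    mv_new <- as.vector(M %*% v_new)
    s_new <- sum(mv_new)
    delta <- sum(abs(v_new - v))
    resid <- sum(abs(mv_new - s_new * v_new))
    v <- v_new
    mv <- mv_new
    if (delta <= tol && s_new > 0 && resid <= tol * s_new) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("power iteration did not converge in ", max_iter,
            " iterations (last L1 residual ",
            format(sum(abs(mv - sum(mv) * v)), digits = 6), ")")
  }
  if (!is.null(ids)) names(v) <- ids
  list(vector = v, iterations = iter, converged = converged,
       degenerate = FALSE)
}

#' Mutual-reinforcement authority ranking on a bipartite relation
#'
#' Implements the two ranking rules of the model: (1) highly ranked targets
#' link to highly ranked attributes, giving the alternating normalized
#' iteration whose fixed point is the principal eigenvector of
#' \eqn{W^T W}; and (2) two attributes co-linked by the same target reinforce
#' each other, via the attribute-attribute relation \eqn{W_{SS}}.  The
#' attribute ranking is the principal eigenvector of
#' \eqn{\alpha W^T W + (1-\alpha) W_{SS}} and the target ranking is the
#' L1-normalized image `W %*% attribute`.
#'
#' With the literal definition \eqn{W_{SS} = W^T W} (the default,
#' `rule2 = "literal"`) the mixture is independent of `alpha`;
#' `rule2 = "stochastic"` row-normalizes \eqn{W_{SS}} so the two meta-path
#' terms genuinely differ.  See the methods vignette.
#'
#' @param W Non-negative relation matrix (targets in rows, attributes in
#'   columns); dimnames, when present, become the object ids.
#' @param alpha Weight of the target-attribute rule versus the
#'   attribute-attribute rule, in `[0, 1]`.  Default 0.8.
#' @param tol,max_iter Passed to [power_iteration()].
#' @param rule2 How to form the attribute-attribute relation: `"literal"`
#'   uses \eqn{W^T W} unchanged; `"stochastic"` row-normalizes it.
#' @param target_type,attribute_type Type labels for the returned
#'   distributions.
#' @return List with `target` and `attribute` [ranking_distribution()]s,
#'   plus `iterations` and `converged` from the power method.  An all-zero
#'   `W` yields uniform distributions flagged degenerate.
#' @examples
#' W <- matrix(c(2, 1, 0, 1), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' authority_rank(W, alpha = 0.8)$attribute$probs
#' @export
authority_rank <- function(W, alpha = 0.8, tol = 1e-8, max_iter = 1000L,
                           rule2 = c("literal", "stochastic"),
                           target_type = "target",
                           attribute_type = "attribute") {
  stopifnot(is.matrix(W), is.numeric(W))
  if (any(W < 0)) stop("W must be non-negative")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  rule2 <- match.arg(rule2)
  tids <- rownames(W) %||% paste0("t", seq_len(nrow(W)))
  aids <- colnames(W) %||% paste0("a", seq_len(ncol(W)))

  if (nrow(W) == 0L || ncol(W) == 0L) {
    stop("W must have at least one row and one column")
  }
  if (all(W == 0)) {
    return(list(
      target = ranking_distribution(target_type, tids,
                                    rep(1 / length(tids), length(tids)),
                                    degenerate = TRUE),
      attribute = ranking_distribution(attribute_type, aids,
                                       rep(1 / length(aids), length(aids)),
                                       degenerate = TRUE),
      iterations = 0L, converged = TRUE))
  }

  WtW <- crossprod(W)                      # W_{SF} W_{FS}
  Wss <- WtW
  if (rule2 == "stochastic") {
    rs <- rowSums(Wss)
    nz <- rs > 0
    Wss[nz, ] <- Wss[nz, , drop = FALSE] / rs[nz]
  }
  M <- alpha * WtW + (1 - alpha) * Wss
  pr <- power_iteration(M, tol = tol, max_iter = max_iter)
  a <- pr$vector
  t_raw <- as.vector(W %*% a)
  degenerate <- pr$degenerate
  if (sum(t_raw) <= 0) {
    t_probs <- rep(1 / length(tids), length(tids))
    degenerate <- TRUE
  } else {
    t_probs <- t_raw / sum(t_raw)
  }
  list(
    target = ranking_distribution(target_type, tids, t_probs,
                                  degenerate = degenerate),
    attribute = ranking_distribution(attribute_type, aids, as.vector(a),
                                     degenerate = pr$degenerate),
    iterations = pr$iterations,
    converged = pr$converged
  )
}

#' Global per-type authority rankings of a star network
#'
#' Convenience wrapper: decomposes the network into bipartite relations and
#' runs [authority_rank()] on each.
#'
#' @param net A [star_network()].
#' @inheritParams authority_rank
#' @return Named list (per attribute type) of [authority_rank()] results.
#' @export
rank_network <- function(net, alpha = 0.8, tol = 1e-8, max_iter = 1000L,
                         rule2 = c("literal", "stochastic")) {
  stopifnot(inherits(net, "star_network"))
  rule2 <- match.arg(rule2)
  Ws <- decompose_bipartite(net)
  out <- lapply(names(Ws), function(a) {
    authority_rank(Ws[[a]], alpha = alpha, tol = tol, max_iter = max_iter,
                   rule2 = rule2, target_type = net$schema$target_type,
                   attribute_type = a)
  })
  names(out) <- names(Ws)
  out
}
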
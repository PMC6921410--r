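#' Planted-partition star-network generator
#'
#' Generates a ground-truthed star network with `K` planted clusters.  Each
#' cluster owns a disjoint vocabulary of attribute objects per type; each
#' target draws `links_per_type` links per attribute type, attaching within
#' its own cluster's vocabulary with probability `1 - noise` and to a
#' uniformly random out-of-cluster attribute otherwise.  Repeated draws of
#' the same (target, attribute) pair aggregate by weight summation, so with
#' the constant weight law the edge weight equals the draw count.
#'
#' The defaults (3 clusters of 30 targets, 3 attribute types named after the
#' TCM schema, 15 attributes per type per cluster, 5 links per target per
#' type, noise 0.05) are the study conditions used throughout the package's
#' tests; see the methods vignette.
#'
#' @param K Number of planted clusters.
#' @param targets_per_cluster Targets per cluster.
#' @param attrs_per_cluster Attribute objects per type per cluster; scalar or
#'   named per-type vector.
#' @param links_per_type Links drawn per target per attribute type.
#' @param noise Probability in `[0, 1]` that a link attaches out-of-cluster.
#' @param attribute_types Attribute type names (schema order).
#' @param target_type Target type name.
#' @param weight_law `"constant"` (every draw has weight 1) or `"poisson"`
#'   (weight `1 + rpois(weight_mu)` per draw).
#' @param weight_mu Poisson mean for `weight_law = "poisson"`.
#' @param rng_seed Integer seed; identical configurations give identical
#'   networks.
#' @return List with `network` (a [star_network()]), `truth` (a
#'   [as_partition()] of the targets) and `labels` (named 1-based integer
#'   vector).
#' @examples
#' sim <- simulate_star_network(K = 2, targets_per_cluster = 5,
#'                              attrs_per_cluster = 4, links_per_type = 3,
#'                              noise = 0, rng_seed = 1)
#' sim$network
#' @export
simulate_star_network <- function(K = 3, targets_per_cluster = 30,
                                  attrs_per_cluster = 15, links_per_type = 5,
                                  noise = 0.05,
                                  attribute_types = c("function", "herb",
                                                      "symptom"),
                                  target_type = "formula",
                                  weight_law = c("constant", "poisson"),
                                  weight_mu = 2, rng_seed = 1L) {
  K <- as.integer(K)
  stopifnot(K >= 1L, targets_per_cluster >= 1L, links_per_type >= 1L,
            noise >= 0, noise <= 1, weight_mu >= 0)
  weight_law <- match.arg(weight_law)
  if (noise > 0 && K == 1L) {
    stop("noise > 0 requires K >= 2 (no out-of-cluster vocabulary exists)")
  }
  if (length(attrs_per_cluster) == 1L && is.null(names(attrs_per_cluster))) {
    attrs_per_cluster <- stats::setNames(
      rep(as.integer(attrs_per_cluster), length(attribute_types)),
      attribute_types)
  } else if (!all(attribute_types %in% names(attrs_per_cluster))) {
    stop("per-type attrs_per_cluster must be named with every attribute type")
  }
  stopifnot(all(attrs_per_cluster >= 1L))
  schema <- star_schema(target_type, attribute_types)

  m <- K * targets_per_cluster
  target_ids <- sprintf("%s%03d", substr(target_type, 1, 1), seq_len(m))
  labels <- stats::setNames(rep(seq_len(K), each = targets_per_cluster),
                            target_ids)
  # disjoint per-cluster vocabularies: vocab[[type]][[cluster]]
  vocab <- lapply(attribute_types, function(a) {
    lapply(seq_len(K), function(k) {
      sprintf("%s_c%d_%02d", a, k, seq_len(attrs_per_cluster[[a]]))
    })
  })
  names(vocab) <- attribute_types

  edges <- with_local_seed(rng_seed, {
    rows <- vector("list", m * length(attribute_types))
    idx <- 0L
    for (i in seq_len(m)) {
      k <- labels[[i]]
      for (a in attribute_types) {
        own <- vocab[[a]][[k]]
        other <- unlist(vocab[[a]][-k], use.names = FALSE)
        cross <- stats::runif(links_per_type) < noise
        picks <- character(links_per_type)
        n_in <- sum(!cross)
        if (n_in > 0) picks[!cross] <- sample(own, n_in, replace = TRUE)
        if (any(cross)) picks[cross] <- sample(other, sum(cross),
                                               replace = TRUE)
        w <- switch(weight_law,
                    constant = rep(1, links_per_type),
                    poisson = 1 + stats::rpois(links_per_type, weight_mu))
        idx <- idx + 1L
        rows[[idx]] <- data.frame(target_id = target_ids[[i]],
                                  attribute_type = a,
                                  attribute_id = picks,
                                  weight = w,
                                  stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows[seq_len(idx)])
  })

  net <- star_network(edges, schema = schema, targets = target_ids)
  truth <- as_partition(labels)
  list(network = net, truth = truth, labels = labels)
}
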
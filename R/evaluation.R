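#' Coerce to a partition
#'
#' A partition is a list of pairwise-disjoint character vectors of object
#' ids.  Accepts either such a list or a named assignment vector
#' (id -> cluster label), which is split by label.
#'
#' @param x A list of id vectors or a named vector of cluster labels.
#' @return A validated list of disjoint character vectors (class
#'   `partition`).
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (is.list(x)) {
    parts <- lapply(x, as.character)
  } else {
    if (is.null(names(x))) {
      stop("assignment vectors must be named by object id")
    }
    parts <- split(names(x), x)
    parts <- lapply(parts, as.character)
  }
  parts <- unname(parts[lengths(parts) > 0])
  ids <- unlist(parts, use.names = FALSE)
  if (anyDuplicated(ids)) {
    stop("partition clusters must be pairwise disjoint")
  }
  structure(parts, class = "partition")
}

#' Fraction of vertices identified correctly (FVIC)
#'
#' Clustering accuracy against a known partition: each found cluster is
#' matched to the known cluster with which it overlaps most, and the matched
#' overlap sizes are summed and divided by the total number of objects:
#' \deqn{FVIC = \sum_{c \in C_F} \max_{c^* \in C_K} |c \cap c^*| / N.}
#' 1 means every found cluster lies inside a single known cluster.  The score
#' is invariant to cluster order in both arguments.
#'
#' @param found Found clustering ([as_partition()]-coercible).
#' @param known Known (ground-truth) clustering over the same objects.
#' @return A number in `(0, 1]`.
#' @examples
#' fvic(list(c("a", "b"), c("c", "d")), list(c("a", "c"), c("b", "d")))  # 0.5
#' @export
fvic <- function(found, known) {
  found <- as_partition(found)
  known <- as_partition(known)
  f_ids <- unlist(found, use.names = FALSE)
  k_ids <- unlist(known, use.names = FALSE)
  if (length(f_ids) != length(k_ids) || !setequal(f_ids, k_ids)) {
    stop("universe mismatch: found and known partitions must cover the ",
         "same objects")
  }
  N <- length(k_ids)
  k_label <- stats::setNames(rep(seq_along(known), lengths(known)), k_ids)
  matched <- vapply(found, function(cl) {
    max(tabulate(k_label[cl], nbins = length(known)))
  }, numeric(1))
  sum(matched) / N
}

#' Read a truth or seed TSV (`target_id <TAB> cluster_index`, 0-based)
#'
#' @param path Path to the TSV; `#` comments and an optional `target_id`
#'   header are skipped.
#' @return Named integer vector target id -> 1-based cluster index.
#' @export
load_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ids <- character(0)
  ks <- integer(0)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(ids) == 0L && any(fields == "target_id")) next
    if (length(fields) != 2L) {
      stop("malformed row at line ", ln, ": expected 2 tab-separated fields")
    }
    k <- suppressWarnings(as.integer(fields[2]))
    if (is.na(k) || k < 0L) {
      stop("malformed row at line ", ln,
           ": cluster index must be a non-negative integer")
    }
    ids <- c(ids, fields[1])
    ks <- c(ks, k)
  }
  if (anyDuplicated(ids)) stop("duplicated target id(s) in ", path)
  stats::setNames(ks + 1L, ids)
}

#' Write labels as a truth/seed TSV (0-based cluster indices)
#'
#' @param labels Named integer vector (1-based cluster indices).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", names(labels), as.integer(labels) - 1L), con)
  invisible(path)
}
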
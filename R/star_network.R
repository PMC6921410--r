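#' Declare a star network schema
#'
#' A star schema has a single *target* type (the object type that gets
#' clustered, e.g. a formula) and one or more *attribute* types (the context
#' types it links to, e.g. herb, function, symptom).  Every edge of a star
#' network joins a target object to an attribute object; attribute objects
#' never link to each other.
#'
#' @param target_type Name of the target object type (length-1 character).
#' @param attribute_types Character vector of attribute type names, in the
#'   order used for matrix decomposition and target embedding.
#' @return An object of class `star_schema`.
#' @examples
#' star_schema("formula", c("function", "herb", "symptom"))
#' @export
star_schema <- function(target_type, attribute_types) {
  stopifnot(is.character(target_type), length(target_type) == 1L,
            nzchar(target_type),
            is.character(attribute_types), length(attribute_types) >= 1L,
            all(nzchar(attribute_types)))
  types <- c(target_type, attribute_types)
  if (anyDuplicated(types)) {
    stop("type names must be unique and the target type must not appear ",
         "among the attribute types")
  }
  structure(list(target_type = target_type,
                 attribute_types = attribute_types),
            class = "star_schema")
}

#' @export
print.star_schema <- function(x, ...) {
  cat("<star_schema> target:", x$target_type,
      "| attributes:", paste(x$attribute_types, collapse = ", "), "\n")
  invisible(x)
}

#' Construct a star network from an edge table
#'
#' Builds a validated weighted star network.  Duplicate
#' (target, attribute-type, attribute) rows are aggregated by summing their
#' weights.  Object registries preserve first-appearance order so that all
#' derived matrices are reproducible.
#'
#' @param edges A data frame with columns `target_id`, `attribute_type`,
#'   `attribute_id` and optionally `weight` (default 1); weights must be
#'   finite and positive.
#' @param schema A [star_schema()]; if `NULL`, inferred with target type
#'   `"target"` and attribute types in order of first appearance.
#' @param targets Optional character vector pre-registering target ids (used
#'   to retain isolated targets); must contain every target id in `edges`.
#' @return An object of class `star_network` with fields `schema`, `targets`,
#'   `attributes` (named list of per-type registries) and the aggregated
#'   `edges` data frame.
#' @examples
#' edges <- data.frame(
#'   target_id = c("f1", "f1", "f2"),
#'   attribute_type = c("herb", "symptom", "herb"),
#'   attribute_id = c("h1", "s1", "h1"),
#'   weight = c(1, 2, 1)
#' )
#' net <- star_network(edges)
#' net
#' @export
star_network <- function(edges, schema = NULL, targets = NULL) {
  stopifnot(is.data.frame(edges))
  required <- c("target_id", "attribute_type", "attribute_id")
  if (!all(required %in% names(edges))) {
    stop("edges must have columns target_id, attribute_type, attribute_id")
  }
  if (is.null(edges$weight)) edges$weight <- 1
  edges <- data.frame(
    target_id = as.character(edges$target_id),
    attribute_type = as.character(edges$attribute_type),
    attribute_id = as.character(edges$attribute_id),
    weight = as.numeric(edges$weight),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) > 0 &&
      (anyNA(edges$weight) || any(!is.finite(edges$weight)) ||
       any(edges$weight <= 0))) {
    stop("edge weights must be finite and > 0")
  }

  if (is.null(schema)) {
    atypes <- unique(edges$attribute_type)
    if (length(atypes) == 0L) {
      stop("cannot infer a schema from an empty edge table; pass `schema`")
    }
    schema <- star_schema("target", atypes)
  }
  stopifnot(inherits(schema, "star_schema"))

  if (nrow(edges) > 0) {
    bad_type <- !(edges$attribute_type %in% schema$attribute_types)
    if (any(edges$attribute_type == schema$target_type)) {
      stop("star-property violation: edge declares the target type '",
           schema$target_type, "' in the attribute-type column")
    }
    if (any(bad_type)) {
      stop("unknown attribute type(s): ",
           paste(unique(edges$attribute_type[bad_type]), collapse = ", "))
    }
  }

  tgt_ids <- unique(edges$target_id)
  if (!is.null(targets)) {
    targets <- as.character(targets)
    if (anyDuplicated(targets)) stop("duplicated ids in `targets`")
    if (!all(tgt_ids %in% targets)) {
      stop("edges reference target ids not present in `targets`")
    }
    tgt_ids <- targets
  }

  attr_reg <- lapply(schema$attribute_types, function(a) {
    unique(edges$attribute_id[edges$attribute_type == a])
  })
  names(attr_reg) <- schema$attribute_types

  # an id may not serve both as a target and as an attribute object
  overlap <- intersect(tgt_ids, unlist(attr_reg, use.names = FALSE))
  if (length(overlap) > 0) {
    stop("star-property violation: id(s) appear both as target and as ",
         "attribute objects: ", paste(utils::head(overlap, 5), collapse = ", "))
  }

  # aggregate duplicate (target, type, attribute) rows, preserving the order
  # of first appearance
  if (nrow(edges) > 0) {
    key <- paste(edges$target_id, edges$attribute_type, edges$attribute_id,
                 sep = "\x1f")
    first <- !duplicated(key)
    w <- vapply(split(edges$weight, factor(key, levels = key[first])),
                sum, numeric(1))
    edges <- edges[first, , drop = FALSE]
    edges$weight <- as.numeric(w)
    rownames(edges) <- NULL
  }

  structure(list(schema = schema,
                 targets = tgt_ids,
                 attributes = attr_reg,
                 edges = edges),
            class = "star_network")
}

#' @export
print.star_network <- function(x, ...) {
  cat("<star_network> ", length(x$targets), " ", x$schema$target_type,
      " object(s), ", nrow(x$edges), " aggregated edge(s)\n", sep = "")
  for (a in x$schema$attribute_types) {
    cat("  ", a, ": ", length(x$attributes[[a]]), " object(s)\n", sep = "")
  }
  invisible(x)
}

#' Read a star network from an edge TSV file
#'
#' The format is one edge per line:
#' `target_id <TAB> attribute_type <TAB> attribute_id <TAB> weight`, UTF-8.
#' The weight column may be omitted (defaults to 1).  Lines starting with
#' `#` are skipped; a header line is detected by the literal string
#' `target_id`.  Duplicate edges are aggregated by weight summation.
#'
#' @param path Path to the TSV file.
#' @param schema Optional [star_schema()]; inferred from the file if `NULL`.
#' @return A validated [star_network()].
#' @export
load_network <- function(path, schema = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  header_seen <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!header_seen && length(rows) == 0L && any(fields == "target_id")) {
      header_seen <- TRUE
      next
    }
    if (length(fields) < 3L || length(fields) > 4L) {
      stop("malformed row at line ", ln, ": expected 3 or 4 tab-separated ",
           "fields, got ", length(fields))
    }
    if (any(!nzchar(trimws(fields[1:3])))) {
      stop("malformed row at line ", ln, ": empty id or type field")
    }
    w <- if (length(fields) == 4L) suppressWarnings(as.numeric(fields[4])) else 1
    if (is.na(w)) {
      stop("malformed row at line ", ln, ": weight '", fields[4],
           "' is not a number")
    }
    if (!is.finite(w) || w <= 0) {
      stop("validation error at line ", ln, ": weight must be finite and > 0")
    }
    rows[[length(rows) + 1L]] <- list(fields[1], fields[2], fields[3], w)
  }
  if (length(rows) == 0L) stop("no edges found in ", path)
  edges <- data.frame(
    target_id = vapply(rows, `[[`, character(1), 1L),
    attribute_type = vapply(rows, `[[`, character(1), 2L),
    attribute_id = vapply(rows, `[[`, character(1), 3L),
    weight = vapply(rows, `[[`, numeric(1), 4L),
    stringsAsFactors = FALSE
  )
  star_network(edges, schema = schema)
}

#' Write a star network to an edge TSV file
#'
#' Writes the aggregated edge table in the format read by [load_network()].
#'
#' @param net A [star_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "star_network"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("target_id\tattribute_type\tattribute_id\tweight", con)
  if (nrow(net$edges) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%s",
                       net$edges$target_id, net$edges$attribute_type,
                       net$edges$attribute_id,
                       format(net$edges$weight, trim = TRUE, digits = 15)),
               con)
  }
  invisible(path)
}

#' Decompose a star network into per-type bipartite relation matrices
#'
#' For each attribute type a matrix W is built with one row per target object
#' and one column per attribute object of that type; `W[i, j]` is the total
#' aggregated link weight between target i and attribute j.  Targets with no
#' links of a type get an all-zero row.
#'
#' @param net A [star_network()].
#' @return Named list (one entry per attribute type, in schema order) of
#'   non-negative numeric matrices with dimnames.
#' @export
decompose_bipartite <- function(net) {
  stopifnot(inherits(net, "star_network"))
  out <- lapply(net$schema$attribute_types, function(a) {
    cols <- net$attributes[[a]]
    W <- matrix(0, nrow = length(net$targets), ncol = length(cols),
                dimnames = list(net$targets, cols))
    e <- net$edges[net$edges$attribute_type == a, , drop = FALSE]
    if (nrow(e) > 0) {
      W[cbind(match(e$target_id, net$targets),
              match(e$attribute_id, cols))] <- e$weight
    }
    W
  })
  names(out) <- net$schema$attribute_types
  out
}

#' Induce the subnetwork spanned by a subset of target objects
#'
#' The subnetwork keeps exactly the targets in `target_subset` (in registry
#' order), every attribute object still linked to at least one of them, and
#' all edges among retained objects.  Attribute objects left with zero links
#' are dropped; by convention their within-cluster rank is 0.
#'
#' @param net A [star_network()].
#' @param target_subset Character vector of target ids (subset of the
#'   registry).
#' @return A [star_network()]; an empty subset yields a degenerate network
#'   flagged with attribute `degenerate = TRUE`.
#' @export
induced_subnetwork <- function(net, target_subset) {
  stopifnot(inherits(net, "star_network"))
  target_subset <- as.character(target_subset)
  unknown <- setdiff(target_subset, net$targets)
  if (length(unknown) > 0) {
    stop("unknown target id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- net$targets[net$targets %in% target_subset]
  e <- net$edges[net$edges$target_id %in% keep, , drop = FALSE]
  rownames(e) <- NULL
  sub <- star_network(e, schema = net$schema, targets = keep)
  if (length(keep) == 0L) attr(sub, "degenerate") <- TRUE
  sub
}
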
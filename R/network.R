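#' Construct an interaction network
#'
#' A directed graph over a fixed strain set in which every edge
#' producer -> receiver carries a non-empty *support set*: the conditions
#' (media) under which the inhibition was detected. The edge weight used
#' throughout is the support size.
#'
#' @param strains character vector of strain identifiers (canonical order).
#' @param edges data.frame with columns `producer`, `receiver`, and a list
#'   column `support` of character vectors (subsets of `conditions`).
#' @param conditions character vector of condition names.
#' @param phylum optional named character vector of phylum labels.
#' @return object of class `interaction_network`: list with `strains`,
#'   `conditions`, `phylum` and `edges` (data.frame with `producer`,
#'   `receiver`, `support`, `support_count`).
#' @export
interaction_network <- function(strains, edges, conditions, phylum = NULL) {
  strains <- as.character(strains)
  if (anyDuplicated(strains)) stop("strain identifiers must be unique")
  if (nrow(edges)) {
    if (any(!edges$producer %in% strains) || any(!edges$receiver %in% strains))
      stop("edge endpoint not in strain set")
    if (any(edges$producer == edges$receiver))
      stop("self-edges are not allowed")
    supp <- edges$support
    if (any(vapply(supp, length, integer(1)) == 0L))
      stop("every edge must have a non-empty support set")
    if (any(!unlist(supp) %in% conditions))
      stop("edge support contains unknown condition")
    if (anyDuplicated(paste(edges$producer, edges$receiver, sep = "\r")))
      stop("duplicate (producer, receiver) edges")
    # canonical edge order: producer then receiver in strain order
    o <- order(match(edges$producer, strains), match(edges$receiver, strains))
    edges <- edges[o, , drop = FALSE]
    edges$support_count <- vapply(edges$support, length, integer(1))
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(producer = character(), receiver = character(),
                        support_count = integer())
    edges$support <- list()
    edges <- edges[c("producer", "receiver", "support", "support_count")]
  }
  structure(list(strains = strains, conditions = as.character(conditions),
                 edges = edges, phylum = phylum),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$strains), "strains,",
      nrow(x$edges), "directed edges,", length(x$conditions),
      if (length(x$conditions) == 1) "condition\n" else "conditions\n")
  if (nrow(x$edges)) {
    cat("Support sizes:\n")
    print(table(x$edges$support_count))
  }
  invisible(x)
}

n_edges <- function(network) nrow(network$edges)

#' Union network across all conditions
#'
#' Collapses a multi-condition tensor into one directed graph: an edge
#' producer -> receiver is present iff the inhibition was detected under at
#' least one condition, and its support set lists exactly the conditions of
#' detection. This is the object all downstream statistics operate on.
#'
#' @param tensor an [inhibition_tensor()]
#' @return an [interaction_network()]
#' @export
union_network <- function(tensor) {
  stopifnot(inherits(tensor, "inhibition_tensor"))
  any_det <- apply(tensor$entries, c(1, 2), max)
  idx <- which(any_det == 1L, arr.ind = TRUE)
  supp <- lapply(seq_len(nrow(idx)), function(i) {
    tensor$conditions[tensor$entries[idx[i, 1], idx[i, 2], ] == 1L]
  })
  edges <- data.frame(producer = tensor$strains[idx[, 1]],
                      receiver = tensor$strains[idx[, 2]])
  edges$support <- supp
  interaction_network(tensor$strains, edges, tensor$conditions,
                      phylum = tensor$phylum)
}

#' Single-condition network slice
#'
#' @param tensor an [inhibition_tensor()]
#' @param condition a condition name present in the tensor.
#' @return an [interaction_network()] whose edges are exactly that
#'   condition's detections, each with singleton support.
#' @export
condition_slice <- function(tensor, condition) {
  stopifnot(inherits(tensor, "inhibition_tensor"))
  if (!condition %in% tensor$conditions)
    stop("unknown condition '", condition, "'; available: ",
         paste(tensor$conditions, collapse = ", "))
  m <- tensor$entries[, , condition]
  idx <- which(m == 1L, arr.ind = TRUE)
  edges <- data.frame(producer = tensor$strains[idx[, 1]],
                      receiver = tensor$strains[idx[, 2]])
  edges$support <- rep(list(condition), nrow(edges))
  interaction_network(tensor$strains, edges, condition,
                      phylum = tensor$phylum)
}

# Dense 0/1 adjacency of the union graph (producers in rows); the fast
# internal representation used by the statistics and the null models.
as_adjacency <- function(network) {
  n <- length(network$strains)
  a <- matrix(0L, n, n, dimnames = list(network$strains, network$strains))
  if (nrow(network$edges))
    a[cbind(match(network$edges$producer, network$strains),
            match(network$edges$receiver, network$strains))] <- 1L
  a
}

# Inverse of as_adjacency for networks without meaningful support: each
# edge gets the full condition label set supplied (default a single
# placeholder condition).
network_from_adjacency <- function(a, conditions = "c1", strains = NULL,
                                   phylum = NULL) {
  if (is.null(strains)) strains <- rownames(a)
  if (is.null(strains)) strains <- sprintf("s%02d", seq_len(nrow(a)))
  idx <- which(a != 0L, arr.ind = TRUE)
  edges <- data.frame(producer = strains[idx[, 1]],
                      receiver = strains[idx[, 2]])
  edges$support <- rep(list(conditions[1]), nrow(edges))
  interaction_network(strains, edges, conditions, phylum = phylum)
}

#' Export a network as Cytoscape SIF
#'
#' One line per edge: `producer<TAB>inhibits<TAB>receiver`. Strains with no
#' edges are appended as bare node lines so Cytoscape shows the full
#' strain set.
#'
#' @param network an [interaction_network()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_sif <- function(network, path) {
  e <- network$edges
  lines <- if (nrow(e)) paste(e$producer, "inhibits", e$receiver, sep = "\t")
           else character()
  isolated <- setdiff(network$strains, c(e$producer, e$receiver))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Uses igraph's GraphML writer. Edges carry `support_count`; nodes carry
#' `phylum` (when known) and, when a hierarchy result is supplied, `score`
#' and `level`.
#'
#' @param network an [interaction_network()]
#' @param path output file
#' @param hierarchy optional result of [hierarchy_scores()] (with levels
#'   assigned) whose `score`/`level` columns are attached to the nodes.
#' @return invisibly, `path`
#' @export
write_graphml <- function(network, path, hierarchy = NULL) {
  g <- igraph::make_empty_graph(n = length(network$strains), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = network$strains)
  if (!is.null(network$phylum))
    g <- igraph::set_vertex_attr(g, "phylum",
                                 value = unname(network$phylum[network$strains]))
  if (!is.null(hierarchy)) {
    tab <- hierarchy$table
    m <- match(network$strains, tab$strain)
    g <- igraph::set_vertex_attr(g, "score", value = tab$score[m])
    if ("level" %in% names(tab))
      g <- igraph::set_vertex_attr(g, "level",
                                   value = as.character(tab$level[m]))
  }
  if (nrow(network$edges)) {
    ends <- rbind(match(network$edges$producer, network$strains),
                  match(network$edges$receiver, network$strains))
    g <- igraph::add_edges(g, as.vector(ends))
    g <- igraph::set_edge_attr(g, "support_count",
                               value = network$edges$support_count)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
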
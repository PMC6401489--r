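subset_label <- function(conds) paste(conds, collapse = "&")

#' Cross-condition conservation summary
#'
#' Partitions the union network's edges by the exact subset of conditions
#' under which each was detected (the Venn partition: every union edge
#' falls in exactly one of the 2^k - 1 non-empty cells), and tabulates the
#' support-size histogram and the "conserved in at least s conditions"
#' counts with percentages relative to the union edge count.
#'
#' @param tensor an [inhibition_tensor()]
#' @return object of class `conservation_summary`: list with
#'   `support_histogram` (named integer vector over support sizes 1..k),
#'   `venn_counts` (named integer vector; names are `&`-joined condition
#'   subsets in condition order), `conserved_at_least` (data.frame `s`,
#'   `count`, `percent` with percent = round(100 * count / union edges)),
#'   `n_union_edges`, `conditions`.
#' @export
conservation_summary <- function(tensor) {
  stopifnot(inherits(tensor, "inhibition_tensor"))
  net <- union_network(tensor)
  k <- length(tensor$conditions)
  sizes <- net$edges$support_count
  hist <- vapply(seq_len(k), function(s) sum(sizes == s), integer(1))
  names(hist) <- seq_len(k)

  # all non-empty subsets, labelled in condition order, smallest first
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(tensor$conditions, m, simplify = FALSE)), recursive = FALSE)
  venn <- stats::setNames(integer(length(subsets)),
                          vapply(subsets, subset_label, character(1)))
  if (nrow(net$edges)) {
    lab <- vapply(net$edges$support, function(s)
      subset_label(tensor$conditions[tensor$conditions %in% s]), character(1))
    tb <- table(lab)
    venn[names(tb)] <- as.integer(tb)
  }
  m <- nrow(net$edges)
  cal <- data.frame(
    s = seq_len(k),
    count = vapply(seq_len(k), function(s) sum(sizes >= s), integer(1)))
  cal$percent <- if (m > 0) as.integer(round(100 * cal$count / m)) else NA_integer_
  stopifnot(sum(venn) == m, sum(hist) == m)  # partition identity
  structure(list(support_histogram = hist, venn_counts = venn,
                 conserved_at_least = cal, n_union_edges = m,
                 conditions = tensor$conditions),
            class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat("Conservation over", length(x$conditions), "conditions;",
      x$n_union_edges, "union edges\n")
  cat("Venn cells:\n")
  print(x$venn_counts)
  cat("Conserved in at least s conditions:\n")
  print(x$conserved_at_least, row.names = FALSE)
  invisible(x)
}

#' Classify reciprocal pairs by conservation
#'
#' A reciprocal pair is `single-medium` when both of its directed edges
#' were detected in exactly one condition, and `multi-medium` when either
#' directed edge was detected in two or more. Per-edge classes are also
#' returned.
#'
#' @param network the union [interaction_network()]
#' @param pairs result of [reciprocity()] on the same network; computed if
#'   omitted.
#' @return the `pairs` data.frame with columns `class_ab`, `class_ba`
#'   (per-edge `single`/`multi`) and `class` (`single-medium` /
#'   `multi-medium`) added.
#' @export
classify_reciprocal <- function(network, pairs = NULL) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(pairs)) pairs <- reciprocity(network)
  if (!nrow(pairs)) {
    pairs$class_ab <- character()
    pairs$class_ba <- character()
    pairs$class <- character()
    return(pairs)
  }
  key <- paste(network$edges$producer, network$edges$receiver, sep = "\r")
  need <- c(paste(pairs$strain_a, pairs$strain_b, sep = "\r"),
            paste(pairs$strain_b, pairs$strain_a, sep = "\r"))
  if (!all(need %in% key))
    stop("pair is not reciprocal in this network")
  pairs$class_ab <- ifelse(pairs$support_ab >= 2, "multi", "single")
  pairs$class_ba <- ifelse(pairs$support_ba >= 2, "multi", "single")
  pairs$class <- ifelse(pairs$class_ab == "multi" | pairs$class_ba == "multi",
                        "multi-medium", "single-medium")
  pairs
}

#' Fraction of nonhierarchical (reciprocated) edges
#'
#' The share of directed edges whose reverse edge also exists -- the
#' operational definition of a "nonhierarchical" interaction. Reported as
#' a percentage rounded to the nearest integer.
#'
#' @param network an [interaction_network()]
#' @return list with `edge_count` (reciprocated directed edges), `fraction`
#'   (unrounded), `percent` (integer).
#' @export
nonhierarchical_fraction <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  m <- n_edges(network)
  if (m == 0L) {
    warning("nonhierarchical fraction is undefined on an edgeless network")
    return(list(edge_count = 0L, fraction = NA_real_, percent = NA_integer_))
  }
  a <- as_adjacency(network)
  count <- sum(a * t(a))
  list(edge_count = as.integer(count), fraction = count / m,
       percent = as.integer(round(100 * count / m)))
}
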
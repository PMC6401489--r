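#' Connectance of an interaction network
#'
#' Fraction of all possible directed interactions that are realized:
#' `|edges| / S^2` for S strains. The denominator deliberately includes the
#' diagonal, matching the convention "number of interactions / number of
#' species squared" used for antagonism matrices (105 edges among 21
#' strains gives 105/441 = 0.238, reported as 0.24).
#'
#' @param network an [interaction_network()]
#' @return a single numeric fraction in \[0, 1\] at full precision; round
#'   for display.
#' @export
connectance <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  n_edges(network) / length(network$strains)^2
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Sender-receiver asymmetry (Q)
#'
#' A signed statistic contrasting how much network structure is carried by
#' producer (sender) identity versus receiver identity. With `V_out` the
#' population variance of per-strain out-degrees (distinct targets) and
#' `V_in` that of in-degrees (distinct sources),
#' `Q = (V_in - V_out) / (V_in + V_out)`, so Q in \[-1, 1\], negative when
#' the producers are the more structured side ("producer determined") and
#' positive when the receivers are. Q flips sign exactly under graph
#' transposition.
#'
#' @param x an [interaction_network()] or an [inhibition_tensor()] (the
#'   union network is used).
#' @param definition only `"degree-variance"` is implemented; the argument
#'   exists so alternative published definitions can be added behind it.
#' @return a single numeric in \[-1, 1\]; `NA` with a warning if the network
#'   has no edges or both variances are zero (statistic undefined).
#' @export
sender_receiver_asymmetry <- function(x, definition = "degree-variance") {
  if (inherits(x, "inhibition_tensor")) x <- union_network(x)
  stopifnot(inherits(x, "interaction_network"))
  if (!identical(definition, "degree-variance"))
    stop("unimplemented Q definition: ", definition)
  if (length(x$strains) < 2)
    stop("Q requires at least 2 strains")
  if (n_edges(x) == 0L) {
    warning("Q is undefined on an edgeless network")
    return(NA_real_)
  }
  a <- as_adjacency(x)
  v_out <- pop_var(rowSums(a))
  v_in <- pop_var(colSums(a))
  if (v_in + v_out == 0) {
    warning("Q is undefined: both degree sequences are constant")
    return(NA_real_)
  }
  (v_in - v_out) / (v_in + v_out)
}

#' Per-strain degree summary
#'
#' Out-degree is the number of distinct receivers a strain inhibits;
#' in-degree the number of distinct producers inhibiting it; the partner
#' count is the number of distinct *other* strains it interacts with in
#' either role (a reciprocal partner is counted once).
#'
#' @param network an [interaction_network()]
#' @return list with `degrees` (data.frame `strain`, `out_degree`,
#'   `in_degree`, `partners`) and `mean_partners` (full precision; report
#'   at 1 decimal).
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  a <- as_adjacency(network)
  und <- (a + t(a)) > 0
  df <- data.frame(strain = network$strains,
                   out_degree = unname(rowSums(a)),
                   in_degree = unname(colSums(a)),
                   partners = unname(rowSums(und)))
  list(degrees = df, mean_partners = mean(df$partners))
}

#' Reciprocal strain pairs
#'
#' All unordered pairs `{i, j}` for which both directed edges `i -> j` and
#' `j -> i` are present; these are the network's "nonhierarchical"
#' interactions. Each pair is annotated with the support counts of its two
#' directed edges.
#'
#' @param network an [interaction_network()]
#' @return data.frame with columns `strain_a`, `strain_b` (a before b in
#'   canonical strain order), `support_ab`, `support_ba`; zero rows when no
#'   pair is reciprocal.
#' @export
reciprocity <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  empty <- data.frame(strain_a = character(), strain_b = character(),
                      support_ab = integer(), support_ba = integer())
  if (!nrow(e)) return(empty)
  key <- paste(e$producer, e$receiver, sep = "\r")
  rev_key <- paste(e$receiver, e$producer, sep = "\r")
  recip <- e[rev_key %in% key, , drop = FALSE]
  if (!nrow(recip)) return(empty)
  pi <- match(recip$producer, network$strains)
  ri <- match(recip$receiver, network$strains)
  fwd <- recip[pi < ri, , drop = FALSE]  # one row per unordered pair
  sc <- stats::setNames(e$support_count, key)
  data.frame(strain_a = fwd$producer, strain_b = fwd$receiver,
             support_ab = unname(sc[paste(fwd$producer, fwd$receiver,
                                          sep = "\r")]),
             support_ba = unname(sc[paste(fwd$receiver, fwd$producer,
                                          sep = "\r")]),
             row.names = NULL)
}

#' Global network statistics
#'
#' Convenience wrapper assembling the standard summary block: connectance,
#' sender-receiver asymmetry Q, degree summaries, reciprocal pairs, and
#' top-k producer concentration.
#'
#' @param network an [interaction_network()]
#' @param k_top number of top-ranked producers for the concentration
#'   statistic (default 4).
#' @return list of class `network_stats` with components `n_strains`,
#'   `n_edges`, `connectance`, `asymmetry_q`, `mean_partners`, `degrees`,
#'   `reciprocal_pairs`, `top_k`.
#' @export
network_stats <- function(network, k_top = 4) {
  k_top <- min(k_top, length(network$strains))
  deg <- degree_summary(network)
  hs <- hierarchy_scores(network)
  structure(list(
    n_strains = length(network$strains),
    n_edges = n_edges(network),
    connectance = connectance(network),
    asymmetry_q = if (n_edges(network) > 0)
      sender_receiver_asymmetry(network) else NA_real_,
    mean_partners = deg$mean_partners,
    degrees = deg$degrees,
    reciprocal_pairs = reciprocity(network),
    top_k = top_k_producer_share(network, hs, k = k_top)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("Network statistics (%d strains, %d edges)\n",
              x$n_strains, x$n_edges))
  cat(sprintf("  connectance C          %.2f\n", x$connectance))
  cat(sprintf("  asymmetry Q            %s\n",
              ifelse(is.na(x$asymmetry_q), "undefined",
                     sprintf("%.2f", x$asymmetry_q))))
  cat(sprintf("  mean partners/strain   %.1f\n", x$mean_partners))
  cat(sprintf("  reciprocal pairs       %d\n", nrow(x$reciprocal_pairs)))
  cat(sprintf("  top-%d producer share   %d edges (%d%%)\n",
              x$top_k$k, x$top_k$edge_count, x$top_k$percent))
  invisible(x)
}
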
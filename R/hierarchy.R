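#' Hierarchy scores from the reward/penalty scheme
#'
#' Each strain earns one reward point per distinct strain it inhibits, one
#' penalty point per distinct strain that inhibits it, and one further
#' penalty point per reciprocal partner (a strain it both inhibits and is
#' inhibited by). The score is
#' `reward - penalty_in - penalty_reciprocal`. Scoring operates on the
#' union network: an edge detected in several media still contributes a
#' single point. Because rewards and in-penalties cancel pairwise across
#' the network, scores sum to minus twice the number of reciprocal pairs.
#'
#' @param network an [interaction_network()] (the union network).
#' @return object of class `hierarchy_result`: list with `table` (data.frame
#'   `strain`, `reward`, `penalty_in`, `penalty_reciprocal`, `score`) and
#'   `n_edges`.
#' @export
hierarchy_scores <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  a <- as_adjacency(network)
  reward <- rowSums(a)
  penalty_in <- colSums(a)
  penalty_recip <- rowSums(a * t(a))
  tab <- data.frame(strain = network$strains,
                    reward = as.integer(reward),
                    penalty_in = as.integer(penalty_in),
                    penalty_reciprocal = as.integer(penalty_recip),
                    score = as.integer(reward - penalty_in - penalty_recip),
                    row.names = NULL)
  structure(list(table = tab, n_edges = n_edges(network)),
            class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, ...) {
  cat("Hierarchy scores for", nrow(x$table), "strains",
      sprintf("(sum %d)\n", sum(x$table$score)))
  print(utils::head(x$table[order(-x$table$score), ], 10), row.names = FALSE)
  invisible(x)
}

#' Assign hierarchy levels (high / medium / low)
#'
#' Default `tertile` scheme: strains are ranked by score (descending) and
#' split into three equal-as-possible groups; strains tied on score always
#' share the *higher* of the levels their positions would straddle, and if
#' all scores are equal every strain is `high`. Alternatively pass two
#' strictly decreasing numeric `thresholds` `c(t_high, t_medium)`:
#' `score >= t_high` is high, `score >= t_medium` is medium, below is low.
#'
#' Levels are presentational grouping only; they never feed back into the
#' scores.
#'
#' @param result a [hierarchy_scores()] result.
#' @param scheme `"tertile"` or `"thresholds"`.
#' @param thresholds numeric length-2, strictly decreasing; required when
#'   `scheme = "thresholds"`.
#' @return the `hierarchy_result` with a `level` column added (factor with
#'   levels high, medium, low).
#' @export
assign_levels <- function(result, scheme = c("tertile", "thresholds"),
                          thresholds = NULL) {
  stopifnot(inherits(result, "hierarchy_result"))
  scheme <- match.arg(scheme)
  tab <- result$table
  if (scheme == "thresholds") {
    if (is.null(thresholds) || length(thresholds) != 2 ||
        !(thresholds[1] > thresholds[2]))
      stop("`thresholds` must be two strictly decreasing numbers")
    lev <- ifelse(tab$score >= thresholds[1], "high",
                  ifelse(tab$score >= thresholds[2], "medium", "low"))
  } else {
    n <- nrow(tab)
    o <- order(-tab$score)
    pos_level <- c("high", "medium", "low")[
      findInterval(seq_len(n), c(1, ceiling(n / 3) + 1,
                                 ceiling(2 * n / 3) + 1))]
    # ties share the higher (better) level of their score group
    lev_by_pos <- pos_level[order(o)]          # per strain, by rank position
    best <- tapply(factor(lev_by_pos, c("high", "medium", "low")),
                   tab$score, function(f) levels(f)[min(as.integer(f))])
    lev <- unname(best[as.character(tab$score)])
  }
  result$table$level <- factor(lev, levels = c("high", "medium", "low"))
  result
}

#' Top-k producer concentration
#'
#' Ranks strains by hierarchy score (descending), breaking ties by reward
#' (descending) then strain identifier (lexicographic), and reports how
#' many of the network's edges are emitted by the k top-ranked producers,
#' both as a count and as a percentage of all edges (round-half-even to the
#' nearest integer).
#'
#' @param network an [interaction_network()]
#' @param result matching [hierarchy_scores()] result; computed if omitted.
#' @param k number of top producers, `1 <= k <= |strains|`.
#' @return list with `k`, `producers` (the k strain IDs in rank order),
#'   `edge_count`, `share` (unrounded fraction), `percent` (integer).
#' @export
top_k_producer_share <- function(network, result = NULL, k = 4) {
  stopifnot(inherits(network, "interaction_network"))
  if (is.null(result)) result <- hierarchy_scores(network)
  tab <- result$table
  if (k < 1 || k > nrow(tab))
    stop("k must be between 1 and the number of strains (", nrow(tab), ")")
  o <- order(-tab$score, -tab$reward, tab$strain)
  top <- tab$strain[o][seq_len(k)]
  count <- sum(network$edges$producer %in% top)
  share <- if (n_edges(network) > 0) count / n_edges(network) else NA_real_
  list(k = k, producers = top, edge_count = count, share = share,
       percent = if (is.na(share)) NA_integer_ else as.integer(round(100 * share)))
}
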
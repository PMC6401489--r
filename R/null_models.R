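# Fast statistic evaluators on a 0/1 adjacency matrix. These are the
# internal single-source-of-truth used by null_test(); the exported
# network-level functions agree with them (asserted in the test suite).
stat_asymmetry_q <- function(a) {
  v_out <- pop_var(rowSums(a))
  v_in <- pop_var(colSums(a))
  if (v_in + v_out == 0) return(NA_real_)
  (v_in - v_out) / (v_in + v_out)
}

stat_reciprocal_pairs <- function(a) sum(a * t(a)) / 2

stat_top_k_share <- function(a, k, strains = rownames(a)) {
  out <- rowSums(a)
  score <- out - colSums(a) - rowSums(a * t(a))
  o <- order(-score, -out, strains)
  sum(out[o][seq_len(k)]) / sum(a) * 100   # unrounded percentage
}

#' Degree-randomized null networks
#'
#' Three null families, all preserving strain count and edge count and
#' never placing self-loops:
#' \describe{
#'   \item{erdos}{edges placed uniformly at random over the off-diagonal
#'     ordered pairs, without replacement.}
#'   \item{out-preserving}{every producer keeps its out-degree; its targets
#'     are resampled uniformly from the other strains without duplicates.}
#'   \item{both-margins}{both the out- and in-degree sequences are
#'     preserved exactly via checkerboard (2x2 submatrix) swaps, starting
#'     from the observed network, with a burn-in of
#'     `burnin_factor * |edges|` accepted swaps.}
#' }
#'
#' @param network an [interaction_network()]
#' @param family one of `"erdos"`, `"out-preserving"`, `"both-margins"`.
#' @param seed integer seed; the result is deterministic given
#'   (network, family, seed).
#' @param burnin_factor accepted checkerboard swaps per edge (both-margins
#'   only; default 10).
#' @return a randomized [interaction_network()] on the same strains, with a
#'   single placeholder condition (condition support is not modelled by the
#'   nulls).
#' @export
randomize_network <- function(network,
                              family = c("erdos", "out-preserving",
                                         "both-margins"),
                              seed, burnin_factor = 10) {
  stopifnot(inherits(network, "interaction_network"))
  family <- match.arg(family)
  a <- as_adjacency(network)
  b <- withr::with_seed(seed, randomize_adjacency(a, family, burnin_factor))
  network_from_adjacency(b, conditions = "randomized",
                         strains = network$strains, phylum = network$phylum)
}

# seed handling is the caller's responsibility
randomize_adjacency <- function(a, family, burnin_factor = 10) {
  n <- nrow(a)
  m <- sum(a)
  b <- matrix(0L, n, n, dimnames = dimnames(a))
  if (family == "erdos") {
    offdiag <- which(row(b) != col(b))
    b[sample(offdiag, m)] <- 1L
  } else if (family == "out-preserving") {
    for (i in seq_len(n)) {
      d <- sum(a[i, ])
      if (d > 0) b[i, sample(setdiff(seq_len(n), i), d)] <- 1L
    }
  } else {  # both-margins: checkerboard swaps from the observed matrix
    if (n < 2 || m == 0) return(a)
    b <- a
    edges <- which(b == 1L, arr.ind = TRUE)  # maintained edge list
    target <- burnin_factor * m
    accepted <- 0L
    attempts <- 0L
    max_attempts <- max(1000L, 200L * target)
    while (accepted < target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("both-margins randomization: could not reach ", target,
             " accepted swaps (degree sequence too constrained)")
      ij <- sample.int(nrow(edges), 2)
      e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
      a1 <- e1[1]; b1 <- e1[2]; a2 <- e2[1]; b2 <- e2[2]
      # swap a1->b1, a2->b2  =>  a1->b2, a2->b1
      if (a1 == a2 || b1 == b2 || a1 == b2 || a2 == b1) next
      if (b[a1, b2] == 1L || b[a2, b1] == 1L) next
      b[a1, b1] <- 0L; b[a2, b2] <- 0L
      b[a1, b2] <- 1L; b[a2, b1] <- 1L
      edges[ij[1], ] <- c(a1, b2)
      edges[ij[2], ] <- c(a2, b1)
      accepted <- accepted + 1L
    }
  }
  b
}

#' Permutation null-model test of a network statistic
#'
#' Computes the statistic on the observed network and on `n_perm`
#' randomized networks drawn from the chosen null family, and returns the
#' add-one empirical p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` for
#' `direction = "greater"` (mirrored for `"less"`), which is never zero and
#' lies in (0, 1\].
#'
#' @param network an [interaction_network()]
#' @param statistic `"top_k_share"`, `"reciprocal_pairs"`, or
#'   `"asymmetry_q"`.
#' @param family null family, see [randomize_network()].
#' @param n_perm number of null draws (>= 99).
#' @param seed integer seed; results are bit-for-bit reproducible given
#'   (seed, n_perm, family).
#' @param k top-k parameter (only for `top_k_share`; default 4).
#' @param direction `"greater"` (default) or `"less"`.
#' @param burnin_factor passed to the both-margins randomizer.
#' @return object of class `null_model_result`: list with `statistic`,
#'   `observed`, `null_sample` (length `n_perm`), `p_value`, `direction`,
#'   `family`, `n_perm`, `n_excluded` (null draws on which the statistic
#'   was undefined; excluded from the comparison), `seed`, `k`.
#' @export
null_test <- function(network,
                      statistic = c("top_k_share", "reciprocal_pairs",
                                    "asymmetry_q"),
                      family = c("erdos", "out-preserving", "both-margins"),
                      n_perm = 999, seed = 1, k = 4,
                      direction = c("greater", "less"),
                      burnin_factor = 10) {
  stopifnot(inherits(network, "interaction_network"))
  statistic <- match.arg(statistic)
  family <- match.arg(family)
  direction <- match.arg(direction)
  if (n_perm < 99) stop("n_perm must be at least 99")
  a <- as_adjacency(network)
  if (sum(a) == 0L) stop("null_test requires a network with edges")
  fn <- switch(statistic,
               top_k_share = function(x) stat_top_k_share(x, k),
               reciprocal_pairs = stat_reciprocal_pairs,
               asymmetry_q = stat_asymmetry_q)
  observed <- fn(a)
  if (is.na(observed)) stop("observed statistic is undefined on this network")
  nulls <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    fn(randomize_adjacency(a, family, burnin_factor))
  }, numeric(1)))
  ok <- !is.na(nulls)
  n_eff <- sum(ok)
  extreme <- if (direction == "greater") sum(nulls[ok] >= observed)
             else sum(nulls[ok] <= observed)
  structure(list(statistic = statistic, observed = observed,
                 null_sample = nulls, p_value = (1 + extreme) / (1 + n_eff),
                 direction = direction, family = family, n_perm = n_perm,
                 n_excluded = as.integer(n_perm - n_eff), seed = seed,
                 k = if (statistic == "top_k_share") k else NA_integer_),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("Null-model test: %s vs %s null (n_perm = %d, seed = %d)\n",
              x$statistic, x$family, x$n_perm, x$seed))
  cat(sprintf("  observed  %.4g\n  null mean %.4g\n  p (%s) = %.4g\n",
              x$observed, mean(x$null_sample, na.rm = TRUE), x$direction,
              x$p_value))
  if (x$n_excluded > 0)
    cat("  (", x$n_excluded, "null draws excluded: statistic undefined )\n")
  invisible(x)
}
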
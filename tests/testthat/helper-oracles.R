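# Shared fixtures and independent brute-force oracles. The oracles
# deliberately re-derive every quantity by explicit looping over strains /
# edges, sharing no code path with the package internals they check.

# random binary tensor: iid Bernoulli(p) entries, zero diagonal
random_tensor <- function(n = 8, k = 3, p = 0.2, seed = 1) {
  strains <- sprintf("t%02d", seq_len(n))
  conds <- paste0("c", seq_len(k))
  withr::with_seed(seed, {
    entries <- array(stats::rbinom(n * n * k, 1, p), dim = c(n, n, k),
                     dimnames = list(strains, strains, conds))
  })
  for (j in seq_len(k)) diag(entries[, , j]) <- 0L
  inhibition_tensor(entries, strains, conds)
}

# tiny network from an explicit edge list over named strains
edge_network <- function(strains, from, to, conditions = "c1") {
  edges <- data.frame(producer = from, receiver = to)
  edges$support <- rep(list(conditions[1]), length(from))
  interaction_network(strains, edges, conditions)
}

# rule-by-rule hierarchy scoring: walk every ordered strain pair and apply
# the three scoring sentences literally
oracle_scores <- function(network) {
  s <- network$strains
  has <- function(p, r) any(network$edges$producer == p &
                            network$edges$receiver == r)
  vapply(s, function(i) {
    reward <- 0L; pen_in <- 0L; pen_rec <- 0L
    for (j in setdiff(s, i)) {
      fwd <- has(i, j); bwd <- has(j, i)
      if (fwd) reward <- reward + 1L          # one reward per strain inhibited
      if (bwd) pen_in <- pen_in + 1L          # one penalty per inhibitor
      if (fwd && bwd) pen_rec <- pen_rec + 1L # one more for reciprocal pairs
    }
    reward - pen_in - pen_rec
  }, integer(1))
}

# Q from first principles: degrees by double loop, population variance via
# E[x^2] - E[x]^2
oracle_q <- function(network) {
  s <- network$strains
  outd <- vapply(s, function(i) sum(network$edges$producer == i), numeric(1))
  ind <- vapply(s, function(i) sum(network$edges$receiver == i), numeric(1))
  v <- function(x) mean(x^2) - mean(x)^2
  (v(ind) - v(outd)) / (v(ind) + v(outd))
}

# reciprocal pairs by double loop over ordered pairs
oracle_reciprocal_pairs <- function(network) {
  s <- network$strains
  has <- function(p, r) any(network$edges$producer == p &
                            network$edges$receiver == r)
  out <- character(0)
  for (i in s) for (j in s) {
    if (i < j && has(i, j) && has(j, i)) out <- c(out, paste(i, j))
  }
  out
}

# per-edge Venn tabulation straight from the tensor entries
oracle_venn <- function(tensor) {
  s <- tensor$strains; k <- tensor$conditions
  cells <- list()
  for (i in seq_along(s)) for (j in seq_along(s)) {
    det <- k[tensor$entries[i, j, ] == 1L]
    if (length(det)) {
      lab <- paste(det, collapse = "&")
      cells[[lab]] <- (cells[[lab]] %||% 0L) + 1L
    }
  }
  unlist(cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
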
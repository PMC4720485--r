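# Independent oracles used by the property tests. These deliberately share
# no code with the package: neighbor generation, connectivity search and the
# master-equation solve are re-derived from first principles here.

oracle_offsets <- local({
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

oracle_lin <- function(v, dims) (v[1] - 1) + (v[2] - 1) * dims[1] +
  (v[3] - 1) * dims[1] * dims[2] + 1

# minimal threshold t such that start and end are connected through voxels
# with energy <= t (26-connectivity); equals the exact minimax bottleneck
oracle_bottleneck <- function(arr, s, e) {
  dims <- dim(arr)
  E <- as.vector(arr)
  is_ <- oracle_lin(s, dims); ie <- oracle_lin(e, dims)
  cands <- sort(unique(E[is.finite(E)]))
  cands <- cands[cands >= max(E[is_], E[ie])]
  for (t in cands) {
    ok <- is.finite(E) & E <= t
    if (!ok[is_] || !ok[ie]) next
    seen <- rep(FALSE, length(E))
    q <- is_; seen[q] <- TRUE
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      u0 <- u - 1
      v <- c(u0 %% dims[1], (u0 %/% dims[1]) %% dims[2],
             u0 %/% (dims[1] * dims[2])) + 1
      nb <- sweep(oracle_offsets, 2, v, `+`)
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      ids <- apply(nb[keep, , drop = FALSE], 1, oracle_lin, dims = dims)
      ids <- ids[ok[ids] & !seen[ids]]
      seen[ids] <- TRUE
      q <- c(q, ids)
    }
    if (seen[ie]) return(t)
  }
  Inf
}

# exhaustive enumeration of every simple 26-connected path (tiny grids only):
# returns the minimum over paths of the maximum node energy
oracle_enumerate_minimax <- function(arr, s, e) {
  dims <- dim(arr)
  best <- Inf
  visit <- function(v, cur, seen) {
    cur <- max(cur, arr[v[1], v[2], v[3]])
    if (cur >= best) return()
    if (all(v == e)) { best <<- cur; return() }
    seen[oracle_lin(v, dims)] <- TRUE
    for (r in seq_len(nrow(oracle_offsets))) {
      w <- v + oracle_offsets[r, ]
      if (any(w < 1) || any(w > dims)) next
      if (!is.finite(arr[w[1], w[2], w[3]])) next
      if (seen[oracle_lin(w, dims)]) next
      visit(w, cur, seen)
    }
  }
  visit(s, -Inf, rep(FALSE, prod(dims)))
  best
}

# absorption probability at the heme end of a birth-death chain, from the
# full master equation: linear solve of the harmonicity equations
oracle_absorption <- function(forward, backward) {
  n <- length(forward)
  A <- matrix(0, n, n)
  rhs_heme <- rhs_solv <- numeric(n)
  for (i in seq_len(n)) {
    tot <- forward[i] + backward[i]  # row-normalized: embedded jump chain
    A[i, i] <- -1
    if (i > 1) A[i, i - 1] <- backward[i] / tot
    if (i < n) A[i, i + 1] <- forward[i] / tot
    if (i == n) rhs_heme[i] <- -forward[i] / tot
    if (i == 1) rhs_solv[i] <- -backward[i] / tot
  }
  # two independent solves; their sum tests probability conservation
  c(to_heme = solve(A, rhs_heme)[1], to_solvent = solve(A, rhs_solv)[1])
}

# greedy representative-set size: smallest prefix of count-sorted combos
# reaching the coverage target
oracle_greedy_prefix <- function(counts, total, target) {
  o <- order(-counts)
  cum <- cumsum(counts[o]) / total
  which(cum >= target - 1e-12)[1]
}

# a standard single-tunnel fixture used across grid/profile tests
fixture_tunnel <- function(wells = c(-2, -1), barriers = 3) {
  tunnel_spec("T", rbind(c(3, 5, 5), c(22, 5, 5)),
              wells = wells, barriers = barriers)
}

fixture_grid <- function(noise_sd = 0, seed = 1, wells = c(-2, -1),
                         barriers = 3) {
  make_grid(c(26, 9, 9), fixture_tunnel(wells, barriers),
            noise_sd = noise_sd, seed = seed)
}

# tiny MSA + annotation for the sequence-feature tests
fixture_msa <- function() {
  mm <- make_msa(30, c("Y-F-L-Q-V" = 0.5, "Y-H-H-Q-W" = 0.3,
                       "L-F-L-V-V" = 0.2), seed = 11)
  mm$map <- map_structural_positions(mm$msa, "REF", mm$annotation)
  mm
}
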
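# 26-neighbor offsets (exclude the null move), fixed column order so all
# tie-breaking downstream is reproducible.
neighbor_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

.lin <- function(ijk, dims) {
  (ijk[, 1] - 1) + (ijk[, 2] - 1) * dims[1] + (ijk[, 3] - 1) * dims[1] * dims[2] + 1
}
.unlin <- function(id, dims) {
  id0 <- id - 1
  ix <- id0 %% dims[1]
  iy <- (id0 %/% dims[1]) %% dims[2]
  iz <- id0 %/% (dims[1] * dims[2])
  cbind(ix + 1, iy + 1, iz + 1)
}

#' Extract the minimax (bottleneck) migration path between two voxels
#'
#' Among all 26-connected voxel paths from `start` to `end` that avoid
#' sterically forbidden (+Inf) voxels, returns a path minimizing the maximum
#' node free energy -- the discrete analogue of the lowest saddle a ligand
#' must cross. This is the primary criterion and it is exact. Ties are broken
#' deterministically: among bottleneck-optimal paths, the one with the
#' smallest energy path-integral (trapezoid over arc length, node energies
#' shifted to be non-negative within the feasible subgraph so the search is
#' a valid Dijkstra), then the shortest arc length, then the smallest voxel
#' linear index at each selection step.
#'
#' @param grid an [energy_grid()].
#' @param start,end 1-based integer voxel index 3-vectors.
#' @return A tibble of class `migration_path` with columns `ix, iy, iz`
#'   (voxel indices), `energy` (kcal/mol) and `arc_length` (cumulative, in
#'   Angstrom; diagonal moves carry their Euclidean length).
#' @export
extract_minimax_path <- function(grid, start, end) {
  stopifnot(inherits(grid, "energy_grid"))
  dims <- grid$dims
  chk <- function(v, nm) {
    v <- as.integer(v)
    if (length(v) != 3 || any(v < 1) || any(v > dims))
      stop_data(paste0("`", nm, "` must be a voxel index inside the grid"))
    v
  }
  start <- chk(start, "start"); end <- chk(end, "end")
  E <- as.vector(grid$values)
  s <- .lin(matrix(start, 1), dims); e <- .lin(matrix(end, 1), dims)
  if (!is.finite(E[s]) || !is.finite(E[e]))
    stop_data("start and end voxels must have finite energy")
  if (s == e) {
    return(new_migration_path(matrix(start, 1), E[s], 0, grid))
  }

  off <- neighbor_offsets()
  steps <- sqrt(rowSums((off %*% diag(grid$spacing))^2))
  nb_of <- function(id) {
    ijk <- .unlin(id, dims)
    cand <- sweep(off, 2, ijk[1, ], `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
      cand[, 2] >= 1 & cand[, 2] <= dims[2] &
      cand[, 3] >= 1 & cand[, 3] <= dims[3]
    list(id = .lin(cand[ok, , drop = FALSE], dims), len = steps[ok])
  }

  n <- length(E)
  # pass 1: bottleneck Dijkstra on node energies
  d <- rep(Inf, n); d[s] <- E[s]
  visited <- rep(FALSE, n)
  repeat {
    d_act <- ifelse(visited, Inf, d)
    u <- which.min(d_act)
    if (!is.finite(d_act[u])) break
    if (u == e) break
    visited[u] <- TRUE
    nb <- nb_of(u)
    keep <- is.finite(E[nb$id]) & !visited[nb$id]
    ids <- nb$id[keep]
    if (length(ids)) {
      cand <- pmax(d[u], E[ids])
      upd <- cand < d[ids]
      d[ids[upd]] <- cand[upd]
    }
  }
  if (!is.finite(d[e]))
    stop_data("end voxel is unreachable through finite-energy voxels")
  bstar <- d[e]

  # pass 2: deterministic tie-break inside the feasible subgraph {E <= bstar}
  feas <- is.finite(E) & E <= bstar + 1e-12
  Emin <- min(E[feas])
  Esh <- E - Emin  # >= 0 on the feasible set
  c1 <- rep(Inf, n); c2 <- rep(Inf, n)
  c1[s] <- 0; c2[s] <- 0
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  tol <- 1e-12
  repeat {
    c1a <- ifelse(done, Inf, c1)
    m1 <- min(c1a)
    if (!is.finite(m1)) break
    cands <- which(c1a <= m1 + tol)
    if (length(cands) > 1) {
      m2 <- min(c2[cands])
      cands <- cands[c2[cands] <= m2 + tol]
    }
    u <- min(cands)
    if (u == e) break
    done[u] <- TRUE
    nb <- nb_of(u)
    keep <- feas[nb$id] & !done[nb$id]
    ids <- nb$id[keep]; lens <- nb$len[keep]
    if (length(ids)) {
      w1 <- lens * (Esh[u] + Esh[ids]) / 2
      n1 <- c1[u] + w1
      n2 <- c2[u] + lens
      better <- n1 < c1[ids] - tol |
        (n1 <= c1[ids] + tol & n2 < c2[ids] - tol)
      if (any(better)) {
        tgt <- ids[better]
        c1[tgt] <- n1[better]; c2[tgt] <- n2[better]
        parent[tgt] <- u
      }
    }
  }
  if (!is.finite(c1[e]))
    stop_internal("tie-break pass failed to reach the end voxel")
  ids <- e
  while (ids[1] != s) ids <- c(parent[ids[1]], ids)
  ijk <- .unlin(ids, dims)
  seg <- sqrt(rowSums((diff(ijk %*% diag(grid$spacing)))^2))
  new_migration_path(ijk, E[ids], c(0, cumsum(seg)), grid)
}

new_migration_path <- function(ijk, energy, arc, grid) {
  out <- tibble(ix = ijk[, 1], iy = ijk[, 2], iz = ijk[, 3],
                energy = energy, arc_length = arc)
  class(out) <- c("migration_path", class(out))
  attr(out, "spacing") <- grid$spacing
  attr(out, "bulk_reference") <- grid$bulk_reference
  out
}
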
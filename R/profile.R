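#' Construct a 1D free-energy profile of wells and barriers
#'
#' An ordered list of stationary points along one ligand tunnel, referenced
#' to bulk solvent (dG = 0 far from the protein). Kinds must strictly
#' alternate and every barrier must lie at or above both adjacent wells.
#'
#' @param kind character vector, `"well"` or `"barrier"`, ordered from the
#'   solvent entrance towards the heme.
#' @param dG free energies relative to bulk, kcal/mol.
#' @param position positions along the tunnel axis, Angstrom, strictly
#'   increasing.
#' @param tunnel tunnel label, one of `"LT"`, `"STG8"`, `"E7G"`, or any
#'   other identifier.
#' @return A tibble of class `fe_profile` with columns `kind, dG, position`.
#' @export
fe_profile <- function(kind, dG, position = seq_along(kind), tunnel = NA_character_) {
  kind <- as.character(kind)
  if (!all(kind %in% c("well", "barrier")))
    stop_data("profile kinds must be 'well' or 'barrier'")
  n <- length(kind)
  if (length(dG) != n || length(position) != n)
    stop_data("kind, dG and position must have equal length")
  if (n > 1) {
    if (any(kind[-1] == kind[-n]))
      stop_data("profile kinds must strictly alternate")
    if (any(diff(position) <= 0))
      stop_data("profile positions must be strictly increasing")
  }
  for (i in which(kind == "barrier")) {
    adj <- c(if (i > 1) dG[i - 1], if (i < n) dG[i + 1])
    if (length(adj) && any(dG[i] < adj - 1e-9))
      stop_data("every barrier must lie at or above its adjacent wells")
  }
  out <- tibble(kind = kind, dG = as.numeric(dG), position = as.numeric(position))
  class(out) <- c("fe_profile", class(out))
  attr(out, "tunnel") <- tunnel
  out
}

#' @export
print.fe_profile <- function(x, ...) {
  cat("<fe_profile> tunnel ", attr(x, "tunnel") %||% "?", ": ",
      sum(x$kind == "well"), " wells / ", sum(x$kind == "barrier"),
      " barriers\n", sep = "")
  NextMethod()
}

# centered moving average over a physical window (Angstrom)
smooth_by_window <- function(y, s, window) {
  if (window <= 0) return(y)
  h <- window / 2
  vapply(seq_along(y), function(i) mean(y[abs(s - s[i]) <= h]), numeric(1))
}

# topographic prominence of interior extrema of a discrete curve.
# Returns tibble(idx, kind, value, prominence); plateaus collapse to their
# middle sample.
stationary_points <- function(y, n_keep_ends = FALSE) {
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- floor((starts + ends) / 2)
  v <- r$values
  m <- length(v)
  if (m < 3) return(tibble(idx = integer(), kind = character(),
                           value = numeric(), prominence = numeric()))
  res <- list()
  for (j in 2:(m - 1)) {
    if (v[j] > v[j - 1] && v[j] > v[j + 1]) k <- "barrier"
    else if (v[j] < v[j - 1] && v[j] < v[j + 1]) k <- "well"
    else next
    sgn <- if (k == "barrier") 1 else -1
    w <- sgn * v
    # reference level on each side: lowest point before reaching a strictly
    # higher value (or the end of the curve)
    base_side <- function(rng) {
      if (!length(rng)) return(w[j])  # at the boundary: zero prominence side
      hi <- which(w[rng] > w[j])
      if (length(hi)) rng <- rng[seq_len(min(hi) - 1)]
      if (!length(rng)) w[j] else min(w[rng])
    }
    bl <- base_side(rev(seq_len(j - 1)))
    br <- base_side(seq(j + 1, m))
    prom <- w[j] - max(bl, br)
    res[[length(res) + 1]] <- tibble(idx = mid[j], kind = k,
                                     value = v[j], prominence = prom)
  }
  if (!length(res)) return(tibble(idx = integer(), kind = character(),
                                  value = numeric(), prominence = numeric()))
  bind_rows(res)
}

#' Detect wells and barriers along a migration path
#'
#' Turns the energy-vs-arc-length curve of a [extract_minimax_path()] result
#' into an alternating well/barrier profile. The curve is optionally smoothed
#' by a centered moving average over a physical window, interior local
#' extrema are detected with a topographic-prominence filter, and strict
#' alternation is enforced by merging the weaker of two same-kind neighbours
#' (the lower barrier, the shallower well). A monotonic curve yields an
#' empty profile.
#'
#' @param path a `migration_path` tibble (columns `energy`, `arc_length`),
#'   or any data frame with those columns.
#' @param smoothing_window moving-average window, Angstrom (0 disables).
#' @param prominence minimum topographic prominence, kcal/mol.
#' @param tunnel tunnel label attached to the result.
#' @return An [fe_profile()].
#' @export
profile_from_path <- function(path, smoothing_window = 1.0, prominence = 0.25,
                              tunnel = NA_character_) {
  if (!all(c("energy", "arc_length") %in% names(path)))
    stop_data("`path` needs columns energy and arc_length")
  y <- path$energy
  s <- path$arc_length
  if (length(y) < 2) stop_data("path must have at least 2 nodes")
  ys <- smooth_by_window(y, s, smoothing_window)
  sp <- stationary_points(ys)
  sp <- sp[sp$prominence >= prominence, , drop = FALSE]
  # enforce alternation: of two same-kind neighbours keep the stronger
  repeat {
    if (nrow(sp) < 2) break
    same <- which(sp$kind[-1] == sp$kind[-nrow(sp)])
    if (!length(same)) break
    i <- same[1]
    stronger <- if (sp$kind[i] == "barrier") {
      if (sp$value[i] >= sp$value[i + 1]) i else i + 1
    } else {
      if (sp$value[i] <= sp$value[i + 1]) i else i + 1
    }
    drop <- setdiff(c(i, i + 1), stronger)
    sp <- sp[-drop, , drop = FALSE]
  }
  fe_profile(sp$kind, sp$value, s[sp$idx], tunnel = tunnel)
}

#' Classify a tunnel as open, intermediate or closed
#'
#' Classification follows the maximum barrier along the profile: barriers of
#' a few kcal/mol (default <= 3) are readily crossed at room temperature and
#' the tunnel is open; barriers of 10 kcal/mol or more block migration on
#' kinetically relevant timescales (closed). A profile with no barrier is
#' open.
#'
#' @param profile an [fe_profile()] (or anything with `kind`/`dG` columns).
#' @param open_max,closed_min class bounds in kcal/mol.
#' @return `"open"`, `"intermediate"` or `"closed"`.
#' @export
classify_tunnel <- function(profile, open_max = 3, closed_min = 10) {
  b <- profile$dG[profile$kind == "barrier"]
  mx <- if (length(b)) max(b) else -Inf
  if (mx <= open_max) "open" else if (mx >= closed_min) "closed" else "intermediate"
}

#' Serialize profiles to a tab-separated table
#'
#' @param profiles a single [fe_profile()] or a list of them.
#' @return A tibble with columns `tunnel, kind, position_A, dG_kcal_mol`.
#' @export
profiles_to_table <- function(profiles) {
  if (inherits(profiles, "fe_profile")) profiles <- list(profiles)
  purrr::map_dfr(profiles, function(p)
    tibble(tunnel = attr(p, "tunnel") %||% NA_character_,
           kind = p$kind, position_A = p$position, dG_kcal_mol = p$dG))
}

#' Parse a profile table back into profiles
#'
#' @param tab a data frame as produced by [profiles_to_table()].
#' @return A named list of [fe_profile()] objects, one per tunnel.
#' @export
table_to_profiles <- function(tab) {
  sp <- split(tab, tab$tunnel)
  lapply(sp, function(d)
    fe_profile(d$kind, d$dG_kcal_mol, d$position_A, tunnel = d$tunnel[1]))
}
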
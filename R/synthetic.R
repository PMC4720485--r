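# All generators take an explicit seed and restore the caller's RNG state,
# so identical seeds give bitwise-identical fixtures regardless of context.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a planted tunnel for [make_grid()]
#'
#' Describes one carved channel: a voxel waypoint polyline and the
#' alternating well/barrier free energies planted along it. The channel
#' energy runs from bulk (0) at the first waypoint through the planted
#' stationary points (each held on a flat plateau so smoothing does not
#' bias its value) and back to 0 at the last waypoint.
#'
#' @param label tunnel label (e.g. `"LT"`).
#' @param waypoints integer matrix of voxel coordinates (rows), defining a
#'   polyline; consecutive waypoints are connected by 26-connected steps.
#' @param wells well free energies, kcal/mol (<= 0, relative to bulk).
#' @param barriers barrier free energies, kcal/mol (>= 0); wells and
#'   barriers are interleaved starting with the first well.
#' @param plateau plateau width held at each stationary point, Angstrom.
#'   Must exceed the profile-smoothing window so detected stationary values
#'   are unbiased; the default (2 A) covers the default 1 A window.
#' @return A `tunnel_spec` list.
#' @export
tunnel_spec <- function(label, waypoints, wells, barriers, plateau = 2.0) {
  waypoints <- as.matrix(waypoints)
  if (ncol(waypoints) != 3 || nrow(waypoints) < 2)
    stop_config("waypoints must be a matrix of >= 2 voxel coordinate rows")
  if (length(barriers) < length(wells) - 1 || length(barriers) > length(wells))
    stop_config("wells and barriers must interleave (n_barriers = n_wells or n_wells - 1)")
  if (any(wells > 0)) stop_config("well energies must be <= 0 (below bulk)")
  if (any(barriers < 0)) stop_config("barrier energies must be >= 0 (above bulk)")
  structure(list(label = label, waypoints = waypoints, wells = wells,
                 barriers = barriers, plateau = plateau),
            class = "tunnel_spec")
}

# rasterize a waypoint polyline into a 26-connected voxel chain
rasterize_waypoints <- function(wp) {
  pts <- wp[1, , drop = FALSE]
  for (i in seq_len(nrow(wp) - 1)) {
    cur <- wp[i, ]
    tgt <- wp[i + 1, ]
    while (any(cur != tgt)) {
      cur <- cur + sign(tgt - cur)
      pts <- rbind(pts, cur)
    }
  }
  unname(pts)
}

# planted energy curve: 0 at both ends, plateaus at stationary values
planted_curve <- function(s_total, wells, barriers, plateau) {
  m_chk <- length(wells) + length(barriers)
  if (s_total / (m_chk + 1) <= plateau)
    stop_config(paste0("channel too short: need spacing > ", plateau,
                       " A between ", m_chk, " stationary points over ",
                       round(s_total, 1), " A"))
  vals <- numeric(0)
  for (i in seq_along(wells)) {
    vals <- c(vals, wells[i])
    if (i <= length(barriers)) vals <- c(vals, barriers[i])
  }
  kinds <- rep(c("well", "barrier"), length.out = length(vals))
  m <- length(vals)
  centers <- s_total * seq_len(m) / (m + 1)
  ctrl_s <- c(0)
  ctrl_v <- c(0)
  for (i in seq_len(m)) {
    ctrl_s <- c(ctrl_s, centers[i] - plateau / 2, centers[i] + plateau / 2)
    ctrl_v <- c(ctrl_v, vals[i], vals[i])
  }
  ctrl_s <- c(ctrl_s, s_total)
  ctrl_v <- c(ctrl_v, 0)
  o <- order(ctrl_s)
  list(fun = stats::approxfun(ctrl_s[o], ctrl_v[o], rule = 2),
       kinds = kinds, values = vals, centers = centers)
}

#' Generate a synthetic free-energy grid with planted tunnels
#'
#' Builds a grid whose outer shell is bulk solvent at 0 kcal/mol, whose
#' interior background sits at a high (closed-tunnel) energy, and into
#' which one or more channels are carved realizing specified well/barrier
#' sequences. Gaussian noise can be added; the grid is then re-referenced
#' so the bulk shell mean is exactly 0. The planted ground truth is
#' returned alongside so every downstream stage has an oracle.
#'
#' @param dims integer 3-vector of voxel counts.
#' @param tunnels a [tunnel_spec()] or list of them.
#' @param background_energy interior background, kcal/mol (default 25:
#'   above the closed-tunnel band, below the steric cap).
#' @param bulk_shell bulk shell width, voxels.
#' @param noise_sd Gaussian noise sigma, kcal/mol.
#' @param spacing voxel spacing, Angstrom.
#' @param seed RNG seed.
#' @return A list: `grid` (an [energy_grid()], bulk-referenced), and
#'   `truth`, one entry per tunnel with `label`, `start`/`end` voxels, and
#'   `profile` (the planted [fe_profile()]).
#' @export
make_grid <- function(dims, tunnels, background_energy = 25, bulk_shell = 2L,
                      noise_sd = 0, spacing = 0.5, seed = 1) {
  if (inherits(tunnels, "tunnel_spec")) tunnels <- list(tunnels)
  dims <- as.integer(dims)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  arr <- array(background_energy, dims)
  shell <- bulk_shell_mask(dims, as.integer(bulk_shell))
  arr[shell] <- 0
  owner <- array(NA_integer_, dims)
  truth <- list()
  for (ti in seq_along(tunnels)) {
    tp <- tunnels[[ti]]
    chain <- rasterize_waypoints(tp$waypoints)
    if (any(chain < 1) || any(sweep(chain, 2, dims, `>`)))
      stop_config(paste0("tunnel '", tp$label, "' leaves the grid"))
    seg <- sqrt(rowSums((diff(chain %*% diag(spacing)))^2))
    s <- c(0, cumsum(seg))
    pc <- planted_curve(max(s), tp$wells, tp$barriers, tp$plateau)
    e <- pc$fun(s)
    for (k in seq_len(nrow(chain))) {
      v <- chain[k, ]
      prev <- owner[v[1], v[2], v[3]]
      if (!is.na(prev) && prev != ti &&
          abs(arr[v[1], v[2], v[3]] - e[k]) > 1e-9)
        stop_data(paste0("tunnels '", tunnels[[prev]]$label, "' and '",
                         tp$label, "' overlap with conflicting energies"))
      arr[v[1], v[2], v[3]] <- e[k]
      owner[v[1], v[2], v[3]] <- ti
    }
    truth[[tp$label]] <- list(
      label = tp$label,
      start = chain[1, ], end = chain[nrow(chain), ],
      profile = fe_profile(pc$kinds, pc$values, pc$centers, tunnel = tp$label))
  }
  arr <- with_local_seed(seed, {
    if (noise_sd > 0) arr + array(rnorm(length(arr), 0, noise_sd), dims) else arr
  })
  g <- energy_grid(arr, spacing = spacing)
  g <- normalize_to_bulk(g, shell_width = as.integer(bulk_shell))
  list(grid = g, truth = truth)
}

#' Reference structural annotation used by the synthetic MSA generator
#'
#' Structural labels of the globin topological positions at fixed ungapped
#' residue indices of the synthetic 60-residue reference scaffold.
#'
#' @return A tibble with columns `ref_index` and `label`.
#' @export
trhb_reference_annotation <- function() {
  tibble(label = c("B2", "B9", "B10", "B16", "CD1", "E7", "E10", "E11",
                   "E15", "E17", "EF1", "EF6", "EF8", "F4", "F8", "G5",
                   "G8", "G9", "G11", "H5", "H9", "H16", "H22"),
         ref_index = c(4L, 11L, 12L, 18L, 20L, 24L, 27L, 28L,
                       32L, 34L, 35L, 36L, 37L, 39L, 41L, 45L,
                       48L, 49L, 51L, 53L, 55L, 57L, 59L))
}

#' Generate a toy trHb alignment with controlled residue combinations
#'
#' Sequences are built on a 60-column ungapped scaffold whose structural
#' positions follow [trhb_reference_annotation()]. Active-site residues at
#' (B10, CD1, E7, E11, G8) are drawn from the requested combination
#' frequencies; all other columns come from a flat background distribution;
#' His is enforced at F8. Optional rejection fixtures plant sequences that
#' violate the curation rules (a non-His F8, or an over-length tail).
#'
#' @param n_sequences number of compliant sequences (the first is named
#'   `reference_id` and doubles as the annotated reference).
#' @param combo_frequencies named numeric vector summing to 1; names are
#'   dash-separated active-site combos, e.g. `"Y-F-L-Q-V"`.
#' @param hallmarks named character vector of residues forced at structural
#'   positions in every compliant sequence (default His at F8).
#' @param n_reject_hallmark,n_reject_length planted rule violators.
#' @param reference_id name given to the reference sequence.
#' @param seed RNG seed.
#' @return A list: `msa` (named character vector), `truth` (tibble id/combo
#'   and planted-violation flags), `combo_counts` (tibble combo/count over
#'   compliant sequences), and `annotation` (the reference annotation).
#' @export
make_msa <- function(n_sequences, combo_frequencies,
                     hallmarks = c(F8 = "H"),
                     n_reject_hallmark = 0, n_reject_length = 0,
                     reference_id = "REF", seed = 1) {
  if (abs(sum(combo_frequencies) - 1) > 1e-9)
    stop_config("combo frequencies must sum to 1")
  ann <- trhb_reference_annotation()
  width <- 60L
  tail_len <- if (n_reject_length > 0) 110L else 0L
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  as_pos <- tunnel_positions("active_site")
  pos_idx <- setNames(ann$ref_index, ann$label)
  with_local_seed(seed, {
    n_total <- n_sequences + n_reject_hallmark + n_reject_length
    combos <- sample(names(combo_frequencies), n_total, replace = TRUE,
                     prob = combo_frequencies)
    build <- function(i, violate = c("none", "hallmark", "length")) {
      violate <- match.arg(violate)
      s <- sample(aa, width, replace = TRUE)
      for (nm in names(hallmarks)) s[pos_idx[[nm]]] <- hallmarks[[nm]]
      res <- strsplit(combos[i], "-", fixed = TRUE)[[1]]
      for (j in seq_along(as_pos)) s[pos_idx[[as_pos[j]]]] <- res[j]
      if (violate == "hallmark") s[pos_idx[["F8"]]] <- "A"
      tail <- if (violate == "length") sample(aa, tail_len, replace = TRUE)
      else rep("-", tail_len)
      paste(c(s, tail), collapse = "")
    }
    seqs <- character(n_total)
    kinds <- c(rep("none", n_sequences), rep("hallmark", n_reject_hallmark),
               rep("length", n_reject_length))
    for (i in seq_len(n_total)) seqs[i] <- build(i, kinds[i])
    ids <- c(reference_id,
             sprintf("SEQ%04d", seq_len(n_total - 1) + 1))
    names(seqs) <- ids
    truth <- tibble(id = ids, combo = combos, planted_violation = kinds)
    cc <- truth |>
      filter(.data$planted_violation == "none") |>
      count(.data$combo, name = "count") |>
      arrange(desc(.data$count), .data$combo)
    list(msa = seqs, truth = truth, combo_counts = cc, annotation = ann)
  })
}

#' Generate a synthetic experimental-vs-calculated rate table
#'
#' Emulates a validation table: model inputs (per-tunnel migration
#' probabilities, water hydrogen-bond counts, excess oxygen stabilization)
#' are drawn from realistic distributions, the "calculated" rates follow
#' the kinetic model exactly, and "experimental" rates add Gaussian noise
#' in log10 space. The noise standard deviations are derived analytically
#' from the requested coefficients of determination: for y = x + e,
#' E\[R^2\] = Var(x) / (Var(x) + Var(e)), so Var(e) = Var(x)(1 - R^2)/R^2.
#' Likewise the spread of the tunnel term is set from the requested
#' tunnel-only R^2: with independent tunnel (variance a) and water
#' (variance b) contributions, R^2_tunnel/R^2_kon = a/(a+b).
#'
#' @param n number of proteins.
#' @param constants a [kinetic_constants()] list.
#' @param r2_kon,r2_tunnel,r2_koff target coefficients of determination for
#'   the full kon model, the tunnel-only predictor, and the koff model.
#' @param hbond_probs probabilities of 0, 1, 2, ... water hydrogen bonds.
#' @param mean_barrier mean net forward barrier of the dominant tunnel,
#'   kcal/mol.
#' @param mean_ddE,sd_ddE distribution of excess oxygen stabilization,
#'   kcal/mol.
#' @param seed RNG seed.
#' @return A tibble with model input columns (`id`, `k_LT`, `k_STG8`,
#'   `k_E7G`, `n_hbonds`, `ddE_O2`), noisy observations (`log10_kon_exp`,
#'   `log10_koff_exp`), and the noise-free truth (`log10_kon_calc`,
#'   `log10_koff_calc`); noise sigmas are stored as attributes
#'   `sigma_kon`/`sigma_koff`.
#' @export
make_rate_table <- function(n,
                            constants = kinetic_constants(),
                            r2_kon = 0.78, r2_tunnel = 0.47, r2_koff = 0.79,
                            hbond_probs = c(0.25, 0.5, 0.25),
                            mean_barrier = 4.25,
                            mean_ddE = 2.5, sd_ddE = 2.06,
                            seed = 1) {
  if (r2_tunnel >= r2_kon)
    stop_config("r2_tunnel must be below r2_kon (the water term adds signal)")
  kc <- constants
  with_local_seed(seed, {
    nh <- sample(seq_along(hbond_probs) - 1L, n, replace = TRUE,
                 prob = hbond_probs)
    log10_kh2o <- -nh * kc$dG_per_hbond / (kc$RT * log(10))
    b <- var(log10_kh2o)
    # tunnel-term spread from the requested R^2 split
    sd_logkt <- sqrt(b * r2_tunnel / (r2_kon - r2_tunnel))
    sd_barrier <- sd_logkt * kc$RT * log(10)
    d <- rnorm(n, mean_barrier, sd_barrier)
    k_dom <- 1 / (1 + exp(d / kc$RT))
    which_dom <- sample(1:3, n, replace = TRUE)
    minor <- function() ifelse(runif(n) < 0.5, 0, runif(n, 0, 0.15)) * k_dom
    k <- cbind(minor(), minor(), minor())
    k[cbind(seq_len(n), which_dom)] <- k_dom
    ddE <- rnorm(n, mean_ddE, sd_ddE)
    tbl <- tibble(id = sprintf("P%04d", seq_len(n)),
                  k_LT = k[, 1], k_STG8 = k[, 2], k_E7G = k[, 3],
                  n_hbonds = nh, ddE_O2 = ddE)
    pred <- predict_rates(tbl, kc)
    lc_on <- log10(pred$kon)
    lc_off <- log10(pred$koff)
    sig_on <- sqrt(var(lc_on) * (1 - r2_kon) / r2_kon)
    sig_off <- sqrt(var(lc_off) * (1 - r2_koff) / r2_koff)
    tbl$log10_kon_calc <- lc_on
    tbl$log10_koff_calc <- lc_off
    tbl$log10_kon_exp <- lc_on + rnorm(n, 0, sig_on)
    tbl$log10_koff_exp <- lc_off + rnorm(n, 0, sig_off)
    attr(tbl, "sigma_kon") <- sig_on
    attr(tbl, "sigma_koff") <- sig_off
    tbl
  })
}

#' Generate a random bifurcating tree
#'
#' @param leaf_labels character vector of unique leaf ids (>= 2).
#' @param seed RNG seed.
#' @return A Newick string with positive branch lengths.
#' @export
make_tree <- function(leaf_labels, seed = 1) {
  if (length(leaf_labels) < 2) stop_config("need at least 2 leaves")
  if (anyDuplicated(leaf_labels)) stop_config("leaf labels must be unique")
  with_local_seed(seed, {
    phy <- ape::rtree(length(leaf_labels))
    phy$tip.label <- leaf_labels
    ape::write.tree(phy)
  })
}
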
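#' Physical constants and model parameters for the kinetic model
#'
#' Bundles every tunable constant of the oxygen-binding kinetic model in one
#' validated list. Defaults correspond to the published protocol: 300 K, a
#' water-displacement penalty of 2.95 kcal/mol per protein-water hydrogen
#' bond, an isolated imidazole-bound heme reference of 22 kcal/mol with
#' koff = 1e4 s^-1, and an O2 solubility of 1.82e-6 M/mmHg for p50.
#'
#' @param T temperature in K.
#' @param dG_per_hbond free-energy penalty per protein-water hydrogen bond,
#'   kcal/mol; sets the water-displacement equilibrium KH2O.
#' @param dE_heme oxygen binding energy of the isolated imidazole-bound heme
#'   reference, kcal/mol.
#' @param koff_freeheme dissociation rate of the free-heme reference, s^-1.
#' @param conc_factor dimensional closure of the association rate, M^-1. The
#'   Eyring product (kB*T/h) * k_tunnels * KH2O has units s^-1; multiplying
#'   by `conc_factor` (default 1 M^-1, i.e. a 1 M standard state) yields a
#'   bimolecular rate in M^-1 s^-1.
#' @param o2_solubility O2 solubility in water, M per mmHg.
#' @param open_max,closed_min tunnel classification bounds on the maximum
#'   barrier, kcal/mol: `<= open_max` is open, `>= closed_min` closed.
#' @param p50_low,p50_high affinity-class bounds in mmHg.
#' @param koff_fast,koff_low dissociation-class bounds in s^-1.
#' @param prominence default stationary-point prominence, kcal/mol.
#' @param smoothing_window default profile smoothing window, Angstrom.
#' @param steric_cap energies above this value (kcal/mol) may be mapped to
#'   +Inf (steric exclusion) when reading grids.
#' @param bulk_shell default bulk-shell width in voxels for normalization.
#'
#' @return A list of class `kinetic_constants`. Derived fields: `R` the gas
#'   constant in kcal/(mol K), `RT` in kcal/mol, and `eyring_prefactor`
#'   kB*T/h in s^-1 (about 6.25e12 at 300 K).
#' @examples
#' kc <- kinetic_constants()
#' kc$eyring_prefactor # ~6.25e12 s^-1
#' @export
kinetic_constants <- function(T = 300,
                              dG_per_hbond = 2.95,
                              dE_heme = 22,
                              koff_freeheme = 1e4,
                              conc_factor = 1,
                              o2_solubility = 1.82e-6,
                              open_max = 3,
                              closed_min = 10,
                              p50_low = 1,
                              p50_high = 5,
                              koff_fast = 100,
                              koff_low = 1,
                              prominence = 0.25,
                              smoothing_window = 1.0,
                              steric_cap = 30,
                              bulk_shell = 2L) {
  kB <- 1.380649e-23    # J/K (SI exact)
  h  <- 6.62607015e-34  # J s (SI exact)
  R  <- 1.987204259e-3  # kcal/(mol K)
  vals <- list(kB = kB, h = h, R = R, T = T,
               RT = R * T,
               eyring_prefactor = kB * T / h,
               dG_per_hbond = dG_per_hbond,
               dE_heme = dE_heme,
               koff_freeheme = koff_freeheme,
               conc_factor = conc_factor,
               o2_solubility = o2_solubility,
               open_max = open_max, closed_min = closed_min,
               p50_low = p50_low, p50_high = p50_high,
               koff_fast = koff_fast, koff_low = koff_low,
               prominence = prominence,
               smoothing_window = smoothing_window,
               steric_cap = steric_cap,
               bulk_shell = as.integer(bulk_shell))
  num <- vapply(vals, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) stop_config("all kinetic constants must be finite scalars")
  pos <- c("kB", "h", "R", "T", "dG_per_hbond", "dE_heme", "koff_freeheme",
           "conc_factor", "o2_solubility", "prominence", "smoothing_window")
  bad <- pos[vapply(pos, function(nm) vals[[nm]] <= 0, logical(1))]
  if (length(bad)) stop_config(paste0("constants must be strictly positive: ",
                                      paste(bad, collapse = ", ")))
  structure(vals, class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("<kinetic_constants>  T =", x$T, "K,  RT =", signif(x$RT, 5), "kcal/mol\n")
  cat("  kB*T/h =", format(x$eyring_prefactor, digits = 4), "s^-1\n")
  cat("  dG/H-bond =", x$dG_per_hbond, " dE_heme =", x$dE_heme,
      " koff_freeheme =", x$koff_freeheme, "\n")
  invisible(x)
}
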
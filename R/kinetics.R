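#' Eyring forward/backward rates for every hop of a tunnel profile
#'
#' Builds the linear kinetic chain implied by a free-energy profile: states
#' are the bulk solvent (free energy 0), the interior wells, and the heme
#' (absorbing). Each transition rate is kB*T/h * exp(-dGdd/RT) with the
#' activation energy dGdd measured from the originating state up to the
#' barrier separating it from its neighbour. Where no explicit barrier lies
#' between two states (e.g. a barrierless entry into the first well), the
#' effective barrier is the higher of the two state energies, i.e. the hop
#' is diffusion-limited downhill. A profile that ends in a well gets a
#' barrierless final bond-formation hop.
#'
#' @param profile an [fe_profile()] ordered from solvent to heme.
#' @param constants a [kinetic_constants()] list.
#' @return A tibble with one row per interior well: `well_dG`, `forward`
#'   and `backward` rate constants in s^-1 (forward = towards the heme).
#'   A profile with no wells is treated as a single transition state: one
#'   pseudo-well at bulk level with a diffusion-limited backward rate.
#' @export
step_rates_from_profile <- function(profile, constants = kinetic_constants()) {
  kc <- constants
  kpre <- kc$eyring_prefactor
  ks <- profile$kind
  dG <- profile$dG
  widx <- which(ks == "well")
  n <- length(widx)
  if (!n) {
    # no docking well: single transition state behind the highest barrier
    # (or a flat pass at bulk level), with diffusion-limited back-escape
    b <- dG[ks == "barrier"]
    eff <- if (length(b)) max(b, 0) else 0
    return(tibble(well_dG = 0,
                  forward = kpre * exp(-eff / kc$RT),
                  backward = kpre))
  }
  wells <- dG[widx]
  # eff[j] = barrier energy between chain state j-1 and j
  # (state 0 = bulk at 0, states 1..n = wells, state n+1 = heme)
  eff <- numeric(n + 1)
  eff[1] <- if (ks[1] == "barrier") dG[1] else max(0, wells[1])
  if (n > 1)
    for (j in 2:n) eff[j] <- dG[widx[j - 1] + 1]  # alternation: always a barrier
  eff[n + 1] <- if (ks[length(ks)] == "barrier") dG[length(ks)] else wells[n]
  gf <- eff[-1] - wells        # towards heme
  gb <- eff[-(n + 1)] - wells  # back towards solvent
  if (any(gf < -1e-9) || any(gb < -1e-9))
    stop_data("negative activation energy: profile is not alternating-consistent")
  tibble(well_dG = wells,
         forward = kpre * exp(-pmax(gf, 0) / kc$RT),
         backward = kpre * exp(-pmax(gb, 0) / kc$RT))
}

#' Ligand migration probability through one tunnel
#'
#' The probability that a ligand sitting in the outermost docking well
#' reaches the heme before escaping back to the solvent -- the splitting
#' (forward-absorption) probability of the birth-death chain built from the
#' profile's Eyring step rates, in closed form:
#' \deqn{k_t = 1 / \sum_{i=0}^{n} \prod_{j=1}^{i} b_j/f_j}
#' For a single interior well this collapses to the familiar
#' kf / (kf + kb).
#'
#' @inheritParams step_rates_from_profile
#' @return A dimensionless probability in \[0, 1\].
#' @export
migration_probability <- function(profile, constants = kinetic_constants()) {
  rates <- step_rates_from_profile(profile, constants)
  splitting_probability(rates$forward, rates$backward)
}

#' Splitting probability of a birth-death chain
#'
#' Probability of absorption at the forward end (heme) before the backward
#' end (solvent), starting from the first interior state, for a linear chain
#' with per-state forward rates `forward` and backward rates `backward`.
#' Products of rate ratios are accumulated in log space for numerical
#' stability on steep landscapes.
#'
#' @param forward,backward positive rate vectors of equal length (state 1 is
#'   nearest the solvent).
#' @return Probability in \[0, 1\].
#' @export
splitting_probability <- function(forward, backward) {
  if (length(forward) != length(backward) || !length(forward))
    stop_data("forward and backward rates must be non-empty and equal length")
  if (any(forward <= 0) || any(backward <= 0))
    stop_data("rates must be strictly positive")
  lr <- cumsum(log(backward) - log(forward))
  # k = 1 / (1 + sum_i exp(lr_i)); use log-sum-exp
  m <- max(0, lr)
  denom <- exp(-m) + sum(exp(lr - m))
  exp(-m) / denom
}

#' Effective-concentration enhancement of a docking well
#'
#' A well of depth d (kcal/mol below bulk) concentrates the ligand by a
#' Boltzmann factor exp(d/RT); a 3 kcal/mol well at 300 K gives roughly a
#' 150-fold enhancement. Within the chain model this same physics enters
#' through the slowed back-escape from the well; the factor is exposed here
#' as a diagnostic.
#'
#' @param depth well depth, kcal/mol (>= 0, measured downwards from bulk).
#' @param constants a [kinetic_constants()] list.
#' @return Dimensionless enhancement factor.
#' @export
well_enhancement <- function(depth, constants = kinetic_constants()) {
  if (any(depth < 0)) stop_data("well depth must be >= 0")
  exp(depth / constants$RT)
}

#' Combine per-tunnel migration probabilities
#'
#' The global tunnel term is the plain sum of the three per-tunnel
#' migration probabilities: parallel entry routes add, and because each term
#' is bounded by 1 a second open tunnel can at most double the rate --
#' multiple open tunnels are largely redundant.
#'
#' @param k_LT,k_STG8,k_E7G migration probabilities in \[0, 1\] (vectorized).
#' @return `k_LT + k_STG8 + k_E7G`.
#' @export
combine_tunnels <- function(k_LT, k_STG8 = 0, k_E7G = 0) {
  for (k in list(k_LT, k_STG8, k_E7G))
    if (any(k < 0 | k > 1)) stop_data("tunnel probabilities must lie in [0, 1]")
  k_LT + k_STG8 + k_E7G
}

#' Water-displacement equilibrium constant
#'
#' Oxygen can only coordinate the iron once the distal water is displaced.
#' The blocked/free equilibrium constant is KH2O = exp(-n * dG_hb / RT)
#' where n is the number of hydrogen bonds the protein donates to that
#' water and dG_hb = 2.95 kcal/mol per bond. More hydrogen bonds mean a
#' tighter-bound water, a smaller KH2O, and a slower kon: each added bond
#' costs a factor exp(2.95/RT), about 141 at 300 K.
#'
#' @param n_hbonds non-negative integer count of protein-water hydrogen
#'   bonds (vectorized).
#' @param constants a [kinetic_constants()] list.
#' @return Dimensionless KH2O in (0, 1\].
#' @export
water_equilibrium <- function(n_hbonds, constants = kinetic_constants()) {
  if (any(n_hbonds < 0)) stop_data("n_hbonds must be >= 0")
  exp(-n_hbonds * constants$dG_per_hbond / constants$RT)
}

#' Oxygen association rate constant
#'
#' kon = (kB*T/h) * k_tunnels * KH2O * conc_factor, combining the Eyring
#' prefactor, the summed tunnel migration probabilities and the
#' water-displacement pre-equilibrium. For hexacoordinated proteins the
#' value is an upper bound (the model assumes the 5c/6c equilibrium fully
#' displaced towards the reactive pentacoordinate state).
#'
#' @param k_tunnels summed tunnel probabilities (from [combine_tunnels()]).
#' @param KH2O water-displacement equilibrium constant.
#' @param constants a [kinetic_constants()] list.
#' @return kon in M^-1 s^-1 (vectorized).
#' @export
association_rate <- function(k_tunnels, KH2O, constants = kinetic_constants()) {
  if (any(k_tunnels < 0) || any(KH2O < 0))
    stop_data("k_tunnels and KH2O must be non-negative")
  constants$eyring_prefactor * k_tunnels * KH2O * constants$conc_factor
}

#' Oxygen dissociation rate constant
#'
#' koff = koff_freeheme * exp(-ddE_O2/RT), where `ddE_O2` is the protein's
#' oxygen stabilization in excess of the isolated imidazole-bound heme
#' reference (22 kcal/mol; the free heme dissociates at 1e4 s^-1). Zero
#' excess stabilization reproduces the free-heme rate exactly; every extra
#' kcal/mol of stabilization slows dissociation by exp(1/RT).
#'
#' @param ddE_O2 excess oxygen stabilization, kcal/mol (vectorized; may be
#'   negative for proteins that stabilize O2 less than free heme).
#' @param constants a [kinetic_constants()] list.
#' @return koff in s^-1.
#' @seealso [ddE_from_binding_energy()] to convert raw QM/MM binding
#'   energies.
#' @export
dissociation_rate <- function(ddE_O2, constants = kinetic_constants()) {
  constants$koff_freeheme * exp(-ddE_O2 / constants$RT)
}

#' Convert a raw QM/MM binding energy to excess stabilization
#'
#' Raw oxygen binding energies dE_O2 are negative for favourable binding;
#' the kinetic model consumes the stabilization in excess of the isolated
#' imidazole-bound heme reference: ddE_O2 = |dE_O2| - dE_heme.
#'
#' @param dE_O2 raw binding energy, kcal/mol (negative = favourable).
#' @param constants a [kinetic_constants()] list.
#' @return ddE_O2 in kcal/mol.
#' @export
ddE_from_binding_energy <- function(dE_O2, constants = kinetic_constants()) {
  abs(dE_O2) - constants$dE_heme
}

#' Oxygen affinity as p50
#'
#' The oxygen partial pressure at which half the protein is loaded:
#' p50 = koff / (kon * s), with s the O2 solubility (M/mmHg). At p = p50
#' the fractional saturation kon*[O2] / (kon*[O2] + koff) equals 1/2
#' exactly.
#'
#' @param kon association rate, M^-1 s^-1 (> 0).
#' @param koff dissociation rate, s^-1.
#' @param constants a [kinetic_constants()] list.
#' @return p50 in mmHg (vectorized).
#' @export
oxygen_affinity_p50 <- function(kon, koff, constants = kinetic_constants()) {
  if (any(kon <= 0))
    stop_data("p50 is undefined for kon <= 0")
  koff / (kon * constants$o2_solubility)
}

#' Affinity class from p50
#'
#' p50 below 1 mmHg marks a high-affinity protein (oxygenated even in
#' microaerobic environments), 1-5 mmHg moderate, above 5 mmHg low
#' affinity.
#'
#' @param p50 p50 values in mmHg.
#' @param constants a [kinetic_constants()] list (bounds `p50_low`,
#'   `p50_high`).
#' @return Character vector: `"low_p50"`, `"moderate_p50"` or `"high_p50"`.
#' @export
classify_affinity <- function(p50, constants = kinetic_constants()) {
  ifelse(p50 < constants$p50_low, "low_p50",
         ifelse(p50 <= constants$p50_high, "moderate_p50", "high_p50"))
}

#' Dissociation-rate class
#'
#' koff of 100 s^-1 and above marks fast dissociation; rates below 1 s^-1
#' give oxy-species half-lives beyond the seconds timescale (low); the band
#' in between is moderate.
#'
#' @param koff dissociation rates, s^-1.
#' @param constants a [kinetic_constants()] list (bounds `koff_fast`,
#'   `koff_low`).
#' @return Character vector: `"fast"`, `"moderate"` or `"low"`.
#' @export
classify_koff <- function(koff, constants = kinetic_constants()) {
  ifelse(koff >= constants$koff_fast, "fast",
         ifelse(koff >= constants$koff_low, "moderate", "low"))
}
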
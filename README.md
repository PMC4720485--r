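# trhbkin

Structure-based prediction of oxygen binding kinetics for truncated
hemoglobins (trHbs), the 2-over-2 globin lineage found in all three
superkingdoms of life.

## The problem and the model

A globin's function — NO detoxification, oxygen transport, peroxidase-like
redox chemistry — is largely set by how fast it binds and releases O₂.
`trhbkin` implements a kinetic model that predicts the association rate
constant k_on, the dissociation rate constant k_off, and the affinity p50
from three structure-derived ingredients:

1. **Ligand-migration free-energy landscapes.** O₂ enters through up to
   three topologically distinct tunnels (the Long Tunnel LT, the Short
   Tunnel at G8, and the E7 gate). From a 3D free-energy grid (OpenDX
   scalar field, e.g. from implicit ligand sampling) the package traces the
   minimax (lowest-saddle) path between portal voxels, detects the wells
   and barriers along it, and converts each tunnel's profile into a
   migration probability k_t — the splitting probability of the
   birth–death chain built from Eyring step rates,

       k_t = 1 / Σᵢ Πⱼ≤ᵢ (k_bⱼ / k_fⱼ),

   which reduces to k_f/(k_f + k_b) for a single barrier. Tunnels add:
   k_tunnels = k_LT + k_STG8 + k_E7G.

2. **Water displacement.** O₂ can only coordinate the heme iron once the
   distal water is displaced; each protein–water hydrogen bond stabilizes
   the blocked state by 2.95 kcal/mol, giving the pre-equilibrium constant
   K_H₂O = exp(−n_HB·2.95/RT) — a factor of ≈141 in k_on per hydrogen bond
   at 300 K. The association rate is

       k_on = (k_B·T/h) · k_tunnels · K_H₂O   [M⁻¹ s⁻¹, 1 M standard state].

3. **Oxygen stabilization.** Dissociation is controlled by the strength of
   the distal hydrogen-bond network around the bound O₂, expressed as the
   stabilization ΔΔE_O₂ in excess of an isolated imidazole-bound heme
   (22 kcal/mol reference, which dissociates at 10⁴ s⁻¹):

       k_off = 10⁴ · exp(−ΔΔE_O₂/RT)   [s⁻¹].

Affinity follows as p50 = k_off/(k_on · s) with s = 1.82·10⁻⁶ M/mmHg.
Around the core model the package provides MSA curation (length < 160,
HisF8 hallmark), active-site and tunnel residue-combination catalogs with
hydrogen-bond donor counts and hexacoordination flags (His/Lys at E10),
phylogenetic annotation of predictions with rough functional typing, and
seeded synthetic-fixture generators for every input format.

## Worked example

A hexacoordinated cyanobacterial trHb with one open short tunnel
(docking well at −2.0 kcal/mol, exit barrier at +1.6 kcal/mol) and two
protein–water hydrogen bonds (TyrB10 + GlnE11):

```r
library(trhbkin)

profs <- table_to_profiles(read.delim(system.file(
  "extdata", "synthetic_validation_profiles.tsv", package = "trhbkin")))
k_stg8 <- migration_probability(profs[["Synechocystis_trHbN.STG8"]])
# 0.0639: a ligand in the entry well reaches the heme 6.4% of the time

pred <- predict_rates(tibble::tibble(
  id = "Synechocystis_trHbN", k_LT = 0, k_STG8 = k_stg8, k_E7G = 0,
  n_hbonds = 2, ddE_O2 = 6, hexacoordinated = TRUE))
pred[, c("k_tunnels", "KH2O", "kon", "koff", "p50", "koff_class")]
#>   k_tunnels     KH2O      kon  koff    p50 koff_class
#>      0.0639 5.03e-05 20119556 0.426 0.0116        low
```

k_on comes out at 2.0·10⁷ M⁻¹ s⁻¹. Because the protein is
hexacoordinated (His at E10 competes for the sixth coordination site) the
prediction is flagged an upper bound (`kon_is_upper_bound = TRUE`); the
measured rate for such proteins can differ by the 5c/6c equilibrium
(about 10-fold here). The low k_off (0.43 s⁻¹) and sub-mmHg p50 mark a
high-affinity protein that stays oxygenated even in microaerobic
environments.

Model validation against (synthetic) experimental-vs-calculated tables:

```r
rt  <- make_rate_table(400, seed = 1)
glance(fit_rate_validation(rt, "kon"))
#>   response r.squared adj.r.squared sigma   n
#> 1      kon     0.777         0.776  1.25 400
```

Dropping the water term (`fit_rate_validation(rt, "kon_tunnel_only")`)
degrades R² to ≈0.47–0.5: tunnels alone overestimate the rates, and the
water-displacement equilibrium is a required ingredient.

## Command line

An installed launcher (`system.file("cli", "trhbkin", package = "trhbkin")`)
exposes the stages as subcommands: `simulate`, `grid-analyze`,
`predict-rates`, `msa-features`, `annotate-tree`. Exit codes: 0 success,
2 configuration error, 3 data error, 4 internal invariant violation.

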
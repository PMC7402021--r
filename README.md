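# msai — microscopic susceptibility anisotropy imaging

The phase of the multi-echo gradient-echo MR signal in brain white matter
depends both on the magnetic susceptibility of the tissue microstructure
(chiefly the myelin sheath) and on how the axons are oriented with respect
to the main magnetic field B₀.  A heavily myelinated bundle running
parallel to the field shows almost no frequency shift; the same bundle
perpendicular to the field shows the full shift.  `msai` disentangles the
two: given the per-voxel axon orientation distribution function (ODF,
estimated upstream from diffusion MRI and supplied as order-8 real
spherical-harmonic coefficients), it recovers the **microscopic frequency
shift** ω_A(t) — the shift a single microdomain would exhibit if oriented
perpendicular to B₀ — per voxel and echo time, unconfounded by fiber
crossings, orientation dispersion, and field direction.

It is aimed at researchers processing multi-orientation gradient-echo
phase data (frequency difference mapping) together with diffusion-derived
fiber ODFs.

## The model

A microdomain with orientation u accrues the frequency shift
δω = ω_A(t) sin²θ, cos θ = ⟨B̂₀, u⟩, relative to a short reference echo
t₀.  Averaging the resulting unit phasors over the voxel's orientation
distribution p(u) gives the ensemble signal shift

    δE(B̂₀, t) = ∫_{S²} exp( i ω_A(t) [1 − ⟨B̂₀,u⟩²] (t − t₀) ) p(u) du ,

evaluated either by antipodal sphere-grid quadrature or via the
Funk–Hecke theorem in the spherical-harmonic basis.  The voxelwise
estimate minimises the summed squared phase distance
D{z₁, z₂} = arccos(Re(z₁* z₂)) between measured and model phasors over
the acquired field directions, with a dense deterministic grid search plus
local refinement, phase-wrap tracking across the echo train (search
interval centred on the previous echo's estimate, half-width π/t), joint
estimation of the per-(orientation, echo) global frequency offsets left
over after background-field removal, and g-factor noise-amplification
maps g = (JᵀJ)⁻¹ from a central-difference linearisation, validated by a
built-in Monte Carlo oracle.

A fully synthetic phantom generator (five tissue archetypes with known
ground truth, the reference 11-echo / 3-orientation acquisition geometry,
Gaussian frequency noise, polynomial background fields, injected global
offsets) makes the entire pipeline testable without scanner data.

## Worked example

Simulate a small noisy phantom and recover the microscopic shift of a
voxel in the two-fiber-crossing region:

```r
library(msai)

scheme  <- default_scheme(3)                    # 11 echoes, 3 head orientations
phantom <- build_phantom(c(5, 5, 2), scheme)
data    <- simulate_measurements(phantom, sigma_y = 0.1, seed = 42)
odfs    <- phantom_odfs(phantom)

v   <- 35                                       # crossing-fiber voxel
fit <- track_echo_train(matrix(data$values[v, , ], nrow = 3), odfs[[v]], scheme)
fit
#> micro_shift_fit:
#>   echo_ms omega_rad_s   omega_hz     residual
#> 1    13.5   -3.712050 -0.5907911 2.756312e-06
#> 2    22.5   -7.567037 -1.2043313 2.417832e-07
#> 3    31.5  -11.262668 -1.7925093 5.717520e-06
#> 4    40.5  -15.023295 -2.3910317 6.299584e-06
#> 5    49.5  -18.730854 -2.9811080 4.109506e-05
```

The estimated per-echo shift (in Hz, the displayed convention ω_A/2π)
tracks the phantom's ground-truth ramp of −0.6, −1.2, −1.8, −2.4, −3 Hz to
within the injected noise; the residual column is the phase-metric
objective at the optimum.  The companion diagnostics:

```r
sapply(1:3, function(p)
  orientation_weighting(odfs[[v]], scheme$b0_directions[p, ]))
#> 0.628 0.513 0.628        # sensitivity weight per head orientation, in [0, 1]

g_factor(fit$omega[4], odfs[[v]], scheme$b0_directions, 0.0405, 0.0045)$g
#> 732.2                    # noise amplification (JᵀJ)⁻¹ at the 40.5 ms echo
```

A weighting of 0 would mean all axons parallel to B₀ (no sensitivity); the
crossing voxel sits comfortably in the middle.  `estimate_offsets()` adds
joint recovery of global frequency offsets when two or more head
orientations were acquired, and `remove_background()` performs the
polynomial field detrending that precedes it.  A thin command-line front
end (`inst/cli/msai.R`) exposes `simulate`, `fdm`, `fit`, `gfactor`,
`weighting` and `entropy` subcommands over NIfTI/JSON/CSV files.

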
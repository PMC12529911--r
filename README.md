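# cdscs

Correlation-driven spin-component-scaled MP2 (CD-SCS-MP2) in R.

Second-order Møller–Plesset perturbation theory (MP2) splits its correlation
energy into opposite-spin (OS) and same-spin (SS) electron-pair
contributions.  Fixed spin-component scalings such as SCS-MP2
(c_OS = 1.2, c_SS = 0.33) improve MP2 on average, but the optimal factors are
system-dependent.  This package implements a *correlation-driven* scaling in
which the factors follow the character of the correlation in each molecule,
measured by indices built from the natural occupancies `n` of the MP2
first-order unrelaxed density:

    I_ND = (1/N) Σ_{i,σ} n(1−n)                        (nondynamic)
    I_D  = (1/2N) Σ_{i,σ} √(n(1−n)) − I_ND             (dynamic)
    I_T  = I_ND + I_D,   r_D = I_D/I_T,   r_ND = I_ND/I_T

and the per-species scaled energy

    E = E_HF + c_OS · E_OS + c_SS · E_SS,
    c_OS = a′·r_D + b′,   c_SS = a·r_ND + b.

The registry ships the published parameterizations: the two-parameter model
(`cd2`: c_OS = 1.38·r_D, c_SS = 2.89·r_ND), the four-parameter model
(`cd4`: c_OS = 0.42·r_D + 0.79, c_SS = 0.47), and the fixed-coefficient
references (`mp2`, `scs`, `scs-star`, `s2opt`).

For whom: quantum chemists who want to apply or refit spin-component
scalings driven by natural-occupancy correlation measures, evaluate them on
benchmark reaction sets (MAD, MAX, RMSD, WTMAD2, with the `I_ND^max > 0.030`
multireference screen), and reproduce the Coulomb-hole analysis that
motivates up-scaling the OS channel.

The package contains a compact, self-contained electronic-structure engine
for small closed-shell molecules: McMurchie–Davidson Gaussian integrals up
to d functions (compiled code), restricted Hartree–Fock with DIIS,
spin-resolved MP2 with unrelaxed natural occupancies, relaxed
(orbital-response, Z-vector) MP2 one- and two-particle densities,
determinant full CI for up to four electrons, and spin-resolved radial
intracules `I(r₁₂)` / Coulomb holes `h(r₁₂)` with pair-count and
repulsion-energy sum-rule certification.  Benchmark-scale data enter
through a documented JSON record schema instead of the engine.

## Worked example

```r
library(cdscs)

scf <- run_rhf(molecule_fixture("H2"), "cc-pvtz")
mp2 <- mp2_components(scf)
ci  <- correlation_indices(unrelaxed_occupancies(scf, mp2))
print(ci)
#> I_ND = 0.020150  I_D = 0.182847  I_T = 0.202997
#> r_D = 0.9007  r_ND = 0.0993  I_ND_max = 0.010038

scaling_coefficients(preset_params("cd4"), ci)
#>   c_OS   c_SS
#> 1.1683 0.4700

sp <- species_energies(scf$E_HF, mp2$E_OS, mp2$E_SS, indices = ci)
assemble_energy(sp, preset_params("cd4"))
#> [1] -1.169969
```

H₂ at equilibrium is strongly dynamic (r_D = 0.90), so the four-parameter
model up-scales its opposite-spin correlation by 1.17; the same-spin
component (exactly zero for a two-electron singlet) keeps the constant 0.47.
The scaled total, −1.16997 hartree, lies between the canonical MP2 total
(−1.16464) and the FCI value (−1.17234) in this basis.

The Coulomb-hole analysis behind this choice:

```r
fci <- fci_solve(scf)
rel <- relaxed_densities(scf, mp2)
delta_vee(fci$two_rdm, hf_two_rdm(scf), mp2$moeri)$total   # -0.0697 au
delta_vee(rel$two_rdm, hf_two_rdm(scf), mp2$moeri)$total   # -0.0511 au
```

MP2 recovers only −0.051 au of the −0.070 au correlation contribution to
the electron repulsion; scaling by 1.2 brings it to −0.061 au.

A command-line interface wraps the same functions
(`inst/cli/cdscs compute|indices|energy|evaluate|fit|hole|heatmap|generate`).

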
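## Physical constants (CODATA 2018) and the unit conversions used package-wide.
## Internal units: length A, time ps, charge e, mass amu, energy kcal/mol.
## Conversions to V, mV and m^2/s happen only at reporting boundaries.

.const <- local({
  e_C <- 1.602176634e-19        # elementary charge, C (exact)
  eps0 <- 8.8541878128e-12      # vacuum permittivity, F/m
  NA_  <- 6.02214076e23         # Avogadro, 1/mol (exact)
  cal  <- 4.184                 # J per thermochemical cal (exact)

  ## e^2/(4 pi eps0) in J*m, then per A and per mole in kcal/mol
  ke_Jm <- e_C^2 / (4 * pi * eps0)
  list(
    ## Coulomb constant for q1*q2/r with q in e, r in A -> kcal/mol
    k_coulomb_kcal = ke_Jm / 1e-10 * NA_ / (cal * 1000),
    ## e/(4 pi eps0 * 1 A) -> volts: potential of 1 e at 1 A
    k_coulomb_volt = e_C / (4 * pi * eps0 * 1e-10),
    avogadro = NA_,
    ## 1 A^2/ps in m^2/s
    A2_per_ps_to_m2_per_s = 1e-8
  )
})
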
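# Internal unit system for all dynamics and width formulas:
#   energy  kcal/mol, length Angstrom, mass amu.
# The derived time unit t0 = sqrt(amu A^2 / (kcal/mol)) ~ 48.888 fs; hbar and
# frequency conversions below are expressed in these reduced units so that
# harmonic widths and trajectory integration share one consistent scale.

.const <- local({
  joule_per_kcalmol <- 4184 / 6.02214076e23   # J per (kcal/mol), per molecule
  kg_per_amu <- 1.66053906660e-27
  m_per_angstrom <- 1e-10
  t0 <- sqrt(kg_per_amu * m_per_angstrom^2 / joule_per_kcalmol)  # seconds
  c_cm <- 2.99792458e10                        # speed of light, cm/s
  list(
    R_kcal = 1.98720425e-3,                    # gas constant, kcal mol^-1 K^-1
    hartree_kcal = 627.5095,                   # kcal/mol per Hartree
    t0_s = t0,
    hbar_red = 1.054571817e-34 / (joule_per_kcalmol * t0),
    # wavenumber (cm^-1) per unit reduced angular frequency (1/t0)
    cm1_per_redfreq = 1 / (2 * pi * c_cm * t0)
  )
})

# convert a wavenumber in cm^-1 to reduced angular frequency (rad / t0)
.omega_red <- function(freq_cm1) freq_cm1 / .const$cm1_per_redfreq

.stop_validation <- function(...) {
  stop(structure(
    class = c("dynaselect_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

.stop_parse <- function(...) {
  stop(structure(
    class = c("dynaselect_parse_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
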
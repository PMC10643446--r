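# Fixed unit conversions. Internal dynamics is in Hartree atomic units;
# interfaces speak fs / eV / Angstrom.
HA2EV <- 27.211386
BOHR2ANG <- 0.529177
AU2FS <- 0.02418884          # 1 a.u. of time in fs
FS2AU <- 1 / AU2FS
KB_EV <- 8.617333e-5         # Boltzmann constant, eV/K
KB_HA <- KB_EV / HA2EV
KCALMOL2HA <- 1 / 627.509474
# kcal/mol/A^2 -> hartree/bohr^2 (force constant conversion)
KFORCE2AU <- KCALMOL2HA * BOHR2ANG^2

#' Unit conversion constants
#'
#' Named vector of the fixed conversion constants the package uses at its
#' interfaces (internal dynamics is carried out in Hartree atomic units).
#'
#' @return Named numeric vector: `hartree_eV` (1 hartree in eV), `bohr_A`
#'   (1 bohr in Angstrom), `autime_fs` (1 atomic time unit in fs),
#'   `k_eV_per_K` (Boltzmann constant in eV/K).
#' @examples
#' unitConstants()["hartree_eV"]
#' @export
unitConstants <- function() {
  c(hartree_eV = HA2EV, bohr_A = BOHR2ANG, autime_fs = AU2FS,
    k_eV_per_K = KB_EV)
}
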
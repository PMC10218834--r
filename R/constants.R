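# Physical constants used throughout (kJ/mol, Angstrom, elementary charge).

#' @keywords internal
.kB <- 0.008314462618            # Boltzmann constant, kJ/(mol K)

# Coulomb constant k_e = 138.935458 kJ nm / (mol e^2); distances are kept in
# Angstrom internally, so the prefactor is 10x larger.
#' @keywords internal
.ke_A <- 1389.35458              # kJ A / (mol e^2)

#' @keywords internal
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' @keywords internal
.WATER_RES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC")

#' @keywords internal
.ION_RES <- c("NA", "CL", "K", "MG", "ZN", "CA", "NA+", "CL-")
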
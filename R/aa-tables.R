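# Amino-acid lookup tables shared across modules.
# All tables are keyed by 1-letter code in the fixed order of .aa_codes.

.aa_codes <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.aa_one <- setNames(names(.aa_three), unname(.aa_three))

# Average (isotope-abundance-weighted) residue masses in Da, as used by the
# ExPASy Compute pI/Mw tool; a peptide mass is the residue sum plus one water.
.aa_avg_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_avg_mass <- 18.01524

# Bjellqvist pKa set (the constants behind the ExPASy Compute pI/Mw tool).
# Side-chain pKa for the seven ionizable residues; terminal pKa depend on the
# identity of the terminal residue.
.pka_side <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
               R = 12.00, Y = 10.00)
.pka_nterm_default <- 7.50
.pka_nterm <- c(A = 7.59, E = 7.70, M = 7.00, P = 8.36, S = 6.93,
                T = 6.82, V = 7.44)
.pka_cterm_default <- 3.55
.pka_cterm <- c(D = 4.55, E = 4.75)

# Distance (Angstrom) from CA to the side-chain centroid pseudo-atom (SC),
# a coarse per-residue-type size proxy used by the structure generators.
.sc_centroid_distance <- c(
  G = 0.5, A = 1.5, S = 1.9, C = 2.1, T = 1.9, V = 2.0, P = 1.9,
  I = 2.3, L = 2.6, M = 2.9, N = 2.5, D = 2.5, Q = 3.0, E = 3.1,
  K = 3.5, R = 4.1, H = 3.1, F = 3.4, W = 3.9, Y = 3.8
)

aa1_to_aa3 <- function(x) {
  out <- .aa_three[x]
  if (anyNA(out)) {
    abort(paste0("non-standard amino-acid letter(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  unname(out)
}

aa3_to_aa1 <- function(x) {
  out <- .aa_one[x]
  if (anyNA(out)) {
    abort(paste0("non-standard residue code(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  unname(out)
}

check_sequence_letters <- function(seq_string) {
  letters1 <- strsplit(seq_string, "")[[1]]
  bad <- setdiff(unique(letters1), .aa_codes)
  if (length(bad) > 0) {
    abort(paste0("sequence contains non-standard amino-acid letter(s): ",
                 paste(bad, collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  letters1
}
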
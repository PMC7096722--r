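# Embedded ideal-geometry templates for the 20 standard amino acids and a toy
# ligand. Side chains are described as z-matrix rows (bond length, bond angle,
# torsion) so that rotamer chi angles can be substituted at build time; the
# monomer dictionary (bonds/angles/chirals) is derived by measuring the built
# template, which keeps builder and restraint targets exactly consistent.

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Backbone geometry (Engh-Huber-style targets; sigmas in the same units)
BB_GEOM <- list(
  b_N_CA  = c(1.458, 0.019), b_CA_C = c(1.525, 0.021),
  b_C_O   = c(1.231, 0.020), b_C_N  = c(1.329, 0.014),
  b_CA_CB = c(1.530, 0.020),
  a_N_CA_C  = c(111.2, 2.8), a_CA_C_O = c(120.8, 1.7),
  a_CA_C_N  = c(116.2, 2.0), a_O_C_N  = c(123.0, 1.6),
  a_C_N_CA  = c(121.7, 1.8),
  a_N_CA_CB = c(110.4, 1.5), a_C_CA_CB = c(110.5, 1.5),
  # improper torsion CB-CA-N-C fixing L-chirality (sign checked by the
  # positive CA chiral volume test)
  t_CB_improper = 122.6
)

# z-matrix rows: atom, element, a1 (bonded ref), a2, a3, bond (A), angle (deg),
# torsion: numeric string, "chiK", or "chiK+/-offset".
.zrow <- function(atom, el, a1, a2, a3, b, ang, tor) {
  list(atom = atom, el = el, a1 = a1, a2 = a2, a3 = a3,
       bond = b, angle = ang, tor = tor)
}

SIDE_CHAIN_ZMAT <- list(
  ALA = list(),
  GLY = list(),
  SER = list(.zrow("OG", "O", "CB", "CA", "N", 1.417, 110.8, "chi1")),
  CYS = list(.zrow("SG", "S", "CB", "CA", "N", 1.808, 114.4, "chi1")),
  THR = list(.zrow("OG1", "O", "CB", "CA", "N", 1.433, 109.6, "chi1"),
             .zrow("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1-120")),
  VAL = list(.zrow("CG1", "C", "CB", "CA", "N", 1.521, 110.5, "chi1"),
             .zrow("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1+122")),
  LEU = list(.zrow("CG", "C", "CB", "CA", "N", 1.530, 116.3, "chi1"),
             .zrow("CD1", "C", "CG", "CB", "CA", 1.521, 110.7, "chi2"),
             .zrow("CD2", "C", "CG", "CB", "CA", 1.521, 110.7, "chi2+122")),
  ILE = list(.zrow("CG1", "C", "CB", "CA", "N", 1.530, 110.4, "chi1"),
             .zrow("CG2", "C", "CB", "CA", "N", 1.521, 110.5, "chi1-122"),
             .zrow("CD1", "C", "CG1", "CB", "CA", 1.513, 113.8, "chi2")),
  MET = list(.zrow("CG", "C", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             .zrow("SD", "S", "CG", "CB", "CA", 1.803, 112.7, "chi2"),
             .zrow("CE", "C", "SD", "CG", "CB", 1.791, 100.9, "chi3")),
  ASP = list(.zrow("CG", "C", "CB", "CA", "N", 1.516, 112.6, "chi1"),
             .zrow("OD1", "O", "CG", "CB", "CA", 1.249, 118.4, "chi2"),
             .zrow("OD2", "O", "CG", "CB", "CA", 1.249, 118.4, "chi2+180")),
  ASN = list(.zrow("CG", "C", "CB", "CA", "N", 1.516, 112.6, "chi1"),
             .zrow("OD1", "O", "CG", "CB", "CA", 1.231, 120.8, "chi2"),
             .zrow("ND2", "N", "CG", "CB", "CA", 1.328, 116.4, "chi2+180")),
  GLU = list(.zrow("CG", "C", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             .zrow("CD", "C", "CG", "CB", "CA", 1.516, 112.6, "chi2"),
             .zrow("OE1", "O", "CD", "CG", "CB", 1.249, 118.4, "chi3"),
             .zrow("OE2", "O", "CD", "CG", "CB", 1.249, 118.4, "chi3+180")),
  GLN = list(.zrow("CG", "C", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             .zrow("CD", "C", "CG", "CB", "CA", 1.516, 112.6, "chi2"),
             .zrow("OE1", "O", "CD", "CG", "CB", 1.231, 120.8, "chi3"),
             .zrow("NE2", "N", "CD", "CG", "CB", 1.328, 116.4, "chi3+180")),
  LYS = list(.zrow("CG", "C", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             .zrow("CD", "C", "CG", "CB", "CA", 1.520, 111.3, "chi2"),
             .zrow("CE", "C", "CD", "CG", "CB", 1.520, 111.3, "chi3"),
             .zrow("NZ", "N", "CE", "CD", "CG", 1.489, 111.9, "chi4")),
  ARG = list(.zrow("CG", "C", "CB", "CA", "N", 1.520, 114.1, "chi1"),
             .zrow("CD", "C", "CG", "CB", "CA", 1.520, 111.3, "chi2"),
             .zrow("NE", "N", "CD", "CG", "CB", 1.460, 112.0, "chi3"),
             .zrow("CZ", "C", "NE", "CD", "CG", 1.329, 124.2, "chi4"),
             .zrow("NH1", "N", "CZ", "NE", "CD", 1.326, 120.0, "0"),
             .zrow("NH2", "N", "CZ", "NE", "CD", 1.326, 120.0, "180")),
  HIS = list(.zrow("CG", "C", "CB", "CA", "N", 1.497, 113.8, "chi1"),
             .zrow("ND1", "N", "CG", "CB", "CA", 1.371, 122.7, "chi2"),
             .zrow("CD2", "C", "CG", "CB", "CA", 1.356, 129.7, "chi2+180"),
             .zrow("CE1", "C", "ND1", "CG", "CB", 1.319, 109.3, "180"),
             .zrow("NE2", "N", "CD2", "CG", "CB", 1.374, 107.2, "180")),
  PHE = list(.zrow("CG", "C", "CB", "CA", "N", 1.502, 113.8, "chi1"),
             .zrow("CD1", "C", "CG", "CB", "CA", 1.384, 120.7, "chi2"),
             .zrow("CD2", "C", "CG", "CB", "CA", 1.384, 120.7, "chi2+180"),
             .zrow("CE1", "C", "CD1", "CG", "CB", 1.382, 120.7, "180"),
             .zrow("CE2", "C", "CD2", "CG", "CB", 1.382, 120.7, "180"),
             .zrow("CZ", "C", "CE1", "CD1", "CG", 1.382, 120.0, "0")),
  TYR = list(.zrow("CG", "C", "CB", "CA", "N", 1.502, 113.8, "chi1"),
             .zrow("CD1", "C", "CG", "CB", "CA", 1.384, 120.7, "chi2"),
             .zrow("CD2", "C", "CG", "CB", "CA", 1.384, 120.7, "chi2+180"),
             .zrow("CE1", "C", "CD1", "CG", "CB", 1.382, 120.7, "180"),
             .zrow("CE2", "C", "CD2", "CG", "CB", 1.382, 120.7, "180"),
             .zrow("CZ", "C", "CE1", "CD1", "CG", 1.382, 120.0, "0"),
             .zrow("OH", "O", "CZ", "CE1", "CD1", 1.376, 119.9, "180")),
  TRP = list(.zrow("CG", "C", "CB", "CA", "N", 1.498, 113.6, "chi1"),
             .zrow("CD1", "C", "CG", "CB", "CA", 1.365, 126.9, "chi2"),
             .zrow("CD2", "C", "CG", "CB", "CA", 1.433, 126.6, "chi2+180"),
             .zrow("NE1", "N", "CD1", "CG", "CB", 1.374, 110.2, "180"),
             .zrow("CE2", "C", "CD2", "CG", "CB", 1.409, 107.2, "180"),
             .zrow("CE3", "C", "CD2", "CG", "CB", 1.398, 133.9, "0"),
             .zrow("CZ2", "C", "CE2", "CD2", "CG", 1.394, 122.4, "180"),
             .zrow("CZ3", "C", "CE3", "CD2", "CE2", 1.382, 118.6, "180"),
             .zrow("CH2", "C", "CZ2", "CE2", "CD2", 1.368, 117.5, "180")),
  PRO = list(.zrow("CG", "C", "CB", "CA", "N", 1.492, 104.5, "chi1"),
             .zrow("CD", "C", "CG", "CB", "CA", 1.503, 106.1, "chi2"))
)

# chi dihedral atom quadruples per residue type, in chi order
CHI_ATOMS <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  CYS = list(c("N", "CA", "CB", "SG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
)

# Torsion-restraint periodicity for the final chi of sp2 groups is 2
CHI_PERIODS <- list(
  SER = 3, CYS = 3, THR = 3, VAL = 3,
  LEU = c(3, 3), ILE = c(3, 3), MET = c(3, 3, 3),
  ASP = c(3, 2), ASN = c(3, 2), GLU = c(3, 3, 2), GLN = c(3, 3, 2),
  LYS = c(3, 3, 3, 3), ARG = c(3, 3, 3, 2),
  HIS = c(3, 2), PHE = c(3, 2), TYR = c(3, 2), TRP = c(3, 2),
  PRO = c(3, 3)
)

# Planar groups (restrained to a common plane) per residue type
PLANAR_GROUPS <- list(
  ASP = list(c("CB", "CG", "OD1", "OD2")),
  ASN = list(c("CB", "CG", "OD1", "ND2")),
  GLU = list(c("CG", "CD", "OE1", "OE2")),
  GLN = list(c("CG", "CD", "OE1", "NE2")),
  ARG = list(c("CD", "NE", "CZ", "NH1", "NH2")),
  HIS = list(c("CB", "CG", "ND1", "CD2", "CE1", "NE2")),
  PHE = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  TRP = list(c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
               "CZ2", "CZ3", "CH2")),
  TOY = list(c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "CL1"))
)

# Compact rotamer library (penultimate-style chi values and prior fractions)
ROTAMER_LIB <- list(
  SER = list(list("p", 0.48, 62), list("m", 0.29, -65), list("t", 0.22, 180)),
  CYS = list(list("m", 0.50, -65), list("t", 0.26, -177), list("p", 0.23, 62)),
  THR = list(list("p", 0.49, 62), list("m", 0.43, -65), list("t", 0.07, -175)),
  VAL = list(list("t", 0.73, 175), list("m", 0.20, -60), list("p", 0.06, 63)),
  LEU = list(list("mt", 0.59, c(-65, 175)), list("tp", 0.29, c(-177, 65)),
             list("mp", 0.02, c(-85, 65)), list("tt", 0.02, c(-172, 147))),
  ILE = list(list("mt", 0.60, c(-65, 170)), list("mm", 0.15, c(-57, -60)),
             list("pt", 0.13, c(62, 170)), list("tt", 0.08, c(-177, 166))),
  MET = list(list("mtp", 0.20, c(-65, 180, 75)),
             list("mtt", 0.15, c(-65, 180, 180)),
             list("mmm", 0.15, c(-65, -65, -70)),
             list("ttp", 0.10, c(-177, 180, 75))),
  ASP = list(list("m-20", 0.51, c(-70, -15)), list("t30", 0.24, c(-177, 30)),
             list("p-10", 0.14, c(62, -10))),
  ASN = list(list("m-40", 0.33, c(-65, -40)), list("t-20", 0.25, c(-174, -20)),
             list("p-10", 0.12, c(62, -10)), list("m120", 0.10, c(-65, 120))),
  GLU = list(list("mt-10", 0.36, c(-67, 177, -10)),
             list("tt0", 0.24, c(-177, 177, 0)),
             list("mm-40", 0.13, c(-65, -75, -40)),
             list("pt-20", 0.08, c(62, 180, -20))),
  GLN = list(list("mt-30", 0.38, c(-67, 180, -25)),
             list("tt0", 0.16, c(-177, 177, 0)),
             list("mm-40", 0.14, c(-65, -65, -40)),
             list("pt20", 0.07, c(62, 180, 20))),
  LYS = list(list("tttt", 0.27, c(-177, 180, 180, 180)),
             list("mttt", 0.25, c(-65, 180, 180, 180)),
             list("mmtt", 0.06, c(-65, -68, 180, 180)),
             list("ttmt", 0.05, c(-177, 180, -65, 180))),
  ARG = list(list("mtt180", 0.13, c(-67, 180, 180, 180)),
             list("mtm180", 0.11, c(-67, 180, -65, 180)),
             list("ttt180", 0.09, c(-177, 177, 180, 180)),
             list("mtp180", 0.08, c(-67, 180, 65, 180))),
  HIS = list(list("m-70", 0.29, c(-65, -70)), list("t75", 0.20, c(-177, 75)),
             list("p-75", 0.14, c(62, -75))),
  PHE = list(list("m-85", 0.44, c(-65, -85)), list("t80", 0.33, c(-177, 80)),
             list("p90", 0.13, c(62, 90))),
  TYR = list(list("m-85", 0.43, c(-65, -85)), list("t80", 0.34, c(-177, 80)),
             list("p90", 0.13, c(62, 90))),
  TRP = list(list("m95", 0.32, c(-65, 95)), list("t-105", 0.19, c(-177, -105)),
             list("p-90", 0.11, c(62, -90))),
  PRO = list(list("exo", 0.44, c(29, -37)), list("endo", 0.44, c(-27, 36)))
)

# van der Waals contact radii (A) used for clashes and nonbonded targets
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               CL = 1.75, ZN = 1.39, MG = 1.73, FE = 1.40, `NA` = 2.27,
               CA = 2.31, MN = 1.39, K = 2.75)

# Atomic numbers for density weighting
ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, `NA` = 11, MG = 12, P = 15,
                   S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26,
                   CU = 29, ZN = 30)

# Metal--ligand bond-length table (A) for LINK-derived restraints, keyed
# "METAL:LIGELEMENT"; element-pair level only (no full atom typing).
METAL_BOND_TABLE <- c(
  "ZN:N" = 2.05, "ZN:O" = 2.05, "ZN:S" = 2.30,
  "MG:O" = 2.08, "MG:N" = 2.15,
  "FE:N" = 2.05, "FE:O" = 2.00, "FE:S" = 2.30,
  "NA:O" = 2.40, "K:O" = 2.80,
  "CA:O" = 2.40, "MN:O" = 2.20, "MN:N" = 2.25,
  "CU:N" = 2.00, "CU:O" = 2.00, "CU:S" = 2.25
)
METAL_ELEMENTS <- c("ZN", "MG", "FE", "NA", "K", "CA", "MN", "CU")

# Toy ligand "TOY": chlorobenzene on a propyl tail C9-C8-C1-ring. The C1-C2
# (ring attachment, period 2) and C8-C1 (sp3-sp3, period 3) bonds are the
# rotatable bonds used by flip examples; the chlorine sits meta (C3... ring
# numbering C2..C7, CL on C3).
TOY_LIGAND_ZMAT <- list(
  .zrow("C2", "C", "C1", NA, NA, 1.510, NA, NA),
  .zrow("C3", "C", "C2", "C1", NA, 1.390, 120.0, NA),
  .zrow("C4", "C", "C3", "C2", "C1", 1.390, 120.0, "180"),
  .zrow("C5", "C", "C4", "C3", "C2", 1.390, 120.0, "0"),
  .zrow("C6", "C", "C5", "C4", "C3", 1.390, 120.0, "0"),
  .zrow("C7", "C", "C6", "C5", "C4", 1.390, 120.0, "0"),
  .zrow("CL1", "CL", "C3", "C2", "C1", 1.740, 119.3, "0"),
  .zrow("C8", "C", "C1", "C2", "C3", 1.530, 112.0, "90"),
  .zrow("C9", "C", "C8", "C1", "C2", 1.530, 112.0, "180")
)
TOY_LIGAND_BONDS <- list(
  c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
  c("C5", "C6"), c("C6", "C7"), c("C7", "C2"), c("C3", "CL1"),
  c("C1", "C8"), c("C8", "C9")
)
# rotatable-bond torsion restraints for the toy ligand (atoms, period)
TOY_TORSIONS <- list(
  list(atoms = c("C9", "C8", "C1", "C2"), period = 3L),
  list(atoms = c("C8", "C1", "C2", "C3"), period = 2L)
)

# ring-closing bonds that are not z-matrix parent bonds
RING_CLOSURES <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CH2", "CZ3")),
  PRO = list(c("CD", "N"))
)

element_of <- function(name) {
  # Atom-name -> element for standard protein/ligand names
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  two <- substr(nm, 1, 2)
  out[two %in% names(VDW_RADII) & nchar(nm) >= 2 &
        two %in% c("CL", "ZN", "MG", "FE", "NA", "MN")] <-
    two[two %in% names(VDW_RADII) & nchar(nm) >= 2 &
          two %in% c("CL", "ZN", "MG", "FE", "NA", "MN")]
  out[out == ""] <- substr(nm[out == ""], 1, 1)
  out
}

atomic_number <- function(element) {
  z <- ATOMIC_NUMBER[toupper(element)]
  z[is.na(z)] <- 6  # unknown elements score as carbon
  unname(z)
}
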
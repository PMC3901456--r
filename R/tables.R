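# Internal constant tables: amino-acid codes, masses, vdW radii, hydrogen-bond
# donor/acceptor atom roles, and side-chain dihedral atom definitions.

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.aa1to3 <- structure(names(.aa3to1), names = unname(.aa3to1))

# Average residue masses in Da (monomer minus water); free chain adds one water.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.02

# van der Waals radii (Angstrom) used by the solvent-accessibility calculation.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Side-chain hydrogen-bond donor heavy atoms (bear at least one H in standard
# protonation chemistry); backbone amide N is a donor for all residues but PRO.
.sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TYR = "OH", TRP = "NE1", CYS = "SG"
)

# Side-chain acceptor heavy atoms; backbone carbonyl O (and OXT) accepts for all.
.sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG"
)

# Fourth atom of chi1 (N-CA-CB-X) per residue type.
.chi1_fourth <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)

# Fourth atom of chi2 (CA-CB-CG-X); for His this is ND1.
.chi2_fourth <- c(
  ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD", HIS = "ND1",
  ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD", PHE = "CD1", PRO = "CD",
  TRP = "CD1", TYR = "CD1"
)

.backbone_names <- c("N", "CA", "C", "O")
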
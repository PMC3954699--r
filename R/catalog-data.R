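# Lookup tables behind the default property catalog.  The printed property
# roster names the groups only; the atom- and residue-level memberships below
# are declared conventions, versioned with the catalog (see the methods
# vignette for rationale).

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# residue property classes; charged residues are also polar
RESIDUE_CLASSES <- list(
  Hydrophobic = c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP"),
  Charged     = c("ASP", "GLU", "LYS", "ARG", "HIS"),
  Polar       = c("SER", "THR", "CYS", "TYR", "ASN", "GLN", "HIS", "LYS",
                  "ARG", "ASP", "GLU"),
  NonPolar    = c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP",
                  "GLY"),
  Basic       = c("LYS", "ARG", "HIS"),
  Acidic      = c("ASP", "GLU")
)

# Kyte-Doolittle hydropathy per residue
KYTE_DOOLITTLE <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5,
                    CYS = 2.5, GLN = -3.5, GLU = -3.5, GLY = -0.4,
                    HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
                    MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8,
                    THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)

# heavy side-chain atom counts (GLY has none; its hydropathy is carried by CA)
SIDECHAIN_COUNT <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5,
                     GLU = 5, GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5,
                     MET = 4, PHE = 7, PRO = 3, SER = 2, THR = 3, TRP = 10,
                     TYR = 8, VAL = 3)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# van der Waals sphere volumes per element (Bondi radii), cubic Angstroms
VDW_VOLUME <- c(C = 20.58, N = 15.60, O = 14.71, S = 24.43, OTHER = 18.0)

# formal side-chain charges spread over the charged group's atoms
ATOM_CHARGE <- c("ASP OD1" = -0.5, "ASP OD2" = -0.5,
                 "GLU OE1" = -0.5, "GLU OE2" = -0.5,
                 "LYS NZ"  =  1.0,
                 "ARG NH1" =  0.5, "ARG NH2" =  0.5,
                 "HIS ND1" =  0.25, "HIS NE2" = 0.25)

# chemical-group membership, keyed "RES ATOM"; backbone carbonyl/peptide
# membership is handled by atom name for standard residues
CHEM_GROUPS <- list(
  Hydroxyl = c("SER OG", "THR OG1", "TYR OH"),
  Amide = c("ASN CG", "ASN OD1", "ASN ND2", "GLN CD", "GLN OE1", "GLN NE2"),
  Amine = c("LYS NZ", "ARG NE", "ARG NH1", "ARG NH2"),
  RingSystem = c(
    paste("PHE", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    paste("TYR", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    paste("TRP", c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                   "CH2")),
    paste("HIS", c("CG", "ND1", "CD2", "CE1", "NE2")),
    paste("PRO", c("N", "CA", "CB", "CG", "CD"))
  )
)

# atom names whose digit-stripped form is a non-C/N/O/S element symbol
NON_CNOS_NAMES <- c("SE", "FE", "ZN", "CU", "MN", "MG", "NA", "CL", "BR",
                    "I", "K", "P", "CD", "NI", "CO", "HG", "AU", "PT")
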
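# Shared chemical vocabularies: standard residues, side-chain donor and
# acceptor atom inventories, and pH-7 formal charge conventions.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.WATER_RES <- c("HOH", "WAT", "DOD")

.SS_LEVELS <- c("helix", "sheet", "turn", "coil")

# Side-chain hydrogen-bond donor heavy atoms.  Donors are side-chain N/O
# only; S- and C-H donors and the backbone amide are excluded by design.
# `charge` is the formal group charge at pH 7.
.DONOR_ATOMS <- data.frame(
  resn   = c("SER", "THR", "TYR", "TRP", "HIS", "HIS", "LYS",
             "ARG", "ARG", "ARG", "ASN", "GLN"),
  atom   = c("OG", "OG1", "OH", "NE1", "ND1", "NE2", "NZ",
             "NE", "NH1", "NH2", "ND2", "NE2"),
  elem   = c("O", "O", "O", "N", "N", "N", "N",
             "N", "N", "N", "N", "N"),
  charge = c(0L, 0L, 0L, 0L, 0L, 0L, 1L,
             1L, 1L, 1L, 0L, 0L),
  stringsAsFactors = FALSE)

# Side-chain acceptor heavy atoms.  His ring nitrogens accept only when
# unprotonated (checked at enumeration time); carboxylate oxygens carry
# the -1 formal charge of the group.
.ACCEPTOR_SC_ATOMS <- data.frame(
  resn   = c("ASP", "ASP", "GLU", "GLU", "ASN", "GLN",
             "SER", "THR", "TYR", "HIS", "HIS"),
  atom   = c("OD1", "OD2", "OE1", "OE2", "OD1", "OE1",
             "OG", "OG1", "OH", "ND1", "NE2"),
  elem   = c("O", "O", "O", "O", "O", "O",
             "O", "O", "O", "N", "N"),
  charge = c(-1L, -1L, -1L, -1L, 0L, 0L,
             0L, 0L, 0L, 0L, 0L),
  stringsAsFactors = FALSE)

# Geometric windows (Angstrom / degrees) defining the two bond classes.
.SHB_R_MIN <- 2.3
.SHB_R_MAX <- 2.7
.NHB_R_MIN <- 2.8
.NHB_R_MAX <- 3.2
.HB_ANGLE_MIN <- 135

# Maximum heavy-atom distance at which a hydrogen attached to a donor is
# considered covalently bonded to it.
.H_COVALENT_MAX <- 1.25
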
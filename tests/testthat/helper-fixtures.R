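# In-code fixtures: fixed-width PDB text and minimal residue geometries
# built from internal coordinates.

pdb_line <- function(record, serial, name, alt, resn, chain, resi,
                     x, y, z, occ = 1, b = 0, elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, alt, resn, chain, resi, x, y, z, occ, b, elem)
}

# A 2-model file: 5 amino acids + an altloc pair + 3 waters + a ligand,
# with quality REMARKs.
toy_pdb_text <- function() {
  l <- c(
    "TITLE     TOY  LYSOZYME  FRAGMENT",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.05 ANGSTROMS.",
    "REMARK   3   R VALUE            (WORKING SET) : 0.180",
    "REMARK   3   FREE R VALUE                     : 0.210",
    "MODEL        1")
  serial <- 0
  nxt <- function(...) { serial <<- serial + 1; pdb_line(serial = serial, ...) }
  for (i in 1:5) {
    l <- c(l,
      nxt("ATOM", name = "N", alt = "", resn = "ALA", chain = "A", resi = i,
          x = i * 4, y = 0, z = 0, elem = "N"),
      nxt("ATOM", name = "CA", alt = "", resn = "ALA", chain = "A", resi = i,
          x = i * 4 + 1.46, y = 0, z = 0, elem = "C"),
      nxt("ATOM", name = "C", alt = "", resn = "ALA", chain = "A", resi = i,
          x = i * 4 + 2.0, y = 1.3, z = 0, elem = "C"),
      nxt("ATOM", name = "O", alt = "", resn = "ALA", chain = "A", resi = i,
          x = i * 4 + 1.6, y = 2.4, z = 0, elem = "O"))
  }
  l <- c(l,
    nxt("ATOM", name = "CB", alt = "A", resn = "ALA", chain = "A", resi = 5,
        x = 21.0, y = -1.0, z = 1.0, occ = 0.4, elem = "C"),
    nxt("ATOM", name = "CB", alt = "B", resn = "ALA", chain = "A", resi = 5,
        x = 21.2, y = -1.0, z = 1.0, occ = 0.6, elem = "C"))
  for (i in 1:3)
    l <- c(l, nxt("HETATM", name = "O", alt = "", resn = "HOH", chain = "A",
                  resi = 100 + i, x = 30 + i, y = 30, z = 30, elem = "O"))
  l <- c(l, nxt("HETATM", name = "C1", alt = "", resn = "LIG", chain = "A",
                resi = 200, x = 40, y = 40, z = 40, elem = "C"))
  l <- c(l, "ENDMDL", "MODEL        2",
         pdb_line("ATOM", 999, "N", "", "ALA", "A", 1, 99, 99, 99, elem = "N"),
         "ENDMDL", "END")
  l
}

write_toy_pdb <- function(lines = toy_pdb_text()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

mk_atoms <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(record = "ATOM", serial = i, name = r$name, alt = "",
               resn = r$resn, chain = r$chain %||% "A", resi = r$resi %||% 1L,
               ins = "", x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occ = 1, b = 0, elem = r$elem, stringsAsFactors = FALSE)
  }))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

at_row <- function(name, elem, xyz, resn = "ALA", chain = "A", resi = 1L)
  list(name = name, elem = elem, xyz = xyz, resn = resn, chain = chain,
       resi = resi)

# A serine residue with realistic internal geometry (no HG).
ser_atoms <- function(resi = 1L, chain = "A", shift = c(0, 0, 0)) {
  pa <- shbpred:::place_atom
  N <- c(-1.458, 0, 0) + shift
  CA <- c(0, 0, 0) + shift
  C <- pa(c(-2, 1, 0) + shift, N, CA, 1.525, 111.2, -60)
  CB <- pa(C, N, CA, 1.53, 110.5, 122)
  OG <- pa(N, CA, CB, 1.41, 110.5, 180)
  mk_atoms(at_row("N", "N", N, "SER", chain, resi),
           at_row("CA", "C", CA, "SER", chain, resi),
           at_row("C", "C", C, "SER", chain, resi),
           at_row("CB", "C", CB, "SER", chain, resi),
           at_row("OG", "O", OG, "SER", chain, resi))
}

# Lysine side chain CD-CE-NZ.
lys_atoms <- function() {
  mk_atoms(at_row("CA", "C", c(0, 0, 0), "LYS"),
           at_row("CD", "C", c(2.0, 0, 0), "LYS"),
           at_row("CE", "C", c(3.2, 0.9, 0), "LYS"),
           at_row("NZ", "N", c(4.5, 0.2, 0), "LYS"))
}

# Planar imidazole ring for histidine protonation/acceptor tests.
his_atoms <- function(h_on = NULL) {
  df <- mk_atoms(at_row("CB", "C", c(-1.3, 0.6, 0), "HIS"),
                 at_row("CG", "C", c(0.00, 0.00, 0), "HIS"),
                 at_row("ND1", "N", c(1.28, 0.58, 0), "HIS"),
                 at_row("CE1", "C", c(2.18, -0.42, 0), "HIS"),
                 at_row("NE2", "N", c(1.57, -1.57, 0), "HIS"),
                 at_row("CD2", "C", c(0.22, -1.36, 0), "HIS"))
  if (!is.null(h_on)) {
    hpos <- as.numeric(df[df$name == h_on, c("x", "y", "z")]) + c(0, 0, 1.0)
    # in-plane H roughly along the external bisector
    base <- as.numeric(df[df$name == h_on, c("x", "y", "z")])
    hpos <- base + if (h_on == "NE2") c(0.4, -0.93, 0) else c(0.3, 0.96, 0)
    df <- rbind(df, mk_atoms(at_row(paste0("H", substr(h_on, 2, 10)), "H",
                                    hpos, "HIS")))
    df$serial <- seq_len(nrow(df))
  }
  df
}

as_structure <- function(atoms, id = "fixture")
  shbpred:::new_protein_structure(atoms, structure_id = id)

# Random box of protonated Ser donors and Asp acceptor fragments, for
# grid-vs-brute equivalence; <= 500 atoms.
random_box_structure <- function(n_ser = 30, n_asp = 30, seed = 5, box = 14) {
  set.seed(seed)
  rows <- list()
  resi <- 0L
  for (i in seq_len(n_ser)) {
    resi <- resi + 1L
    og <- runif(3, 0, box)
    hg <- og + c(0.96, 0, 0)
    rows <- c(rows, list(at_row("OG", "O", og, "SER", "A", resi),
                         at_row("HG", "H", hg, "SER", "A", resi)))
  }
  for (i in seq_len(n_asp)) {
    resi <- resi + 1L
    od <- runif(3, 0, box)
    rows <- c(rows, list(at_row("OD1", "O", od, "ASP", "A", resi)))
  }
  as_structure(do.call(mk_atoms, rows), id = "box")
}

fast_test_params <- function(n_trees = 150, depth_grid = 1:2, cv_folds = 3)
  shb_params("fast", n_trees = n_trees, depth_grid = depth_grid,
             cv_folds = cv_folds)

donor_only_config <- function(n = 1500, seed = 3, mode = "balanced")
  synth_config(n = n, seed = seed, mode = mode,
               donor_dist = c(TYR = 0.27, SER = 0.25, THR = 0.20,
                              HIS = 0.14, ARG = 0.14),
               base_prob = c(TYR = 0.86, SER = 0.53, THR = 0.40,
                             HIS = 0.29, ARG = 0.10),
               acceptor_logodds_shift = 0, motif_frac = 0)
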
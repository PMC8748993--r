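# Idealized placement of polar side-chain hydrogens.  O-H bonds are set
# to 0.96 A and N-H bonds to 1.01 A; sp2 N-H are placed in the plane of
# the attached group, and rotatable hydroxyls are oriented by a 10-degree
# torsion scan that maximizes the best donor-H-acceptor angle to any
# nearby N/O atom.  Existing hydrogens are never moved and heavy-atom
# coordinates are never altered.

res_atoms <- function(s, reskey) s$atoms[s$atoms$reskey == reskey, , drop = FALSE]

atom_xyz <- function(df, name) {
  i <- which(df$name == name)
  if (length(i) == 0) return(NULL)
  as.numeric(df[i[1L], c("x", "y", "z")])
}

has_attached_h <- function(df, heavy_xyz, max_dist = .H_COVALENT_MAX) {
  h <- df[df$elem == "H", , drop = FALSE]
  if (nrow(h) == 0) return(FALSE)
  d <- sqrt((h$x - heavy_xyz[1])^2 + (h$y - heavy_xyz[2])^2 + (h$z - heavy_xyz[3])^2)
  any(d <= max_dist)
}

#' Place idealized polar hydrogens on side-chain donor groups
#'
#' Adds hydrogens to side-chain donor heavy atoms (Ser OG, Thr OG1, Tyr
#' OH, Trp NE1, His NE2 by default tautomer, Lys NZ, Arg NE/NH1/NH2,
#' Asn ND2, Gln NE2) that lack them.  Rotatable hydroxyls are oriented
#' by scanning the C-O torsion in 10-degree steps and keeping the
#' orientation that maximizes the best donor-H-acceptor angle to any
#' N/O heavy atom of another residue within 3.5 A; with no acceptor in
#' range the anti orientation is used.  Because the scan biases the
#' hydrogen towards nearby acceptors, detection pipelines treat
#' placement as opt-in (see the package vignette).  Residues whose
#' parent heavy atoms are missing are skipped with a warning.
#'
#' @param s a `protein_structure`.
#' @param his_tautomer which His ring nitrogen carries the hydrogen
#'   when neither does: `"NE2"` (default) or `"ND1"`.
#' @return the structure with hydrogens appended; existing atoms are
#'   returned bit-for-bit unchanged.
#' @export
place_polar_hydrogens <- function(s, his_tautomer = c("NE2", "ND1")) {
  stopifnot(inherits(s, "protein_structure"))
  his_tautomer <- match.arg(his_tautomer)
  heavy <- s$atoms[s$atoms$elem %in% c("N", "O"), , drop = FALSE]
  new_h <- list()
  skipped <- character()

  add_h <- function(reskey, name, xyz) {
    r <- s$atoms[match(reskey, s$atoms$reskey), ]
    new_h[[length(new_h) + 1L]] <<- data.frame(
      record = "ATOM", serial = NA_integer_, name = name, alt = "",
      resn = r$resn, chain = r$chain, resi = r$resi, ins = r$ins,
      x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0, elem = "H",
      reskey = reskey, stringsAsFactors = FALSE)
  }

  hydroxyl_scan <- function(df, reskey, o_name, parent, gparent, h_name) {
    o <- atom_xyz(df, o_name); p <- atom_xyz(df, parent); g <- atom_xyz(df, gparent)
    if (is.null(o) || is.null(p) || is.null(g)) return(FALSE)
    if (has_attached_h(df, o)) return(TRUE)
    acc <- heavy[heavy$reskey != reskey, , drop = FALSE]
    d <- sqrt((acc$x - o[1])^2 + (acc$y - o[2])^2 + (acc$z - o[3])^2)
    acc <- acc[d <= 3.5, , drop = FALSE]
    best_h <- place_atom(g, p, o, 0.96, 109.5, 180)
    if (nrow(acc) > 0) {
      best_ang <- -1
      for (tors in seq(0, 350, by = 10)) {
        h <- place_atom(g, p, o, 0.96, 109.5, tors)
        ang <- max(vapply(seq_len(nrow(acc)), function(i)
          vertex_angle(o, h, as.numeric(acc[i, c("x", "y", "z")])), numeric(1)))
        if (ang > best_ang) { best_ang <- ang; best_h <- h }
      }
    }
    add_h(reskey, h_name, best_h)
    TRUE
  }

  # H on a planar ring/sp2 nitrogen: along the external bisector of its
  # two ring/substituent neighbours.
  bisector_h <- function(df, reskey, n_name, nb1, nb2, h_name) {
    n <- atom_xyz(df, n_name); a <- atom_xyz(df, nb1); b <- atom_xyz(df, nb2)
    if (is.null(n) || is.null(a) || is.null(b)) return(FALSE)
    if (has_attached_h(df, n)) return(TRUE)
    u <- -(unit_vec(a - n) + unit_vec(b - n))
    add_h(reskey, h_name, n + 1.01 * unit_vec(u))
    TRUE
  }

  # Two in-plane amide/guanidinium hydrogens at 120 degrees.
  sp2_nh2 <- function(df, reskey, n_name, parent, ref, h_names) {
    n <- atom_xyz(df, n_name); p <- atom_xyz(df, parent); r <- atom_xyz(df, ref)
    if (is.null(n) || is.null(p) || is.null(r)) return(FALSE)
    if (has_attached_h(df, n)) return(TRUE)
    add_h(reskey, h_names[1L], place_atom(r, p, n, 1.01, 120, 0))
    add_h(reskey, h_names[2L], place_atom(r, p, n, 1.01, 120, 180))
    TRUE
  }

  for (k in seq_len(nrow(s$residues))) {
    resn <- s$residues$resn[k]
    if (!resn %in% unique(.DONOR_ATOMS$resn)) next
    reskey <- s$residues$reskey[k]
    df <- res_atoms(s, reskey)
    ok <- switch(resn,
      SER = hydroxyl_scan(df, reskey, "OG", "CB", "CA", "HG"),
      THR = hydroxyl_scan(df, reskey, "OG1", "CB", "CA", "HG1"),
      TYR = hydroxyl_scan(df, reskey, "OH", "CZ", "CE1", "HH"),
      TRP = bisector_h(df, reskey, "NE1", "CD1", "CE2", "HE1"),
      HIS = {
        nd1_h <- !is.null(atom_xyz(df, "ND1")) && has_attached_h(df, atom_xyz(df, "ND1"))
        ne2_h <- !is.null(atom_xyz(df, "NE2")) && has_attached_h(df, atom_xyz(df, "NE2"))
        if (nd1_h || ne2_h) TRUE
        else if (his_tautomer == "NE2")
          bisector_h(df, reskey, "NE2", "CD2", "CE1", "HE2")
        else bisector_h(df, reskey, "ND1", "CG", "CE1", "HD1")
      },
      LYS = {
        nz <- atom_xyz(df, "NZ"); ce <- atom_xyz(df, "CE"); cd <- atom_xyz(df, "CD")
        if (is.null(nz) || is.null(ce) || is.null(cd)) FALSE
        else if (has_attached_h(df, nz)) TRUE
        else {
          for (j in 1:3)
            add_h(reskey, paste0("HZ", j),
                  place_atom(cd, ce, nz, 1.01, 109.5, 60 + 120 * (j - 1)))
          TRUE
        }
      },
      ARG = {
        r1 <- bisector_h(df, reskey, "NE", "CD", "CZ", "HE")
        r2 <- sp2_nh2(df, reskey, "NH1", "CZ", "NE", c("HH11", "HH12"))
        r3 <- sp2_nh2(df, reskey, "NH2", "CZ", "NE", c("HH21", "HH22"))
        r1 && r2 && r3
      },
      ASN = sp2_nh2(df, reskey, "ND2", "CG", "OD1", c("HD21", "HD22")),
      GLN = sp2_nh2(df, reskey, "NE2", "CD", "OE1", c("HE21", "HE22")),
      TRUE)
    if (!ok) skipped <- c(skipped, sprintf("%s %s%s", resn,
                                           s$residues$chain[k], s$residues$resi[k]))
  }
  if (length(skipped) > 0)
    warning("missing parent heavy atoms; residue(s) skipped as donors: ",
            paste(skipped, collapse = ", "))
  if (length(new_h) > 0) {
    h <- do.call(rbind, new_h)
    h$serial <- max(s$atoms$serial, 0, na.rm = TRUE) + seq_len(nrow(h))
    s$atoms <- rbind(s$atoms, h)
  }
  s
}
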
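# Backbone hydrogen-bond based secondary structure assignment using the
# Kabsch-Sander electrostatic energy, collapsed to four coarse classes:
# helix (3-10/alpha/pi turns), sheet (bridge patterns), turn (isolated
# turns) and coil (default).

ks_energy <- function(N, H, C, O) {
  rON <- vec_norm(O - N); rCH <- vec_norm(C - H)
  rOH <- vec_norm(O - H); rCN <- vec_norm(C - N)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clash, treat as bonded
  0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
}

#' Assign secondary structure from backbone geometry
#'
#' Detects backbone amide-carbonyl hydrogen bonds with the
#' Kabsch-Sander energy
#' `E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332` kcal/mol
#' (bond when `E < -0.5`), idealizing the amide hydrogen along the
#' preceding carbonyl C=O direction when no explicit hydrogen is
#' present, then collapses the hydrogen-bond patterns to four classes:
#' consecutive i -> i+3/4/5 turns become `helix`, bridge patterns become
#' `sheet`, isolated turns become `turn`, and everything else `coil`.
#' Residues with missing backbone atoms are labeled `coil` with a
#' warning.
#'
#' @param s a `protein_structure`.
#' @return the structure with `s$residues$ss` filled; assignment is a
#'   total function over standard residues.
#' @export
assign_secondary_structure <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  res <- s$residues
  n <- nrow(res)
  bb <- array(NA_real_, dim = c(n, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  for (i in seq_len(n)) {
    df <- res_atoms(s, res$reskey[i])
    for (a in c("N", "CA", "C", "O")) {
      xyz <- atom_xyz(df, a)
      if (!is.null(xyz)) bb[i, a, ] <- xyz
    }
  }
  complete <- apply(bb, 1, function(m) !anyNA(m))
  if (any(!complete))
    warning(sum(!complete), " residue(s) with missing backbone atoms labeled coil")

  same_chain_step <- function(i, k) {
    j <- i + k
    ifelse(j >= 1 & j <= n & res$chain[pmin(pmax(j, 1), n)] == res$chain[i] &
             res$serial[pmin(pmax(j, 1), n)] == res$serial[i] + k, j, NA_integer_)
  }
  prev_idx <- vapply(seq_len(n), function(i) same_chain_step(i, -1L), integer(1))

  # amide H: explicit H bonded to backbone N, else idealized along the
  # previous residue's C=O direction (1.0 A); Pro and chain starts
  # cannot donate.
  Hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    df <- res_atoms(s, res$reskey[i])
    Ni <- bb[i, "N", ]
    h <- df[df$elem == "H", , drop = FALSE]
    if (nrow(h) > 0) {
      d <- sqrt((h$x - Ni[1])^2 + (h$y - Ni[2])^2 + (h$z - Ni[3])^2)
      if (any(d <= .H_COVALENT_MAX)) {
        Hpos[i, ] <- as.numeric(h[which.min(d), c("x", "y", "z")])
        next
      }
    }
    if (res$resn[i] == "PRO") next
    p <- prev_idx[i]
    if (!is.na(p) && complete[p])
      Hpos[i, ] <- Ni + unit_vec(bb[p, "C", ] - bb[p, "O", ])
  }

  # Hb[a, b]: C=O of residue a accepts from N-H of residue b.
  Hb <- matrix(FALSE, n, n)
  donors <- which(complete & !is.na(Hpos[, 1]))
  acceptors <- which(complete)
  for (b in donors) {
    for (a in acceptors) {
      if (a == b) next
      if (vec_norm(bb[a, "CA", ] - bb[b, "CA", ]) > 9) next
      e <- ks_energy(bb[b, "N", ], Hpos[b, ], bb[a, "C", ], bb[a, "O", ])
      if (e < -0.5) Hb[a, b] <- TRUE
    }
  }

  turn_at <- function(i, k) {
    j <- same_chain_step(i, k)
    !is.na(j) && Hb[i, j]
  }

  ss <- rep("coil", n)
  is_helix <- rep(FALSE, n)
  in_turn <- rep(FALSE, n)
  for (k in 3:5) {
    tk <- vapply(seq_len(n), function(i) turn_at(i, k), logical(1))
    for (i in seq_len(n)) {
      if (tk[i]) {
        hi <- min(i + k - 1L, n)
        if (i + 1L <= hi) in_turn[(i + 1L):(hi)] <- TRUE
      }
      if (i >= 2 && tk[i] && tk[i - 1L]) {
        hi <- min(i + k - 1L, n)
        is_helix[i:hi] <- TRUE
      }
    }
  }

  is_sheet <- rep(FALSE, n)
  hb_any <- which(Hb, arr.ind = TRUE)
  cand <- unique(c(hb_any[, 1], hb_any[, 2]))
  for (i in cand) {
    for (j in cand) {
      if (j <= i) next
      if (res$chain[i] == res$chain[j] && abs(res$serial[i] - res$serial[j]) < 3) next
      im1 <- same_chain_step(i, -1L); ip1 <- same_chain_step(i, 1L)
      jm1 <- same_chain_step(j, -1L); jp1 <- same_chain_step(j, 1L)
      hb <- function(a, b) !is.na(a) && !is.na(b) && Hb[a, b]
      par <- (hb(im1, j) && hb(j, ip1)) || (hb(jm1, i) && hb(i, jp1))
      anti <- (hb(i, j) && hb(j, i)) || (hb(im1, jp1) && hb(jm1, ip1))
      if (par || anti) { is_sheet[i] <- TRUE; is_sheet[j] <- TRUE }
    }
  }

  ss[in_turn] <- "turn"
  ss[is_sheet] <- "sheet"
  ss[is_helix] <- "helix"
  s$residues$ss <- ss
  s
}
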
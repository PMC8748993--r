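# Enumeration of side-chain donors and N/O acceptors, geometric
# hydrogen-bond detection, SHB/NHB labeling, and dataset statistics.
#
# A donor-H...acceptor contact is a short hydrogen bond (SHB) when the
# heavy-atom separation R lies in [2.3, 2.7] A, a normal hydrogen bond
# (NHB) when R lies in [2.8, 3.2] A, in both cases with the angle at
# the hydrogen >= 135 degrees; the 2.7-2.8 A gap deliberately separates
# the two classes and falls through as "unlabeled".

#' Enumerate side-chain hydrogen-bond donors
#'
#' Donors are the side-chain N/O heavy atoms of Ser (OG), Thr (OG1),
#' Tyr (OH), Trp (NE1), His (ND1/NE2 when protonated), Lys (NZ), Arg
#' (NE, NH1, NH2), Asn (ND2) and Gln (NE2) that carry at least one
#' hydrogen.  S-containing and C-H donors are excluded, and the
#' backbone amide is never a donor.  Donor atoms lacking hydrogens are
#' skipped with a warning.
#'
#' @param s a `protein_structure`.
#' @param warn warn about donor atoms without attached hydrogens.
#' @return data frame with one row per donor heavy atom: residue
#'   identity, `atom`, `elem`, group `charge`, coordinates, and the
#'   atom-table indices of its hydrogens in `h_idx` (list column).
#' @export
enumerate_donors <- function(s, warn = TRUE) {
  at <- s$atoms
  key <- paste(at$resn, at$name)
  dkey <- paste(.DONOR_ATOMS$resn, .DONOR_ATOMS$atom)
  idx <- which(key %in% dkey & at$record == "ATOM")
  rows <- list(); no_h <- character()
  hset <- which(at$elem == "H")
  for (i in idx) {
    hx <- at$x[hset] - at$x[i]; hy <- at$y[hset] - at$y[i]; hz <- at$z[hset] - at$z[i]
    near <- hset[sqrt(hx^2 + hy^2 + hz^2) <= .H_COVALENT_MAX &
                   at$reskey[hset] == at$reskey[i]]
    spec <- .DONOR_ATOMS[match(paste(at$resn[i], at$name[i]), dkey), ]
    if (length(near) == 0) {
      no_h <- c(no_h, sprintf("%s %s%s %s", at$resn[i], at$chain[i], at$resi[i], at$name[i]))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = at$chain[i], resi = at$resi[i], ins = at$ins[i], resn = at$resn[i],
      reskey = at$reskey[i], atom = at$name[i], elem = spec$elem,
      charge = spec$charge, x = at$x[i], y = at$y[i], z = at$z[i],
      atom_idx = i, stringsAsFactors = FALSE)
    rows[[length(rows)]]$h_idx <- I(list(near))
  }
  if (warn && length(no_h) > 0)
    warning(length(no_h), " donor atom(s) without hydrogens skipped: ",
            paste(utils::head(no_h, 5), collapse = "; "),
            if (length(no_h) > 5) " ...")
  if (length(rows) == 0)
    return(data.frame(chain = character(), resi = integer(), ins = character(),
                      resn = character(), reskey = character(), atom = character(),
                      elem = character(), charge = integer(), x = numeric(),
                      y = numeric(), z = numeric(), atom_idx = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate hydrogen-bond acceptors
#'
#' Acceptors are the backbone carbonyl oxygen of every residue plus the
#' side-chain atoms Asp OD1/OD2, Glu OE1/OE2, Asn OD1, Gln OE1, Ser OG,
#' Thr OG1, Tyr OH, and unprotonated His ring nitrogens.  Carboxylate
#' oxygens carry a -1 group charge, all others 0.
#'
#' @param s a `protein_structure`.
#' @return data frame with one row per acceptor heavy atom, including
#'   `location` (`"backbone"` or `"side_chain"`) and `charge`.
#' @export
enumerate_acceptors <- function(s) {
  at <- s$atoms
  bb <- which(at$name == "O" & at$record == "ATOM")
  key <- paste(at$resn, at$name)
  akey <- paste(.ACCEPTOR_SC_ATOMS$resn, .ACCEPTOR_SC_ATOMS$atom)
  sc <- which(key %in% akey & at$record == "ATOM")
  # His ring N accepts only when unprotonated
  if (length(sc) > 0) {
    hset <- which(at$elem == "H")
    keep <- vapply(sc, function(i) {
      if (at$elem[i] != "N") return(TRUE)
      if (length(hset) == 0) return(TRUE)
      d <- sqrt((at$x[hset] - at$x[i])^2 + (at$y[hset] - at$y[i])^2 +
                  (at$z[hset] - at$z[i])^2)
      !any(d <= .H_COVALENT_MAX & at$reskey[hset] == at$reskey[i])
    }, logical(1))
    sc <- sc[keep]
  }
  idx <- c(bb, sc)
  loc <- c(rep("backbone", length(bb)), rep("side_chain", length(sc)))
  chg <- c(rep(0L, length(bb)),
           .ACCEPTOR_SC_ATOMS$charge[match(key[sc], akey)])
  out <- data.frame(
    chain = at$chain[idx], resi = at$resi[idx], ins = at$ins[idx],
    resn = at$resn[idx], reskey = at$reskey[idx], atom = at$name[idx],
    elem = ifelse(loc == "backbone", "O",
                  .ACCEPTOR_SC_ATOMS$elem[match(key[idx], akey)]),
    location = loc, charge = chg,
    x = at$x[idx], y = at$y[idx], z = at$z[idx], atom_idx = idx,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify hydrogen-bond geometry
#'
#' @param R donor-acceptor heavy-atom distance(s), Angstrom; must be
#'   positive.
#' @param angle donor-H-acceptor angle(s) at the hydrogen, degrees.
#' @return character vector over `{"SHB", "NHB", "unlabeled"}`:
#'   `"SHB"` iff `2.3 <= R <= 2.7` and `angle >= 135`; `"NHB"` iff
#'   `2.8 <= R <= 3.2` and `angle >= 135`; otherwise `"unlabeled"`
#'   (including the deliberate 2.7-2.8 A gap).  All window boundaries
#'   are inclusive.
#' @examples
#' classify_geometry(2.65, 160)  # "SHB"
#' classify_geometry(2.75, 160)  # "unlabeled" (gap)
#' @export
classify_geometry <- function(R, angle) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be positive and finite")
  out <- rep("unlabeled", length(R))
  ok <- angle >= .HB_ANGLE_MIN
  out[ok & R >= .SHB_R_MIN & R <= .SHB_R_MAX] <- "SHB"
  out[ok & R >= .NHB_R_MIN & R <= .NHB_R_MAX] <- "NHB"
  out
}

#' Detect hydrogen bonds in a structure
#'
#' Evaluates all donor x acceptor heavy-atom pairs with `R <= 3.2` A
#' (via a 3.2 A spatial grid, or brute-force all pairs), excluding
#' same-residue pairs.  For each donor atom the hydrogen maximizing the
#' angle at the hydrogen defines the recorded geometry; records are at
#' atom-pair granularity, so a residue pair may contribute more than
#' one record.  Output is sorted by donor then acceptor identity.
#'
#' @param s a `protein_structure`.
#' @param method `"grid"` (default) or `"brute"`; both return the exact
#'   same record set.
#' @return data frame of hydrogen-bond records: donor and acceptor
#'   residue/atom identity and 0-based chain `serial` indices,
#'   `acceptor_location`, group charges, `h_atom`, `R` (Angstrom),
#'   `angle` (degrees) and `label` from [classify_geometry()].
#' @export
detect_hydrogen_bonds <- function(s, method = c("grid", "brute")) {
  method <- match.arg(method)
  don <- enumerate_donors(s)
  acc <- enumerate_acceptors(s)
  if (nrow(don) == 0 && sum(s$atoms$elem == "H") == 0)
    stop("no donors usable: structure has no hydrogens ",
         "(add them or run place_polar_hydrogens())")
  empty <- data.frame(structure_id = character(), chain_d = character(),
                      resi_d = integer(), ins_d = character(), resn_d = character(),
                      atom_d = character(), serial_d = integer(),
                      chain_a = character(), resi_a = integer(), ins_a = character(),
                      resn_a = character(), atom_a = character(), serial_a = integer(),
                      acceptor_location = character(), donor_charge = integer(),
                      acceptor_charge = integer(), donor_elem = character(),
                      acceptor_elem = character(), h_atom = character(),
                      R = numeric(), angle = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty)

  pairs <- if (method == "grid") grid_pairs(don, acc, 3.2) else {
    expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
  }
  if (nrow(pairs) == 0) return(empty)

  at <- s$atoms
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$d[k]; j <- pairs$a[k]
    if (don$reskey[i] == acc$reskey[j]) next
    D <- c(don$x[i], don$y[i], don$z[i])
    A <- c(acc$x[j], acc$y[j], acc$z[j])
    R <- vec_norm(D - A)
    if (R > 3.2) next
    hs <- don$h_idx[[i]]
    ang <- max(vapply(hs, function(h)
      vertex_angle(D, c(at$x[h], at$y[h], at$z[h]), A), numeric(1)))
    hbest <- hs[which.max(vapply(hs, function(h)
      vertex_angle(D, c(at$x[h], at$y[h], at$z[h]), A), numeric(1)))]
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = s$structure_id,
      chain_d = don$chain[i], resi_d = don$resi[i], ins_d = don$ins[i],
      resn_d = don$resn[i], atom_d = don$atom[i],
      serial_d = s$residues$serial[match(don$reskey[i], s$residues$reskey)],
      chain_a = acc$chain[j], resi_a = acc$resi[j], ins_a = acc$ins[j],
      resn_a = acc$resn[j], atom_a = acc$atom[j],
      serial_a = s$residues$serial[match(acc$reskey[j], s$residues$reskey)],
      acceptor_location = acc$location[j],
      donor_charge = don$charge[i], acceptor_charge = acc$charge[j],
      donor_elem = don$elem[i], acceptor_elem = acc$elem[j],
      h_atom = at$name[hbest], R = R, angle = ang,
      label = classify_geometry(R, ang), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$structure_id, out$chain_d, out$serial_d, out$atom_d,
                   out$chain_a, out$serial_a, out$atom_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Spatial hashing on a `cell` Angstrom grid: candidate donor/acceptor
# index pairs from the 27 neighbouring cells of each donor.
grid_pairs <- function(don, acc, cell) {
  cd <- cbind(floor(don$x / cell), floor(don$y / cell), floor(don$z / cell))
  ca <- cbind(floor(acc$x / cell), floor(acc$y / cell), floor(acc$z / cell))
  akey <- paste(ca[, 1], ca[, 2], ca[, 3])
  amap <- split(seq_len(nrow(acc)), akey)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d_out <- integer(0); a_out <- integer(0)
  for (i in seq_len(nrow(don))) {
    nb <- sweep(off, 2, cd[i, ], "+")
    keys <- paste(nb[, 1], nb[, 2], nb[, 3])
    cand <- unlist(amap[keys], use.names = FALSE)
    if (length(cand)) {
      d_out <- c(d_out, rep.int(i, length(cand)))
      a_out <- c(a_out, cand)
    }
  }
  data.frame(d = d_out, a = a_out)
}

#' Summarize a labeled hydrogen-bond table
#'
#' Counts SHB and NHB records and reports the SHB fraction
#' `nSHB / (nSHB + nNHB)` as a percentage rounded to one decimal,
#' overall and (when an `acceptor_location` column is present) grouped
#' by acceptor location.  With zero labeled records the fraction is
#' `NA`, not 0.
#'
#' @param records data frame with a `label` column (`"SHB"`, `"NHB"`,
#'   `"unlabeled"`), e.g. from [detect_hydrogen_bonds()].
#' @return data frame with columns `group`, `n_shb`, `n_nhb`,
#'   `n_unlabeled`, `shb_pct`.
#' @export
summarize_hbonds <- function(records) {
  stopifnot("label" %in% names(records))
  one <- function(df, group) {
    ns <- sum(df$label == "SHB"); nn <- sum(df$label == "NHB")
    pct <- if (ns + nn == 0) NA_real_ else round(100 * ns / (ns + nn), 1)
    data.frame(group = group, n_shb = ns, n_nhb = nn,
               n_unlabeled = sum(df$label == "unlabeled"),
               shb_pct = pct, stringsAsFactors = FALSE)
  }
  out <- one(records, "overall")
  if ("acceptor_location" %in% names(records) && nrow(records) > 0) {
    for (loc in sort(unique(records$acceptor_location)))
      out <- rbind(out, one(records[records$acceptor_location == loc, ], loc))
  }
  rownames(out) <- NULL
  out
}

#' Per residue-pair SHB statistics
#'
#' For each (donor residue, acceptor residue) pair: number of labeled
#' hydrogen bonds, SHB probability (%), and the median R among SHBs and
#' among NHBs.  Additionally reports, for same-chain pairs whose donor
#' and acceptor are separated by exactly two positions in sequence (the
#' donor-Xxx-acceptor motif), the motif count and SHB probability.
#'
#' @param records labeled hydrogen-bond records carrying residue
#'   identities and chain serial indices.
#' @return data frame with one row per residue pair, sorted by
#'   descending `n`.
#' @export
pair_statistics <- function(records) {
  lab <- records[records$label %in% c("SHB", "NHB"), , drop = FALSE]
  if (nrow(lab) == 0)
    return(data.frame(resn_d = character(), resn_a = character(), n = integer(),
                      shb_pct = numeric(), median_r_shb = numeric(),
                      median_r_nhb = numeric(), n_seq2 = integer(),
                      shb_pct_seq2 = numeric(), stringsAsFactors = FALSE))
  key <- paste(lab$resn_d, lab$resn_a, sep = "-")
  seq2 <- if (all(c("chain_d", "chain_a", "serial_d", "serial_a") %in% names(lab)))
    lab$chain_d == lab$chain_a & abs(lab$serial_d - lab$serial_a) == 2
  else rep(FALSE, nrow(lab))
  out <- do.call(rbind, lapply(split(seq_len(nrow(lab)), key), function(i) {
    df <- lab[i, ]
    shb <- df$label == "SHB"
    m2 <- seq2[i]
    data.frame(resn_d = df$resn_d[1L], resn_a = df$resn_a[1L],
               n = nrow(df), shb_pct = round(100 * mean(shb), 1),
               median_r_shb = if (any(shb)) stats::median(df$R[shb]) else NA_real_,
               median_r_nhb = if (any(!shb)) stats::median(df$R[!shb]) else NA_real_,
               n_seq2 = sum(m2),
               shb_pct_seq2 = if (any(m2)) round(100 * mean(shb[m2]), 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n, out$resn_d, out$resn_a), ]
  rownames(out) <- NULL
  out
}

#' Write / read hydrogen-bond records as TSV
#'
#' The TSV carries `R` to 3 decimals and `angle` to 1 decimal.
#'
#' @param records hydrogen-bond records from [detect_hydrogen_bonds()].
#' @param path file path.
#' @return `write_hbonds` returns `path` invisibly; `read_hbonds`
#'   returns the records data frame.
#' @export
write_hbonds <- function(records, path) {
  out <- records
  out$R <- sprintf("%.3f", out$R)
  out$angle <- sprintf("%.1f", out$angle)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hbonds
#' @export
read_hbonds <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(R = "numeric", angle = "numeric"))
}
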
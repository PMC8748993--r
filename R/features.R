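# Encoding of hydrogen bonds as the 21 categorical predictors used by
# the classifier: donor/acceptor residue, heteroatom element, group
# charge, acceptor location, donor/acceptor secondary structure, and
# the residue identities within 3 positions before and after the donor
# and acceptor in their chains.  The bond geometry (R, angle) defines
# the label and is deliberately NOT a predictor.

.FEATURE_NAMES <- c("donor_res", "acceptor_res", "donor_elem", "acceptor_elem",
                    "donor_chg", "acceptor_chg", "acceptor_loc",
                    "donor_ss", "acceptor_ss",
                    "d_m3", "d_m2", "d_m1", "d_p1", "d_p2", "d_p3",
                    "a_m3", "a_m2", "a_m1", "a_p1", "a_p2", "a_p3")

#' Fixed encoding map for the 21 features
#'
#' Closed vocabularies for every feature.  `TER` (chain terminus) and
#' `UNK` (non-standard residue) are distinct tokens.
#'
#' @return named list mapping each feature to its level set.
#' @export
default_encoding_map <- function() {
  res_v <- c(.AA3, "UNK")
  ctx_v <- c(.AA3, "UNK", "TER")
  m <- list(donor_res = res_v, acceptor_res = res_v,
            donor_elem = c("N", "O"), acceptor_elem = c("N", "O"),
            donor_chg = c("-1", "0", "1"), acceptor_chg = c("-1", "0", "1"),
            acceptor_loc = c("backbone", "side_chain"),
            donor_ss = .SS_LEVELS, acceptor_ss = .SS_LEVELS)
  for (f in .FEATURE_NAMES[10:21]) m[[f]] <- ctx_v
  m
}

std_res <- function(x) ifelse(x %in% .AA3, x, "UNK")

#' Extract the 21-feature vectors for hydrogen-bond records
#'
#' Sequence context is indexed by the chain's 0-based serial position
#' (not author numbering), so numbering gaps and insertion codes cannot
#' shift the window; positions beyond the chain termini yield `TER` and
#' non-standard residues `UNK`.  Donor and acceptor each use their own
#' chain's context.  Secondary structure must already be assigned.
#'
#' @param records hydrogen-bond records from [detect_hydrogen_bonds()]
#'   for structure `s`.
#' @param s the `protein_structure` the records refer to, with
#'   secondary structure assigned.
#' @return data frame with the 21 feature columns plus `label` and
#'   `structure_id` carried over from `records`.
#' @export
extract_features <- function(records, s) {
  stopifnot(inherits(s, "protein_structure"))
  if (nrow(records) == 0)
    return(cbind(as.data.frame(setNames(rep(list(character()), 21), .FEATURE_NAMES)),
                 label = character(), structure_id = character()))
  if (all(is.na(s$residues$ss)))
    stop("secondary structure not assigned; run assign_secondary_structure() first")
  res <- s$residues
  chains <- split(res, res$chain)
  chains <- lapply(chains, function(df) df[order(df$serial), , drop = FALSE])

  ctx <- function(chain, serial, off) {
    df <- chains[[chain]]
    j <- serial + off + 1L
    ifelse(j < 1L | j > nrow(df), "TER", std_res(df$resn[pmin(pmax(j, 1L), nrow(df))]))
  }
  ss_of <- function(chain, serial) {
    df <- chains[[chain]]
    v <- df$ss[match(serial, df$serial)]
    ifelse(is.na(v), "coil", v)
  }
  miss_d <- is.na(match(paste(records$chain_d, records$serial_d),
                        paste(res$chain, res$serial)))
  miss_a <- is.na(match(paste(records$chain_a, records$serial_a),
                        paste(res$chain, res$serial)))
  if (any(miss_d | miss_a))
    stop("encoding error: record(s) ", paste(which(miss_d | miss_a), collapse = ", "),
         " refer to residues not present in structure ", s$structure_id)

  out <- data.frame(
    donor_res = std_res(records$resn_d),
    acceptor_res = std_res(records$resn_a),
    donor_elem = records$donor_elem,
    acceptor_elem = records$acceptor_elem,
    donor_chg = as.character(records$donor_charge),
    acceptor_chg = as.character(records$acceptor_charge),
    acceptor_loc = records$acceptor_location,
    donor_ss = mapply(ss_of, records$chain_d, records$serial_d),
    acceptor_ss = mapply(ss_of, records$chain_a, records$serial_a),
    stringsAsFactors = FALSE)
  offs <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  for (k in seq_along(offs)) {
    out[[.FEATURE_NAMES[9L + k]]] <-
      mapply(ctx, records$chain_d, records$serial_d, MoreArgs = list(off = offs[k]))
    out[[.FEATURE_NAMES[15L + k]]] <-
      mapply(ctx, records$chain_a, records$serial_a, MoreArgs = list(off = offs[k]))
  }
  out$label <- records$label
  out$structure_id <- records$structure_id
  rownames(out) <- NULL
  out
}

#' Assemble a labeled feature dataset from structures
#'
#' Runs secondary-structure assignment (if needed), hydrogen-bond
#' detection and feature extraction on each structure, drops unlabeled
#' (gap) records with a message, and binds the rows in deterministic
#' detection order.
#'
#' @param structures a list of `protein_structure` objects, or a
#'   character vector of PDB file paths.
#' @param place_h add idealized polar hydrogens before detection.
#' @return an `shb_dataset`: data frame of 21 feature columns plus
#'   `label`, with a `provenance` attribute listing structure ids.
#' @export
build_dataset <- function(structures, place_h = FALSE) {
  if (is.character(structures)) structures <- lapply(structures, read_structure)
  rows <- list(); ids <- character(); n_unlab <- 0L
  for (s in structures) {
    if (place_h) s <- place_polar_hydrogens(s)
    if (all(is.na(s$residues$ss))) s <- assign_secondary_structure(s)
    rec <- detect_hydrogen_bonds(s)
    fv <- extract_features(rec, s)
    n_unlab <- n_unlab + sum(fv$label == "unlabeled")
    fv <- fv[fv$label != "unlabeled", , drop = FALSE]
    rows[[length(rows) + 1L]] <- fv
    ids <- c(ids, s$structure_id)
  }
  out <- do.call(rbind, rows)
  if (n_unlab > 0) message(n_unlab, " unlabeled (gap) record(s) dropped")
  out$structure_id <- NULL
  as_shb_dataset(out, provenance = ids)
}

#' Validate and class a labeled feature table
#'
#' @param x data frame with the 21 feature columns and a `label` column
#'   in `{SHB, NHB}`.
#' @param provenance optional character vector of source structure ids.
#' @return `x` with class `shb_dataset`; vocabulary violations raise an
#'   error naming the offending value.
#' @export
as_shb_dataset <- function(x, provenance = character()) {
  miss <- setdiff(c(.FEATURE_NAMES, "label"), names(x))
  if (length(miss) > 0)
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[, c(.FEATURE_NAMES, "label")]
  for (f in .FEATURE_NAMES) x[[f]] <- as.character(x[[f]])
  map <- default_encoding_map()
  for (f in .FEATURE_NAMES) {
    bad <- setdiff(unique(x[[f]]), map[[f]])
    if (length(bad) > 0)
      stop("schema error: column '", f, "' contains value(s) outside its ",
           "vocabulary: ", paste(utils::head(bad, 3), collapse = ", "))
  }
  bad <- setdiff(unique(x$label), c("SHB", "NHB"))
  if (length(bad) > 0)
    stop("schema error: label contains ", paste(bad, collapse = ", "),
         " (unlabeled rows must be dropped before training)")
  rownames(x) <- NULL
  structure(x, provenance = provenance, class = c("shb_dataset", "data.frame"))
}

#' @export
print.shb_dataset <- function(x, ...) {
  cat(sprintf("<shb_dataset> %d hydrogen bonds: %d SHB, %d NHB (%d structures)\n",
              nrow(x), sum(x$label == "SHB"), sum(x$label == "NHB"),
              length(attr(x, "provenance"))))
  NextMethod()
}

#' Write / read a labeled feature dataset as TSV
#'
#' @param d an `shb_dataset`.
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset`
#'   returns a validated `shb_dataset`.
#' @export
write_dataset <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  n_unlab <- sum(x$label == "unlabeled")
  if (n_unlab > 0) {
    message(n_unlab, " unlabeled row(s) dropped")
    x <- x[x$label != "unlabeled", , drop = FALSE]
  }
  as_shb_dataset(x, provenance = path)
}

#' One-hot encode feature vectors
#'
#' Encodes the 21 categorical features against a fixed encoding map
#' into a sparse indicator matrix whose columns are named
#' `feature=level`, so that split-gain importances can be aggregated
#' back to the 21 parent features.  Values outside a feature's
#' vocabulary are mapped to its `UNK` level with a warning (features
#' without an `UNK` level contribute an all-zero block).
#'
#' @param x data frame containing the 21 feature columns.
#' @param map encoding map, by default [default_encoding_map()].
#' @return sparse `dgCMatrix` with `nrow(x)` rows.
#' @export
encode_features <- function(x, map = default_encoding_map()) {
  n <- nrow(x)
  sizes <- lengths(map)
  offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(map)
  ii <- integer(0); jj <- integer(0)
  unseen <- character(0)
  for (f in names(map)) {
    v <- as.character(x[[f]])
    m <- match(v, map[[f]])
    if (anyNA(m)) {
      unseen <- c(unseen, unique(v[is.na(m)]))
      if ("UNK" %in% map[[f]]) m[is.na(m)] <- match("UNK", map[[f]])
    }
    keep <- !is.na(m)
    ii <- c(ii, which(keep))
    jj <- c(jj, offs[[f]] + m[keep])
  }
  if (length(unseen) > 0)
    warning("unseen categorical value(s) mapped to UNK: ",
            paste(unique(unseen), collapse = ", "))
  Matrix::sparseMatrix(
    i = ii, j = jj, x = 1,
    dims = c(n, sum(sizes)),
    dimnames = list(NULL, unlist(lapply(names(map), function(f)
      paste0(f, "=", map[[f]])), use.names = FALSE)))
}

#' @rdname encode_features
#' @param mat matrix produced by `encode_features`.
#' @return `decode_features` returns the data frame of feature values
#'   (all-zero blocks decode to `UNK`).
#' @export
decode_features <- function(mat, map = default_encoding_map()) {
  sizes <- lengths(map)
  offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(map)
  out <- list()
  dm <- as.matrix(mat)
  for (f in names(map)) {
    block <- dm[, offs[[f]] + seq_len(sizes[[f]]), drop = FALSE]
    hit <- apply(block, 1, function(r) {
      w <- which(r > 0)
      if (length(w) == 0) "UNK" else map[[f]][w[1L]]
    })
    out[[f]] <- hit
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
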
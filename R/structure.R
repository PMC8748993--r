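# Reading, validating and preparing protein structures (PDB dialect).
# Atom-record parsing and writing are delegated to bio3d; header REMARK
# metadata, altloc/occupancy resolution, water removal and model
# selection are handled here.

#' @importFrom stats median setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

new_protein_structure <- function(atoms, structure_id = "struct",
                                  title = "", experiment = "other",
                                  quality = list(resolution = NA_real_,
                                                 r_factor = NA_real_,
                                                 r_free = NA_real_),
                                  het = NULL) {
  atoms$reskey <- paste(atoms$chain, atoms$resi, atoms$ins, sep = "|")
  res <- atoms[!duplicated(atoms$reskey), c("chain", "resi", "ins", "resn", "reskey")]
  rownames(res) <- NULL
  res$serial <- stats::ave(seq_len(nrow(res)), res$chain, FUN = seq_along) - 1L
  res$ss <- NA_character_
  structure(list(structure_id = structure_id,
                 title = title,
                 experiment = experiment,
                 quality = quality,
                 atoms = atoms,
                 residues = res,
                 het = het),
            class = "protein_structure")
}

#' Read a protein structure from a PDB file
#'
#' Reads the first MODEL only.  For alternate locations the
#' highest-occupancy conformer is kept (ties broken in favour of altLoc
#' `A`); crystallographic waters are removed; HETATM ligand records are
#' retained in the `het` slot but excluded from the residue chains.
#' Resolution, R-factor and R-free are parsed from REMARK 2 / REMARK 3
#' header records when present.
#'
#' @param path path to a PDB-format file.
#' @param structure_id identifier stored with the structure; defaults to
#'   the file name without extension.
#' @return an object of class `protein_structure` with elements
#'   `structure_id`, `title`, `experiment` (`"xray"`, `"neutron"` or
#'   `"other"`), `quality` (list with `resolution`, `r_factor`,
#'   `r_free`), `atoms` (data frame of chain atoms), `residues` (one row
#'   per residue with a 0-based `serial` index and a `ss` secondary
#'   structure slot) and `het` (ligand atoms).
#' @seealso [validate_quality()], [place_polar_hydrogens()],
#'   [assign_secondary_structure()], [detect_hydrogen_bonds()]
#' @export
read_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("PDB parse error reading '", path,
                                             "': ", conditionMessage(e)))
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))

  rec <- substr(lines, 1, 6)
  title <- paste(trimws(substr(lines[rec == "TITLE "], 11, 80)), collapse = " ")
  expd <- paste(lines[rec == "EXPDTA"], collapse = " ")
  experiment <- if (grepl("NEUTRON", expd)) "neutron"
                else if (grepl("X-RAY", expd)) "xray"
                else "other"
  quality <- parse_quality_remarks(lines)

  # first MODEL only
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1L])]

  atom_idx <- which(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0)
    stop("PDB parse error in '", path, "': no ATOM/HETATM records found")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("PDB parse error in '", path, "' near line ", atom_idx[1L], ": ",
           conditionMessage(e))
    })
  at <- pdb$atom
  atoms <- data.frame(
    record = at$type,
    serial = at$eleno,
    name = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resn = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resi = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    elem = guess_element(at$elesy, at$elety),
    stringsAsFactors = FALSE)

  atoms <- resolve_altloc(atoms)
  atoms <- atoms[!(atoms$resn %in% .WATER_RES), , drop = FALSE]

  het <- atoms[atoms$record == "HETATM", , drop = FALSE]
  atoms <- atoms[atoms$record == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0)
    stop("empty structure: '", path, "' contains no standard (ATOM) residues")
  rownames(atoms) <- NULL
  rownames(het) <- NULL
  new_protein_structure(atoms, structure_id = structure_id, title = title,
                        experiment = experiment, quality = quality, het = het)
}

parse_quality_remarks <- function(lines) {
  q <- list(resolution = NA_real_, r_factor = NA_real_, r_free = NA_real_)
  num <- function(x) {
    m <- regmatches(x, regexpr("[0-9]+\\.?[0-9]*", x))
    if (length(m) && nzchar(m[1L])) as.numeric(m[1L]) else NA_real_
  }
  r2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(r2)) q$resolution <- num(sub(".*RESOLUTION\\.", "", r2[1L]))
  rw <- grep("^REMARK   3.*\\bR VALUE\\s+\\(WORKING SET\\)", lines, value = TRUE)
  if (!length(rw)) rw <- grep("^REMARK   3\\s+R VALUE\\s*:", lines, value = TRUE)
  if (length(rw)) q$r_factor <- num(sub(".*:", "", rw[1L]))
  rf <- grep("^REMARK   3\\s+FREE R VALUE\\s*:", lines, value = TRUE)
  if (length(rf)) q$r_free <- num(sub(".*:", "", rf[1L]))
  q
}

guess_element <- function(elesy, name) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(e)
  if (any(miss)) {
    n <- gsub("[0-9']", "", toupper(name[miss]))
    first <- substr(n, 1, 1)
    two <- substr(n, 1, 2)
    guess <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"),
                    two, first)
    e[miss] <- guess
  }
  e
}

# Keep one conformer per (chain, resi, ins, name): highest occupancy,
# ties broken by altLoc letter ('' sorts before 'A').
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resi, atoms$ins, atoms$resn, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' Writes chain atoms (and retained HETATM records) in fixed-width PDB
#' format via bio3d.  Coordinates survive a read -> write -> read
#' round trip to the 3 decimals of the format.
#'
#' @param s a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  at <- s$atoms
  if (!is.null(s$het) && nrow(s$het) > 0) {
    het <- s$het
    het$reskey <- paste(het$chain, het$resi, het$ins, sep = "|")
    at <- rbind(at, het[, names(at)])
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = at$record,
                   resno = at$resi,
                   resid = at$resn,
                   eleno = seq_len(nrow(at)),
                   elety = at$name,
                   chain = at$chain,
                   insert = ifelse(nzchar(at$ins), at$ins, NA),
                   o = at$occ,
                   b = at$b,
                   elesy = at$elem)
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$structure_id, "\n", sep = "")
  nch <- length(unique(x$residues$chain))
  cat(sprintf("  %d residues in %d chain(s), %d atoms (%d hydrogens)\n",
              nrow(x$residues), nch, nrow(x$atoms), sum(x$atoms$elem == "H")))
  q <- x$quality
  cat(sprintf("  experiment: %s; resolution %s A, R %s, Rfree %s\n",
              x$experiment, format(q$resolution), format(q$r_factor),
              format(q$r_free)))
  if (!all(is.na(x$residues$ss)))
    cat("  secondary structure: ",
        paste(sprintf("%s=%d", names(table(x$residues$ss)),
                      as.integer(table(x$residues$ss))), collapse = " "), "\n")
  invisible(x)
}

#' Validate structure quality metadata
#'
#' A structure passes when its resolution is at or below
#' `max_resolution`, the R-factor at or below `max_r_factor`, and the
#' R-free minus R-factor gap at or below `max_r_gap`.  Missing fields
#' are reported as warnings, not failures.  `permissive = TRUE` relaxes
#' the R-factor ceiling to 0.28 for structures whose refinement
#' statistics fall slightly outside the strict filter.
#'
#' @param q quality list (`resolution`, `r_factor`, `r_free`) or a
#'   `protein_structure`.
#' @param max_resolution maximum resolution, Angstrom (default 1.1).
#' @param max_r_factor maximum R-factor (default 0.20).
#' @param max_r_gap maximum R-free minus R-factor (default 0.07).
#' @param permissive relax the R-factor ceiling to 0.28.
#' @return list with `pass` (logical), `reasons` (character vector of
#'   failures) and `warnings` (missing-field notes).
#' @export
validate_quality <- function(q, max_resolution = 1.1, max_r_factor = 0.20,
                             max_r_gap = 0.07, permissive = FALSE) {
  if (inherits(q, "protein_structure")) q <- q$quality
  if (max_resolution <= 0 || max_r_factor <= 0 || max_r_gap <= 0)
    stop("quality thresholds must be positive")
  if (permissive) max_r_factor <- max(max_r_factor, 0.28)
  reasons <- character()
  warns <- character()
  if (is.na(q$resolution)) warns <- c(warns, "resolution missing")
  else if (q$resolution > max_resolution)
    reasons <- c(reasons, sprintf("resolution %.2f A > %.2f A",
                                  q$resolution, max_resolution))
  if (is.na(q$r_factor)) warns <- c(warns, "r_factor missing")
  else if (q$r_factor > max_r_factor)
    reasons <- c(reasons, sprintf("R-factor %.3f > %.3f", q$r_factor, max_r_factor))
  if (is.na(q$r_free) || is.na(q$r_factor)) {
    if (is.na(q$r_free)) warns <- c(warns, "r_free missing")
  } else if (q$r_free - q$r_factor > max_r_gap) {
    reasons <- c(reasons, sprintf("R-free - R-factor gap %.3f > %.3f",
                                  q$r_free - q$r_factor, max_r_gap))
  }
  list(pass = length(reasons) == 0, reasons = reasons, warnings = warns)
}

#' Split structures into training and test pools by molecule name
#'
#' Keeps one representative per unique normalized molecule name (first
#' by sorted structure id) as the training pool; all remaining entries
#' go to the test pool.  The split is deterministic.
#'
#' @param ids character vector of structure ids.
#' @param names character vector of molecule names (e.g. header titles),
#'   same length as `ids`.
#' @return list with character vectors `train` and `test`.
#' @export
split_by_name <- function(ids, names) {
  stopifnot(length(ids) == length(names))
  norm <- tolower(gsub("\\s+", " ", trimws(names)))
  ok <- !is.na(norm) & nzchar(norm)
  if (any(!ok)) {
    warning(sum(!ok), " structure(s) without a molecule name excluded from the split")
    ids <- ids[ok]; norm <- norm[ok]
  }
  if (length(ids) == 0) return(list(train = character(), test = character()))
  ord <- order(norm, ids)
  first <- !duplicated(norm[ord])
  list(train = ids[ord][first], test = ids[ord][!first])
}
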
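# Synthetic data: (a) labeled feature tables whose class-conditional
# SHB probabilities follow configured per-donor values, with an
# optional additive log-odds shift for carboxylate acceptors and a
# sequence-motif override; (b) toy PDB structures with a hydrogen bond
# planted at an exact donor-acceptor distance and angle.  Together they
# make the whole pipeline testable without any external structure.

.DONOR_ATOM_ONE <- c(SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1",
                     HIS = "NE2", LYS = "NZ", ARG = "NH1", ASN = "ND2",
                     GLN = "NE2")
.ACCEPTOR_ATOM_ONE <- c(ASP = "OD1", GLU = "OE1", ASN = "OD1", GLN = "OE1",
                        SER = "OG", THR = "OG1", TYR = "OH", HIS = "ND1")

#' Configuration for the synthetic feature-table generator
#'
#' The default per-donor SHB probabilities reproduce the observed
#' preferences of the donor groups: Tyr 0.86; Ser 0.53, Thr 0.40, His
#' 0.29; and below 0.15 for the N-donor group (Arg, Lys, Asn, Gln,
#' Trp).  The default acceptor shift of 1.92 log-odds units is the
#' logit difference between a Thr donor's SHB probability with a
#' carboxylate acceptor (0.738) and with a neutral one (0.292); when
#' the shift is enabled the per-donor table is interpreted as the
#' neutral-acceptor probability.  The motif override (0.825) applies to
#' Ser/Thr-Xxx-Asp arrangements where donor and acceptor are separated
#' by exactly two sequence positions.
#'
#' @param n number of rows to generate.
#' @param seed integer seed; the generator is fully deterministic.
#' @param mode `"balanced"` (rejection-sample to a 50/50 class
#'   marginal) or `"prevalence"` (rejection-sample to `prevalence`).
#' @param prevalence SHB marginal for `mode = "prevalence"`; default
#'   0.187, the prevalence of SHBs among labeled hydrogen bonds.
#' @param donor_dist named sampling distribution over donor residues.
#' @param base_prob named per-donor SHB probability table.
#' @param acceptor_dist named sampling distribution over side-chain
#'   acceptor residues.
#' @param backbone_frac fraction of bonds with a backbone acceptor.
#' @param acceptor_logodds_shift additive log-odds applied when the
#'   acceptor is a side-chain Asp/Glu; 0 gives a donor-only signal.
#' @param motif_frac fraction of rows forced into the Ser/Thr-Xxx-Asp
#'   motif arrangement.
#' @param motif_prob SHB probability override for motif rows.
#' @param ss_dist sampling distribution over secondary structures.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n = 5000L, seed = 1L,
                         mode = c("balanced", "prevalence"),
                         prevalence = 0.187,
                         donor_dist = c(SER = 0.22, THR = 0.18, TYR = 0.12,
                                        ARG = 0.15, LYS = 0.12, ASN = 0.08,
                                        GLN = 0.07, HIS = 0.04, TRP = 0.02),
                         base_prob = c(TYR = 0.86, SER = 0.53, THR = 0.40,
                                       HIS = 0.29, ARG = 0.10, LYS = 0.10,
                                       ASN = 0.12, GLN = 0.12, TRP = 0.14),
                         acceptor_dist = c(ASP = 0.32, GLU = 0.28, ASN = 0.10,
                                           GLN = 0.08, SER = 0.09, THR = 0.07,
                                           TYR = 0.04, HIS = 0.02),
                         backbone_frac = 0.35,
                         acceptor_logodds_shift = 1.92,
                         motif_frac = 0.03, motif_prob = 0.825,
                         ss_dist = c(helix = 0.35, sheet = 0.22,
                                     turn = 0.12, coil = 0.31)) {
  mode <- match.arg(mode)
  chk_dist <- function(d, what) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-6)
      stop("config error: ", what, " must be non-negative and sum to 1")
  }
  chk_prob <- function(p, what) {
    if (any(p <= 0 | p >= 1))
      stop("config error: ", what, " must lie strictly inside (0, 1)")
  }
  chk_dist(donor_dist, "donor_dist"); chk_dist(acceptor_dist, "acceptor_dist")
  chk_dist(ss_dist, "ss_dist")
  chk_prob(base_prob, "base_prob"); chk_prob(motif_prob, "motif_prob")
  chk_prob(prevalence, "prevalence")
  if (!all(names(donor_dist) %in% names(base_prob)))
    stop("config error: every donor in donor_dist needs a base_prob entry")
  structure(list(n = as.integer(n), seed = as.integer(seed), mode = mode,
                 prevalence = prevalence, donor_dist = donor_dist,
                 base_prob = base_prob, acceptor_dist = acceptor_dist,
                 backbone_frac = backbone_frac,
                 acceptor_logodds_shift = acceptor_logodds_shift,
                 motif_frac = motif_frac, motif_prob = motif_prob,
                 ss_dist = ss_dist),
            class = "synth_config")
}

draw_rows <- function(cfg, n) {
  donor <- sample(names(cfg$donor_dist), n, TRUE, cfg$donor_dist)
  motif <- stats::runif(n) < cfg$motif_frac
  donor[motif] <- sample(c("SER", "THR"), sum(motif), TRUE)
  backbone <- stats::runif(n) < cfg$backbone_frac
  backbone[motif] <- FALSE
  acc <- character(n)
  acc[backbone] <- sample(.AA3, sum(backbone), TRUE)
  acc[!backbone] <- sample(names(cfg$acceptor_dist), sum(!backbone), TRUE,
                           cfg$acceptor_dist)
  acc[motif] <- "ASP"

  x <- data.frame(donor_res = donor, acceptor_res = acc,
                  donor_elem = ifelse(donor %in% c("SER", "THR", "TYR"), "O", "N"),
                  acceptor_elem = ifelse(backbone, "O",
                                         ifelse(acc == "HIS", "N", "O")),
                  donor_chg = ifelse(donor %in% c("ARG", "LYS"), "1", "0"),
                  acceptor_chg = ifelse(!backbone & acc %in% c("ASP", "GLU"),
                                        "-1", "0"),
                  acceptor_loc = ifelse(backbone, "backbone", "side_chain"),
                  donor_ss = sample(names(cfg$ss_dist), n, TRUE, cfg$ss_dist),
                  acceptor_ss = sample(names(cfg$ss_dist), n, TRUE, cfg$ss_dist),
                  stringsAsFactors = FALSE)
  for (f in .FEATURE_NAMES[10:21]) x[[f]] <- sample(.AA3, n, TRUE)
  # motif arrangement: acceptor two positions after the donor (and the
  # donor two before the acceptor) in the shared chain
  x$d_p2[motif] <- "ASP"
  x$a_m2[motif] <- donor[motif]

  lo <- stats::qlogis(cfg$base_prob[donor]) +
    cfg$acceptor_logodds_shift * (!backbone & acc %in% c("ASP", "GLU"))
  p <- stats::plogis(lo)
  p[motif] <- cfg$motif_prob
  x$label <- ifelse(stats::rbinom(n, 1, p) == 1, "SHB", "NHB")
  x
}

#' Generate a labeled synthetic feature table
#'
#' Rows are drawn independently: donor, acceptor and context features
#' are sampled from the configured distributions and the SHB
#' probability of a row is
#' `plogis(qlogis(base_prob[donor]) + shift * [acceptor is side-chain
#' Asp/Glu])`, with the motif override where applicable; labels are
#' Bernoulli draws.  In balanced (or prevalence) mode the generator
#' rejection-samples to the target class marginal.  Fully deterministic
#' given the config seed, which is echoed into the `config` attribute.
#'
#' @param cfg a [synth_config()].
#' @return an `shb_dataset` with `config` attribute.
#' @export
generate_feature_table <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  target <- if (cfg$mode == "balanced") 0.5 else cfg$prevalence
  n_shb <- round(cfg$n * target)
  n_nhb <- cfg$n - n_shb
  got <- draw_rows(cfg, cfg$n)
  for (attempt in 1:200) {
    if (sum(got$label == "SHB") >= n_shb && sum(got$label == "NHB") >= n_nhb)
      break
    got <- rbind(got, draw_rows(cfg, cfg$n))
  }
  i_shb <- which(got$label == "SHB")
  i_nhb <- which(got$label == "NHB")
  if (length(i_shb) < n_shb || length(i_nhb) < n_nhb)
    stop("config error: class marginal ", target, " unreachable under the ",
         "configured probabilities")
  out <- got[sort(c(i_shb[seq_len(n_shb)], i_nhb[seq_len(n_nhb)])), , drop = FALSE]
  rownames(out) <- NULL
  out <- as_shb_dataset(out, provenance = sprintf("synthetic(seed=%d)", cfg$seed))
  attr(out, "config") <- cfg
  out
}

#' Build an idealized peptide backbone
#'
#' Constructs N/CA/C/O backbone coordinates for a single chain from
#' standard bond lengths and angles and the supplied phi/psi torsions
#' (omega fixed at 180).  Used by the toy-structure generator and for
#' constructing analytic secondary-structure cases.
#'
#' @param resn character vector of 3-letter residue codes.
#' @param phi,psi backbone torsions in degrees, recycled along the
#'   chain; the default (-180, 180) gives a fully extended chain with
#'   no internal backbone hydrogen bonds.
#' @param chain chain identifier.
#' @return atoms data frame suitable for [new_protein_structure()].
#' @export
build_peptide_backbone <- function(resn, phi = 180, psi = 180, chain = "A") {
  n <- length(resn)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, phi[1])
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  for (i in seq_len(n))
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
  rows <- lapply(seq_len(n), function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(record = "ATOM", serial = NA_integer_,
               name = c("N", "CA", "C", "O"), alt = "",
               resn = resn[i], chain = chain, resi = i, ins = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, b = 0, elem = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  rownames(at) <- NULL
  at
}

#' Generate a toy structure with a planted hydrogen bond
#'
#' Writes a two-fragment structure: a short extended host peptide
#' carrying the donor residue (with flanking sequence for the context
#' features) and a free acceptor fragment, with the donor heavy atom,
#' its hydrogen and the acceptor heavy atom placed so the written
#' coordinates realize the requested donor-acceptor distance within
#' 0.01 A and angle at the hydrogen within 0.5 degrees.  The donor side
#' chain extends perpendicular to the host backbone plane so that no
#' unintended contact falls inside the 3.2 A detection cutoff.
#'
#' @param donor donor residue type (SER, THR, TYR, TRP, HIS, LYS, ARG,
#'   ASN or GLN).
#' @param acceptor acceptor residue type (side-chain acceptor set).
#' @param r planted donor-acceptor heavy-atom distance, Angstrom, in
#'   \[2.0, 4.0\].
#' @param angle planted angle at the hydrogen, degrees, in \[90, 180\].
#' @param flank_before,flank_after flanking residue codes on the host
#'   chain around the donor.
#' @param path optional PDB output path.
#' @param structure_id structure identifier.
#' @return the `protein_structure` (invisibly written to `path` when
#'   given).
#' @export
simulate_toy_structure <- function(donor = "TYR", acceptor = "ASP",
                                   r = 2.65, angle = 165,
                                   flank_before = c("ALA", "ALA", "ALA"),
                                   flank_after = c("ALA", "ALA", "ALA"),
                                   path = NULL,
                                   structure_id = sprintf("toy_%s_%s", donor, acceptor)) {
  if (!donor %in% names(.DONOR_ATOM_ONE))
    stop("config error: unsupported donor residue ", donor)
  if (!acceptor %in% names(.ACCEPTOR_ATOM_ONE))
    stop("config error: unsupported acceptor residue ", acceptor)
  if (r < 2.0 || r > 4.0) stop("config error: r must lie in [2.0, 4.0] A")
  if (angle < 90 || angle > 180) stop("config error: angle must lie in [90, 180] degrees")

  seqn <- c(flank_before, donor, flank_after)
  at <- build_peptide_backbone(seqn, 180, 180, chain = "A")
  k <- length(flank_before) + 1L
  res_k <- at[at$resi == k, ]
  CA <- as.numeric(res_k[res_k$name == "CA", c("x", "y", "z")])
  Nk <- as.numeric(res_k[res_k$name == "N", c("x", "y", "z")])
  Ck <- as.numeric(res_k[res_k$name == "C", c("x", "y", "z")])
  nrm <- unit_vec(cross3(CA - Nk, Ck - CA))          # backbone plane normal
  along <- unit_vec(Ck - Nk)                          # in-plane chain direction

  ext <- c(SER = 2.4, THR = 2.4, TYR = 6.0, TRP = 3.3, HIS = 3.4,
           LYS = 4.7, ARG = 5.8, ASN = 3.3, GLN = 4.5)[[donor]]
  d_atom <- .DONOR_ATOM_ONE[[donor]]
  d_elem <- if (donor %in% c("SER", "THR", "TYR")) "O" else "N"
  hlen <- if (d_elem == "O") 0.96 else 1.01
  D <- CA + ext * nrm
  H <- D + hlen * nrm

  # Coordinates are quantized to the PDB's 3 decimals so the in-memory
  # structure is identical to its file representation.  Quantization
  # can move an exact-boundary geometry (R = 2.3/2.7/2.8/3.2 or angle =
  # 135) a hair across the inclusive boundary, so the acceptor is
  # nudged deterministically - within the 0.01 A / 0.5 degree placement
  # contract - until the realized geometry classifies as requested.
  q3 <- function(x) round(x, 3)
  D <- q3(D); H <- q3(H)
  want <- classify_geometry(r, angle)
  A <- NULL
  for (dth in c(0, 0.1, -0.1, 0.2, -0.2)) {
    for (dr in c(0, 0.002, -0.002, 0.004, -0.004, 0.006)) {
      th <- (angle + dth) * pi / 180
      rr <- r + dr
      d_ha <- hlen * cos(th) + sqrt(rr^2 - (hlen * sin(th))^2)
      v <- cos(th) * (-nrm) + sin(th) * along         # ray H -> acceptor
      A_try <- q3(H + d_ha * v)
      got_r <- vec_norm(D - A_try)
      got_ang <- vertex_angle(D, H, A_try)
      ok_class <- if (r > 3.2) got_r > 3.2 else
        classify_geometry(got_r, got_ang) == want && got_r <= 3.2
      if (ok_class && abs(got_r - r) <= 0.01 && abs(got_ang - angle) <= 0.5) {
        A <- A_try
        break
      }
    }
    if (!is.null(A)) break
  }
  if (is.null(A)) stop("internal geometry error: planted (R, angle) not realizable")

  add <- function(df, name, resn, chain, resi, xyz, elem) {
    rbind(df, data.frame(record = "ATOM", serial = NA_integer_, name = name,
                         alt = "", resn = resn, chain = chain, resi = resi,
                         ins = "", x = xyz[1], y = xyz[2], z = xyz[3],
                         occ = 1, b = 0, elem = elem, stringsAsFactors = FALSE))
  }
  at <- add(at, "CB", donor, "A", k, q3(CA + 1.53 * nrm), "C")
  at <- add(at, d_atom, donor, "A", k, D, d_elem)
  h_name <- c(SER = "HG", THR = "HG1", TYR = "HH", TRP = "HE1", HIS = "HE2",
              LYS = "HZ1", ARG = "HH11", ASN = "HD21", GLN = "HE21")[[donor]]
  at <- add(at, h_name, donor, "A", k, H, "H")

  # acceptor fragment extends away from the bond along H -> A
  w <- unit_vec(A - H)
  a_atom <- .ACCEPTOR_ATOM_ONE[[acceptor]]
  a_elem <- if (acceptor == "HIS") "N" else "O"
  parent_name <- c(ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD",
                   SER = "CB", THR = "CB", TYR = "CZ", HIS = "CG")[[acceptor]]
  at <- add(at, a_atom, acceptor, "B", 1L, A, a_elem)
  at <- add(at, parent_name, acceptor, "B", 1L, A + 1.3 * w, "C")
  at <- add(at, "CA", acceptor, "B", 1L, A + 3.9 * w, "C")
  at <- add(at, "N", acceptor, "B", 1L, A + 4.8 * w + 0.6 * perp_vec(w), "N")
  at <- add(at, "C", acceptor, "B", 1L, A + 5.3 * w - 0.8 * perp_vec(w), "C")
  at <- add(at, "O", acceptor, "B", 1L, A + 6.5 * w - 0.9 * perp_vec(w), "O")
  if (acceptor %in% c("SER", "THR", "TYR"))
    at <- add(at, c(SER = "HG", THR = "HG1", TYR = "HH")[[acceptor]],
              acceptor, "B", 1L, A + 0.96 * perp_vec(w), "H")

  at$x <- q3(at$x); at$y <- q3(at$y); at$z <- q3(at$z)
  at$serial <- seq_len(nrow(at))
  s <- new_protein_structure(at, structure_id = structure_id,
                             title = structure_id)
  if (!is.null(path)) write_structure(s, path)
  s
}

#' Write a fixed benchmark fixture set
#'
#' Writes ~24 toy Tyr-Asp structures spanning the (R, angle) grid
#' `{2.3, 2.5, 2.65, 2.7, 2.75, 2.8, 3.0, 3.2} x {130, 135, 160}`, two
#' synthetic feature tables (balanced and prevalence marginal, n = 5000
#' each), and a JSON manifest of expected labels and per-donor
#' generating frequencies.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the feature tables.
#' @return the manifest list, invisibly.
#' @export
make_benchmark_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(r = c(2.3, 2.5, 2.65, 2.7, 2.75, 2.8, 3.0, 3.2),
                      angle = c(130, 135, 160))
  grid$file <- sprintf("toy_R%.2f_A%d.pdb", grid$r, grid$angle)
  grid$expected_label <- classify_geometry(grid$r, grid$angle)
  for (i in seq_len(nrow(grid)))
    simulate_toy_structure("TYR", "ASP", grid$r[i], grid$angle[i],
                           path = file.path(dir, grid$file[i]))
  cfg_bal <- synth_config(n = 5000L, seed = seed, mode = "balanced")
  cfg_prev <- synth_config(n = 5000L, seed = seed + 1L, mode = "prevalence")
  write_dataset(generate_feature_table(cfg_bal),
                file.path(dir, "synth_balanced.tsv"))
  write_dataset(generate_feature_table(cfg_prev),
                file.path(dir, "synth_prevalence.tsv"))
  manifest <- list(
    seed = seed,
    toys = grid,
    tables = list(
      balanced = list(file = "synth_balanced.tsv", n = cfg_bal$n,
                      shb_fraction = 0.5,
                      base_prob = as.list(cfg_bal$base_prob)),
      prevalence = list(file = "synth_prevalence.tsv", n = cfg_prev$n,
                        shb_fraction = cfg_prev$prevalence,
                        base_prob = as.list(cfg_prev$base_prob))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
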
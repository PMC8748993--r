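test_that("geometry classification honours every inclusive window boundary", {
  cases <- rbind(
    data.frame(r = 2.3, a = 135, lab = "SHB"),
    data.frame(r = 2.7, a = 180, lab = "SHB"),
    data.frame(r = 2.65, a = 160, lab = "SHB"),
    data.frame(r = 2.75, a = 160, lab = "unlabeled"),  # deliberate gap
    data.frame(r = 2.8, a = 135, lab = "NHB"),
    data.frame(r = 3.2, a = 135, lab = "NHB"),
    data.frame(r = 3.21, a = 170, lab = "unlabeled"),
    data.frame(r = 2.29, a = 170, lab = "unlabeled"),
    data.frame(r = 2.6, a = 134.9, lab = "unlabeled"))
  expect_equal(classify_geometry(cases$r, cases$a), cases$lab)
  expect_error(classify_geometry(0, 150), "positive")
  expect_error(classify_geometry(-1, 150), "positive")
})

test_that("classification partitions the (R, angle) domain", {
  set.seed(11)
  r <- runif(500, 0.1, 5)
  a <- runif(500, 0, 180)
  lab <- classify_geometry(r, a)
  expect_true(all(lab %in% c("SHB", "NHB", "unlabeled")))
  manual <- ifelse(a >= 135 & r >= 2.3 & r <= 2.7, "SHB",
                   ifelse(a >= 135 & r >= 2.8 & r <= 3.2, "NHB", "unlabeled"))
  expect_equal(lab, manual)
})

test_that("donor enumeration follows the side-chain atom inventory", {
  tyr <- assign_secondary_structure(simulate_toy_structure("TYR", "ASP", 2.65, 165))
  d <- enumerate_donors(tyr)
  expect_equal(d$atom[d$resn == "TYR"], "OH")
  # Gly has no side-chain donor
  gly <- as_structure(build_peptide_backbone(rep("GLY", 3)))
  expect_equal(nrow(enumerate_donors(gly)), 0L)
  # Arg with all hydrogens present contributes NE, NH1 and NH2
  pa <- shbpred:::place_atom
  cd <- c(0, 0, 0); ne <- c(1.46, 0, 0)
  cz <- pa(c(0, 1, 0), cd, ne, 1.33, 124, 180)
  at <- mk_atoms(at_row("CD", "C", cd, "ARG"), at_row("NE", "N", ne, "ARG"),
                 at_row("CZ", "C", cz, "ARG"),
                 at_row("NH1", "N", pa(cd, ne, cz, 1.33, 120, 0), "ARG"),
                 at_row("NH2", "N", pa(cd, ne, cz, 1.33, 120, 180), "ARG"))
  arg <- place_polar_hydrogens(as_structure(at))
  d <- enumerate_donors(arg)
  expect_setequal(d$atom, c("NE", "NH1", "NH2"))
  expect_true(all(d$charge == 1L))
  # donors without hydrogens are skipped with a warning
  bare <- as_structure(ser_atoms())
  expect_warning(d <- enumerate_donors(bare), "without hydrogens")
  expect_equal(nrow(d), 0L)
})

test_that("acceptor enumeration covers backbone O and side-chain sets", {
  at <- rbind(build_peptide_backbone(c("ASP", "ALA")),
              mk_atoms(at_row("OD1", "O", c(8, 8, 0), "ASP", "A", 1L),
                       at_row("OD2", "O", c(9, 8, 0), "ASP", "A", 1L)))
  at$serial <- seq_len(nrow(at))
  acc <- enumerate_acceptors(as_structure(at))
  asp <- acc[acc$resn == "ASP", ]
  expect_setequal(asp$atom, c("O", "OD1", "OD2"))
  expect_equal(sort(asp$charge), c(-1L, -1L, 0L))
  expect_equal(asp$location[asp$atom == "O"], "backbone")
  ala <- acc[acc$resn == "ALA", ]
  expect_equal(ala$atom, "O")
  # His with H on NE2: ND1 accepts, NE2 does not
  his <- as_structure(his_atoms(h_on = "NE2"))
  acc <- enumerate_acceptors(his)
  expect_true("ND1" %in% acc$atom)
  expect_false("NE2" %in% acc$atom)
})

test_that("planted bonds are recovered at exact geometry and sorted deterministically", {
  for (spec in list(c(2.3, 135), c(2.5, 160), c(3.0, 150), c(3.2, 135))) {
    s <- simulate_toy_structure("SER", "GLU", spec[1], spec[2])
    rec <- detect_hydrogen_bonds(s)
    rec <- rec[rec$resn_d == "SER", ]
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$R, spec[1], tolerance = 0.01)
    expect_equal(rec$angle, spec[2], tolerance = 0.5)
  }
  # beyond the cutoff: no record
  s <- simulate_toy_structure("TYR", "ASP", 3.5, 160)
  expect_equal(nrow(detect_hydrogen_bonds(s)), 0L)
  # determinism: identical structure -> identical table
  s <- simulate_toy_structure("TYR", "ASP", 2.65, 165)
  expect_identical(detect_hydrogen_bonds(s), detect_hydrogen_bonds(s))
})

test_that("grid detection equals brute force on a dense random structure", {
  s <- random_box_structure()
  expect_lte(nrow(s$atoms), 500)
  g <- detect_hydrogen_bonds(s, method = "grid")
  b <- detect_hydrogen_bonds(s, method = "brute")
  expect_identical(g, b)
  expect_gt(nrow(g), 0)
})

test_that("structures without any hydrogens raise the no-donors error", {
  s <- as_structure(build_peptide_backbone(c("SER", "ALA")))
  expect_error(suppressWarnings(detect_hydrogen_bonds(s)), "no donors usable")
})

test_that("dataset summaries reproduce SHB fractions from counts", {
  mk <- function(ns, nn)
    data.frame(label = c(rep("SHB", ns), rep("NHB", nn)))
  expect_equal(summarize_hbonds(mk(6181, 26929))$shb_pct, 18.7)
  expect_equal(summarize_hbonds(mk(3980, 17942))$shb_pct, 18.2)
  expect_equal(summarize_hbonds(mk(0, 100))$shb_pct, 0.0)
  # zero labeled records: undefined, not 0
  expect_true(is.na(summarize_hbonds(data.frame(label = "unlabeled"))$shb_pct))
  # grouped by acceptor location when available
  df <- data.frame(label = c("SHB", "NHB", "NHB", "SHB"),
                   acceptor_location = c("backbone", "backbone",
                                         "side_chain", "side_chain"))
  out <- summarize_hbonds(df)
  expect_equal(out$shb_pct[out$group == "backbone"], 50.0)
})

test_that("pair statistics report probability, medians and the motif flag", {
  rec <- data.frame(
    resn_d = "SER", resn_a = "ASP",
    chain_d = "A", chain_a = "A",
    serial_d = c(0, 0, 5, 5), serial_a = c(2, 2, 9, 9),
    R = c(2.5, 2.6, 2.9, 3.0),
    label = c("SHB", "SHB", "NHB", "NHB"))
  out <- pair_statistics(rec)
  expect_equal(out$n, 4L)
  expect_equal(out$shb_pct, 50.0)
  expect_equal(out$median_r_shb, 2.55)
  expect_equal(out$median_r_nhb, 2.95)
  expect_equal(out$n_seq2, 2L)          # the two |dseq| = 2 records
  expect_equal(out$shb_pct_seq2, 100.0)
  expect_equal(nrow(pair_statistics(rec[0, ])), 0L)
})

test_that("hydrogen-bond TSV round trips with fixed precision", {
  s <- simulate_toy_structure("TYR", "ASP", 2.65, 165)
  rec <- detect_hydrogen_bonds(s)
  f <- tempfile(fileext = ".tsv")
  write_hbonds(rec, f)
  back <- read_hbonds(f)
  expect_equal(back$R, round(rec$R, 3))
  expect_equal(back$angle, round(rec$angle, 1))
  expect_equal(back$label, rec$label)
})

test_that("a bidentate pair contributes one record per atom pair", {
  # Arg guanidinium reaching an Asp carboxylate with both NH groups:
  # NH1...OD1 at 2.85 A (NHB) and NH2...OD2 at 2.79 A (in the gap)
  at <- mk_atoms(
    at_row("NH1", "N", c(0, 0, 0), "ARG", "A", 1L),
    at_row("HH11", "H", c(0, 1.01, 0), "ARG", "A", 1L),
    at_row("NH2", "N", c(3.0, 0, 0), "ARG", "A", 1L),
    at_row("HH21", "H", c(3.0, 1.01, 0), "ARG", "A", 1L),
    at_row("OD1", "O", c(0, 2.85, 0), "ASP", "A", 2L),
    at_row("OD2", "O", c(3.0, 2.79, 0), "ASP", "A", 2L))
  rec <- detect_hydrogen_bonds(as_structure(at))
  expect_equal(nrow(rec), 2L)
  expect_setequal(paste(rec$atom_d, rec$atom_a),
                  c("NH1 OD1", "NH2 OD2"))
  expect_setequal(rec$label, c("NHB", "unlabeled"))
})
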
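test_that("the generator is deterministic and hits its class marginal", {
  cfg <- donor_only_config(n = 1000, seed = 17)
  d1 <- generate_feature_table(cfg)
  d2 <- generate_feature_table(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(sum(d1$label == "SHB"), 500L)
  # prevalence mode reproduces the configured 18.7% marginal
  dp <- generate_feature_table(donor_only_config(n = 1000, seed = 18,
                                                 mode = "prevalence"))
  expect_equal(mean(dp$label == "SHB"), 0.187, tolerance = 0.001)
})

natural_marginal <- function(cfg)
  sum(cfg$donor_dist * cfg$base_prob[names(cfg$donor_dist)])

test_that("per-donor SHB frequencies match the generating table", {
  cfg <- donor_only_config(n = 8000, seed = 19, mode = "prevalence")
  # target the natural marginal so label rejection leaves conditionals alone
  cfg$prevalence <- natural_marginal(cfg)
  d <- generate_feature_table(cfg)
  for (dn in names(cfg$base_prob)) {
    rows <- d$donor_res == dn
    n <- sum(rows)
    p <- cfg$base_prob[[dn]]
    sigma <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(d$label[rows] == "SHB") - p), 3 * sigma + 0.01)
  }
})

test_that("generator marginals converge at large n", {
  cfg <- donor_only_config(n = 50000, seed = 23, mode = "prevalence")
  cfg$prevalence <- natural_marginal(cfg)
  d <- generate_feature_table(cfg)
  for (dn in names(cfg$base_prob))
    expect_lt(abs(mean(d$label[d$donor_res == dn] == "SHB") -
                    cfg$base_prob[[dn]]), 0.01)
})

test_that("the acceptor shift and motif override act as configured", {
  cfg <- synth_config(n = 20000, seed = 29, mode = "prevalence",
                      prevalence = 0.5, motif_frac = 0.1)
  d <- generate_feature_table(cfg)
  thr <- d$donor_res == "THR" & d$d_p2 != "ASP" & d$a_m2 != "THR"
  anionic <- d$acceptor_loc == "side_chain" & d$acceptor_res %in% c("ASP", "GLU")
  p_an <- mean(d$label[thr & anionic] == "SHB")
  p_ne <- mean(d$label[thr & !anionic] == "SHB")
  expect_gt(p_an, p_ne + 0.2)
  # motif rows: Ser/Thr donor, Asp two positions downstream, p = 0.825
  motif <- d$d_p2 == "ASP" & d$a_m2 %in% c("SER", "THR") & d$acceptor_res == "ASP"
  expect_gt(sum(motif), 300)
  expect_equal(mean(d$label[motif] == "SHB"), 0.825, tolerance = 0.03)
})

test_that("degenerate configurations are caught or produce no SHBs", {
  expect_error(synth_config(base_prob = c(TYR = 1.2)), "config error")
  expect_error(synth_config(donor_dist = c(TYR = 0.5, SER = 0.2)), "sum to 1")
  expect_error(synth_config(donor_dist = c(XXX = 1)), "base_prob entry")
  # all-tiny probabilities make a balanced marginal unreachable
  cfg <- donor_only_config(n = 1000, seed = 31)
  cfg$base_prob[] <- 0.001
  expect_error(generate_feature_table(cfg), "unreachable")
})

test_that("toy structures realize the requested geometry exactly", {
  for (r in c(2.3, 2.65, 3.2)) for (ang in c(135, 165)) {
    s <- simulate_toy_structure("TYR", "ASP", r, ang)
    rec <- detect_hydrogen_bonds(s)
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$R, r, tolerance = 0.01)
    expect_equal(rec$angle, ang, tolerance = 0.5)
    expect_equal(rec$label, classify_geometry(r, ang))
  }
  expect_error(simulate_toy_structure("GLY", "ASP", 2.6, 160), "unsupported")
  expect_error(simulate_toy_structure("TYR", "ASP", 5, 160), "config error")
})

test_that("toy structures pass cleanly through the whole pipeline", {
  s <- simulate_toy_structure("THR", "GLU", 2.5, 170)
  expect_no_warning({
    s <- place_polar_hydrogens(s)
    s <- assign_secondary_structure(s)
    rec <- detect_hydrogen_bonds(s)
    fv <- extract_features(rec, s)
  })
  expect_equal(nrow(fv), 1L)
  expect_equal(fv$label, "SHB")
})

test_that("the benchmark suite writes the grid and reproducible tables", {
  dir1 <- tempfile(); dir2 <- tempfile()
  m1 <- make_benchmark_suite(dir1, seed = 3)
  m2 <- make_benchmark_suite(dir2, seed = 3)
  expect_equal(nrow(m1$toys), 24L)
  expect_true(all(file.exists(file.path(dir1, m1$toys$file))))
  # boundary grid points labeled per the inclusive windows
  expect_equal(m1$toys$expected_label[m1$toys$r == 2.3 & m1$toys$angle == 135], "SHB")
  expect_equal(m1$toys$expected_label[m1$toys$r == 3.0 & m1$toys$angle == 130],
               "unlabeled")
  # regeneration is byte-identical
  for (f in c("synth_balanced.tsv", "synth_prevalence.tsv", "manifest.json"))
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  # detection on a grid structure agrees with the manifest expectation
  s <- read_structure(file.path(dir1, "toy_R2.80_A160.pdb"))
  rec <- detect_hydrogen_bonds(s)
  expect_equal(rec$label, "NHB")
})
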
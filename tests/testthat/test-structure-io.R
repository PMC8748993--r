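test_that("reading keeps the first model, best altloc, and drops waters", {
  f <- write_toy_pdb()
  s <- read_structure(f)

  # only MODEL 1 survives (model 2 has an atom at x=99)
  expect_false(any(s$atoms$x > 90))
  # 5 amino acids; the 3 HOH are gone entirely
  expect_equal(nrow(s$residues), 5L)
  expect_false(any(s$atoms$resn %in% c("HOH", "WAT")))
  # altloc: B (occupancy 0.6) kept over A (0.4)
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$x, 21.2)
  # HETATM ligand retained outside the chains
  expect_equal(s$het$resn, "LIG")
  # quality metadata parsed from REMARK 2/3
  expect_equal(s$quality$resolution, 1.05)
  expect_equal(s$quality$r_factor, 0.18)
  expect_equal(s$quality$r_free, 0.21)
  expect_equal(s$experiment, "xray")
  # residue serial index is 0-based within the chain
  expect_equal(s$residues$serial, 0:4)
})

test_that("unreadable or empty structures raise informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  f <- write_toy_pdb(c("TITLE     ONLY WATER",
                       pdb_line("HETATM", 1, "O", "", "HOH", "A", 1, 0, 0, 0),
                       "END"))
  expect_error(read_structure(f), "no standard")
  f2 <- write_toy_pdb(c("TITLE     NOTHING", "END"))
  expect_error(read_structure(f2), "parse error")
})

test_that("quality validation applies the resolution, R and gap filters", {
  q <- function(res, rf, rfree)
    list(resolution = res, r_factor = rf, r_free = rfree)
  expect_true(validate_quality(q(1.0, 0.18, 0.22))$pass)   # gap 4% <= 7%
  v <- validate_quality(q(1.2, 0.15, 0.18))
  expect_false(v$pass)
  expect_match(v$reasons, "resolution")
  v <- validate_quality(q(1.0, 0.18, 0.26))                # gap 8% > 7%
  expect_false(v$pass)
  expect_match(v$reasons, "gap")
  # boundary values pass (<= comparisons)
  expect_true(validate_quality(q(1.1, 0.20, 0.27))$pass)
  # permissive mode relaxes the R-factor ceiling to 0.28
  expect_false(validate_quality(q(1.0, 0.25, 0.26))$pass)
  expect_true(validate_quality(q(1.0, 0.25, 0.26), permissive = TRUE)$pass)
  # missing fields warn but do not fail
  v <- validate_quality(q(NA, NA, NA))
  expect_true(v$pass)
  expect_length(v$warnings, 3L)
  expect_error(validate_quality(q(1, 0.1, 0.1), max_resolution = -1), "positive")
})

test_that("relaxing any quality threshold never converts pass to fail", {
  set.seed(42)
  for (i in 1:50) {
    q <- list(resolution = runif(1, 0.8, 1.6), r_factor = runif(1, 0.1, 0.3),
              r_free = runif(1, 0.1, 0.35))
    base <- validate_quality(q)
    for (relax in list(c(0.3, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1))) {
      v <- validate_quality(q, max_resolution = 1.1 + relax[1],
                            max_r_factor = 0.20 + relax[2],
                            max_r_gap = 0.07 + relax[3])
      if (base$pass) expect_true(v$pass)
    }
  }
})

test_that("write -> read round trip preserves coordinates to 3 decimals", {
  s <- simulate_toy_structure("TYR", "ASP", 2.65, 165)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                      as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  expect_equal(s2$atoms$name, s$atoms$name)
})

test_that("split_by_name keeps one representative per unique name", {
  sp <- split_by_name(c("s1", "s2", "s3"), c("Protein A", "protein  a", "prot B"))
  expect_equal(sort(sp$train), c("s1", "s3"))
  expect_equal(sp$test, "s2")
  # all unique -> empty test pool
  sp <- split_by_name(c("x", "y"), c("a", "b"))
  expect_equal(length(sp$test), 0L)
  # empty input -> two empty pools
  sp <- split_by_name(character(), character())
  expect_equal(lengths(sp), c(train = 0L, test = 0L))
  # missing names excluded with a warning
  expect_warning(sp <- split_by_name(c("a", "b"), c("name", "")), "without")
  expect_equal(sp$train, "a")
})
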
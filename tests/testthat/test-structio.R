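# Structure/trajectory I/O, heteroatom stripping, mutation, sequence utilities.

minimal_pdb_text <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
  "END"
)

test_that("read_pdb parses a minimal structure and validates records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text, f)
  s <- read_pdb(f)
  expect_s3_class(s, "pdb_structure")
  expect_equal(nrow(s$atoms), 5L)
  expect_equal(unique(s$atoms$resnum), 1L)
  expect_equal(s$atoms$name, c("N", "CA", "C", "O", "CB"))

  bad <- minimal_pdb_text
  bad[3] <- "ATOM      3  C   ALA A   1       2.009   xx.420   0.000  1.00  0.00           C"
  writeLines(bad, f)
  expect_error(read_pdb(f), "malformed ATOM record at line 3")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("multi-model files become trajectories with consistent topology", {
  f <- withr::local_tempfile(fileext = ".pdb")
  body <- minimal_pdb_text[1:5]
  shift <- sub("       0\\.000   0\\.000", "       0.500   0.000", body)
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", shift, "ENDMDL",
               "MODEL        3", body, "ENDMDL", "END"), f)
  tr <- read_pdb(f, model_policy = "all", dt_ps = 2)
  expect_s3_class(tr, "pdb_trajectory")
  expect_equal(n_frames(tr), 3L)
  expect_equal(tr$dt_ps, 2)
  expect_equal(nrow(tr$topology$atoms), 5L)
  s <- read_pdb(f, model_policy = "first")
  expect_s3_class(s, "pdb_structure")
  expect_equal(nrow(s$atoms), 5L)

  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", body[1:4], "ENDMDL", "END"), f)
  expect_error(read_pdb(f, model_policy = "all"), "topology error")
})

test_that("write/read round trip preserves identity and 3-decimal coordinates", {
  s <- ang_model_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$resnum, s$atoms$resnum)
  expect_equal(s2$atoms$resname, s$atoms$resname)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(round(s$atoms[, c("x", "y", "z")], 3)),
               ignore_attr = TRUE, tolerance = 1e-9)

  tr <- generate_trajectory(synthetic_spec(s, n_frames = 3, noise_sigma = 0.2,
                                           seed = 11))
  write_pdb(tr, f)
  tr2 <- read_pdb(f, model_policy = "all")
  expect_equal(n_frames(tr2), 3L)
  expect_equal(tr2$xyz, round(tr$xyz, 3), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("strip_heteroatoms removes exactly the HETATM residues", {
  s <- ang_model_fixture()
  expect_equal(strip_heteroatoms(s)$atoms, s$atoms)  # nothing to strip

  hoh <- make_atoms(200L, "HOH", "O", "O", matrix(c(50, 50, 50), 1), het = TRUE)
  hoh2 <- make_atoms(201L, "HOH", "O", "O", matrix(c(60, 60, 60), 1), het = TRUE)
  cit <- make_atoms(202L, "CIT", c("C1", "O1"), c("C", "O"),
                    rbind(c(70, 0, 0), c(71, 0, 0)), het = TRUE)
  withhet <- angtraj:::new_structure(rbind(s$atoms, hoh, hoh2, cit))
  out <- strip_heteroatoms(withhet)
  expect_equal(nrow(out$atoms), nrow(s$atoms))
  expect_false(any(out$atoms$het))
  expect_false(any(out$atoms$resname %in% c("HOH", "CIT")))
})

test_that("mutate_residue swaps one side chain and leaves the backbone intact", {
  s <- ang_model_fixture()
  for (case in list(list(tok = "K17I", res = "ILE", pos = 17L),
                    list(tok = "L35P", res = "PRO", pos = 35L))) {
    m <- mutate_residue(s, case$tok)
    expect_equal(unique(m$atoms$resname[m$atoms$resnum == case$pos]), case$res)
    bbsel <- function(x) x$atoms$name %in% c("N", "CA", "C", "O")
    expect_equal(as.matrix(m$atoms[bbsel(m), c("x", "y", "z")]),
                 as.matrix(s$atoms[bbsel(s), c("x", "y", "z")]),
                 ignore_attr = TRUE)
    # all residues but the mutated one are bit-identical
    other <- function(x) x$atoms[x$atoms$resnum != case$pos,
                                 setdiff(names(x$atoms), "serial")]
    expect_equal(other(m), other(s), ignore_attr = TRUE)
  }
  expect_error(parse_mutation("K17K"), "degenerate")
  expect_error(mutate_residue(s, "A17I"), "wild-type mismatch")
  expect_error(mutate_residue(s, "K999I"), "no residue")
})

test_that("sequence_of reports one letter per polymer residue", {
  gly <- angtraj:::new_structure(make_atoms(
    1L, "GLY", c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0), c(1.2, 2.4, 0))))
  expect_equal(sequence_of(gly), "G")

  tri <- do.call(rbind, lapply(1:3, function(i)
    make_atoms(i, c("ALA", "HIS", "LYS")[i], "CA", "C",
               matrix(c(4 * i, 0, 0), 1))))
  expect_equal(sequence_of(angtraj:::new_structure(tri)), "AHK")

  seq <- sequence_of(ang_model_fixture())
  expect_equal(nchar(seq), 123L)
  expect_equal(substr(seq, 13, 13), "H")
  expect_equal(substr(seq, 114, 114), "H")
  expect_equal(substr(seq, 31, 33), "RRR")
})

test_that("molecular_weight matches residue-mass arithmetic and is additive", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:5) {
    a <- paste(sample(names(angtraj:::.residue_mass), 6, TRUE), collapse = "")
    b <- paste(sample(names(angtraj:::.residue_mass), 4, TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.02,
                 tolerance = 1e-9)
  }
  expect_error(molecular_weight("GXZ"), "unknown amino-acid")
})

test_that("mutation tokens round-trip through parse/format", {
  for (tok in c("K17I", "L35P", "Q12R")) {
    expect_equal(format(parse_mutation(tok)), tok)
  }
  expect_error(parse_mutation("17KI"), "cannot parse")
  expect_error(parse_mutation("K17B"), "unknown amino-acid")
})
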
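test_that("read_pdb parses a minimal one-residue record", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C4'   G A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), tf)
  s <- read_pdb(tf)
  rt <- residue_table(s)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$base, "G")
  expect_equal(unname(coords_matrix(s)[1, ]), c(1, 2, 3))
})

test_that("read_pdb agrees with an independent fixed-width parser on a two-chain file", {
  hx <- fixture_helix()
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(hx$structure, tf)
  s <- read_pdb(tf)
  # independent parser: raw substring extraction from the ATOM records
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  ora <- data.frame(
    atom = trimws(substr(lines, 13, 16)),
    base = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)))
  expect_equal(nrow(s$atoms), nrow(ora))
  expect_equal(s$atoms$atom, ora$atom)
  expect_equal(s$atoms$base, ora$base)
  expect_equal(s$atoms$chain, ora$chain)
  expect_equal(coords_matrix(s), as.matrix(ora[, c("x", "y", "z")]),
               ignore_attr = TRUE, tolerance = 1e-8)
  # per-chain residue indices restart at 0
  for (ch in unique(s$atoms$chain))
    expect_equal(min(s$atoms$res_index[s$atoms$chain == ch]), 0L)
})

test_that("read_pdb rejects files without RNA residues", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), tf)
  expect_error(read_pdb(tf), "no RNA residues")
  expect_error(read_pdb(file.path(tempdir(), "no-such-file.pdb")))
})

test_that("write_pdb/read_pdb round-trips coordinates to PDB precision", {
  hp <- fixture_hairpin()
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(hp$structure, tf)
  s2 <- read_pdb(tf)
  expect_lt(max(abs(coords_matrix(hp$structure) - coords_matrix(s2))), 1e-3)
  expect_identical(residue_table(hp$structure)$base, residue_table(s2)$base)
})

test_that("coarse-grained purines and pyrimidines emit their designated atoms", {
  hx <- make_helix("GU")
  cg <- coarse_grain(hx$structure)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cg, tf)
  lines <- grep("^ATOM", readLines(tf), value = TRUE)
  base <- trimws(substr(lines, 18, 20))
  name <- trimws(substr(lines, 13, 16))
  expect_setequal(name[base == "G"], c("P", "C4'", "N9", "C2", "C6"))
  expect_setequal(name[base == "U"], c("P", "C4'", "N1", "C2", "C4"))
  expect_setequal(name[base == "A"], c("P", "C4'", "N9", "C2", "C6"))
  expect_setequal(name[base == "C"], c("P", "C4'", "N1", "C2", "C4"))
})

test_that("dot-bracket parsing matches the analytic nested case", {
  p <- parse_dotbracket("GGGGAAAACCCC\n((((....))))")
  expect_equal(p$ss$pairs,
               cbind(0:3, 11:8)[order(0:3), , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(nrow(parse_dotbracket("ACGU\n....")$ss$pairs), 0L)
})

test_that("dot-bracket parsing matches a stack-per-layer oracle, pseudoknots included", {
  p <- parse_dotbracket("GGAAUUAAGGAAUU\n((..[[..))..]]")
  expect_equal(p$ss$pairs, oracle_dotbracket_pairs("((..[[..))..]]"),
               ignore_attr = TRUE)
  for (seed in 1:25) {
    db <- random_dotbracket(14, seed)
    seq <- paste(rep("A", 14), collapse = "")
    expect_equal(parse_dotbracket(paste(seq, db, sep = "\n"))$ss$pairs,
                 oracle_dotbracket_pairs(db), ignore_attr = TRUE,
                 info = db)
  }
})

test_that("dot-bracket parser validates its input", {
  expect_error(parse_dotbracket("ACGU\n(((("), "unbalanced")
  expect_error(parse_dotbracket("ACGU\n(.."), "length")
  expect_error(parse_dotbracket("ACGT\n...."), "sequence")
})

test_that("multi-strand Vienna input yields global indices and strand breaks", {
  p <- parse_dotbracket("GGC&GCC\n(((&)))")
  expect_equal(p$sequences, c("GGC", "GCC"))
  expect_equal(p$ss$strand_breaks, 3L)
  expect_equal(p$ss$pairs, cbind(0:2, 5:3), ignore_attr = TRUE)
  tf <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(p$sequences, p$ss, tf)
  p2 <- read_vienna(tf)
  expect_equal(p2$ss$pairs, p$ss$pairs)
})

test_that("coarse_grain keeps five atoms per residue and is idempotent", {
  hx <- fixture_helix()
  cg <- coarse_grain(hx$structure)
  expect_true(cg$coarse_grained)
  counts <- table(paste(cg$atoms$chain, cg$atoms$res_index))
  expect_true(all(counts == 5))
  a_res <- cg$atoms[cg$atoms$base == "A", ]
  expect_setequal(unique(a_res$atom), c("P", "C4'", "N9", "C2", "C6"))
  c_res <- cg$atoms[cg$atoms$base == "C", ]
  expect_setequal(unique(c_res$atom), c("P", "C4'", "N1", "C2", "C4"))
  expect_identical(coarse_grain(cg), cg)
})

test_that("coarse_grain drops broken residues with a warning and fails past 50%", {
  hx <- make_helix("GGCAUG")
  s <- hx$structure
  broken <- s
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "A" &
                                   broken$atoms$res_index == 1L &
                                   broken$atoms$atom == "C2"), ]
  expect_warning(cg <- coarse_grain(broken), "dropped")
  expect_equal(n_residues(cg), 11L)
  crippled <- s
  crippled$atoms <- crippled$atoms[crippled$atoms$atom != "C2", ]
  expect_error(coarse_grain(crippled), "more than half")
})

test_that("center_and_scale is an exact bijection with the stated normalisation", {
  hp <- fixture_hairpin()
  cs <- center_and_scale(hp$structure)
  expect_lt(sqrt(sum(colMeans(coords_matrix(cs))^2)), 1e-6)
  expect_equal(cs$scale_applied, 10)
  # a coordinate at 80 A from the centroid lands at 8
  shifted <- hp$structure
  ctr <- colMeans(coords_matrix(shifted))
  shifted$atoms$x[1] <- ctr[1] + 80
  cs2 <- center_and_scale(shifted)
  ctr2 <- colMeans(coords_matrix(shifted))
  expect_equal(cs2$atoms$x[1], unname((shifted$atoms$x[1] - ctr2[1]) / 10),
               tolerance = 1e-9)
  inv <- invert_center_and_scale(cs)
  expect_lt(max(abs(coords_matrix(inv) - coords_matrix(hp$structure))), 1e-9)
  # single atom is allowed
  one <- hp$structure
  one$atoms <- one$atoms[1, , drop = FALSE]
  expect_silent(center_and_scale(one))
})

test_that("coarse_grain + write_pdb + read_pdb is coordinate identity to PDB precision", {
  hp <- fixture_hairpin()
  cg <- coarse_grain(hp$structure)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(center_and_scale(cg), tf)   # writer must un-scale first
  s2 <- read_pdb(tf)
  expect_lt(max(abs(coords_matrix(cg) - coords_matrix(s2))), 1e-3)
})
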
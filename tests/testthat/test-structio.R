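# Structure reading/writing, selections, CA extraction, centers of mass.

test_that("a handwritten 3-atom PDB parses with bit-equal coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, mini_atoms())
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(natoms(m), 3L)
  expect_identical(m$atoms$x, c(1.234, 2.345, 3.456))
  expect_identical(m$atoms$y, c(0.111, 1.222, 2.333))
  expect_identical(m$atoms$elety, c("N", "CA", "C"))
  expect_identical(m$atoms$chain, rep("B", 3))
  expect_identical(m$atoms$resno, rep(5L, 3))
})

test_that("the same content parses identically from PDB and mmCIF", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  write_mini_pdb(fp, mini_atoms())
  write_mini_cif(fc, mini_atoms())
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  cols <- c("chain", "resno", "elety", "x", "y", "z")
  expect_equal(mp$atoms[, cols], mc$atoms[, cols], ignore_attr = TRUE)
})

test_that("alternate locations keep the highest-occupancy conformer", {
  atoms <- mini_atoms()
  # duplicate the CA with altloc A (0.6) and B (0.4) at different x
  dup <- atoms[c(1, 2, 2, 3), ]
  dup$altloc <- c(" ", "A", "B", " ")
  dup$occ <- c(1, 0.6, 0.4, 1)
  dup$x[3] <- 9.999
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, dup)
  m <- read_structure(f)
  expect_equal(natoms(m), 3L)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 2.345)  # conformer A

  # occupancy tie breaks to the lexicographically smallest altloc
  dup$occ <- c(1, 0.5, 0.5, 1)
  write_mini_pdb(f, dup)
  m2 <- read_structure(f)
  expect_equal(m2$atoms$x[m2$atoms$elety == "CA"], 2.345)
})

test_that("unparseable and empty files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", f)
  expect_error(read_structure(f))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("select_calpha returns one CA per selected residue, in order", {
  model <- quick_model(chain = "B", resno = rep(3:27, each = 2),
                       elety = rep(c("N", "CA"), 25),
                       x = seq_len(50), y = 0, z = 0)
  ca <- select_calpha(model, residue_selection("B", 3, 27))
  expect_equal(nrow(ca), 25L)
  expect_equal(ca$resno, 3:27)
  expect_equal(nrow(attr(ca, "skipped")), 0L)
})

test_that("selections spanning gaps skip and report the missing residues", {
  keep <- setdiff(3:27, 10:12)
  model <- quick_model(chain = "B", resno = keep, elety = "CA",
                       x = seq_along(keep), y = 0, z = 0)
  ca <- select_calpha(model, residue_selection("B", 3, 27))
  expect_equal(nrow(ca), 22L)
  expect_equal(attr(ca, "skipped")$resno, 10:12)
  expect_error(select_calpha(model, residue_selection("Z", 1, 5)),
               "matches no CA")
})

test_that("centers of mass are mass-weighted over heavy atoms by default", {
  m <- quick_model(chain = "A", resno = c(1, 1), elety = c("C1", "O1"),
                   element = c("C", "O"), x = c(0, 1), y = 0, z = 0)
  com_w <- residue_centers_of_mass(m, residue_selection("A", 1, 1))
  expect_equal(com_w$x, 15.999 / (12.011 + 15.999), tolerance = 1e-12)
  com_u <- residue_centers_of_mass(m, residue_selection("A", 1, 1),
                                   mass_weighted = FALSE)
  expect_equal(com_u$x, 0.5)

  # two identical-mass atoms: symmetric midpoint
  m2 <- quick_model(chain = "A", resno = c(1, 1), elety = c("C1", "C2"),
                    element = "C", x = c(0, 2), y = 0, z = 0)
  expect_equal(residue_centers_of_mass(m2, residue_selection("A", 1, 1))$x, 1)

  # hydrogens excluded unless requested
  m3 <- quick_model(chain = "A", resno = c(1, 1), elety = c("C1", "H1"),
                    element = c("C", "H"), x = c(0, 1), y = 0, z = 0)
  expect_equal(residue_centers_of_mass(m3, residue_selection("A", 1, 1))$x, 0)
  with_h <- residue_centers_of_mass(m3, residue_selection("A", 1, 1),
                                    include_hydrogens = TRUE)
  expect_equal(with_h$x, 1.008 / (12.011 + 1.008), tolerance = 1e-12)
})

test_that("write/read round-trips atom identity and coordinates", {
  m <- quick_model(chain = "A", resno = 1:3, elety = "CA", element = "C",
                   x = c(1.2345, -2.71828, 100.5), y = c(0.1, 0.2, 0.3),
                   z = c(-9.87654, 3.14159, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(m2$atoms$elety, m$atoms$elety)
  expect_true(all(abs(m2$atoms$x - m$atoms$x) < 1e-3))
  expect_true(all(abs(m2$atoms$y - m$atoms$y) < 1e-3))
  expect_true(all(abs(m2$atoms$z - m$atoms$z) < 1e-3))
  # idempotence: a second round trip reproduces the first exactly
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  m3 <- read_structure(f2)
  expect_identical(m3$atoms[, c("x", "y", "z")], m2$atoms[, c("x", "y", "z")])
})

test_that("long chain ids are remapped on write with the mapping emitted", {
  m <- quick_model(chain = c("AB", "AB", "C"), resno = c(1, 2, 1),
                   elety = "CA", element = "C", x = 1:3, y = 0, z = 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  map <- write_structure(m, f)
  expect_true(all(nchar(map$written) == 1))
  expect_true("C" %in% map$written)
  expect_true(file.exists(paste0(f, ".chains.tsv")))
  m2 <- read_structure(f)
  expect_equal(sort(unique(m2$atoms$chain)), sort(map$written))
})

test_that("constructor enforces the atom-table invariants", {
  df <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                   element = "C", x = 1, y = 2, z = 3)
  expect_error(structure_model(df[0, ]), "empty")
  bad <- rbind(df, df)  # duplicate key
  expect_error(structure_model(bad), "duplicate")
  df$x <- NaN
  expect_error(structure_model(df), "finite")
})

test_that("selection validation rejects inverted and overlapping ranges", {
  expect_error(residue_selection("A", 10, 5), "start > end")
  expect_error(residue_selection(c("A", "A"), c(1, 5), c(6, 9)),
               "overlapping")
  sel <- residue_selection(c("A", "B"), c(1, NA), c(10, NA))
  expect_true(selection_contains(sel, "A", 10))
  expect_false(selection_contains(sel, "A", 11))
  expect_true(selection_contains(sel, "B", 99999))
})

test_that("selection files round-trip through read_selection", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("C 3 27", "D 343 368"), f)
  sel <- read_selection(f)
  expect_equal(sel$parts$chain, c("C", "D"))
  expect_equal(sel$parts$start, c(3L, 343L))
})

test_that("COM of a residue union equals the mass-weighted combination", {
  set.seed(11)
  n <- 5
  at <- do.call(rbind, lapply(1:n, function(r) {
    k <- sample(2:5, 1)
    data.frame(chain = "A", resno = r, resid = "ALA",
               elety = paste0("C", seq_len(k)),
               element = sample(c("C", "N", "O", "S"), k, replace = TRUE),
               x = rnorm(k), y = rnorm(k), z = rnorm(k))
  }))
  m <- structure_model(at)
  per <- residue_centers_of_mass(m, residue_selection("A", 1, n))
  mass <- vapply(1:n, function(r) sum(m$atoms$mass[m$atoms$resno == r]),
                 numeric(1))
  pooled <- colSums(as.matrix(per[, c("x", "y", "z")]) * mass) / sum(mass)
  direct <- colSums(as.matrix(at[, c("x", "y", "z")]) *
                      m$atoms$mass) / sum(m$atoms$mass)
  expect_equal(unname(pooled), unname(direct), tolerance = 1e-12)

  # order determinism
  per2 <- residue_centers_of_mass(m, residue_selection("A", 1, n))
  expect_identical(per, per2)
})
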
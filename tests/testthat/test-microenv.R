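test_that("vector TSV round trip preserves the matrix bit-exactly", {
  set.seed(42)
  ms <- ms_from_matrix(matrix(rnorm(18), 3, 6))
  path <- tempfile(fileext = ".tsv")
  write_vectors(ms, path)
  back <- read_vectors(path)
  expect_identical(unname(back$features), unname(ms$features))
  expect_equal(back$sites, ms$sites)
  expect_identical(back$space_tag, "raw")
})

test_that("malformed vector files are rejected with informative errors", {
  ms <- ms_from_matrix(matrix(1:12, 3, 4))
  path <- tempfile(fileext = ".tsv")
  write_vectors(ms, path)

  lines <- readLines(path)
  fields <- strsplit(lines[2], "\t")[[1]]
  fields[length(fields)] <- "not_a_number"
  lines[2] <- paste(fields, collapse = "\t")
  writeLines(lines, path)
  expect_error(suppressWarnings(read_vectors(path)), "non-numeric")

  dup <- rbind(ms$sites, ms$sites[1, ])
  expect_error(microenv_set(dup, rbind(ms$features, ms$features[1, ])),
               "duplicate site")
})

test_that("standardize divides by population sd and guards constants", {
  x <- cbind(a = c(10, 20, 30), b = c(5, 5, 5), c = c(1, 2, 4))
  std <- standardize(ms_from_matrix(x))
  # population sd of (10,20,30) is sqrt(200/3)
  expect_equal(std$features[, "a"], c(10, 20, 30) / sqrt(200 / 3),
               tolerance = 1e-12)
  expect_equal(unname(std$features[, "a"]), c(1.224745, 2.449490, 3.674235),
               tolerance = 1e-6)
  expect_identical(std$features[, "b"], x[, "b"])
  expect_identical(std$space_tag, "standardized")
  # every non-constant output column has unit population sd
  sds <- apply(std$features, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(unname(sds[c("a", "c")]), c(1, 1), tolerance = 1e-9)
})

test_that("standardize is idempotent and rejects degenerate input", {
  set.seed(7)
  ms <- ms_from_matrix(matrix(rnorm(40), 8, 5))
  once <- standardize(ms)
  again <- once
  again$space_tag <- "raw"
  expect_equal(standardize(again)$features, once$features, tolerance = 1e-9)
  expect_error(standardize(ms_from_matrix(matrix(1:4, 1))), "single site")
  expect_error(standardize(once), "raw-space")
})

test_that("cysteine extraction honors the disulfide distance rule", {
  lines <- c(
    pdb_atom_line(1, "CA", "CYS", "A", 10, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", "A", 10, 0, 0, 1),
    pdb_atom_line(3, "CA", "CYS", "A", 20, 10, 0, 0),
    pdb_atom_line(4, "SG", "CYS", "A", 20, 10, 0, 1),
    # disulfide pair: SG-SG 2.05 A apart
    pdb_atom_line(5, "SG", "CYS", "A", 30, 20, 0, 0),
    pdb_atom_line(6, "SG", "CYS", "A", 40, 22.05, 0, 0),
    pdb_atom_line(7, "CA", "GLY", "A", 50, 30, 0, 0))
  path <- write_pdb_fixture(lines)

  free <- extract_cys_sites(path, exclude_disulfides = TRUE)
  all4 <- extract_cys_sites(path, exclude_disulfides = FALSE)
  expect_equal(sort(free$residue_number), c(10, 20))
  expect_equal(sort(all4$residue_number), c(10, 20, 30, 40))
  # exclusion always yields a subset
  expect_true(all(free$residue_number %in% all4$residue_number))

  no_cys <- write_pdb_fixture(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0))
  expect_equal(nrow(extract_cys_sites(no_cys)), 0)
})

test_that("surrogate properties bin atoms into half-open shells", {
  # center CYS SG at origin; GLY CA at 3 A -> bin floor(3/1.25) = shell 3
  # (1-based); GLY CA at exactly 1.25 A sits on a boundary -> outer shell 2
  lines <- c(
    pdb_atom_line(1, "SG", "CYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0),
    pdb_atom_line(3, "CA", "ALA", "A", 3, 0, 1.25, 0))
  path <- write_pdb_fixture(lines)
  v <- simple_properties(path, list(chain = "A", residue_number = 1),
                         n_shells = 6, radius = 7.5)
  expect_equal(length(v), 26 * 6)
  expect_equal(unname(v["res_GLY@shell3"]), 1)
  expect_equal(sum(v[grep("res_GLY", names(v))]), 1)
  expect_equal(unname(v["res_ALA@shell2"]), 1)
  # CYS SG itself: shell 1 residue count and S atom
  expect_equal(unname(v["res_CYS@shell1"]), 1)
  expect_equal(unname(v["elem_S@shell1"]), 1)
  # empty shells are all-zero blocks
  expect_true(all(v[grep("@shell5$", names(v))] == 0))
  # only charge sums may be negative
  expect_true(all(v[-grep("charge", names(v))] >= 0))
  expect_error(simple_properties(path, list(chain = "B", residue_number = 99)),
               "not found")
})

test_that("HETATM codes are parsed and water excluded", {
  lines <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "ZN", "ZN", "A", 90, 1, 1, 1, record = "HETATM"),
             pdb_atom_line(3, "O", "HOH", "A", 91, 2, 2, 2, record = "HETATM"))
  path <- write_pdb_fixture(lines)
  het <- read_hetatm_codes(path)
  expect_equal(het$het_code, "ZN")
})
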
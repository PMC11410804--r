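test_that("mmCIF fixture with two chains reads back correctly", {
  m <- merge_models(list(build_peptide(10, chain = "A"),
                         build_peptide(10, chain = "B")))
  path <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_equal(chain_ids(m2), c("A", "B"))
  expect_length(chain_resnos(m2, "A"), 10)
  expect_length(chain_resnos(m2, "B"), 10)
})

test_that("write/read round trips preserve numbering and coordinates", {
  m <- make_monomer(2, 24, seed = 5)
  for (ext in c(".cif", ".pdb")) {
    path <- withr::local_tempfile(fileext = ext)
    write_structure(m, path)
    m2 <- read_structure(path)
    expect_equal(chain_ids(m2), chain_ids(m))
    expect_equal(chain_resnos(m2, "A"), chain_resnos(m, "A"))
    expect_lt(max(abs(atom_coords(m2) - atom_coords(m))), 1e-3)
  }
  ## cross-format: pdb -> mmcif -> pdb
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, p1)
  write_structure(read_structure(p1), p2)
  m3 <- read_structure(p2)
  expect_lt(max(abs(atom_coords(m3) - atom_coords(m))), 1e-3)
})

test_that("malformed and missing coordinate files raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_broken", "#", "loop_", "_atom_site.id"), bad)
  expect_error(read_structure(bad))
  expect_error(read_structure("does-not-exist.cif"), "not found")
})

test_that("score sidecars: combined score arithmetic and dialects", {
  expect_equal(combined_score(1, 1), 1.0)
  expect_equal(combined_score(1, 0), 0.8)
  expect_equal(combined_score(0.5, 0.9), 0.58)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    model_1 = list(iptm = 0.5, ptm = 0.9, relaxed = TRUE),
    model_2 = list(iptm = 1.0, ptm = 0.0, relaxed = FALSE)),
    path, auto_unbox = TRUE)
  sc <- read_scores(path)
  expect_equal(score_entry(sc, "model_1")$combined, 0.58)
  expect_equal(score_entry(sc, "model_2")$combined, 0.8)
  expect_false(score_entry(sc, "model_2")$relaxed)
  expect_error(score_entry(sc, "model_9"), "not present")
  ## precombined ranking dialect passes through
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list("iptm+ptm" = list(m1 = 0.76, m2 = 0.31)), path2,
                       auto_unbox = TRUE)
  sc2 <- read_scores(path2)
  expect_equal(sort(sc2$combined), c(0.31, 0.76))
  ## validation: out-of-range scores rejected
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(m1 = list(iptm = 1.4, ptm = 0.2)), path3,
                       auto_unbox = TRUE)
  expect_error(read_scores(path3), "outside")
})

test_that("combined score is linear in its components", {
  for (alpha in c(0, 0.25, 0.7, 1)) {
    expect_equal(combined_score(alpha * 0.6, alpha * 0.8),
                 alpha * combined_score(0.6, 0.8))
  }
})

test_that("secondary structure: helix H, paired strands E, lone chain C", {
  h <- assign_sse(build_peptide(12, -57, -47))
  lab_h <- h$sse$A
  expect_true(all(lab_h[3:10] == "H"))
  e <- assign_sse(build_strand_pair(8))
  expect_true(all(e$sse$A[3:6] == "E"))
  expect_true(all(e$sse$B[3:6] == "E"))
  c1 <- assign_sse(build_peptide(10, -139, 135))
  expect_true(all(c1$sse$A == "C"))
})

test_that("contact_count matches the brute-force oracle and edge cases", {
  ## two residues at a known distance
  a <- data.frame(chain = c("A", "B"), resno = 1L, resid = "ALA",
                  elety = "CA", element = "C",
                  x = c(0, 3), y = 0, z = 0)
  m <- structure_model(a)
  sa <- residue_selection(m, chain = "A"); sb <- residue_selection(m, chain = "B")
  expect_equal(contact_count(m, sa, sb, cutoff = 5), 1)
  expect_equal(contact_count(m, sa, sb, cutoff = 2), 0)
  expect_warning(n0 <- contact_count(m, sa[0, ], sb, 5), "empty")
  expect_equal(n0, 0)
  ## 3x3 residue grid vs oracle
  grid <- expand.grid(x = c(0, 4, 8), y = c(0, 4, 8))
  g <- data.frame(chain = "A", resno = seq_len(9), resid = "ALA",
                  elety = "CA", element = "C", x = grid$x, y = grid$y, z = 0)
  gm <- structure_model(g)
  sel <- residue_selection(gm)
  expect_equal(contact_count(gm, sel, sel, cutoff = 4.5),
               oracle_contact_count(gm, sel, sel, 4.5))
  expect_equal(contact_count(gm, sel, sel, cutoff = 6),
               oracle_contact_count(gm, sel, sel, 6))
  ## symmetry in selections
  s1 <- residue_selection(gm, resno = 1:4); s2 <- residue_selection(gm, resno = 5:9)
  expect_equal(contact_count(gm, s1, s2, 6), contact_count(gm, s2, s1, 6))
})

test_that("surface area: closed-form sphere, additivity, occlusion", {
  one <- structure_model(data.frame(chain = "A", resno = 1L, resid = "ALA",
                                    elety = "CA", element = "C",
                                    x = 0, y = 0, z = 0))
  area <- surface_area(one, n_points = 960)
  expect_equal(area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
  ## two far-apart atoms: areas add
  two <- structure_model(data.frame(chain = "A", resno = c(1L, 2L),
                                    resid = "ALA", elety = "CA",
                                    element = "C", x = c(0, 50), y = 0, z = 0))
  expect_equal(surface_area(two, n_points = 960), 2 * area, tolerance = 0.02)
  ## buried atom enclosed by a shell of neighbors
  sh <- symlattice:::sphere_points(30) * 2.5
  shell <- data.frame(chain = "A", resno = 2:31, resid = "ALA", elety = "CA",
                      element = "C", x = sh[, 1], y = sh[, 2], z = sh[, 3])
  buried <- structure_model(rbind(
    data.frame(chain = "A", resno = 1L, resid = "ALA", elety = "CA",
               element = "C", x = 0, y = 0, z = 0), shell))
  a_buried <- surface_area(buried, sel = residue_selection(buried, resno = 1))
  expect_lt(a_buried, 1)
  ## unknown element warns and uses the default radius
  odd <- structure_model(data.frame(chain = "A", resno = 1L, resid = "UNK",
                                    elety = "X1", element = "XX",
                                    x = 0, y = 0, z = 0))
  expect_warning(a_odd <- surface_area(odd, n_points = 960), "unknown")
  expect_equal(a_odd, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
})

test_that("structure model validates its invariants", {
  expect_error(structure_model(data.frame()), "missing columns")
  base <- data.frame(chain = "A", resno = 1L, resid = "ALA", elety = "CA",
                     element = "C", x = 0, y = 0, z = 0)
  expect_error(structure_model(base[0, ]), "zero atoms")
  bad <- base; bad$x <- NaN
  expect_error(structure_model(bad), "non-finite")
  ## residue with only hydrogens is rejected
  hyd <- rbind(base, data.frame(chain = "A", resno = 2L, resid = "ALA",
                                elety = "H", element = "H",
                                x = 1, y = 0, z = 0))
  expect_error(structure_model(hyd), "heavy atom")
})
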
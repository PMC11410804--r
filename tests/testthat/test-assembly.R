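cfg <- default_config()

p4_fixture <- function() cached("p4_flat", {
  fx <- make_lattice_pair("p4", a = 100, noise_sigma = 0, seed = 7)
  list(fx = fx,
       cxa = detect_symmetry(fx$complex_a, "layer", cfg),
       cxb = detect_symmetry(fx$complex_b, "layer", cfg))
})

test_that("axis alignment to z is exact and chirality-preserving", {
  cx <- detect_symmetry(tiny_oligomer(3, 3), "layer", cfg)
  al <- align_axis_to_z(cx)
  expect_lt(max(abs(al$placement$rotation - diag(3))), 1e-9)  # already z
  ## tilt the complex, re-detect, re-align
  tilted <- cx
  R <- rotation_about(c(0, 1, 0), 90)
  tilted$oligomer$model <- transform_model(cx$oligomer$model,
                                           rigid_transform(R, c(5, 0, 0)))
  cx2 <- detect_symmetry(tilted$oligomer, "layer", cfg)
  expect_false(is_rejected(cx2))
  al2 <- align_axis_to_z(cx2)
  re <- classify_axis(scored_oligomer(al2$model_placed, 0.9), config = cfg)
  expect_equal(abs(re$direction[3]), 1, tolerance = 1e-6)
  expect_gt(det(al2$placement$rotation), 0)
})

test_that("B copies land on the planted p4 tile with tiny overlap RMSD", {
  p4 <- p4_fixture()
  tile <- place_B_copies(align_axis_to_z(p4$cxa), p4$cxb, cfg)
  expect_length(tile$B_copies, 4)
  expect_lt(max(vapply(tile$B_copies, `[[`, numeric(1), "overlap_rmsd")), 0.1)
  expect_lt(max(vapply(tile$B_copies, `[[`, numeric(1), "tilt")), 1e-4)
  ## disjoint numbering: cannot connect
  shifted <- p4$cxb
  shifted$oligomer$model$atoms$resno <- shifted$oligomer$model$atoms$resno + 500
  expect_error(place_B_copies(align_axis_to_z(p4$cxa), shifted, cfg),
               class = "cannot_connect")
  ## internally deformed partner: the shared region no longer fits
  warped <- p4$cxb
  wa <- warped$oligomer$model$atoms
  ctr <- colMeans(as.matrix(wa[, c("x", "y", "z")]))
  wa$x <- ctr[1] + 1.3 * (wa$x - ctr[1])
  wa$y <- ctr[2] + 1.3 * (wa$y - ctr[2])
  warped$oligomer$model$atoms <- wa
  expect_error(place_B_copies(align_axis_to_z(p4$cxa), warped, cfg),
               class = "gap_too_large")
})

test_that("propagation fills the nearest-neighbor lattice patch", {
  p4 <- p4_fixture()
  tile <- propagate_A(place_B_copies(align_axis_to_z(p4$cxa), p4$cxb, cfg))
  expect_gte(length(tile$peripheral_A), 4)
  centers <- do.call(rbind, lapply(tile$peripheral_A, `[[`, "center"))
  shell <- sort(sqrt(rowSums(centers[, 1:2]^2)))[1:4]
  expect_equal(shell, rep(100, 4), tolerance = 1e-3)
  ## rigid copies: re-detected order of a peripheral A equals the central
  pm <- tile$peripheral_A[[1]]$model
  re <- classify_axis(scored_oligomer(pm, 0.9), config = cfg)
  expect_equal(re$order_k, tile$central$axis$order_k)
})

test_that("bending score endpoints and linearity", {
  expect_equal(bending_score(rep(0, 4)), 0)
  expect_equal(bending_score(rep(90, 4)), 1)
  expect_equal(bending_score(rep(45, 4)), 0.5)
  expect_equal(bending_score(c(30, 30)), (2 / pi) * (30 * pi / 180))
  expect_equal(bending_score(numeric(0)), 0)
})

test_that("clash and quality scores combine per the scoring model", {
  expect_equal(quality_score(0, 0), 0)
  expect_equal(quality_score(0.05, 0.5), 0.55)
  p4 <- p4_fixture()
  lat <- assemble_lattice(p4$cxa, p4$cxb, cfg)
  expect_s3_class(lat, "lattice_model")
  expect_equal(lat$scores$score_clash, 0, tolerance = 1e-9)
  ## clash score equals the clash-count oracle on the merged tile
  tm <- symlattice:::tile_model(lat$tile)
  n_res <- nrow(unique(tm$atoms[, c("chain", "resno")]))
  expect_equal(lat$scores$score_clash,
               count_clashes(tm, cfg, full_length = n_res)$n_clashes / n_res)
  expect_equal(lat$scores$score_quality,
               lat$scores$score_clash + lat$scores$score_bend)
})

test_that("termination: tilt strictly above 45 degrees, rigid unit check", {
  p4 <- p4_fixture()
  tile <- propagate_A(place_B_copies(align_axis_to_z(p4$cxa), p4$cxb, cfg))
  expect_length(check_termination(tile, config = cfg), 0)
  ## synthetic tilt injection: exactly 45 passes, 50 fails
  tile45 <- tile
  for (i in seq_along(tile45$B_copies)) tile45$B_copies[[i]]$tilt <- 45
  expect_length(check_termination(tile45, config = cfg), 0)
  tile50 <- tile
  for (i in seq_along(tile50$B_copies)) tile50$B_copies[[i]]$tilt <- 50
  expect_equal(check_termination(tile50, config = cfg), "tilt")
  ## internally deformed monomers: not rigid
  bent <- tile
  m <- bent$central$model_placed
  idx <- m$atoms$chain == chain_ids(m)[1]
  m$atoms$z[idx] <- m$atoms$z[idx] + 0.15 * seq_len(sum(idx))
  bent$central$model_placed <- m
  expect_true("not_rigid" %in% check_termination(bent, config = cfg))
})

test_that("unit cells are recovered and snapped to group constraints", {
  p4 <- p4_fixture()
  lat4 <- assemble_lattice(p4$cxa, p4$cxb, cfg)
  expect_equal(lat4$cell$group, "p4")
  expect_equal(lat4$cell$a, 100, tolerance = 1e-3)
  expect_equal(lat4$cell$b, lat4$cell$a)
  expect_equal(lat4$cell$gamma, 90)
  fx6 <- make_lattice_pair("p6", a = 170, noise_sigma = 0, seed = 9)
  lat6 <- assemble_lattice(detect_symmetry(fx6$complex_a, "layer", cfg),
                           detect_symmetry(fx6$complex_b, "layer", cfg), cfg)
  expect_equal(lat6$cell$group, "p6")
  expect_equal(lat6$cell$a, 170, tolerance = 1e-3)
  expect_equal(lat6$cell$gamma, 120)
  ## noisy p4: cell within 1 percent over repeated seeds
  for (seed in 1:5) {
    fx <- make_lattice_pair("p4", a = 100, noise_sigma = 0.3, seed = seed)
    lat <- assemble_lattice(detect_symmetry(fx$complex_a, "layer", cfg),
                            detect_symmetry(fx$complex_b, "layer", cfg), cfg)
    expect_s3_class(lat, "lattice_model")
    expect_lt(abs(lat$cell$a - 100) / 100, 0.01)
  }
})

test_that("emitted lattice mmCIF round-trips as a fixed point", {
  p4 <- p4_fixture()
  lat <- assemble_lattice(p4$cxa, p4$cxb, cfg)
  path <- withr::local_tempfile(fileext = ".cif")
  emit_lattice(lat, path)
  back <- read_lattice(path)
  expect_equal(back$cell$a, lat$cell$a, tolerance = 1e-3)
  expect_equal(back$cell$gamma, lat$cell$gamma, tolerance = 1e-3)
  expect_equal(back$cell$group, "p4")
  expect_length(back$symops, 4)
  ## applying the operators reproduces the central complex
  cellful <- expand_lattice(back)
  target <- p4$cxa
  placed <- align_axis_to_z(target)$model_placed
  X <- atom_coords(cellful); Y <- atom_coords(placed)
  ## match mates by nearest centroid, then compare atom by atom
  expect_equal(nrow(X), nrow(Y))
  for (ch in chain_ids(cellful)) {
    cc <- symlattice:::chain_centroid(cellful, ch)
    dists <- vapply(chain_ids(placed), function(c2)
      sqrt(sum((symlattice:::chain_centroid(placed, c2) - cc)^2)), numeric(1))
    mate <- chain_ids(placed)[which.min(dists)]
    expect_lt(max(abs(atom_coords(cellful, chain = ch) -
                        atom_coords(placed, chain = mate))), 2e-3)
  }
  ## re-emitting the re-read model leaves the cell unchanged
  path2 <- withr::local_tempfile(fileext = ".cif")
  emit_lattice(back, path2)
  back2 <- read_lattice(path2)
  expect_equal(back2$cell$a, back$cell$a, tolerance = 1e-6)
})

test_that("wallpaper operator strings parse and count correctly", {
  expect_length(wallpaper_symops("p1"), 1)
  expect_length(wallpaper_symops("p4"), 4)
  expect_length(wallpaper_symops("p6"), 6)
  op <- symlattice:::parse_symop("-y,x-y,z")
  expect_equal(op$M, matrix(c(0, -1, 0, 1, -1, 0, 0, 0, 1), 3, 3,
                            byrow = TRUE))
  ## p4 operators applied twice give the half-turn
  p4ops <- lapply(wallpaper_symops("p4"), symlattice:::parse_symop)
  expect_equal(p4ops[[2]]$M %*% p4ops[[2]]$M, p4ops[[3]]$M)
})

test_that("p1 assembly recovers the planted oblique cell", {
  fx <- make_lattice_pair("p1", a = 73, b = 89, gamma = 105, seed = 3)
  lat <- assemble_p1(fx$full_model, fx$heterodimers, cfg)
  expect_equal(lat$cell$group, "p1")
  expect_lt(abs(lat$cell$a - 73) / 73, 0.01)
  expect_lt(abs(lat$cell$b - 89) / 89, 0.01)
  expect_lt(abs(lat$cell$gamma - 105), 1)
  expect_length(lat$symops, 1)
  ## one strong interaction only: insufficient
  expect_error(assemble_p1(fx$full_model, fx$heterodimers[1], cfg),
               class = "p1_insufficient")
  ## weak scores do not count as interactions
  weak <- lapply(fx$heterodimers, function(h) { h$score$combined <- 0.1; h })
  expect_error(assemble_p1(fx$full_model, weak, cfg),
               class = "p1_insufficient")
  ## collinear translations: degenerate cell
  coll <- list(fx$heterodimers[[1]], fx$heterodimers[[1]])
  expect_error(assemble_p1(fx$full_model, coll, cfg),
               class = "degenerate_cell")
})

test_that("p2 requires and uses a second 2-fold axis", {
  fx <- make_lattice_pair("p2", a = 90, gamma = 100, noise_sigma = 0,
                          seed = 13)
  cxa <- detect_symmetry(fx$complex_a, "layer", cfg)
  cxb <- detect_symmetry(fx$complex_b, "layer", cfg)
  cxb2 <- detect_symmetry(fx$complex_b2, "layer", cfg)
  ## a single pair of half-turns spans only a strip
  res1 <- assemble_lattice(cxa, cxb, cfg)
  expect_s3_class(res1, "assembly_termination")
  expect_true("collinear_needs_second_axis" %in% res1$reasons)
  res2 <- assemble_lattice(cxa, cxb, cfg, complex_b2 = cxb2)
  expect_s3_class(res2, "lattice_model")
  expect_equal(res2$cell$group, "p2")
  expect_equal(res2$cell$a, 90, tolerance = 0.1)
  expect_equal(res2$cell$gamma, 100, tolerance = 0.2)
})

test_that("capsid tile keeps the icosahedral inter-axis angle", {
  ccfg <- default_config("capsid")
  cp <- make_capsid_patch(seed = 5)
  pent <- detect_symmetry(cp$pentamer, "capsid", ccfg)
  tri <- detect_symmetry(cp$trimer, "capsid", ccfg)
  expect_equal(pent$axis$order_k, 5)
  expect_equal(tri$axis$order_k, 3)
  tile <- assemble_capsid_tile(pent, tri, ccfg)
  ## icosahedral vertex-to-face angle, from the polyhedron itself
  expect_equal(unname(tile$inter_axis_angles),
               rep(cp$truth$inter_axis_angle, 5), tolerance = 0.5)
  expect_equal(cp$truth$inter_axis_angle, 37.377, tolerance = 0.01)
  ## flat layer input through the capsid path: tilt stays ~0
  p4 <- p4_fixture()
  flat <- assemble_capsid_tile(p4$cxa, p4$cxb, ccfg)
  expect_lt(max(flat$inter_axis_angles), 1e-4)
})
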
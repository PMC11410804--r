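## Lattice assembly: z-alignment of the higher-order axis, overlapping
## superposition of the partner complex, propagation of peripheral copies,
## quality scoring, termination checks, unit-cell extraction and
## idealization, and mmCIF emission with symmetry operators.

#' Align a symmetry complex's axis to +z
#'
#' Rotates the complex so its rotational axis points along (0,0,1) and
#' translates the axis anchor to the origin. The applied transform is
#' recorded in the result.
#'
#' @param complex a `symmetry_complex`.
#' @return the complex with transformed model and axis; the rigid transform
#'   in `$placement`.
#' @export
align_axis_to_z <- function(complex) {
  ax <- complex$axis
  R <- rotation_between(ax$direction, c(0, 0, 1))
  tr <- rigid_transform(R, -as.numeric(R %*% ax$anchor))
  complex$model_placed <- transform_model(complex$oligomer$model, tr)
  complex$axis$direction <- c(0, 0, 1)
  complex$axis$anchor <- c(0, 0, 0)
  complex$placement <- tr
  complex
}

## shared full-length residue numbers between a chain of A and a chain of B
shared_resnos <- function(model_a, chain_a, off_a, model_b, chain_b, off_b) {
  ra <- chain_resnos(model_a, chain_a) + off_a
  rb <- chain_resnos(model_b, chain_b) + off_b
  intersect(ra, rb)
}

## superpose the best-matching chain of `src_model` onto `dst_chain` of
## `dst_model` using CA atoms at shared full-length residue numbers
superpose_chain <- function(dst_model, dst_chain, off_dst, src_model, off_src,
                            min_shared = 10) {
  best <- NULL
  for (sc in chain_ids(src_model)) {
    shared <- shared_resnos(dst_model, dst_chain, off_dst, src_model, sc,
                            off_src)
    if (length(shared) < min_shared) next
    dst <- ca_coords(dst_model, dst_chain)
    src <- ca_coords(src_model, sc)
    di <- as.character(shared - off_dst); si <- as.character(shared - off_src)
    di <- di[di %in% rownames(dst) & si %in% rownames(src)]
    si <- as.character(as.integer(di) + off_dst - off_src)
    if (length(di) < min_shared) next
    k <- kabsch(dst[di, , drop = FALSE], src[si, , drop = FALSE])
    if (is.null(best) || k$rmsd < best$rmsd)
      best <- list(transform = k$transform, rmsd = k$rmsd, chain = sc,
                   n_shared = length(di))
  }
  best
}

#' Place copies of complex B on every monomer of the central complex A
#'
#' For each monomer of the z-aligned central complex, a copy of B is
#' superposed on the shared-domain residues (least squares on matched CA).
#' In layer mode each placed B axis is then re-rotated to be parallel to z
#' about a pivot at the centroid of the linker residues between the shared
#' and non-shared regions; the pre-realignment tilt is recorded and feeds
#' the bending score. In capsid mode axes keep their tilt.
#'
#' @param central a z-aligned `symmetry_complex` (see [align_axis_to_z()]).
#' @param complex_b the partner `symmetry_complex`.
#' @param config a [default_config()] list.
#' @param realign re-parallelize B axes to z (TRUE in layer mode).
#' @return an `assembly_tile` with `B_copies` placed.
#' @export
place_B_copies <- function(central, complex_b, config = default_config(),
                           realign = TRUE) {
  if (is.null(central$model_placed)) central <- align_axis_to_z(central)
  mA <- central$model_placed
  offA <- central$oligomer$residue_offset
  mB0 <- complex_b$oligomer$model
  offB <- complex_b$oligomer$residue_offset
  copies <- list()
  for (achain in central$axis$chain_order) {
    sp <- superpose_chain(mA, achain, offA, mB0, offB)
    if (is.null(sp))
      stop(errorCondition("no shared domain between complexes A and B",
                          class = "cannot_connect"))
    if (sp$rmsd > config$gap_max)
      stop(errorCondition(
        sprintf("gap too large: overlap RMSD %.2f A exceeds %.2f A",
                sp$rmsd, config$gap_max),
        class = "gap_too_large"))
    mB <- transform_model(mB0, sp$transform)
    axis_dir <- as.numeric(sp$transform$rotation %*% complex_b$axis$direction)
    axis_anchor <- apply_transform(sp$transform,
                                   matrix(complex_b$axis$anchor, 1))[1, ]
    tilt <- acos(min(1, abs(axis_dir[3]))) * 180 / pi
    if (realign && tilt > 1e-9) {
      pivot <- linker_pivot(mA, achain, offA, mB, offB, sp$chain)
      Rz <- rotation_between(orient_axis(axis_dir), c(0, 0, 1))
      trz <- rigid_transform(Rz, pivot - as.numeric(Rz %*% pivot))
      mB <- transform_model(mB, trz)
      axis_dir <- c(0, 0, 1)
      axis_anchor <- apply_transform(trz, matrix(axis_anchor, 1))[1, ]
    }
    ## anchor as the point on the axis at z = 0
    u <- orient_axis(axis_dir)
    if (abs(u[3]) > 1e-6)
      axis_anchor <- axis_anchor - (axis_anchor[3] / u[3]) * u
    copies[[length(copies) + 1]] <-
      list(model = mB, anchor_chain = sp$chain, on_chain = achain,
           overlap_rmsd = sp$rmsd, axis_dir = u, axis_anchor = axis_anchor,
           tilt = tilt)
  }
  structure(list(central = central, B_copies = copies, complex_b = complex_b,
                 peripheral_A = list(), config = config, realign = realign),
            class = "assembly_tile")
}

## pivot for axis re-parallelization: centroid of the linker residues of the
## overlapped A monomer (shared-region residues bordering the non-shared
## region); falls back to the shared-region centroid when the monomers
## coincide completely
linker_pivot <- function(mA, achain, offA, mB, offB, bchain, width = 5) {
  ra <- chain_resnos(mA, achain) + offA
  rb <- chain_resnos(mB, bchain) + offB
  shared <- intersect(ra, rb)
  only_b <- setdiff(rb, ra)
  if (length(only_b)) {
    edge <- if (min(only_b) > max(shared)) max(shared) else min(shared)
    lnk <- shared[abs(shared - edge) < width]
  } else lnk <- shared
  colMeans(atom_coords(mB, chain = bchain, resno = lnk - offB, elety = "CA"))
}

#' Propagate peripheral copies of complex A across the placed B copies
#'
#' Every non-anchor monomer of each placed B copy receives a superposed copy
#' of complex A, aligned likewise; duplicate placements (same axis position)
#' are collapsed. The result is the lattice patch of one central complex
#' plus its nearest neighbors.
#'
#' @param tile an `assembly_tile` from [place_B_copies()].
#' @return the tile with `peripheral_A` filled (each entry records the
#'   transformed model, the A-axis position, and the overlap RMSD).
#' @export
propagate_A <- function(tile) {
  config <- tile$config
  central <- tile$central
  mA0 <- central$model_placed
  offA <- central$oligomer$residue_offset
  offB <- tile$complex_b$oligomer$residue_offset
  periph <- list()
  for (bc in tile$B_copies) {
    for (bchain in chain_ids(bc$model)) {
      if (bchain == bc$anchor_chain) next
      sp <- superpose_chain(bc$model, bchain, offB, mA0, offA)
      if (is.null(sp))
        stop(errorCondition("no shared domain during propagation",
                            class = "cannot_connect"))
      if (sp$rmsd > config$gap_max)
        stop(errorCondition(
          sprintf("gap too large during propagation: %.2f A", sp$rmsd),
          class = "gap_too_large"))
      ctr <- apply_transform(sp$transform, matrix(c(0, 0, 0), 1))[1, ]
      ## positions compared in the lattice plane: noisy axis realignment can
      ## leave small z offsets between routes to the same lattice point
      if (sqrt(sum(ctr[1:2]^2)) < 6) next              # central itself
      dup <- any(vapply(periph, function(p)
        sqrt(sum((p$center[1:2] - ctr[1:2])^2)) < 6, logical(1)))
      if (dup) next
      dirA <- as.numeric(sp$transform$rotation %*% c(0, 0, 1))
      mA <- transform_model(mA0, sp$transform)
      if (tile$realign) {
        tiltA <- acos(min(1, abs(dirA[3]))) * 180 / pi
        if (tiltA > 1e-9) {
          Rz <- rotation_between(orient_axis(dirA), c(0, 0, 1))
          trz <- rigid_transform(Rz, ctr - as.numeric(Rz %*% ctr))
          mA <- transform_model(mA, trz)
          dirA <- c(0, 0, 1)
        }
      }
      periph[[length(periph) + 1]] <-
        list(model = mA, center = ctr, overlap_rmsd = sp$rmsd,
             axis_dir = orient_axis(dirA))
    }
  }
  tile$peripheral_A <- periph
  tile
}

#' @export
print.assembly_tile <- function(x, ...) {
  cat(sprintf("assembly_tile: central %d-fold A, %d B cop%s, %d peripheral A\n",
              x$central$axis$order_k, length(x$B_copies),
              if (length(x$B_copies) == 1) "y" else "ies",
              length(x$peripheral_A)))
  if (length(x$B_copies)) {
    cat(sprintf("  overlap RMSD %.3f-%.3f A, B-axis tilt %.2f-%.2f deg\n",
                min(vapply(x$B_copies, `[[`, numeric(1), "overlap_rmsd")),
                max(vapply(x$B_copies, `[[`, numeric(1), "overlap_rmsd")),
                min(vapply(x$B_copies, `[[`, numeric(1), "tilt")),
                max(vapply(x$B_copies, `[[`, numeric(1), "tilt"))))
  }
  invisible(x)
}

## merged tile model with coincident chains dropped (same chain placed twice
## through different routes), for whole-tile clash scoring
tile_model <- function(tile) {
  seen <- list(); parts <- list()
  addm <- function(m) {
    for (ch in chain_ids(m)) {
      ctr <- chain_centroid(m, ch)
      if (any(vapply(seen, function(s) sqrt(sum((s[1:2] - ctr[1:2])^2)) < 6,
                     logical(1)))) next
      seen[[length(seen) + 1]] <<- ctr
      parts[[length(parts) + 1]] <<- subset_chains(m, ch)
    }
  }
  addm(tile$central$model_placed)
  for (bc in tile$B_copies) addm(bc$model)
  for (p in tile$peripheral_A) addm(p$model)
  merge_models(parts)
}

#' Bending score of an assembly tile
#'
#' The normalized RMSD of the tilt angles between the central A axis and the
#' neighbor B axes: `(2/pi) * sqrt(mean(phi_i^2))` with `phi_i` in radians
#' (reference angle 0 after z-alignment). 0 for a flat assembly, 1 when all
#' B axes are perpendicular to A.
#'
#' @param tile an `assembly_tile`, or a numeric vector of tilt angles in
#'   degrees.
#' @return the bending score.
#' @export
bending_score <- function(tile) {
  tilts <- if (is.numeric(tile)) tile
           else vapply(tile$B_copies, `[[`, numeric(1), "tilt")
  if (!length(tilts)) return(0)
  phi <- tilts * pi / 180
  (2 / pi) * sqrt(mean(phi^2))
}

#' Clash score of an assembly tile
#'
#' Average intermolecular clashes per residue over the merged tile:
#' `N_clashes / N_res`.
#'
#' @param tile an `assembly_tile`.
#' @param config a [default_config()] list.
#' @return list with `score` (clashes per residue), `n_clashes`, `n_res`.
#' @export
clash_score <- function(tile, config = tile$config) {
  m <- tile_model(tile)
  n_res <- nrow(unique(m$atoms[, c("chain", "resno")]))
  rep1 <- count_clashes(m, config, full_length = n_res)
  list(score = rep1$n_clashes / n_res, n_clashes = rep1$n_clashes,
       n_res = n_res)
}

#' Combined quality score
#'
#' The sum of the clash score (clashes per residue) and the bending score;
#' lower is better, and candidate pairs are ranked by it.
#'
#' @param score_clash,score_bend the two components.
#' @return `score_clash + score_bend`.
#' @export
quality_score <- function(score_clash, score_bend) score_clash + score_bend

#' Termination checks for an assembled tile
#'
#' The pipeline stops when any of these is true: a B-axis tilt above 45
#' degrees; a recorded overlap gap above `gap_max`; relative deviation of
#' the modeled lattice constant from the idealized cell above
#' `dev_cell_max`; or a non-rigid folding unit (median pairwise
#' intra-monomer RMSD above `rigid_max`).
#'
#' @param tile an `assembly_tile` (after [propagate_A()]).
#' @param cell optional `unit_cell` draft from [extract_cell()] (supplies
#'   the lattice-deviation check).
#' @param config a [default_config()] list.
#' @return character vector of reasons (empty when the tile is acceptable),
#'   from `{tilt, gap, lattice_deviation, not_rigid}`.
#' @export
check_termination <- function(tile, cell = NULL, config = tile$config) {
  reasons <- character()
  tilts <- vapply(tile$B_copies, `[[`, numeric(1), "tilt")
  if (length(tilts) && max(tilts) > config$tilt_max)
    reasons <- c(reasons, "tilt")
  gaps <- c(vapply(tile$B_copies, `[[`, numeric(1), "overlap_rmsd"),
            vapply(tile$peripheral_A, `[[`, numeric(1), "overlap_rmsd"))
  if (length(gaps) && max(gaps) > config$gap_max)
    reasons <- c(reasons, "gap")
  if (!is.null(cell) && !is.null(attr(cell, "rel_dev")) &&
      attr(cell, "rel_dev") > config$dev_cell_max)
    reasons <- c(reasons, "lattice_deviation")
  ## rigid folding unit: pairwise intra-monomer RMSD across central chains
  mA <- tile$central$model_placed
  ch <- chain_ids(mA)
  rms <- c()
  for (i in seq_len(length(ch) - 1)) for (j in (i + 1):length(ch)) {
    ci <- ca_coords(mA, ch[i]); cj <- ca_coords(mA, ch[j])
    shared <- intersect(rownames(ci), rownames(cj))
    if (length(shared) >= 3)
      rms <- c(rms, kabsch(ci[shared, , drop = FALSE],
                           cj[shared, , drop = FALSE])$rmsd)
  }
  if (length(rms) && stats::median(rms) > config$rigid_max)
    reasons <- c(reasons, "not_rigid")
  reasons
}

## cluster in-plane vectors into collinear families
vector_families <- function(V, angle_tol = 10) {
  ang <- atan2(V[, 2], V[, 1]) * 180 / pi
  ang <- ang %% 180
  fam <- rep(NA_integer_, nrow(V)); k <- 0
  for (i in order(rowSums(V^2))) {
    if (!is.na(fam[i])) next
    k <- k + 1
    d <- abs(ang - ang[i]); d <- pmin(d, 180 - d)
    fam[is.na(fam) & d < angle_tol] <- k
  }
  fam
}

#' Extract and idealize the unit cell from an assembled tile
#'
#' Lattice vectors are the symmetry-averaged xy translations from the
#' central complex A to its peripheral copies. The wallpaper group follows
#' the maximum detected axis order (6 -> p6, 4 -> p4, 3 -> p3, 2 -> p2) and
#' the cell is snapped to the group constraints (p4: a = b, gamma = 90;
#' p3/p6: a = b, gamma = 120). The asymmetric unit (reference monomer) is
#' re-placed in the exact cell.
#'
#' @param tile an `assembly_tile` after [propagate_A()] (for p2, after
#'   augmentation with a second B cluster).
#' @param config a [default_config()] list.
#' @return a `lattice_model`: list with `cell` (a, b, gamma, group),
#'   `asym_unit`, `basis` (2 x 2 ideal cell vectors, columns), `symops`,
#'   `scores` and `tile`.
#' @export
extract_cell <- function(tile, config = tile$config) {
  if (length(tile$peripheral_A) < 2)
    stop("fewer than 2 peripheral copies; cannot determine lattice vectors")
  V <- do.call(rbind, lapply(tile$peripheral_A, function(p) p$center[1:2]))
  kA <- tile$central$axis$order_k
  kB <- tile$complex_b$axis$order_k
  group <- switch(as.character(max(kA, kB)),
                  "6" = "p6", "4" = "p4", "3" = "p3", "2" = "p2")
  fam <- vector_families(V)
  lens <- sqrt(rowSums(V^2))
  fmean <- tapply(lens, fam, mean)
  ford <- as.integer(names(sort(fmean)))
  if (length(ford) < 2)
    stop(errorCondition("lattice vectors are collinear: one translation only",
                        class = "degenerate_cell"))
  f1 <- ford[1]
  ## representative of family 1: align member signs before averaging
  ref <- V[which(fam == f1)[1], ]
  mem1 <- V[fam == f1, , drop = FALSE]
  sgn <- sign(mem1 %*% ref); sgn[sgn == 0] <- 1
  v1 <- colMeans(mem1 * as.numeric(sgn))
  ## second basis family: prefer the shortest non-collinear family whose
  ## angle to v1 can satisfy the group's gamma
  target_gamma <- switch(group, p4 = 90, p3 = 120, p6 = 120, p2 = NA)
  best <- NULL
  for (f2 in ford[-1]) {
    mem2 <- V[fam == f2, , drop = FALSE]
    ref2 <- mem2[1, ]
    sgn2 <- sign(mem2 %*% ref2); sgn2[sgn2 == 0] <- 1
    v2 <- colMeans(mem2 * as.numeric(sgn2))
    for (cand in list(v2, -v2)) {
      gamma <- angle_deg_2d(v1, cand)
      ## free (oblique) cells use the obtuse-angle convention: gamma >= 90
      score <- if (is.na(target_gamma)) {
        if (gamma >= 90) -gamma else -1000 - gamma
      } else -abs(gamma - target_gamma)
      if (is.null(best) || score > best$score)
        best <- list(v2 = cand, gamma = gamma, score = score, fam = f2)
    }
    if (!is.na(target_gamma) && abs(best$gamma - target_gamma) < 15) break
  }
  v2 <- best$v2; gamma <- best$gamma
  a_len <- sqrt(sum(v1^2)); b_len <- sqrt(sum(v2^2))
  ## relative deviation of individual vectors from the family means
  both <- c(abs(lens[fam == f1] - a_len) / a_len,
            abs(lens[fam == best$fam] - b_len) / b_len)
  rel_dev <- max(both)
  if (group %in% c("p3", "p4", "p6")) {
    ab <- mean(c(a_len, b_len))
    a_len <- b_len <- ab
    gamma <- if (group == "p4") 90 else 120
  }
  cell <- structure(list(a = a_len, b = b_len, gamma = gamma, group = group),
                    class = "unit_cell")
  attr(cell, "rel_dev") <- rel_dev
  ## ideal basis: v1 direction kept, v2 at exactly gamma from v1
  u1 <- v1 / sqrt(sum(v1^2))
  th <- atan2(u1[2], u1[1]) + gamma * pi / 180
  basis <- cbind(a_len * u1, b_len * c(cos(th), sin(th)))
  ## asymmetric unit: reference monomer of the central complex
  refch <- tile$central$axis$chain_order[1]
  asym <- subset_chains(tile$central$model_placed, refch, rename = "A")
  sc <- clash_score(tile, config)
  sb <- bending_score(tile)
  scores <- list(score_clash = sc$score, score_bend = sb,
                 score_quality = quality_score(sc$score, sb),
                 n_clashes = sc$n_clashes, n_res = sc$n_res)
  structure(list(cell = cell, asym_unit = asym, basis = basis,
                 symops = wallpaper_symops(group), scores = scores,
                 tile = tile),
            class = "lattice_model")
}

angle_deg_2d <- function(u, v) {
  cosg <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosg))) * 180 / pi
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit_cell (%s): a = %.2f A, b = %.2f A, gamma = %.1f deg\n",
              x$group, x$a, x$b, x$gamma))
  invisible(x)
}

#' @export
print.lattice_model <- function(x, ...) {
  print(x$cell)
  cat(sprintf("  %d symmetry operator(s); quality score %.4f (clash %.4f + bend %.4f)\n",
              length(x$symops), x$scores$score_quality, x$scores$score_clash,
              x$scores$score_bend))
  invisible(x)
}

#' Symmetry operators of the wallpaper point groups about the origin
#'
#' Operator strings act on fractional coordinates and leave z unchanged.
#' @param group one of p1, p2, p3, p4, p6.
#' @return character vector of `x,y,z`-style operators.
#' @export
wallpaper_symops <- function(group) {
  switch(group,
         p1 = "x,y,z",
         p2 = c("x,y,z", "-x,-y,z"),
         p3 = c("x,y,z", "-y,x-y,z", "-x+y,-x,z"),
         p4 = c("x,y,z", "-y,x,z", "-x,-y,z", "y,-x,z"),
         p6 = c("x,y,z", "x-y,x,z", "-y,x-y,z", "-x,-y,z", "-x+y,-x,z",
                "y,-x+y,z"),
         stop("unknown wallpaper group: ", group))
}

## parse one "x-y,x,z" style operator into a 3x3 matrix + shift
parse_symop <- function(op) {
  comps <- strsplit(gsub(" ", "", op), ",")[[1]]
  stopifnot(length(comps) == 3)
  M <- matrix(0, 3, 3); shift <- numeric(3)
  for (i in 1:3) {
    s <- comps[i]
    ## split into signed terms
    terms <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body == "x") M[i, 1] <- M[i, 1] + sign
      else if (body == "y") M[i, 2] <- M[i, 2] + sign
      else if (body == "z") M[i, 3] <- M[i, 3] + sign
      else if (grepl("^[0-9]+/[0-9]+$", body)) {
        fr <- as.numeric(strsplit(body, "/")[[1]])
        shift[i] <- shift[i] + sign * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", body)) {
        shift[i] <- shift[i] + sign * as.numeric(body)
      } else stop("cannot parse symmetry operator term: ", tm)
    }
  }
  list(M = M, shift = shift)
}

lattice_cell_matrix <- function(lat, c_len = 500) {
  cbind(rbind(lat$basis, c(0, 0)), c(0, 0, c_len))
}

#' Expand a lattice model by its symmetry operators
#'
#' Applies every operator (in fractional coordinates of the embedded 3D
#' cell) to the asymmetric unit and merges the mates into one model — the
#' primitive unit cell contents.
#'
#' @param lat a `lattice_model` (from [extract_cell()] or [read_lattice()]).
#' @return a [structure_model] with one chain per symmetry mate.
#' @export
expand_lattice <- function(lat) {
  Mcell <- lattice_cell_matrix(lat)
  Minv <- solve(Mcell)
  xyz <- atom_coords(lat$asym_unit)
  frac <- xyz %*% t(Minv)
  mates <- lapply(lat$symops, function(op) {
    p <- parse_symop(op)
    f2 <- sweep(frac %*% t(p$M), 2, p$shift, "+")
    out <- lat$asym_unit
    cart <- f2 %*% t(Mcell)
    out$atoms$x <- cart[, 1]; out$atoms$y <- cart[, 2]; out$atoms$z <- cart[, 3]
    out
  })
  merge_models(mates)
}

#' Write a lattice model to mmCIF
#'
#' Emits the primitive unit cell: cell parameters (2D cell embedded in a 3D
#' cell with c = 500 A, alpha = beta = 90), the wallpaper-group symmetry
#' operators as explicit xyz strings, and the asymmetric unit's atoms.
#'
#' @param lat a `lattice_model`.
#' @param path output mmCIF path.
#' @export
emit_lattice <- function(lat, path) {
  cellspec <- list(a = lat$cell$a, b = lat$cell$b, c = 500,
                   gamma = lat$cell$gamma, group = lat$cell$group)
  lines <- format_mmcif(lat$asym_unit, data_name = "lattice",
                        cell = cellspec, symops = lat$symops)
  ## record the in-plane basis orientation so the cell is fully reproducible
  th <- atan2(lat$basis[2, 1], lat$basis[1, 1]) * 180 / pi
  lines <- c(lines, sprintf("_symlattice.basis_theta %.6f", th), "#")
  writeLines(lines, path)
  invisible(path)
}

#' Read a lattice mmCIF written by [emit_lattice()]
#'
#' @param path mmCIF path.
#' @return a `lattice_model` (without scores/tile).
#' @export
read_lattice <- function(path) {
  ln <- readLines(path)
  getnum <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), ln, value = TRUE)[1]
    as.numeric(strsplit(trimws(hit), "\\s+")[[1]][2])
  }
  a <- getnum("_cell.length_a"); b <- getnum("_cell.length_b")
  gamma <- getnum("_cell.angle_gamma")
  grp <- sub(".*'(.*)'.*", "\\1",
             grep("_symmetry.space_group_name", ln, value = TRUE)[1])
  opl <- grep("^[0-9]+ '", ln, value = TRUE)
  symops <- sub("^[0-9]+ '(.*)'$", "\\1", opl)
  th <- getnum("_symlattice.basis_theta") * pi / 180
  if (is.na(th)) th <- 0
  u1 <- c(cos(th), sin(th))
  th2 <- th + gamma * pi / 180
  basis <- cbind(a * u1, b * c(cos(th2), sin(th2)))
  asym <- read_structure(path, format = "mmcif")
  cell <- structure(list(a = a, b = b, gamma = gamma, group = grp),
                    class = "unit_cell")
  structure(list(cell = cell, asym_unit = asym, basis = basis,
                 symops = symops, scores = NULL, tile = NULL),
            class = "lattice_model")
}

#' Assemble a lattice from a pair of symmetry complexes
#'
#' The full layer-mode assembly: the complex with the higher axis order
#' becomes the central complex A and is aligned to z; B copies are placed by
#' overlapping superposition and re-parallelized; peripheral A copies are
#' propagated; termination conditions are checked; and the unit cell is
#' extracted and idealized. When both axes are 2-fold, a single pair yields
#' only collinear translations (two half-turns generate a frieze, not a
#' plane group), so a second B complex on a distinct 2-fold axis must be
#' supplied via `complex_b2` to span the oblique p2 cell.
#'
#' @param complex_a,complex_b the two symmetry complexes (order decides
#'   which is central).
#' @param config a [default_config()] list.
#' @param complex_b2 optional second B complex for the p2 route.
#' @return a `lattice_model`, or a `termination` object (class
#'   `assembly_termination`) carrying the reason codes.
#' @export
assemble_lattice <- function(complex_a, complex_b, config = default_config(),
                             complex_b2 = NULL) {
  ## central = higher order
  if (complex_b$axis$order_k > complex_a$axis$order_k) {
    tmp <- complex_a; complex_a <- complex_b; complex_b <- tmp
  }
  central <- align_axis_to_z(complex_a)
  tile <- place_B_copies(central, complex_b, config)
  tile <- propagate_A(tile)
  if (!is.null(complex_b2)) {
    tile2 <- place_B_copies(central, complex_b2, config)
    tile2 <- propagate_A(tile2)
    tile$B_copies <- c(tile$B_copies, tile2$B_copies)
    for (p in tile2$peripheral_A) {
      dup <- any(vapply(tile$peripheral_A, function(q)
        sqrt(sum((q$center[1:2] - p$center[1:2])^2)) < 6, logical(1)))
      if (!dup) tile$peripheral_A <- c(tile$peripheral_A, list(p))
    }
  }
  lat <- tryCatch(extract_cell(tile, config), error = function(e) e)
  cell <- if (inherits(lat, "lattice_model")) lat$cell else NULL
  reasons <- check_termination(tile, cell, config)
  if (inherits(lat, "error")) {
    if (inherits(lat, "degenerate_cell") && is.null(complex_b2) &&
        complex_a$axis$order_k == 2)
      reasons <- unique(c(reasons, "collinear_needs_second_axis"))
    else reasons <- unique(c(reasons, "cell_extraction_failed"))
  }
  if (length(reasons))
    return(structure(list(reasons = reasons, tile = tile),
                     class = "assembly_termination"))
  lat
}

#' @export
print.assembly_termination <- function(x, ...) {
  cat("assembly terminated:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a p1 lattice from full-length/single-domain heterodimers
#'
#' In a p1 layer no rotational axis of order 2 or higher exists; instead,
#' heterodimers of the full-length protein with each single domain define
#' translational neighbors. For every heterodimer passing the
#' symmetry-stage score gate, the full-length model is superposed onto the
#' bound single-domain copy; the resulting displacement is a lattice
#' translation. Two independent translations span the oblique p1 cell.
#'
#' @param full_model a [structure_model] of the full-length monomer (one
#'   chain).
#' @param heterodimers list of [scored_oligomer] objects (`hetero = TRUE`;
#'   first chain full-length, second chain one single domain placed at a
#'   neighbor position).
#' @param config a [default_config()] list.
#' @return a `lattice_model` with group p1.
#' @export
assemble_p1 <- function(full_model, heterodimers, config = default_config()) {
  strong <- Filter(function(hd) score_gate(hd$score$combined, "symmetry",
                                           config), heterodimers)
  if (length(strong) < 2)
    stop(errorCondition(
      "fewer than 2 strong heterodimer interactions; p1 assembly impossible",
      class = "p1_insufficient"))
  ref_ca <- ca_coords(full_model, chain_ids(full_model)[1])
  vecs <- list()
  for (hd in strong) {
    ch <- chain_ids(hd$model)
    dom_chain <- ch[2]
    dst <- ca_coords(hd$model, dom_chain)
    shared <- intersect(rownames(ref_ca), rownames(dst))
    if (length(shared) < 10) next
    k <- kabsch(dst[shared, , drop = FALSE], ref_ca[shared, , drop = FALSE])
    ctr <- colMeans(ref_ca)
    vecs[[length(vecs) + 1]] <-
      apply_transform(k$transform, matrix(ctr, 1))[1, ] - ctr
  }
  if (length(vecs) < 2)
    stop(errorCondition("fewer than 2 mappable heterodimers",
                        class = "p1_insufficient"))
  v1 <- vecs[[1]][1:2]
  ## first non-collinear partner
  v2 <- NULL
  for (v in vecs[-1]) {
    g <- angle_deg_2d(v1, v[1:2])
    if (g > 10 && g < 170) { v2 <- v[1:2]; break }
  }
  if (is.null(v2))
    stop(errorCondition("translation vectors are collinear: degenerate cell",
                        class = "degenerate_cell"))
  gamma <- angle_deg_2d(v1, v2)
  cell <- structure(list(a = sqrt(sum(v1^2)), b = sqrt(sum(v2^2)),
                         gamma = gamma, group = "p1"), class = "unit_cell")
  basis <- cbind(v1, v2)
  asym <- subset_chains(full_model, chain_ids(full_model)[1], rename = "A")
  structure(list(cell = cell, asym_unit = asym, basis = basis,
                 symops = wallpaper_symops("p1"),
                 scores = list(score_clash = NA_real_, score_bend = 0,
                               score_quality = NA_real_),
                 tile = NULL),
            class = "lattice_model")
}

#' Assemble a curved capsid tile
#'
#' Capsid variant of the superposition: B copies are placed on the central
#' complex by overlapping superposition but their axes are *not*
#' re-parallelized; the tilt between the central axis and each B axis is
#' reported (for an icosahedral 5-fold/3-fold pair this is the icosahedral
#' vertex-to-face angle). No closure of the full capsid is attempted.
#'
#' @param complex_a,complex_b symmetry complexes detected in capsid mode
#'   (orders may include 5).
#' @param config a [default_config()] list (capsid mode).
#' @return an `assembly_tile` with per-copy `tilt` angles in degrees.
#' @export
assemble_capsid_tile <- function(complex_a, complex_b,
                                 config = default_config("capsid")) {
  if (complex_b$axis$order_k > complex_a$axis$order_k) {
    tmp <- complex_a; complex_a <- complex_b; complex_b <- tmp
  }
  central <- align_axis_to_z(complex_a)
  tile <- place_B_copies(central, complex_b, config, realign = FALSE)
  tile$inter_axis_angles <- vapply(tile$B_copies, `[[`, numeric(1), "tilt")
  tile
}
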
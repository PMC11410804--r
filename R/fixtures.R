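## Synthetic fixture generation: rigid pseudo-protein monomers, k-fold
## oligomers with controllable noise and partial axis representation,
## planted wallpaper lattices with known cell constants, capsid patches,
## and AlphaFold-style score sidecars. Everything is deterministic for a
## fixed seed; fixtures are geometric, not energetic.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

## compact helical bundle: antiparallel helices (about 12 res each) along z,
## arranged on a ring with a consistent inward face so every consecutive
## helix pair is congruent and stays in crosslinking contact
build_bundle <- function(n_res, chain = "A", start_resno = 1L) {
  helix_len <- 12L
  n_helix <- max(2L, round(n_res / helix_len))
  lens <- rep(floor(n_res / n_helix), n_helix)
  extra <- n_res - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  spacing <- 8.5                       # adjacent helix-axis separation
  r_ring <- if (n_helix == 2) spacing / 2 else
    spacing / (2 * sin(pi / n_helix))
  parts <- list(); resno <- start_resno
  for (i in seq_len(n_helix)) {
    h <- build_peptide(lens[i], -57, -47, chain = chain, start_resno = resno)
    resno <- resno + lens[i]
    ## orient helix axis along +z or -z (antiparallel packing)
    ca <- ca_coords(h, chain)
    ax <- ca[nrow(ca), ] - ca[1, ]; ax <- ax / sqrt(sum(ax^2))
    updown <- if (i %% 2 == 1) c(0, 0, 1) else c(0, 0, -1)
    R <- rotation_between(ax, updown)
    ctr <- colMeans(ca)
    h <- transform_model(h, rigid_transform(R, -as.numeric(R %*% ctr)))
    ## co-rotate the helix with its ring position (same face inward)
    ang <- (i - 1) * 360 / n_helix
    Rs <- rotation_about(c(0, 0, 1), ang)
    pos <- r_ring * c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    h <- transform_model(h, rigid_transform(Rs, pos))
    parts[[i]] <- h$atoms
  }
  m <- structure_model(do.call(rbind, parts))
  ## center the bundle at the origin
  ctr <- colMeans(atom_coords(m))
  transform_model(m, rigid_transform(diag(3), -ctr))
}

## straight pseudo-extended linker placed along from -> to (even CA spacing;
## geometric object only, labels C under SSE assignment)
build_linker <- function(n_res, from, to, chain = "A", start_resno = 1L) {
  seg <- build_peptide(n_res, -139, 135, chain = chain,
                       start_resno = start_resno)
  ca <- ca_coords(seg, chain)
  ax <- ca[nrow(ca), ] - ca[1, ]
  R <- rotation_between(ax, to - from)
  ctr <- colMeans(ca)
  seg <- transform_model(seg, rigid_transform(R, -as.numeric(R %*% ctr)))
  ## scale CA span onto the from-to gap by spreading residue units
  ca2 <- ca_coords(seg, chain)
  span <- ca2[nrow(ca2), ] - ca2[1, ]
  gap <- to - from
  scale <- sqrt(sum(gap^2)) / sqrt(sum(span^2))
  a <- seg$atoms
  t_res <- (match(a$resno, sort(unique(a$resno))) - 1) / max(1, n_res - 1)
  stretch <- (scale - 1) * outer(t_res - 0.5, span)
  a$x <- a$x + stretch[, 1]; a$y <- a$y + stretch[, 2]; a$z <- a$z + stretch[, 3]
  seg$atoms <- a
  mid <- (from + to) / 2
  ctr2 <- colMeans(atom_coords(seg))
  transform_model(seg, rigid_transform(diag(3), mid - ctr2))
}

#' Generate a rigid pseudo-protein monomer
#'
#' Compact helical-bundle domains (backbone + CB, real element types) joined
#' by extended linkers of at least 12 residues, with domain centers
#' separated by at least 15 A. Deterministic for a fixed seed.
#'
#' @param n_domains number of domains (>= 1).
#' @param residues_per_domain residues in each domain.
#' @param seed RNG seed.
#' @param linker_len linker length in residues (>= 12).
#' @return a [structure_model] (chain A) with attribute `domains` (the
#'   ground-truth intervals) and `seed`.
#' @export
make_monomer <- function(n_domains, residues_per_domain = 48, seed = 1,
                         linker_len = 14L) {
  stopifnot(n_domains >= 1, linker_len >= 12)
  with_seed(seed, {
    parts <- list(); truth <- list(); resno <- 1L
    offset_x <- 0
    for (d in seq_len(n_domains)) {
      b <- build_bundle(residues_per_domain, chain = "A", start_resno = resno)
      ext <- diff(range(b$atoms$x))
      b <- transform_model(b, rigid_transform(diag(3),
                                              c(offset_x + ext / 2, 0, 0)))
      truth[[d]] <- c(start = resno, end = resno + residues_per_domain - 1L)
      parts[[length(parts) + 1]] <- b
      resno <- resno + residues_per_domain
      if (d < n_domains) {
        from <- c(offset_x + ext + 2, 0, 0)
        to <- c(offset_x + ext + 2 + max(15, linker_len * 2.8), 0, 0)
        lk <- build_linker(linker_len, from, to, chain = "A",
                           start_resno = resno)
        parts[[length(parts) + 1]] <- lk
        resno <- resno + linker_len
        offset_x <- to[1] + 2
      }
    }
    m <- merge_models(parts)
    m$atoms$chain <- "A"
    m <- structure_model(m$atoms)
    ## small seeded jitter so distinct seeds give distinct (still rigid)
    ## monomers without perturbing secondary structure or contacts
    m <- add_noise(m, 0.03)
    attr(m, "domains") <- do.call(rbind, lapply(truth, function(t1)
      data.frame(start = t1["start"], end = t1["end"], row.names = NULL)))
    attr(m, "seed") <- seed
    m
  })
}

add_noise <- function(model, sigma) {
  if (sigma <= 0) return(model)
  n <- nrow(model$atoms)
  model$atoms$x <- model$atoms$x + stats::rnorm(n, 0, sigma)
  model$atoms$y <- model$atoms$y + stats::rnorm(n, 0, sigma)
  model$atoms$z <- model$atoms$z + stats::rnorm(n, 0, sigma)
  model
}

## smallest ring radius at which adjacent k-fold copies of `model` keep a
## minimum heavy-atom separation near `target` Angstrom: inside the 5 A
## residue-contact cutoff but clear of the steric-clash threshold even
## under the default coordinate-noise levels
fit_ring_radius <- function(model, k, target = 4.5, lo = 1, hi = 400) {
  min_sep <- function(r) {
    m1 <- transform_model(model, rigid_transform(diag(3), c(r, 0, 0)))
    R <- rotation_about(c(0, 0, 1), 360 / k)
    m2 <- transform_model(m1, rigid_transform(R, c(0, 0, 0)))
    min(sqrt(dist2_matrix(atom_coords(m1, heavy_only = TRUE),
                          atom_coords(m2, heavy_only = TRUE))))
  }
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (min_sep(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Generate a k-fold oligomer fixture
#'
#' Places `m <= k` copies of the monomer at successive angles of 360/k
#' degrees about the z axis at the given ring radius, optionally with a
#' screw shift per step and isotropic Gaussian coordinate noise, and
#' attaches an AlphaFold-style score entry.
#'
#' @param monomer a [structure_model] (e.g. from [make_monomer()]).
#' @param k axis order (2-6).
#' @param m number of placed copies (2 <= m <= k).
#' @param radius ring radius in Angstrom; `NULL` fits the smallest radius
#'   keeping adjacent copies about 4 A apart.
#' @param noise_sigma per-atom Gaussian noise, Angstrom.
#' @param screw translation along z per step, Angstrom.
#' @param seed RNG seed.
#' @param iptm,ptm,relaxed score-sidecar fields.
#' @param subchain_id provenance tag.
#' @return a [scored_oligomer] with attribute `truth` (list with k, m,
#'   radius, noise_sigma, screw, seed).
#' @export
make_oligomer <- function(monomer, k, m = k, radius = NULL, noise_sigma = 0,
                          screw = 0, seed = 1, iptm = 0.8, ptm = 0.7,
                          relaxed = TRUE, subchain_id = "full") {
  stopifnot(m >= 2, m <= k, k >= 2, k <= 6)
  if (is.null(radius)) radius <- fit_ring_radius(monomer, k)
  with_seed(seed, {
    parts <- list()
    for (i in seq_len(m) - 1) {
      cp <- transform_model(monomer, rigid_transform(diag(3), c(radius, 0, 0)))
      R <- rotation_about(c(0, 0, 1), i * 360 / k)
      cp <- transform_model(cp, rigid_transform(R, c(0, 0, i * screw)))
      cp <- add_noise(cp, noise_sigma)
      cp$atoms$chain <- LETTERS[i + 1]
      parts[[i + 1]] <- cp$atoms
    }
    model <- structure_model(do.call(rbind, parts))
    sc <- data.frame(model = "model_1", iptm = iptm, ptm = ptm,
                     combined = combined_score(iptm, ptm), relaxed = relaxed)
    olig <- scored_oligomer(model, sc, subchain_id = subchain_id)
    attr(olig, "truth") <- list(k = k, m = m, radius = radius,
                                noise_sigma = noise_sigma, screw = screw,
                                seed = seed)
    olig
  })
}

## wallpaper-group geometry: basis vectors, axis sites and orders
wallpaper_geometry <- function(group, a, b = a, gamma = NULL) {
  if (group %in% c("p3", "p6")) gamma <- 120
  if (group == "p4") gamma <- 90
  if (is.null(gamma)) gamma <- if (group == "p1") 105 else 90
  v1 <- c(a, 0)
  v2 <- b * c(cos(gamma * pi / 180), sin(gamma * pi / 180))
  sites <- switch(group,
    p4 = list(list(frac = c(0, 0), k = 4), list(frac = c(0.5, 0.5), k = 4)),
    p6 = list(list(frac = c(0, 0), k = 6), list(frac = c(1/3, 2/3), k = 3)),
    p3 = list(list(frac = c(0, 0), k = 3), list(frac = c(1/3, 2/3), k = 3)),
    p2 = list(list(frac = c(0, 0), k = 2), list(frac = c(0.5, 0), k = 2),
              list(frac = c(0, 0.5), k = 2)),
    p1 = list(),
    stop("invalid wallpaper group: ", group))
  cart <- lapply(sites, function(s)
    c(s$frac[1] * v1 + s$frac[2] * v2))
  list(v1 = v1, v2 = v2, gamma = gamma, sites = sites, cart = cart)
}

## monomer spanning the axis sites of one cell: one bundle domain per site,
## placed on rings around each site, joined by linkers (later domains lifted
## in z to keep linker paths clear of the rings)
lattice_monomer <- function(geom, dom_res = 24, linker_len = 14L) {
  sites3 <- lapply(geom$cart, function(p) c(p, 0))
  bundles <- list(); radii <- numeric(length(sites3))
  resno <- 1L; parts <- list(); truth <- list()
  anchors <- list()
  for (s in seq_along(sites3)) {
    b <- build_bundle(dom_res, chain = "A", start_resno = resno)
    truth[[s]] <- c(start = resno, end = resno + dom_res - 1L)
    radii[s] <- fit_ring_radius(b, geom$sites[[s]]$k)
    ## place the domain on the ring of its site, on the segment toward the
    ## previous site (or +x for the first)
    origin <- sites3[[s]]
    toward <- if (s == 1) c(1, 0, 0) else {
      d <- sites3[[1]] - origin; d / sqrt(sum(d^2))
    }
    pos <- origin + radii[s] * toward
    ## spin the bundle so its packing face points along the ring direction
    ## (the ring-radius fit assumes approach along +x)
    spin <- rotation_between(c(1, 0, 0), toward)
    b <- transform_model(b, rigid_transform(spin, pos))
    anchors[[s]] <- pos
    parts[[length(parts) + 1]] <- b
    resno <- resno + dom_res
    if (s < length(sites3)) {
      nxt <- sites3[[s + 1]] +
        fit_ring_radius(build_bundle(dom_res), geom$sites[[s + 1]]$k) *
        (if (s + 1 == 1) c(1, 0, 0) else {
          d <- sites3[[1]] - sites3[[s + 1]]; d / sqrt(sum(d^2))
        })
      lift <- 16       # clear of the bundle rings (helices span |z| < 10)
      p_from <- anchors[[s]] + c(0, 0, lift)
      p_to <- nxt + c(0, 0, lift)
      if (s == 1) {
        ## leave the origin axis radially before turning toward the B site:
        ## rotated mates' linkers would otherwise crowd each other near the
        ## high-order ring (60-degree neighbors around a 6-fold axis)
        r0 <- sqrt(sum(anchors[[1]][1:2]^2))
        way <- c(anchors[[1]][1:2] * (r0 + 22) / r0, lift)
        n1 <- max(6L, floor(linker_len / 2)); n2 <- linker_len - n1
        lk1 <- build_linker(n1, p_from, way, chain = "A",
                            start_resno = resno)
        lk2 <- build_linker(n2, way, p_to, chain = "A",
                            start_resno = resno + n1)
        parts[[length(parts) + 1]] <- lk1
        parts[[length(parts) + 1]] <- lk2
      } else {
        parts[[length(parts) + 1]] <- build_linker(linker_len, p_from, p_to,
                                                   chain = "A",
                                                   start_resno = resno)
      }
      resno <- resno + linker_len
    }
  }
  m <- merge_models(parts)
  m$atoms$chain <- "A"
  m <- structure_model(m$atoms)
  attr(m, "domains") <- do.call(rbind, lapply(truth, function(t1)
    data.frame(start = t1["start"], end = t1["end"], row.names = NULL)))
  m
}

rotate_about_point <- function(model, point, angle) {
  R <- rotation_about(c(0, 0, 1), angle)
  transform_model(model, rigid_transform(R, point - as.numeric(R %*% point)))
}

#' Generate a planted wallpaper-lattice fixture pair
#'
#' Builds the lattice coordinates of the requested group with known cell
#' constants, then cuts complex A (the monomers around the origin axis) and
#' complex B (around the second axis site) sharing one monomer, exactly as
#' the assembly pipeline expects. For p2 two B complexes are produced (the
#' (1/2,0) and (0,1/2) 2-fold sites), since two half-turn axes alone span
#' only a frieze. For p1 the full-length/single-domain heterodimers are
#' produced instead.
#'
#' @param group one of p1, p2, p3, p4, p6.
#' @param a,b cell constants, Angstrom (b defaults to a; forced equal for
#'   p3/p4/p6).
#' @param gamma cell angle, degrees (forced 90 for p4, 120 for p3/p6).
#' @param noise_sigma per-atom Gaussian noise, Angstrom.
#' @param seed RNG seed.
#' @param iptm_a,iptm_b sidecar ipTM for the A and B complexes (pTM 0.7).
#' @param dir optional output directory; when given, mmCIF models, a JSON
#'   sidecar and a ground-truth JSON are written.
#' @return list with `complex_a`, `complex_b` (and `complex_b2` for p2, or
#'   `full_model` + `heterodimers` for p1), `monomer`, `truth`, and `files`
#'   when `dir` is given.
#' @export
make_lattice_pair <- function(group, a = 100, b = a, gamma = NULL,
                              noise_sigma = 0, seed = 1, iptm_a = 0.9,
                              iptm_b = 0.85, dir = NULL) {
  group <- match.arg(group, c("p1", "p2", "p3", "p4", "p6"))
  if (group %in% c("p3", "p4", "p6")) b <- a
  geom <- wallpaper_geometry(group, a, b, gamma)
  if (group == "p1")
    return(make_p1_fixture(geom, a, b, noise_sigma, seed, iptm_a, iptm_b, dir))
  with_seed(seed, {
    mono <- lattice_monomer(geom)
    sites3 <- lapply(geom$cart, function(p) c(p, 0))
    orders <- vapply(geom$sites, `[[`, numeric(1), "k")
    ## symmetry mates around each axis site (mate 0 is the shared monomer)
    mates <- function(site_i) {
      k <- orders[site_i]
      lapply(seq_len(k) - 1, function(j)
        rotate_about_point(mono, sites3[[site_i]], j * 360 / k))
    }
    cut_complex <- function(site_i, m_count, iptm, id) {
      ms <- mates(site_i)[seq_len(m_count)]
      parts <- list()
      for (i in seq_along(ms)) {
        cp <- add_noise(ms[[i]], noise_sigma)
        cp$atoms$chain <- LETTERS[i]
        parts[[i]] <- cp$atoms
      }
      sc <- data.frame(model = paste0("model_", id), iptm = iptm, ptm = 0.7,
                       combined = combined_score(iptm, 0.7), relaxed = TRUE)
      scored_oligomer(structure_model(do.call(rbind, parts)), sc,
                      subchain_id = id)
    }
    complex_a <- cut_complex(1, orders[1], iptm_a, "axisA")
    complex_b <- cut_complex(2, orders[2], iptm_b, "axisB")
    complex_b2 <- if (group == "p2") cut_complex(3, orders[3], iptm_b - 0.05,
                                                 "axisB2") else NULL
    truth <- list(group = group, a = a, b = b, gamma = geom$gamma,
                  orders = orders, noise_sigma = noise_sigma, seed = seed)
    out <- list(complex_a = complex_a, complex_b = complex_b,
                complex_b2 = complex_b2, monomer = mono, truth = truth)
    if (!is.null(dir)) out$files <- write_fixture_set(out, dir)
    out
  })
}

## p1: oblique lattice of a two-domain monomer; heterodimers of the
## full-length protein with each neighbor-placed single domain
make_p1_fixture <- function(geom, a, b, noise_sigma, seed, iptm_a, iptm_b,
                            dir) {
  with_seed(seed, {
    mono <- make_monomer(2, residues_per_domain = 24, seed = seed,
                         linker_len = 14L)
    dom <- attr(mono, "domains")
    v1 <- c(geom$v1, 0); v2 <- c(geom$v2, 0)
    mk_het <- function(vec, dom_i, iptm, id) {
      full <- add_noise(mono, noise_sigma)
      dpart <- subset_residues(mono, dom$start[dom_i]:dom$end[dom_i])
      dpart <- transform_model(dpart, rigid_transform(diag(3), vec))
      dpart <- add_noise(dpart, noise_sigma)
      dpart$atoms$chain <- "B"
      sc <- data.frame(model = paste0("model_", id), iptm = iptm, ptm = 0.7,
                       combined = combined_score(iptm, 0.7), relaxed = TRUE)
      scored_oligomer(structure_model(rbind(full$atoms, dpart$atoms)), sc,
                      subchain_id = id, hetero = TRUE)
    }
    het1 <- mk_het(v1, 1, iptm_a, "het1")
    het2 <- mk_het(v2, 2, iptm_b, "het2")
    truth <- list(group = "p1", a = a, b = b, gamma = geom$gamma,
                  orders = c(1, 1), noise_sigma = noise_sigma, seed = seed)
    out <- list(full_model = mono, heterodimers = list(het1, het2),
                monomer = mono, truth = truth)
    if (!is.null(dir)) out$files <- write_fixture_set(out, dir)
    out
  })
}

## persist a fixture set: mmCIF per complex + one sidecar + ground truth
write_fixture_set <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  sc_rows <- list()
  dump1 <- function(olig, stem) {
    p <- file.path(dir, paste0(stem, ".cif"))
    write_structure(olig$model, p, format = "mmcif")
    sc_rows[[stem]] <<- data.frame(model = stem, iptm = olig$score$iptm,
                                   ptm = olig$score$ptm,
                                   relaxed = olig$score$relaxed)
    files[[stem]] <<- p
  }
  if (!is.null(fx$complex_a)) dump1(fx$complex_a, "axisA")
  if (!is.null(fx$complex_b)) dump1(fx$complex_b, "axisB")
  if (!is.null(fx$complex_b2)) dump1(fx$complex_b2, "axisB2")
  if (!is.null(fx$heterodimers))
    for (i in seq_along(fx$heterodimers))
      dump1(fx$heterodimers[[i]], paste0("het", i))
  if (!is.null(fx$full_model)) {
    p <- file.path(dir, "monomer.cif")
    write_structure(fx$full_model, p, format = "mmcif")
    files$monomer <- p
  } else if (!is.null(fx$monomer)) {
    p <- file.path(dir, "monomer.cif")
    write_structure(fx$monomer, p, format = "mmcif")
    files$monomer <- p
  }
  write_scores(do.call(rbind, sc_rows), file.path(dir, "scores.json"))
  jsonlite::write_json(fx$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files$scores <- file.path(dir, "scores.json")
  files$truth <- file.path(dir, "truth.json")
  files
}

#' Generate a T=1 icosahedral capsid patch fixture
#'
#' A vertex pentamer and an adjacent face trimer cut from one icosahedral
#' arrangement of 60 identical subunits, sharing one subunit orientation.
#' The angle between the 5-fold (vertex) and 3-fold (face) axes is the
#' icosahedral value (about 37.38 degrees).
#'
#' @param seed RNG seed.
#' @param radius capsid radius, Angstrom; `NULL` fits subunit contacts.
#' @param noise_sigma per-atom Gaussian noise, Angstrom.
#' @return list with `pentamer`, `trimer` ([scored_oligomer]s) and `truth`
#'   (incl. the exact `inter_axis_angle`).
#' @export
make_capsid_patch <- function(seed = 1, radius = NULL, noise_sigma = 0) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    expand_signs(c(0, 1, phi)), expand_signs(c(1, phi, 0)),
    expand_signs(c(phi, 0, 1)))
  verts <- verts / sqrt(1 + phi^2)          # unit sphere
  V <- verts[which.max(verts[, 3]), ]       # apex vertex
  ## faces adjacent to V: triples of mutually nearest vertices
  nb <- order(apply(verts, 1, function(w) sum((w - V)^2)))[2:6]
  ## one face: V plus the two neighbors closest to each other
  d2 <- as.matrix(dist(verts[nb, ]))
  diag(d2) <- Inf
  ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  F3 <- (V + verts[nb[ij[1]], ] + verts[nb[ij[2]], ]) / 3
  Fhat <- F3 / sqrt(sum(F3^2))
  inter_axis <- acos(sum(V * Fhat)) * 180 / pi
  with_seed(seed, {
    sub0 <- build_bundle(24, chain = "A")
    place_subunit <- function(Rcap) {
      p <- 0.72 * V + 0.28 * Fhat
      p <- p / sqrt(sum(p^2))                        # unit
      pos <- Rcap * p
      e3 <- p
      e1 <- Fhat - sum(Fhat * e3) * e3; e1 <- e1 / sqrt(sum(e1^2))
      R <- cbind(e1, c(e3[2] * e1[3] - e3[3] * e1[2],
                       e3[3] * e1[1] - e3[1] * e1[3],
                       e3[1] * e1[2] - e3[2] * e1[1]) * -1, e3)
      if (det(R) < 0) R[, 2] <- -R[, 2]
      transform_model(sub0, rigid_transform(R, pos))
    }
    if (is.null(radius)) {
      ## fit: adjacent pentamer subunits about 4 A apart
      sep_at <- function(Rcap) {
        s1 <- place_subunit(Rcap)
        Rv <- rotation_about(V, 72)
        s2 <- transform_model(s1, rigid_transform(Rv, c(0, 0, 0)))
        min(sqrt(dist2_matrix(atom_coords(s1, heavy_only = TRUE),
                              atom_coords(s2, heavy_only = TRUE))))
      }
      lo <- 10; hi <- 400
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (sep_at(mid) < 4) lo <- mid else hi <- mid
      }
      radius <- hi
    }
    s0 <- place_subunit(radius)
    mk <- function(axis, k, iptm, id) {
      parts <- list()
      for (j in seq_len(k) - 1) {
        R <- rotation_about(axis, j * 360 / k)
        cp <- transform_model(s0, rigid_transform(R, c(0, 0, 0)))
        cp <- add_noise(cp, noise_sigma)
        cp$atoms$chain <- LETTERS[j + 1]
        parts[[j + 1]] <- cp$atoms
      }
      sc <- data.frame(model = id, iptm = iptm, ptm = 0.7,
                       combined = combined_score(iptm, 0.7), relaxed = TRUE)
      scored_oligomer(structure_model(do.call(rbind, parts)), sc,
                      subchain_id = id)
    }
    pent <- mk(V, 5, 0.85, "pentamer")
    tri <- mk(Fhat, 3, 0.8, "trimer")
    list(pentamer = pent, trimer = tri,
         truth = list(group = "capsid", radius = radius,
                      inter_axis_angle = inter_axis, orders = c(5, 3),
                      noise_sigma = noise_sigma, seed = seed))
  })
}

expand_signs <- function(v) {
  nz <- which(v != 0)
  out <- list()
  grid <- expand.grid(rep(list(c(1, -1)), length(nz)))
  for (r in seq_len(nrow(grid))) {
    w <- v
    w[nz] <- w[nz] * as.numeric(grid[r, ])
    out[[r]] <- w
  }
  unique(do.call(rbind, out))
}
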
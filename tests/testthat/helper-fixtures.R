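## Shared fixture builders and independent oracles for the test suite.
## Heavier fixtures are cached per session to keep the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

## small single-domain monomer used across symmetry/filter tests
tiny_monomer <- function() cached("tiny_monomer", make_monomer(1, 36, seed = 42))

## ring radius per axis order for the tiny monomer (fit once)
tiny_radius <- function(k) {
  key <- paste0("radius_k", k)
  cached(key, symlattice:::fit_ring_radius(tiny_monomer(), k))
}

## larger monomer for the noise-robustness property: the step-angle
## precision for a two-copy (m = 2) oligomer is set by the monomer's own
## spread, so a realistic ~70-residue domain is used there
noise_monomer <- function() cached("noise_monomer", make_monomer(1, 72, seed = 77))

noise_radius <- function(k) {
  key <- paste0("noise_radius_k", k)
  cached(key, symlattice:::fit_ring_radius(noise_monomer(), k))
}

tiny_oligomer <- function(k, m = k, noise_sigma = 0, seed = 1,
                          radius = tiny_radius(k), ...) {
  make_oligomer(tiny_monomer(), k = k, m = m, radius = radius,
                noise_sigma = noise_sigma, seed = seed, ...)
}

## brute-force residue-contact oracle: all residue pairs, all heavy-atom
## pairs, no pooling tricks
oracle_contact_count <- function(model, sel_a, sel_b, cutoff) {
  a <- model$atoms[!model$atoms$hydrogen, ]
  key <- function(s) paste(s$chain, s$resno)
  ka <- key(sel_a); kb <- key(sel_b)
  hits <- 0
  pairs_seen <- character()
  for (ra in ka) for (rb in kb) {
    if (setequal(ka, kb)) {
      pr <- paste(sort(c(ra, rb)), collapse = "|")
      if (ra == rb || pr %in% pairs_seen) next
      pairs_seen <- c(pairs_seen, pr)
    }
    pa <- a[paste(a$chain, a$resno) == ra, c("x", "y", "z")]
    pb <- a[paste(a$chain, a$resno) == rb, c("x", "y", "z")]
    dmin <- Inf
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
      dmin <- min(dmin, sqrt(sum((as.numeric(pa[i, ]) - as.numeric(pb[j, ]))^2)))
    if (dmin < cutoff) hits <- hits + 1
  }
  hits
}

## brute-force clash oracle: every inter-chain heavy-atom pair
oracle_clash_count <- function(model, allowance = 0.6) {
  a <- model$atoms[!model$atoms$hydrogen, ]
  rad <- symlattice::vdw_radii
  r <- unname(rad[a$element]); r[is.na(r)] <- 1.7
  n <- 0
  for (i in seq_len(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
    if (a$chain[i] == a$chain[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d < r[i] + r[j] - allowance) n <- n + 1
  }
  n
}

## independent rotation-search oracle for the minimal superposition RMSD:
## multi-start quasi-Newton minimization over the axis-angle parameterization
## (never calls the SVD path)
oracle_min_rmsd <- function(A, B, n_starts = 24) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  rot_from_w <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    u <- w / th
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(w) {
    R <- rot_from_w(w)
    sqrt(mean(rowSums((B0 %*% t(R) - A0)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(matrix(stats::runif(3 * (n_starts - 1), -pi, pi),
                         ncol = 3), c(0, 0, 0))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    if (fit$value < best) best <- fit$value
  }
  best
}

## planted two-interface complex set: A-type and B-type complexes across
## several subchain crops of one planted p4 lattice
planted_interface_set <- function() {
  cached("planted_interface_set", {
    fx <- make_lattice_pair("p4", a = 100, noise_sigma = 0, seed = 21)
    cfg <- default_config()
    dom <- attr(fx$monomer, "domains")
    chain_max <- max(fx$monomer$atoms$resno)
    out <- list(); truth <- character()
    for (side in c("a", "b")) {
      olig <- if (side == "a") fx$complex_a else fx$complex_b
      iface_dom <- if (side == "a") 1 else 2
      ## subchain crops around the interface domain: full + widening margins
      crops <- list(full = NULL, m0 = 0, m6 = 6, m12 = 12, m18 = 18)
      for (nm in names(crops)) {
        m2 <- if (is.null(crops[[nm]])) olig$model else {
          keep <- max(1, dom$start[iface_dom] - crops[[nm]]):
            min(chain_max, dom$end[iface_dom] + crops[[nm]])
          subset_residues(olig$model, keep)
        }
        sc <- olig$score; sc$combined <- sc$combined - 0.01 * length(out)
        cx <- detect_symmetry(
          scored_oligomer(m2, sc, subchain_id = paste(side, nm, sep = "_")),
          "layer", cfg)
        if (is_rejected(cx)) next
        ok <- tryCatch({ interface_matrix(cx, cfg); TRUE },
                       error = function(e) FALSE)
        if (!ok) next
        out[[paste(side, nm, sep = "_")]] <- cx
        truth <- c(truth, side)
      }
    }
    list(complexes = out, truth = truth)
  })
}

## clash score of the noise-free planted tile for a group (the planted-truth
## clash level that noisy assemblies are compared against)
clash_truth <- function(group) {
  key <- paste0("clash_truth_", group)
  cached(key, {
    cfg <- default_config()
    a_true <- switch(group, p2 = 90, p3 = 120, p4 = 100, p6 = 170)
    fx <- make_lattice_pair(group, a = a_true,
                            gamma = if (group == "p2") 100 else NULL,
                            noise_sigma = 0, seed = 1)
    cxa <- detect_symmetry(fx$complex_a, "layer", cfg)
    cxb <- detect_symmetry(fx$complex_b, "layer", cfg)
    cxb2 <- if (!is.null(fx$complex_b2))
      detect_symmetry(fx$complex_b2, "layer", cfg) else NULL
    lat <- assemble_lattice(cxa, cxb, cfg, complex_b2 = cxb2)
    lat$scores$score_clash
  })
}
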
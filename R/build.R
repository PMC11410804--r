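## Ideal-geometry backbone construction (NeRF internal-coordinate placement).
## Used by the synthetic fixture generator and by secondary-structure tests.

## place atom D given A-B-C, bond |C-D|, angle B-C-D, torsion A-B-C-D
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

## standard backbone geometry (Engh-Huber-like averages)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ca_cb = 1.521,
            ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
            ang_ca_c_o = 120.8)

#' Build an ideal-geometry polypeptide backbone
#'
#' Constructs N, CA, C, O (and optionally CB) atoms for a poly-alanine chain
#' with the given backbone torsions, using standard bond lengths and angles.
#'
#' @param n number of residues.
#' @param phi,psi backbone torsions in degrees; recycled to length `n`
#'   (alpha-helix: -57/-47; beta-strand: -139/135; extended: -180/180).
#' @param omega peptide-bond torsion, degrees (default 180, trans).
#' @param chain chain id.
#' @param start_resno first residue number.
#' @param cb include CB atoms.
#' @return a [structure_model] with one chain of ALA residues.
#' @export
build_peptide <- function(n, phi = -57, psi = -47, omega = 180, chain = "A",
                          start_resno = 1L, cb = TRUE) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  ## seed the first residue in a canonical pose
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  C[1, ] <- nerf_place(c(-1, 1, 0), N[1, ], CA[1, ], .bb$ca_c, .bb$ang_n_ca_c,
                       phi[1])
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .bb$c_n,
                           .bb$ang_ca_c_n, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], .bb$n_ca,
                            .bb$ang_c_n_ca, omega[i - 1])
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], .bb$ca_c,
                           .bb$ang_n_ca_c, phi[i])
    }
    ## carbonyl O: torsion N-CA-C-O = psi + 180 (trans to the next N)
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], .bb$c_o, .bb$ang_ca_c_o,
                         psi[i] + 180)
    if (cb) CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ])
  }
  rows <- list()
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (cb) { nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, CB[i, ]) }
    rows[[i]] <- data.frame(chain = chain, resno = resno, resid = "ALA",
                            elety = nm, element = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows))
}

## CB from the backbone frame: tetrahedral carbon, L-configuration
place_cb <- function(N, CA, C) {
  n1 <- N - CA; n1 <- n1 / sqrt(sum(n1^2))
  n2 <- C - CA; n2 <- n2 / sqrt(sum(n2^2))
  v <- n1 + n2; v <- v / sqrt(sum(v^2))
  u <- c(n1[2] * n2[3] - n1[3] * n2[2],
         n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  u <- u / sqrt(sum(u^2))
  ca <- cos(110.5 * pi / 180)
  a <- ca / sum(v * n1)
  b <- -sqrt(max(0, 1 - a^2))       # sign picks the L-configuration side
  CA + .bb$ca_cb * (a * v + b * u)
}

#' Amide-hydrogen positions for hydrogen-bond energies
#'
#' Places H on each backbone N (except chain N-termini) one Angstrom from N
#' along the direction of the preceding C=O bond reversed, the classic
#' rigid-geometry approximation.
#' @param model a [structure_model] with backbone atoms.
#' @return data.frame chain, resno, hx, hy, hz (rows only where placeable).
#' @keywords internal
amide_hydrogens <- function(model) {
  out <- list(); k <- 0
  for (ch in chain_ids(model)) {
    rn <- chain_resnos(model, ch)
    a <- model$atoms[model$atoms$chain == ch, ]
    get1 <- function(resno, nm) {
      r <- a[a$resno == resno & a$elety == nm, c("x", "y", "z")]
      if (nrow(r) != 1) return(NULL)
      as.numeric(r)
    }
    for (i in seq_along(rn)[-1]) {
      if (rn[i] != rn[i - 1] + 1) next       # chain break
      N <- get1(rn[i], "N"); Cp <- get1(rn[i - 1], "C")
      Op <- get1(rn[i - 1], "O")
      if (is.null(N) || is.null(Cp) || is.null(Op)) next
      d <- Cp - Op; d <- d / sqrt(sum(d^2))
      H <- N + 1.01 * d
      k <- k + 1
      out[[k]] <- data.frame(chain = ch, resno = rn[i], hx = H[1], hy = H[2],
                             hz = H[3], stringsAsFactors = FALSE)
    }
  }
  if (k == 0) return(data.frame(chain = character(), resno = integer(),
                                hx = numeric(), hy = numeric(), hz = numeric()))
  do.call(rbind, out)
}

#' Build an antiparallel two-strand beta pair as two chains
#'
#' Two extended strands placed with canonical inter-strand hydrogen-bond
#' geometry (in-register antiparallel pairing); interior residues are
#' assigned E by [assign_sse()].
#'
#' @param n residues per strand.
#' @return a [structure_model] with chains A and B.
#' @export
build_strand_pair <- function(n = 8) {
  sA <- build_peptide(n, -139, 135, chain = "A")
  caA <- ca_coords(sA, "A")
  ax <- caA[n, ] - caA[1, ]; ax <- ax / sqrt(sum(ax^2))
  zz <- c(0, 0, 1); perp <- zz - sum(zz * ax) * ax
  perp <- perp / sqrt(sum(perp^2))
  perp2 <- c(ax[2] * perp[3] - ax[3] * perp[2],
             ax[3] * perp[1] - ax[1] * perp[3],
             ax[1] * perp[2] - ax[2] * perp[1])
  sB <- build_peptide(n, -139, 135, chain = "B")
  ctr <- colMeans(ca_coords(sB, "B"))
  R1 <- rotation_about(perp, 180)
  sB <- transform_model(sB, rigid_transform(R1, ctr - as.numeric(R1 %*% ctr)))
  ## placement calibrated once for canonical N-H..O=C geometry
  sB <- transform_model(sB, rigid_transform(diag(3), 1.75 * ax + 4.0 * perp2))
  merge_models(list(sA, sB))
}
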
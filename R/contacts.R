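## Contact, clash and surface primitives shared by the domain separator,
## the model-quality filters and the interface clustering.

#' Van der Waals radius table
#'
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Angstrom; unknown elements fall
#' back to 1.70 with a warning from the caller where relevant.
#' @export
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(element) {
  r <- unname(vdw_radii[element])
  r[is.na(r)] <- 1.70
  r
}

## squared distances between two row-coordinate matrices
dist2_matrix <- function(A, B) {
  a2 <- rowSums(A * A); b2 <- rowSums(B * B)
  D2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

## min-pool a matrix over row/column groups (factors); returns grouped matrix
## with dimnames from group levels
minpool <- function(D, gr, gc) {
  ur <- unique(gr); uc <- unique(gc)
  rows <- lapply(ur, function(g) {
    ix <- which(gr == g)
    if (length(ix) == 1) D[ix, ] else do.call(pmin, asplit(D[ix, , drop = FALSE], 1))
  })
  Dr <- do.call(rbind, rows)
  cols <- lapply(uc, function(g) {
    ix <- which(gc == g)
    if (length(ix) == 1) Dr[, ix] else do.call(pmin, asplit(Dr[, ix, drop = FALSE], 2))
  })
  M <- do.call(cbind, cols)
  dimnames(M) <- list(ur, uc)
  M
}

## residue keys "chain:resno"
res_key <- function(chain, resno) paste(chain, resno, sep = ":")

#' Build a residue selection
#'
#' @param model a [structure_model].
#' @param chain chain id(s); default all.
#' @param resno residue numbers; default all in the selected chains.
#' @return data.frame with `chain` and `resno` columns.
#' @export
residue_selection <- function(model, chain = NULL, resno = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  u <- unique(a[keep, c("chain", "resno")])
  rownames(u) <- NULL
  u
}

## min heavy-atom distance matrix between two residue selections
residue_min_dist <- function(model, sel_a, sel_b) {
  a <- model$atoms[!model$atoms$hydrogen, ]
  ka <- res_key(a$chain, a$resno)
  keys_a <- res_key(sel_a$chain, sel_a$resno)
  keys_b <- res_key(sel_b$chain, sel_b$resno)
  ia <- which(ka %in% keys_a); ib <- which(ka %in% keys_b)
  if (!length(ia) || !length(ib)) return(NULL)
  A <- as.matrix(a[ia, c("x", "y", "z")]); B <- as.matrix(a[ib, c("x", "y", "z")])
  D2 <- dist2_matrix(A, B)
  sqrt(minpool(D2, ka[ia], ka[ib]))
}

#' Count residue pairs in contact
#'
#' A residue pair is in contact when the minimum distance between their heavy
#' atoms is below `cutoff`. Pairs are counted once; when the selections are
#' identical, self pairs and double counting are excluded.
#'
#' @param model a [structure_model].
#' @param sel_a,sel_b residue selections (see [residue_selection()]).
#' @param cutoff distance cutoff, Angstrom.
#' @return integer count of residue pairs.
#' @export
contact_count <- function(model, sel_a, sel_b, cutoff = 5) {
  stopifnot(cutoff > 0)
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) {
    warning("empty residue selection; contact count 0")
    return(0L)
  }
  M <- residue_min_dist(model, sel_a, sel_b)
  if (is.null(M)) {
    warning("empty residue selection; contact count 0")
    return(0L)
  }
  hit <- M < cutoff
  same <- setequal(res_key(sel_a$chain, sel_a$resno),
                   res_key(sel_b$chain, sel_b$resno))
  if (same) {
    hit <- hit[rownames(M), rownames(M), drop = FALSE]
    hit[lower.tri(hit, diag = TRUE)] <- FALSE
  }
  sum(hit)
}

## deterministic quasi-uniform sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Approximate solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric sphere-sampling area of the selected residues' heavy atoms, with
#' occlusion by all heavy atoms of the model. Deterministic for a fixed
#' point count.
#'
#' @param model a [structure_model].
#' @param sel residue selection; default whole model.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 240).
#' @return area in Angstrom^2.
#' @export
surface_area <- function(model, sel = NULL, probe = 1.4, n_points = 240) {
  a <- model$atoms[!model$atoms$hydrogen, ]
  if (is.null(sel)) sel <- residue_selection(model)
  if (any(!(a$element %in% names(vdw_radii))))
    warning("unknown element(s); using default radius 1.70 A")
  keys <- res_key(a$chain, a$resno)
  in_sel <- keys %in% res_key(sel$chain, sel$resno)
  if (!any(in_sel)) return(0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element) + probe
  pts <- sphere_points(n_points)
  total <- 0
  idx_sel <- which(in_sel)
  ## neighbor prefilter via squared distances to selected atoms
  D2 <- dist2_matrix(xyz[idx_sel, , drop = FALSE], xyz)
  maxr <- max(rad)
  for (k in seq_along(idx_sel)) {
    i <- idx_sel[k]
    nb <- which(D2[k, ] < (rad[i] + maxr)^2)
    nb <- setdiff(nb, i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & d2 >= rad[j]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  total
}
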
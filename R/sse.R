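## Secondary-structure assignment from backbone hydrogen-bond energies,
## reduced to the three states {H, E, C} consumed downstream.

## Kabsch-Sander electrostatic hydrogen-bond energy between donor NH and
## acceptor C=O groups; a bond exists below the -0.5 kcal/mol cutoff.
hbond_table <- function(model, e_cut = -0.5) {
  a <- model$atoms
  pick <- function(nm) {
    r <- a[a$elety == nm & !a$hydrogen, c("chain", "resno", "x", "y", "z")]
    rownames(r) <- res_key(r$chain, r$resno)
    r
  }
  N <- pick("N"); C <- pick("C"); O <- pick("O")
  H <- amide_hydrogens(model)
  if (nrow(H) == 0) return(NULL)
  rownames(H) <- res_key(H$chain, H$resno)
  ## donors: residues with N and placed H; acceptors: residues with C and O
  don <- intersect(rownames(N), rownames(H))
  acc <- intersect(rownames(C), rownames(O))
  if (!length(don) || !length(acc)) return(NULL)
  Nm <- as.matrix(N[don, c("x", "y", "z")])
  Hm <- as.matrix(H[don, c("hx", "hy", "hz")])
  Cm <- as.matrix(C[acc, c("x", "y", "z")])
  Om <- as.matrix(O[acc, c("x", "y", "z")])
  d_on <- sqrt(dist2_matrix(Nm, Om))
  ## prefilter: N..O under 5.2 A
  cand <- which(d_on < 5.2, arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  di <- cand[, 1]; ai <- cand[, 2]
  d_ch <- sqrt(rowSums((Hm[di, , drop = FALSE] - Cm[ai, , drop = FALSE])^2))
  d_oh <- sqrt(rowSums((Hm[di, , drop = FALSE] - Om[ai, , drop = FALSE])^2))
  d_cn <- sqrt(rowSums((Nm[di, , drop = FALSE] - Cm[ai, , drop = FALSE])^2))
  E <- 27.888 * (1 / d_on[cand] + 1 / d_ch - 1 / d_oh - 1 / d_cn)
  keep <- E < e_cut
  if (!any(keep)) return(NULL)
  don_key <- don[di[keep]]; acc_key <- acc[ai[keep]]
  dk <- do.call(rbind, strsplit(don_key, ":"))
  ak <- do.call(rbind, strsplit(acc_key, ":"))
  hb <- data.frame(don_chain = dk[, 1], don_res = as.integer(dk[, 2]),
                   acc_chain = ak[, 1], acc_res = as.integer(ak[, 2]),
                   energy = E[keep], stringsAsFactors = FALSE)
  ## drop self and sequence-adjacent same-chain pairs
  same <- hb$don_chain == hb$acc_chain & abs(hb$don_res - hb$acc_res) < 2
  hb[!same, , drop = FALSE]
}

## beta bridges (parallel and antiparallel) from the hydrogen-bond table;
## hb(d, a) means donor NH of d bonds the C=O of a
bridge_table <- function(model, hb = NULL) {
  if (is.null(hb)) hb <- hbond_table(model)
  empty <- data.frame(chain_i = character(), res_i = integer(),
                      chain_j = character(), res_j = integer(),
                      type = character())
  if (is.null(hb) || nrow(hb) == 0) return(empty)
  key <- paste(hb$don_chain, hb$don_res, hb$acc_chain, hb$acc_res)
  has <- function(dc, dr, ac, ar) paste(dc, dr, ac, ar) %in% key
  ## candidate (i, j) pairs: residues linked by any hbond within +-1
  cand <- unique(rbind(
    data.frame(ci = hb$don_chain, ri = hb$don_res, cj = hb$acc_chain,
               rj = hb$acc_res),
    data.frame(ci = hb$acc_chain, ri = hb$acc_res, cj = hb$don_chain,
               rj = hb$don_res)))
  grid <- expand.grid(di = -1:1, dj = -1:1)
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(grid)), function(g)
    data.frame(ci = cand$ci, ri = cand$ri + grid$di[g], cj = cand$cj,
               rj = cand$rj + grid$dj[g]))))
  ci <- cand$ci; ri <- cand$ri; cj <- cand$cj; rj <- cand$rj
  near <- ci == cj & abs(ri - rj) < 3
  anti <- (has(ci, ri, cj, rj) & has(cj, rj, ci, ri)) |
          (has(ci, ri - 1, cj, rj + 1) & has(cj, rj - 1, ci, ri + 1))
  par <- (has(ci, ri, cj, rj - 1) & has(cj, rj + 1, ci, ri)) |
         (has(cj, rj, ci, ri - 1) & has(ci, ri + 1, cj, rj))
  keep <- !near & (anti | par)
  if (!any(keep)) return(empty)
  out <- data.frame(chain_i = ci[keep], res_i = ri[keep],
                    chain_j = cj[keep], res_j = rj[keep],
                    type = ifelse(anti[keep], "antiparallel", "parallel"),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Assign secondary structure (H/E/C) from backbone hydrogen bonds
#'
#' Hydrogen bonds are detected with the classic electrostatic energy
#' criterion (cutoff -0.5 kcal/mol, amide H placed by rigid geometry).
#' Residues in two consecutive i -> i+4 turns are labeled H; residues in
#' parallel or antiparallel bridges are labeled E; everything else is C.
#' Residues with incomplete backbones are labeled C and counted in the
#' `sse_warnings` attribute.
#'
#' @param model a [structure_model] with backbone N, CA, C, O atoms.
#' @return the model with `$sse` filled (named list chain -> per-residue
#'   labels named by residue number).
#' @export
assign_sse <- function(model) {
  hb <- hbond_table(model)
  br <- bridge_table(model, hb)
  sse <- list()
  n_missing <- 0
  for (ch in chain_ids(model)) {
    rn <- chain_resnos(model, ch)
    lab <- rep("C", length(rn)); names(lab) <- rn
    a <- model$atoms[model$atoms$chain == ch, ]
    for (r in rn) {
      nm <- a$elety[a$resno == r]
      if (!all(c("N", "CA", "C", "O") %in% nm)) n_missing <- n_missing + 1
    }
    sse[[ch]] <- lab
  }
  ## helices: two consecutive 4-turns starting at i mark i+1 .. i+4
  if (!is.null(hb) && nrow(hb)) {
    t4 <- hb[hb$don_chain == hb$acc_chain & hb$don_res == hb$acc_res + 4, ]
    if (nrow(t4)) {
      for (ch in unique(t4$acc_chain)) {
        starts <- sort(t4$acc_res[t4$acc_chain == ch])
        run <- starts[(starts + 1) %in% starts]
        for (i in run) {
          hit <- as.character((i + 1):(i + 4))
          hit <- hit[hit %in% names(sse[[ch]])]
          sse[[ch]][hit] <- "H"
        }
      }
    }
  }
  ## strands: bridge partners get E unless already helix
  if (nrow(br)) {
    mark <- rbind(data.frame(chain = br$chain_i, res = br$res_i),
                  data.frame(chain = br$chain_j, res = br$res_j))
    for (k in seq_len(nrow(mark))) {
      ch <- mark$chain[k]; r <- as.character(mark$res[k])
      if (!is.null(sse[[ch]]) && r %in% names(sse[[ch]]) &&
          sse[[ch]][r] != "H")
        sse[[ch]][r] <- "E"
    }
  }
  model$sse <- sse
  attr(model, "sse_warnings") <- n_missing
  model
}

## residues involved in inter-chain beta bridges (for the beta-strand filter)
interchain_beta_residues <- function(model) {
  br <- bridge_table(model)
  br <- br[br$chain_i != br$chain_j, , drop = FALSE]
  if (!nrow(br)) return(character())
  unique(c(res_key(br$chain_i, br$res_i), res_key(br$chain_j, br$res_j)))
}
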
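## The universal coordinate container: hierarchical chains/residues/atoms
## held as a flat atom table, in the style of bio3d's pdb$atom.

#' Construct a structure model
#'
#' The central coordinate container of the package. Atoms are held in a flat
#' data frame (one row per atom) ordered by chain, then residue number.
#' Secondary-structure labels (H/E/C per residue) are attached per chain once
#' [assign_sse()] has run.
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based author
#'   numbering, strictly increasing within a chain), `resid` (3-letter
#'   residue code), `elety` (atom name), `element` (element symbol), `x`,
#'   `y`, `z` (Angstrom), and optionally `occ`, `b`, `hydrogen`.
#' @param sse optional named list (chain id -> character vector of per-residue
#'   labels in `{H, E, C}`).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, sse = NULL) {
  req <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: zero atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (is.null(atoms$occ)) atoms$occ <- 1.00
  if (is.null(atoms$b)) atoms$b <- 0.00
  if (is.null(atoms$hydrogen)) atoms$hydrogen <- atoms$element %in% c("H", "D")
  atoms$chain <- as.character(atoms$chain)
  atoms$element <- toupper(as.character(atoms$element))
  ## stable ordering: chain (first-appearance order), then resno
  ch_order <- unique(atoms$chain)
  atoms <- atoms[order(match(atoms$chain, ch_order), atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  for (ch in ch_order) {
    rn <- atoms$resno[atoms$chain == ch]
    heavy <- atoms$resno[atoms$chain == ch & !atoms$hydrogen]
    if (!all(unique(rn) %in% unique(heavy)))
      stop("chain ", ch, ": residue without a heavy atom")
  }
  structure(list(atoms = atoms, sse = sse), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(c1) length(chain_resnos(x, c1)), integer(1))
  cat(sprintf("structure_model: %d chain(s), %d atoms\n", length(ch),
              nrow(x$atoms)))
  for (i in seq_along(ch))
    cat(sprintf("  chain %s: %d residues%s\n", ch[i], nres[i],
                if (!is.null(x$sse[[ch[i]]])) " [sse]" else ""))
  invisible(x)
}

#' Chain identifiers in file order
#' @param model a [structure_model].
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Residue numbers of one chain
#' @param model a [structure_model].
#' @param chain chain id.
#' @export
chain_resnos <- function(model, chain) {
  unique(model$atoms$resno[model$atoms$chain == chain])
}

#' One-letter sequence of a chain
#' @inheritParams chain_resnos
#' @export
chain_sequence <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, ]
  res3 <- a$resid[!duplicated(a$resno)]
  aa_three_to_one(res3)
}

aa_table <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa_three_to_one <- function(res3) {
  out <- unname(aa_table[toupper(res3)])
  out[is.na(out)] <- "X"
  paste(out, collapse = "")
}

#' Coordinates of selected atoms
#'
#' @param model a [structure_model].
#' @param chain optional chain id filter.
#' @param resno optional residue-number filter.
#' @param elety optional atom-name filter (e.g. `"CA"`).
#' @param heavy_only drop hydrogens.
#' @return N x 3 numeric matrix.
#' @export
atom_coords <- function(model, chain = NULL, resno = NULL, elety = NULL,
                        heavy_only = FALSE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (heavy_only) keep <- keep & !a$hydrogen
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

#' CA coordinates of one chain, ordered by residue number
#' @inheritParams chain_resnos
#' @export
ca_coords <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain & model$atoms$elety == "CA", ]
  a <- a[order(a$resno), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Apply a rigid transform to a whole model (or selected chains)
#'
#' @param model a [structure_model].
#' @param tr a [rigid_transform].
#' @param chain optional chain subset to move.
#' @return transformed [structure_model].
#' @export
transform_model <- function(model, tr, chain = NULL) {
  a <- model$atoms
  idx <- if (is.null(chain)) seq_len(nrow(a)) else which(a$chain %in% chain)
  xyz <- apply_transform(tr, as.matrix(a[idx, c("x", "y", "z")]))
  a$x[idx] <- xyz[, 1]; a$y[idx] <- xyz[, 2]; a$z[idx] <- xyz[, 3]
  model$atoms <- a
  model
}

#' Keep only the named chains
#' @inheritParams transform_model
#' @param chains chain ids to keep.
#' @param rename optional new ids (same length as `chains`).
#' @export
subset_chains <- function(model, chains, rename = NULL) {
  a <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  sse <- model$sse[intersect(names(model$sse), chains)]
  if (!is.null(rename)) {
    a$chain <- rename[match(a$chain, chains)]
    if (length(sse)) names(sse) <- rename[match(names(sse), chains)]
  }
  structure_model(a, sse = if (length(sse)) sse else NULL)
}

#' Keep only the named residue numbers (applied to every chain)
#' @inheritParams transform_model
#' @param resno residue numbers to keep.
#' @export
subset_residues <- function(model, resno) {
  a <- model$atoms[model$atoms$resno %in% resno, , drop = FALSE]
  sse <- model$sse
  if (!is.null(sse))
    sse <- lapply(sse, function(v) v[names(v) %in% as.character(resno)])
  structure_model(a, sse = sse)
}

#' Merge several models into one, relabeling chains uniquely
#'
#' @param models list of [structure_model] objects.
#' @return a single [structure_model]; chains renamed `A`, `B`, ... in order.
#' @export
merge_models <- function(models) {
  pool <- c(LETTERS, letters, as.character(0:9),
            paste0(rep(LETTERS, each = 26), rep(LETTERS, 26)))
  out <- list(); k <- 0
  for (m in models) {
    for (ch in chain_ids(m)) {
      k <- k + 1
      a <- m$atoms[m$atoms$chain == ch, , drop = FALSE]
      a$chain <- pool[k]
      out[[k]] <- a
    }
  }
  structure_model(do.call(rbind, out))
}

#' Per-chain residue centroid (CA if present, else heavy atoms)
#' @keywords internal
chain_centroid <- function(model, chain) {
  m <- ca_coords(model, chain)
  if (nrow(m) == 0)
    m <- atom_coords(model, chain = chain, heavy_only = TRUE)
  colMeans(m)
}
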
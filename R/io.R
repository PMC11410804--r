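## Reading and writing of the standard formats: PDB and mmCIF coordinates
## (bio3d parsers), AlphaFold-style JSON score sidecars, and domain FASTA.

#' Read a coordinate file into a structure model
#'
#' Wraps `bio3d::read.pdb()` / `bio3d::read.cif()`. Hydrogens are retained
#' but flagged; author residue numbering is preserved.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension; `.cif` and
#'   `.mmcif` read as mmCIF).
#' @return a [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  obj <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e)),
    warning = function(w) suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE)))
  a <- obj$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure (zero atoms): ", path)
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- guess_element(a$elety)
  el[is.na(el) | el == ""] <- guess_element(a$elety[is.na(el) | el == ""])
  atoms <- data.frame(chain = as.character(a$chain), resno = a$resno,
                      resid = a$resid, elety = a$elety, element = toupper(el),
                      x = a$x, y = a$y, z = a$z,
                      occ = if (is.null(a$o)) 1 else ifelse(is.na(a$o), 1, a$o),
                      b = if (is.null(a$b)) 0 else ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  structure_model(atoms)
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  first <- toupper(substr(e, 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, toupper(e))
}

#' Write a structure model to PDB or mmCIF
#'
#' @param model a [structure_model].
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` by extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, o = a$occ, b = a$b, elesy = a$element,
                     end = TRUE)
  } else {
    writeLines(format_mmcif(model), path)
  }
  invisible(path)
}

## mmCIF atom_site serialization (optionally with cell + symmetry operators)
format_mmcif <- function(model, data_name = "model", cell = NULL,
                         symops = NULL) {
  a <- model$atoms
  hdr <- c(paste0("data_", data_name), "#")
  if (!is.null(cell)) {
    hdr <- c(hdr,
             sprintf("_cell.length_a    %.4f", cell$a),
             sprintf("_cell.length_b    %.4f", cell$b),
             sprintf("_cell.length_c    %.4f", cell$c),
             sprintf("_cell.angle_alpha %.4f", 90),
             sprintf("_cell.angle_beta  %.4f", 90),
             sprintf("_cell.angle_gamma %.4f", cell$gamma),
             sprintf("_symmetry.space_group_name_H-M '%s'", cell$group),
             "#")
  }
  if (!is.null(symops)) {
    hdr <- c(hdr, "loop_", "_space_group_symop.id",
             "_space_group_symop.operation_xyz",
             sprintf("%d '%s'", seq_along(symops), symops), "#")
  }
  ## canonical PDBx/mmCIF atom_site layout (21 items, as deposited files use)
  cols <- c("loop_",
            "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
            "_atom_site.label_atom_id", "_atom_site.label_alt_id",
            "_atom_site.label_comp_id", "_atom_site.label_asym_id",
            "_atom_site.label_entity_id", "_atom_site.label_seq_id",
            "_atom_site.pdbx_PDB_ins_code",
            "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
            "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
            "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
            "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
            "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain,
    a$resno, a$x, a$y, a$z, a$occ, a$b, a$resno, a$resid, a$chain, a$elety)
  c(hdr, cols, rows, "#")
}

#' Read an AlphaFold-style score sidecar
#'
#' Accepts two JSON dialects: per-model component scores
#' (`{"model_1": {"iptm": 0.8, "ptm": 0.7, "relaxed": true}}`) or a
#' precombined ranking-style map (`{"iptm+ptm": {"model_1": 0.76}}`). The
#' combined model-confidence score is `0.8*iptm + 0.2*ptm`; precombined
#' values are passed through. Models without a `relaxed` flag are treated as
#' relaxed.
#'
#' @param path JSON file path.
#' @return a `score_sidecar`: data.frame with columns `model`, `iptm`,
#'   `ptm`, `combined`, `relaxed`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path)
  rows <- list()
  if (!is.null(js[["iptm+ptm"]])) {
    pre <- js[["iptm+ptm"]]
    rel <- js[["relaxed"]]
    for (nm in names(pre)) {
      rows[[nm]] <- data.frame(model = nm, iptm = NA_real_, ptm = NA_real_,
                               combined = as.numeric(pre[[nm]]),
                               relaxed = if (!is.null(rel[[nm]]))
                                 isTRUE(rel[[nm]]) else TRUE,
                               stringsAsFactors = FALSE)
    }
  } else {
    for (nm in names(js)) {
      e <- js[[nm]]
      if (!is.list(e)) next
      iptm <- as.numeric(e$iptm); ptm <- as.numeric(e$ptm)
      comb <- if (!is.null(e[["iptm+ptm"]])) as.numeric(e[["iptm+ptm"]])
              else combined_score(iptm, ptm)
      rows[[nm]] <- data.frame(model = nm,
                               iptm = if (length(iptm)) iptm else NA_real_,
                               ptm = if (length(ptm)) ptm else NA_real_,
                               combined = comb,
                               relaxed = if (!is.null(e$relaxed))
                                 isTRUE(e$relaxed) else TRUE,
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no model scores found in ", path)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- !is.na(out$combined) & (out$combined < 0 | out$combined > 1)
  bad <- bad | (!is.na(out$iptm) & (out$iptm < 0 | out$iptm > 1))
  bad <- bad | (!is.na(out$ptm) & (out$ptm < 0 | out$ptm > 1))
  if (any(bad)) stop("score outside [0,1] for model(s): ",
                     paste(out$model[bad], collapse = ", "))
  class(out) <- c("score_sidecar", class(out))
  out
}

#' Weighted model-confidence score for complex predictions
#'
#' `0.8*iptm + 0.2*ptm`, the standard interface-weighted confidence used to
#' rank multimer predictions.
#' @param iptm,ptm numeric in `[0, 1]`.
#' @export
combined_score <- function(iptm, ptm) 0.8 * iptm + 0.2 * ptm

#' Look up one model's score entry
#' @param scores a `score_sidecar` from [read_scores()].
#' @param model model name.
#' @return one-row data.frame.
#' @export
score_entry <- function(scores, model) {
  i <- match(model, scores$model)
  if (is.na(i)) stop("model not present in sidecar: ", model)
  scores[i, , drop = FALSE]
}

#' Write a score sidecar (component dialect)
#' @param scores data.frame with `model`, `iptm`, `ptm`, `relaxed`.
#' @param path output JSON path.
#' @export
write_scores <- function(scores, path) {
  out <- list()
  for (i in seq_len(nrow(scores))) {
    out[[scores$model[i]]] <- list(iptm = scores$iptm[i], ptm = scores$ptm[i],
                                   relaxed = isTRUE(scores$relaxed[i]))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a domain FASTA (domains separated by line breaks)
#'
#' One record per chain; each domain's sequence is placed on its own line so
#' that line breaks encode the domain boundaries.
#'
#' @param model a [structure_model].
#' @param partition a `domain_partition` (see [merge_to_domains()]).
#' @param path output path.
#' @param name record name.
#' @export
write_domain_fasta <- function(model, partition, path, name = "protein") {
  ch <- chain_ids(model)[1]
  seq1 <- strsplit(chain_sequence(model, ch), "")[[1]]
  rn <- chain_resnos(model, ch)
  lines <- paste0(">", name)
  for (i in seq_len(nrow(partition$intervals))) {
    iv <- partition$intervals[i, ]
    lines <- c(lines, paste(seq1[rn >= iv$start & rn <= iv$end], collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a domain FASTA back into intervals
#'
#' @param path FASTA path where line breaks separate domains.
#' @return list with `name`, `sequence` (concatenated) and `intervals`
#'   data.frame (start, end, 1-based inclusive).
#' @export
read_domain_fasta <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- grep("^>", ln)
  if (!length(hdr)) stop("not a FASTA file: ", path)
  name <- sub("^>\\s*", "", ln[hdr[1]])
  segs <- ln[(hdr[1] + 1):(if (length(hdr) > 1) hdr[2] - 1 else length(ln))]
  lens <- nchar(segs)
  ends <- cumsum(lens)
  starts <- c(1, head(ends, -1) + 1)
  list(name = name, sequence = paste(segs, collapse = ""),
       intervals = data.frame(start = starts, end = ends))
}
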
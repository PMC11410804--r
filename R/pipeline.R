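## Pipeline driver: runs domains -> detection -> filtering -> clustering ->
## pair ranking -> assembly -> cell extraction -> emission on a directory of
## oligomer models with score sidecars, with structured per-stage logging.

log_line <- function(log, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%H:%M:%S")),
             list(...))
  c(log, list(entry))
}

#' Run the full assembly pipeline on a fixture/prediction directory
#'
#' Expects `<input_dir>` to contain oligomer coordinate models (`*.cif` or
#' `*.pdb`), a `scores.json` sidecar whose model names match the file stems,
#' and optionally `monomer.cif` (used by the domain stage and the p1 route;
#' p1 additionally expects `het*.cif` heterodimers). Stages run in order;
#' the pipeline stops with an explicit reason when no symmetry complex
#' survives, when only one axis cluster is found, or when a termination
#' condition fires — no lattice is emitted in that case.
#'
#' @param config a [default_config()] list (`mode` selects the route).
#' @param input_dir input directory.
#' @param output_dir output directory (created); lattice and tile mmCIF,
#'   `report.json`, `symplot.tsv`, `pipeline.log.jsonl` and the domain
#'   products are written here.
#' @return invisible list: `status` (`"ok"`/`"stopped"`), `reason`,
#'   `lattice` (a `lattice_model` or NULL), `report` (the report list).
#' @export
run_pipeline <- function(config, input_dir, output_dir) {
  stopifnot(dir.exists(input_dir))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  finish <- function(status, reason, lattice = NULL, extra = list()) {
    report <- c(list(status = status, reason = reason,
                     config = unclass(config)), extra)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(vapply(log, function(e)
      jsonlite::toJSON(e, auto_unbox = TRUE), character(1)),
      file.path(output_dir, "pipeline.log.jsonl"))
    invisible(list(status = status, reason = reason, lattice = lattice,
                   report = report))
  }
  ## ---- domain stage (optional monomer) ----
  monomer_path <- file.path(input_dir, "monomer.cif")
  partition <- NULL
  if (file.exists(monomer_path)) {
    monomer <- read_structure(monomer_path)
    monomer <- assign_sse(monomer)
    partition <- identify_domains(monomer, config)
    write_domain_fasta(monomer, partition,
                       file.path(output_dir, "domains.fasta"))
    write_domain_report(monomer, partition,
                        file.path(output_dir, "domains.tsv"))
    log <- log_line(log, "domains", n_domains = nrow(partition$intervals))
    if (nrow(partition$intervals) > 1) {
      sub <- make_subchains(partition, config = config)
      utils::write.table(sub, file.path(output_dir, "subchains.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      log <- log_line(log, "subchains", n = nrow(sub))
    }
  }
  ## ---- p1 route ----
  if (config$mode == "p1") {
    if (is.null(partition))
      return(finish("stopped", "p1_needs_monomer"))
    het_files <- list.files(input_dir, pattern = "^het.*\\.(cif|pdb)$",
                            full.names = TRUE)
    scores <- read_scores(file.path(input_dir, "scores.json"))
    hets <- lapply(het_files, function(p) {
      nm <- tools::file_path_sans_ext(basename(p))
      scored_oligomer(read_structure(p), score_entry(scores, nm),
                      subchain_id = nm, hetero = TRUE)
    })
    log <- log_line(log, "p1_heterodimers", n = length(hets))
    lat <- tryCatch(assemble_p1(monomer, hets, config), error = function(e) e)
    if (inherits(lat, "error"))
      return(finish("stopped", conditionMessage(lat)))
    emit_lattice(lat, file.path(output_dir, "lattice.cif"))
    log <- log_line(log, "emit", cell_a = lat$cell$a, cell_b = lat$cell$b)
    return(finish("ok", NULL, lat, list(cell = unclass(lat$cell))))
  }
  ## ---- read oligomers + scores ----
  files <- list.files(input_dir, pattern = "\\.(cif|pdb)$", full.names = TRUE)
  files <- files[!grepl("monomer|lattice|tile", basename(files))]
  if (!length(files)) return(finish("stopped", "no_input_models"))
  scores <- read_scores(file.path(input_dir, "scores.json"))
  oligs <- list()
  for (p in files) {
    nm <- tools::file_path_sans_ext(basename(p))
    if (!nm %in% scores$model) next
    oligs[[nm]] <- scored_oligomer(read_structure(p), score_entry(scores, nm),
                                   subchain_id = nm)
  }
  log <- log_line(log, "read", n_models = length(oligs))
  ## ---- detect + filter ----
  mode <- if (config$mode == "capsid") "capsid" else "layer"
  complexes <- list(); reject <- list()
  for (nm in names(oligs)) {
    cx <- detect_symmetry(oligs[[nm]], mode, config)
    if (is_rejected(cx)) { reject[[nm]] <- cx$reason; next }
    fo <- apply_filters(oligs[[nm]], config)
    if (!fo$passed) { reject[[nm]] <- paste(fo$reasons, collapse = ","); next }
    complexes[[nm]] <- cx
  }
  log <- log_line(log, "detect", n_in = length(oligs),
                  n_complexes = length(complexes),
                  rejected = if (length(reject)) reject else NULL)
  if (!length(complexes))
    return(finish("stopped", "no_symmetry_complexes"))
  write_symplot(complexes, file.path(output_dir, "symplot.tsv"))
  ## ---- cluster ----
  igr <- build_graph(complexes, config)
  clusters <- louvain_partition(igr, config$louvain_seed, config)
  log <- log_line(log, "cluster", n_clusters = length(clusters))
  prov <- lapply(clusters, function(cl) list(
    consensus_order = cl$consensus_order,
    members = vapply(cl$members, function(cx) cx$oligomer$subchain_id,
                     character(1))))
  ## ---- rank pairs + assemble ----
  pairs <- tryCatch(rank_pairs(clusters), error = function(e) e)
  if (inherits(pairs, "one_axis_only"))
    return(finish("stopped", "one_axis_only", extra = list(clusters = prov)))
  if (inherits(pairs, "error"))
    return(finish("stopped", conditionMessage(pairs)))
  last_reason <- "no_pair_assembled"
  for (r in seq_len(nrow(pairs))) {
    ca <- clusters[[pairs$cluster_a[r]]]$members[[pairs$member_a[r]]]
    cb <- clusters[[pairs$cluster_b[r]]]$members[[pairs$member_b[r]]]
    if (mode == "capsid") {
      tile <- tryCatch(assemble_capsid_tile(ca, cb, config),
                       error = function(e) e)
      if (inherits(tile, "error")) { last_reason <- conditionMessage(tile); next }
      write_structure(tile_model(tile), file.path(output_dir, "tile.cif"))
      log <- log_line(log, "capsid_tile",
                      inter_axis_angles = tile$inter_axis_angles)
      return(finish("ok", NULL, NULL,
                    list(inter_axis_angles = tile$inter_axis_angles,
                         clusters = prov)))
    }
    lat <- tryCatch(assemble_lattice(ca, cb, config), error = function(e) e)
    if (inherits(lat, "assembly_termination") &&
        "collinear_needs_second_axis" %in% lat$reasons) {
      ## p2: augment with the best cluster outside this pair
      others <- setdiff(seq_along(clusters),
                        c(pairs$cluster_a[r], pairs$cluster_b[r]))
      if (length(others)) {
        cb2 <- clusters[[others[1]]]$representative
        lat <- tryCatch(assemble_lattice(ca, cb, config, complex_b2 = cb2),
                        error = function(e) e)
      }
    }
    if (inherits(lat, "lattice_model")) {
      emit_lattice(lat, file.path(output_dir, "lattice.cif"))
      write_structure(tile_model(lat$tile), file.path(output_dir, "tile.cif"))
      log <- log_line(log, "assemble", pair = r,
                      quality = lat$scores$score_quality)
      return(finish("ok", NULL, lat,
                    list(cell = unclass(lat$cell), scores = lat$scores,
                         clusters = prov, pair_rank = r)))
    }
    last_reason <- if (inherits(lat, "assembly_termination"))
      paste(lat$reasons, collapse = ",") else conditionMessage(lat)
    log <- log_line(log, "assemble_failed", pair = r, reason = last_reason)
  }
  finish("stopped", last_reason, extra = list(clusters = prov))
}

#' Write the symmetry-complex scatter table (TSV)
#'
#' One row per accepted symmetry complex: subchain, molecule count, deduced
#' axis order, filled fraction, and combined score — the data behind the
#' score-vs-order scatter used to survey candidate axes.
#'
#' @param complexes list of `symmetry_complex` objects.
#' @param path output TSV path.
#' @export
write_symplot <- function(complexes, path) {
  rows <- lapply(complexes, function(cx) data.frame(
    subchain = cx$oligomer$subchain_id, n_copies = cx$oligomer$n_copies,
    order = cx$axis$order_k, filled = cx$axis$filled,
    score = cx$oligomer$score$combined))
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scatter plot of symmetry complexes (score vs axis order)
#'
#' @param symplot data.frame from [write_symplot()]'s TSV (or the same
#'   structure built in memory).
#' @param ... passed to [graphics::plot()].
#' @export
plot_symplot <- function(symplot, ...) {
  graphics::plot(symplot$order, symplot$score, cex = 1 + 2 * symplot$filled,
                 pch = 21, bg = grDevices::hcl.colors(
                   max(3, length(unique(symplot$subchain))))[
                     as.integer(factor(symplot$subchain))],
                 xlab = "axis order (k-fold)", ylab = "ipTM+pTM score",
                 ylim = c(0, 1), xaxt = "n", ...)
  graphics::axis(1, at = sort(unique(symplot$order)))
  invisible(symplot)
}
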
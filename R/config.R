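## Pipeline configuration: every threshold used by a stage lives here so the
## whole parameterization is auditable in one place and serializable into
## every output report.

#' Default pipeline configuration
#'
#' @param mode `"layer"` (orders 2/3/4/6, flat lattice), `"p1"` (heterodimer
#'   route) or `"capsid"` (adds 5-fold axes, no axis re-parallelization).
#' @param ... named overrides of any config key.
#' @return named list of class `pipeline_config`.
#'
#' @details Keys and defaults:
#' * `min_score_prefilter` 0.3 — homodimer predictability gate.
#' * `min_score_symmetry` 0.20 — symmetry-complex score gate (inclusive).
#' * `angle_tol` 10 — max deviation (deg) of the observed inter-monomer
#'   angle from 360/k.
#' * `dev_monomer_max` 5 — max per-monomer axis deviation, Angstrom.
#' * `screw_tol` 3 — max screw shift per step (Angstrom) in layer mode;
#'   unlimited in capsid mode.
#' * `clash_allowance` 0.6 — vdW overlap allowance for a clash, Angstrom.
#' * `clash_global_relaxed` 3.0 / `clash_global_unrelaxed` 60.0 — clashes
#'   per 100 aa at or above which a model is excluded.
#' * `clash_window_relaxed` 6.0 / `clash_window_unrelaxed` 120.0 — clashes
#'   per 100 aa allowed (inclusive) in any 200-aa window.
#' * `clash_window_len` 200 — window length, residues.
#' * `beta_max` 0.25 — max fraction of residues in intermolecular beta
#'   pairing.
#' * `contact_cutoff` 5 — residue-contact distance, Angstrom.
#' * `d_cap` 10 — interface-distogram distance cap, Angstrom.
#' * `w_min` 0.2 — minimum interface-correlation edge weight.
#' * `louvain_seed` 17 — community-detection seed.
#' * `k_link` 8 — contacts required to crosslink consecutive secondary
#'   structure segments into one subsection.
#' * `tau_merge` 0.08 — domain-merge saturation threshold.
#' * `min_domain_len` 25 — minimum domain length, residues.
#' * `subchain_min_len` 120 / `subchain_max_len` 1200 — subchain clamp.
#' * `gap_max` 5 — max overlap RMSD (Angstrom) when connecting complexes.
#' * `tilt_max` 45 — max B-axis tilt, degrees (termination strictly above).
#' * `dev_cell_max` 0.10 — max relative lattice-constant deviation.
#' * `rigid_max` 2.5 — max median intra-monomer RMSD, Angstrom.
#' @export
default_config <- function(mode = c("layer", "p1", "capsid"), ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode,
    min_score_prefilter = 0.3,
    min_score_symmetry = 0.20,
    allowed_orders = if (mode == "capsid") c(2, 3, 4, 5, 6) else c(2, 3, 4, 6),
    angle_tol = 10,
    dev_monomer_max = 5,
    screw_tol = 3,
    clash_allowance = 0.6,
    clash_global_relaxed = 3.0,
    clash_global_unrelaxed = 60.0,
    clash_window_relaxed = 6.0,
    clash_window_unrelaxed = 120.0,
    clash_window_len = 200,
    beta_max = 0.25,
    contact_cutoff = 5,
    d_cap = 10,
    w_min = 0.2,
    louvain_seed = 17,
    k_link = 8,
    tau_merge = 0.08,
    min_domain_len = 25,
    subchain_min_len = 120,
    subchain_max_len = 1200,
    gap_max = 5,
    tilt_max = 45,
    dev_cell_max = 0.10,
    rigid_max = 2.5,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file; keys override [default_config()] values.
#' @param mode pipeline mode (overridden by a `mode` key in the file).
#' @export
read_config <- function(path, mode = "layer") {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$mode)) { mode <- vals$mode; vals$mode <- NULL }
  do.call(default_config, c(list(mode = mode), vals))
}

#' Write a pipeline configuration to YAML
#' @param cfg a `pipeline_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config (mode:", x$mode, ")\n")
  for (nm in setdiff(names(x), "mode"))
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
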
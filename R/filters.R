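## Model-quality gates: confidence score, global and windowed steric-clash
## limits, intermolecular beta-strand content, and interface existence.

#' Count intermolecular steric clashes
#'
#' A clash is an inter-chain heavy-atom pair closer than
#' `r_i + r_j - allowance` (vdW radii from [vdw_radii], allowance 0.6 A by
#' default). The windowed maximum scans every contiguous `window_len`-residue
#' sequence window of each chain.
#'
#' @param oligomer a [scored_oligomer] or [structure_model].
#' @param config a [default_config()] list.
#' @param full_length full protein chain length in residues; defaults to the
#'   longest chain in the model plus the oligomer's residue offset.
#' @return a `clash_report`: list with `n_clashes`, `n_res`, `per_window`,
#'   `relaxed`, and `pairs` (data.frame of clashing residue pairs).
#' @export
count_clashes <- function(oligomer, config = default_config(),
                          full_length = NULL) {
  model <- if (inherits(oligomer, "scored_oligomer")) oligomer$model else oligomer
  relaxed <- if (inherits(oligomer, "scored_oligomer"))
    isTRUE(oligomer$score$relaxed) else TRUE
  offset <- if (inherits(oligomer, "scored_oligomer"))
    oligomer$residue_offset else 0L
  a <- model$atoms[!model$atoms$hydrogen, ]
  ch <- unique(a$chain)
  if (is.null(full_length))
    full_length <- max(vapply(ch, function(c1)
      length(unique(a$resno[a$chain == c1])), integer(1))) + offset
  pairs <- list(); np <- 0
  for (i in seq_along(ch)) {
    ai <- a[a$chain == ch[i], ]
    Xi <- as.matrix(ai[, c("x", "y", "z")])
    ri <- vdw_radius(ai$element)
    for (j in seq_along(ch)) {
      if (j <= i) next
      aj <- a[a$chain == ch[j], ]
      Xj <- as.matrix(aj[, c("x", "y", "z")])
      ## bounding-box prefilter: skip far-apart chain pairs
      if (any(apply(Xi, 2, min) > apply(Xj, 2, max) + 4) ||
          any(apply(Xj, 2, min) > apply(Xi, 2, max) + 4)) next
      rj <- vdw_radius(aj$element)
      thr <- outer(ri, rj, "+") - config$clash_allowance
      D2 <- dist2_matrix(Xi, Xj)
      hit <- which(D2 < thr^2, arr.ind = TRUE)
      if (nrow(hit)) {
        np <- np + 1
        pairs[[np]] <- data.frame(chain_i = ch[i], res_i = ai$resno[hit[, 1]],
                                  chain_j = ch[j], res_j = aj$resno[hit[, 2]],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (np) do.call(rbind, pairs) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer())
  n_clashes <- nrow(pairs)
  ## windowed max over contiguous sequence windows of each chain
  wlen <- config$clash_window_len
  per_window <- 0L
  if (n_clashes) {
    for (c1 in ch) {
      res_hits <- c(pairs$res_i[pairs$chain_i == c1],
                    pairs$res_j[pairs$chain_j == c1])
      if (!length(res_hits)) next
      rn <- sort(unique(a$resno[a$chain == c1]))
      for (s in rn) {
        cnt <- sum(res_hits >= s & res_hits <= s + wlen - 1)
        if (cnt > per_window) per_window <- cnt
      }
    }
  }
  structure(list(n_clashes = n_clashes, n_res = full_length,
                 per_window = per_window, relaxed = relaxed, pairs = pairs),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash_report: %d clashes / %d res (%.2f per 100aa), window max %d (%s)\n",
              x$n_clashes, x$n_res, 100 * x$n_clashes / x$n_res, x$per_window,
              if (x$relaxed) "relaxed" else "unrelaxed"))
  invisible(x)
}

#' Confidence-score gate
#'
#' The prefilter stage passes combined scores of at least 0.3 (homodimer
#' predictability); the symmetry stage passes scores of at least 0.20, both
#' inclusive at the threshold.
#'
#' @param score combined model-confidence score in `[0, 1]`.
#' @param stage `"prefilter"` or `"symmetry"`.
#' @param config a [default_config()] list.
#' @return logical.
#' @export
score_gate <- function(score, stage = c("prefilter", "symmetry"),
                       config = default_config()) {
  stage <- match.arg(stage)
  stopifnot(score >= 0, score <= 1)
  thr <- if (stage == "prefilter") config$min_score_prefilter
         else config$min_score_symmetry
  score >= thr
}

#' Steric-clash gate
#'
#' Relaxed models are excluded at 3.0 or more clashes per 100 aa globally
#' (exclusive-at-threshold: exactly 3.0 fails), and when any 200-aa window
#' holds more than 6.0 clashes per 100 aa (inclusive-at-threshold: exactly
#' 6.0 passes). Unrelaxed thresholds are 60.0 and 120.0 per 100 aa.
#'
#' @param report a `clash_report` from [count_clashes()].
#' @param config a [default_config()] list.
#' @return list with `passed` and `reasons` (subset of
#'   `{global_clash, window_clash}`).
#' @export
clash_gate <- function(report, config = default_config()) {
  glim <- if (report$relaxed) config$clash_global_relaxed
          else config$clash_global_unrelaxed
  wlim <- if (report$relaxed) config$clash_window_relaxed
          else config$clash_window_unrelaxed
  reasons <- character()
  rate <- 100 * report$n_clashes / report$n_res
  if (rate >= glim) reasons <- c(reasons, "global_clash")
  wmax_allowed <- wlim * config$clash_window_len / 100
  if (report$per_window > wmax_allowed) reasons <- c(reasons, "window_clash")
  list(passed = length(reasons) == 0, reasons = reasons)
}

#' Intermolecular beta-strand gate
#'
#' Fails models in which the fraction of residues participating in
#' inter-chain beta bridges exceeds `beta_max` — the signature of a chain
#' passing incorrectly through the neighboring molecule.
#'
#' @param oligomer a [scored_oligomer] or [structure_model] (SSE assigned or
#'   assignable).
#' @param config a [default_config()] list.
#' @return list with `passed` and `fraction`.
#' @export
beta_gate <- function(oligomer, config = default_config()) {
  model <- if (inherits(oligomer, "scored_oligomer")) oligomer$model else oligomer
  n_total <- nrow(unique(model$atoms[, c("chain", "resno")]))
  inter <- interchain_beta_residues(model)
  f <- length(inter) / n_total
  list(passed = f <= config$beta_max, fraction = f)
}

#' Apply all quality gates to a scored oligomer
#'
#' Evaluates the symmetry-stage score gate, the global and windowed clash
#' gates, the intermolecular beta-strand gate, and interface existence
#' (at least one inter-chain residue contact at the contact cutoff). All
#' gates are evaluated — no short-circuiting — so the reason list is
#' complete.
#'
#' @param oligomer a [scored_oligomer].
#' @param config a [default_config()] list.
#' @return a `filter_outcome`: list with `passed` and `reasons` (subset of
#'   `{low_score, global_clash, window_clash, beta_strand, no_interface}`).
#' @export
apply_filters <- function(oligomer, config = default_config()) {
  reasons <- character()
  if (!score_gate(oligomer$score$combined, "symmetry", config))
    reasons <- c(reasons, "low_score")
  cg <- clash_gate(count_clashes(oligomer, config), config)
  reasons <- c(reasons, cg$reasons)
  if (!beta_gate(oligomer, config)$passed)
    reasons <- c(reasons, "beta_strand")
  if (!has_interface(oligomer$model, config))
    reasons <- c(reasons, "no_interface")
  structure(list(passed = length(reasons) == 0, reasons = reasons),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  if (x$passed) cat("filter_outcome: passed\n")
  else cat("filter_outcome: failed:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

## at least one inter-chain residue contact at the contact cutoff
has_interface <- function(model, config = default_config()) {
  ch <- chain_ids(model)
  for (i in seq_along(ch)) for (j in seq_along(ch)) {
    if (j <= i) next
    n <- suppressWarnings(contact_count(
      model, residue_selection(model, chain = ch[i]),
      residue_selection(model, chain = ch[j]), cutoff = config$contact_cutoff))
    if (n >= 1) return(TRUE)
  }
  FALSE
}
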
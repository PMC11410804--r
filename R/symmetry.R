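## Rotational symmetry detection: pairwise chain superpositions, consensus
## axis fitting, and k-fold order classification with partial representations
## (m <= k copies of a k-fold axis).

#' A scored oligomer model
#'
#' Couples a coordinate model with its confidence score and subchain
#' provenance. All chains must share one sequence (homo-oligomer), except in
#' the p1 heterodimer route.
#'
#' @param model a [structure_model] with >= 2 chains.
#' @param score one-row score entry (see [score_entry()]), or a numeric
#'   combined score.
#' @param subchain_id provenance tag (e.g. `"full"`, `"no_nterm"`).
#' @param residue_offset integer added to model residue numbers to recover
#'   full-length numbering.
#' @param hetero allow non-identical chain sequences (p1 heterodimers).
#' @return object of class `scored_oligomer`.
#' @export
scored_oligomer <- function(model, score, subchain_id = "full",
                            residue_offset = 0L, hetero = FALSE) {
  ch <- chain_ids(model)
  if (length(ch) < 2) stop("oligomer needs >= 2 chains")
  if (!hetero) {
    seqs <- vapply(ch, function(c1) chain_sequence(model, c1), character(1))
    if (length(unique(seqs)) != 1)
      stop("chains are not sequence-identical; use hetero = TRUE for the p1 route")
  }
  if (is.numeric(score))
    score <- data.frame(model = "model", iptm = NA_real_, ptm = NA_real_,
                        combined = score, relaxed = TRUE)
  structure(list(model = model, n_copies = length(ch), score = score,
                 subchain_id = subchain_id,
                 residue_offset = as.integer(residue_offset)),
            class = "scored_oligomer")
}

#' @export
print.scored_oligomer <- function(x, ...) {
  cat(sprintf("scored_oligomer: %d copies, subchain %s, score %.3f (%s)\n",
              x$n_copies, x$subchain_id, x$score$combined,
              if (isTRUE(x$score$relaxed)) "relaxed" else "unrelaxed"))
  invisible(x)
}

#' Rotation relating two chains of an oligomer
#'
#' Superposes chain `chain_i` onto chain `chain_j` on CA atoms matched by
#' residue number and decomposes the transform into a screw motion.
#'
#' @param oligomer a [scored_oligomer] or [structure_model].
#' @param chain_i,chain_j chain ids.
#' @return list with `angle` (deg, in (0, 180]), `direction` (unit axis),
#'   `anchor` (point on axis), `screw_shift` (Angstrom) and `rmsd`.
#' @export
pairwise_rotation <- function(oligomer, chain_i, chain_j) {
  model <- if (inherits(oligomer, "scored_oligomer")) oligomer$model else oligomer
  ci <- ca_coords(model, chain_i); cj <- ca_coords(model, chain_j)
  shared <- intersect(rownames(ci), rownames(cj))
  if (length(shared) < 3) stop("fewer than 3 matched CA atoms between chains ",
                               chain_i, " and ", chain_j)
  k <- kabsch(cj[shared, , drop = FALSE], ci[shared, , drop = FALSE])
  sd <- screw_decompose(k$transform)
  c(sd, list(rmsd = k$rmsd))
}

## rotation angle between two chains from an all-heavy-atom superposition
## (atoms matched by residue number and atom name); more noise-tolerant
## than the CA-only fit used for axis direction extraction
heavy_rotation_angle <- function(model, chain_i, chain_j) {
  a <- model$atoms[!model$atoms$hydrogen, ]
  ai <- a[a$chain == chain_i, ]; aj <- a[a$chain == chain_j, ]
  ki <- paste(ai$resno, ai$elety); kj <- paste(aj$resno, aj$elety)
  shared <- intersect(ki, kj)
  xi <- as.matrix(ai[match(shared, ki), c("x", "y", "z")])
  xj <- as.matrix(aj[match(shared, kj), c("x", "y", "z")])
  rotation_angle(kabsch(xj, xi)$transform$rotation)
}

## canonical sign: axis z-component non-negative (then x, then y)
orient_axis <- function(u) {
  s <- sign(u[3])
  if (abs(u[3]) < 1e-9) s <- sign(u[1])
  if (s == 0) s <- sign(u[2])
  if (s < 0) -u else u
}

## angular position of chain centroids around an axis
angular_order <- function(model, direction, anchor) {
  ch <- chain_ids(model)
  u <- direction / sqrt(sum(direction^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ang <- vapply(ch, function(c1) {
    v <- chain_centroid(model, c1) - anchor
    atan2(sum(v * e2), sum(v * e1))
  }, numeric(1))
  ord <- order(ang)
  list(chains = ch[ord], angles = ang[ord] * 180 / pi)
}

axis_rejection <- function(reason, detail = NULL) {
  structure(list(reason = reason, detail = detail), class = "axis_rejection")
}

#' @export
print.axis_rejection <- function(x, ...) {
  cat("axis rejected:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")") else "", "\n")
  invisible(x)
}

#' Test for a rejection result
#' @param x object returned by [classify_axis()] or [detect_symmetry()].
#' @export
is_rejected <- function(x) inherits(x, "axis_rejection")

#' Classify the rotational symmetry axis of an oligomer
#'
#' Fits a consensus axis to all pairwise chain-to-chain rotations, orders the
#' chains angularly around it, deduces the axis order k from the mean
#' successive inter-monomer angle (k = round(360 / delta_phi)), and verifies
#' axis uniformity: every monomer's CA centroid must lie within
#' `dev_monomer_max` of its predecessor's centroid rotated by 360/k.
#' Partial representations (m < k chains) are accepted and reported through
#' the `filled = m/k` fraction.
#'
#' @param oligomer a [scored_oligomer] or [structure_model].
#' @param allowed_orders admissible k values (layer: 2/3/4/6; capsid adds 5).
#' @param config a [default_config()] list (angle, deviation and screw
#'   tolerances).
#' @param check_screw enforce `screw_tol` (TRUE in layer mode).
#' @return a `symmetry_axis` object, or an `axis_rejection` with a reason
#'   code in `{few_chains, inconsistent_angle, order_not_allowed,
#'   deviation, screw}`.
#' @export
classify_axis <- function(oligomer, allowed_orders = c(2, 3, 4, 6),
                          config = default_config(), check_screw = TRUE) {
  model <- if (inherits(oligomer, "scored_oligomer")) oligomer$model else oligomer
  ch <- chain_ids(model)
  m <- length(ch)
  if (m < 2) return(axis_rejection("few_chains"))
  ## consensus direction: principal eigenvector of summed outer products of
  ## all ordered-pair axes (sign-invariant least squares)
  pr <- list(); M <- matrix(0, 3, 3); anchors <- NULL
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    p <- pairwise_rotation(model, ch[i], ch[j])
    pr[[paste(ch[i], ch[j])]] <- p
    M <- M + outer(p$direction, p$direction)
    anchors <- rbind(anchors, p$anchor)
  }
  u <- orient_axis(eigen(M, symmetric = TRUE)$vectors[, 1])
  anchor <- colMeans(anchors)
  anchor <- anchor - sum(anchor * u) * u
  ## angular chain order; successive sorted chains can be several symmetry
  ## steps apart (a partial ring spanning more than 180 degrees wraps in the
  ## angular sort), so each observed step is interpreted as a multiple of
  ## the elementary angle
  ao <- angular_order(model, u, anchor)
  steps <- list()
  for (i in seq_len(m - 1))
    steps[[i]] <- pairwise_rotation(model, ao$chains[i], ao$chains[i + 1])
  ang <- vapply(steps, `[[`, numeric(1), "angle")
  delta0 <- min(ang)                    # smallest gap = one elementary step
  kfit <- allowed_orders[which.min(abs(delta0 - 360 / allowed_orders))]
  if (abs(delta0 - 360 / kfit) > config$angle_tol || m > kfit)
    return(axis_rejection("order_not_allowed",
                          sprintf("delta_phi %.1f deg fits no allowed order", delta0)))
  mult <- pmax(1, round(ang / (360 / kfit)))
  if (any(abs(ang - mult * 360 / kfit) > config$angle_tol))
    return(axis_rejection("inconsistent_angle",
                          sprintf("step angles inconsistent with %d-fold", kfit)))
  ## refined elementary angle: all-heavy-atom rotation angles over every
  ## ordered chain pair, each read as its nearest step multiple
  est <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ang_ij <- heavy_rotation_angle(model, ch[i], ch[j])
    mp <- round(ang_ij / (360 / kfit))
    if (mp >= 1) est <- c(est, ang_ij / mp)
  }
  delta_phi <- mean(est)
  if (abs(delta_phi - 360 / kfit) > config$angle_tol)
    return(axis_rejection("inconsistent_angle",
                          sprintf("refined delta_phi %.1f deg off %d-fold", delta_phi, kfit)))
  ## per-monomer deviation: predecessor centroid rotated by the step
  ## multiple of 360/k about the consensus axis
  cents <- lapply(ao$chains, function(c1) chain_centroid(model, c1))
  dev <- numeric(m - 1)
  for (i in seq_len(m - 1)) {
    R <- rotation_about(u, mult[i] * 360 / kfit)
    img <- as.numeric(R %*% (cents[[i]] - anchor)) + anchor
    dev[i] <- sqrt(sum((cents[[i + 1]] - img)^2))
  }
  if (length(dev) && max(dev) > config$dev_monomer_max)
    return(axis_rejection("deviation",
                          sprintf("max per-monomer deviation %.2f A", max(dev))))
  screw <- mean(vapply(seq_along(steps), function(i)
    steps[[i]]$screw_shift / mult[i], numeric(1)))
  if (check_screw && abs(screw) > config$screw_tol)
    return(axis_rejection("screw", sprintf("screw shift %.2f A", screw)))
  structure(list(direction = u, anchor = anchor, order_k = kfit,
                 delta_phi = delta_phi, filled = m / kfit,
                 per_monomer_dev = dev, screw_shift = screw, m = m,
                 chain_order = ao$chains),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf(
    "symmetry_axis: %d-fold (filled %.2f), delta_phi %.2f deg, screw %.2f A\n",
    x$order_k, x$filled, x$delta_phi, x$screw_shift))
  cat(sprintf("  direction (%.3f, %.3f, %.3f), max monomer deviation %.3f A\n",
              x$direction[1], x$direction[2], x$direction[3],
              if (length(x$per_monomer_dev)) max(x$per_monomer_dev) else 0))
  invisible(x)
}

#' Detect a symmetry complex in a scored oligomer
#'
#' Runs [classify_axis()] with the mode's allowed orders (layer: 2/3/4/6;
#' capsid adds 5-fold and drops the screw restriction). The quality gates of
#' [apply_filters()] are applied separately by the pipeline.
#'
#' @param oligomer a [scored_oligomer].
#' @param mode `"layer"` or `"capsid"`.
#' @param config a [default_config()] list.
#' @return a `symmetry_complex` (oligomer + axis) or an `axis_rejection`.
#' @export
detect_symmetry <- function(oligomer, mode = c("layer", "capsid"),
                            config = default_config()) {
  mode <- match.arg(mode)
  allowed <- if (mode == "capsid") c(2, 3, 4, 5, 6) else c(2, 3, 4, 6)
  if (!is.null(config$allowed_orders) && config$mode == mode)
    allowed <- config$allowed_orders
  axis <- classify_axis(oligomer, allowed_orders = allowed, config = config,
                        check_screw = (mode == "layer"))
  if (is_rejected(axis)) return(axis)
  structure(list(oligomer = oligomer, axis = axis, interface = NULL),
            class = "symmetry_complex")
}

#' @export
print.symmetry_complex <- function(x, ...) {
  cat(sprintf("symmetry_complex: subchain %s, score %.3f\n",
              x$oligomer$subchain_id, x$oligomer$score$combined))
  print(x$axis)
  invisible(x)
}
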
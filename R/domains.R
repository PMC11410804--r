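## Structure-based domain segmentation: secondary-structure crosslinking into
## subsections, iterative contact-driven merging to saturation, and linker
## cropping; plus the five-subchain truncation scheme.

#' Initial domain subsections from local secondary-structure crosslinking
#'
#' Secondary-structure segments (maximal non-coil runs) are walked in
#' sequence order; consecutive segments sharing at least `k_link` residue
#' contacts (5 A cutoff) are merged into one subsection. Interstitial coil
#' is split at the midpoint between subsections.
#'
#' @param model a [structure_model] with SSE assigned (see [assign_sse()]).
#' @param config a [default_config()] list (`k_link`, `contact_cutoff`).
#' @param chain chain id (default: first chain).
#' @return data.frame of intervals (`start`, `end`; 1-based inclusive,
#'   covering the chain).
#' @export
initial_subsections <- function(model, config = default_config(),
                                chain = NULL) {
  if (is.null(chain)) chain <- chain_ids(model)[1]
  if (is.null(model$sse)) model <- assign_sse(model)
  lab <- model$sse[[chain]]
  rn <- as.integer(names(lab))
  in_sse <- lab != "C"
  if (!any(in_sse)) {
    warning("all-coil chain; one interval per chain")
    return(data.frame(start = min(rn), end = max(rn)))
  }
  ## maximal non-coil runs
  r <- rle(in_sse)
  stops <- cumsum(r$lengths); starts <- c(1, head(stops, -1) + 1)
  seg <- data.frame(start = rn[starts[r$values]], end = rn[stops[r$values]])
  ## crosslink consecutive segments by contact count
  grp <- 1; group <- integer(nrow(seg)); group[1] <- 1
  for (i in seq_len(nrow(seg))[-1]) {
    n <- contact_count(model,
                       residue_selection(model, chain = chain,
                                         resno = seg$start[i - 1]:seg$end[i - 1]),
                       residue_selection(model, chain = chain,
                                         resno = seg$start[i]:seg$end[i]),
                       cutoff = config$contact_cutoff)
    if (n < config$k_link) grp <- grp + 1
    group[i] <- grp
  }
  iv <- do.call(rbind, lapply(split(seg, group), function(s)
    data.frame(start = min(s$start), end = max(s$end))))
  ## extend intervals over interstitial coil (split at midpoints)
  iv <- iv[order(iv$start), , drop = FALSE]
  iv$start[1] <- min(rn); iv$end[nrow(iv)] <- max(rn)
  if (nrow(iv) > 1) {
    for (i in seq_len(nrow(iv) - 1)) {
      mid <- floor((iv$end[i] + iv$start[i + 1]) / 2)
      iv$end[i] <- mid; iv$start[i + 1] <- mid + 1
    }
  }
  rownames(iv) <- NULL
  iv
}

interval_len <- function(iv) iv$end - iv$start + 1

## merge score: contacts relative to the smaller partner's surface and length
merge_score <- function(contacts, surf_i, surf_j, len_i, len_j) {
  contacts / (sqrt(min(surf_i, surf_j)) * sqrt(min(len_i, len_j)))
}

#' Merge subsections into domains until saturation
#'
#' Greedy iterative merging: at each step the adjacent interval pair with
#' the highest merge score
#' `s = contacts / (sqrt(min(surface)) * sqrt(min(length)))` is fused; the
#' process stops when the best score drops below `tau_merge` (saturation).
#' Ties resolve to the lower start index, making the procedure
#' deterministic. Undersized intervals (below `min_domain_len`) are fused
#' into their more-contacting neighbor afterwards.
#'
#' @param model a [structure_model] with SSE assigned.
#' @param subsections data.frame of intervals from [initial_subsections()].
#' @param config a [default_config()] list.
#' @param chain chain id (default: first chain).
#' @return a `domain_partition`: list with `intervals` (data.frame start,
#'   end) and `chain`.
#' @export
merge_to_domains <- function(model, subsections, config = default_config(),
                             chain = NULL) {
  if (is.null(chain)) chain <- chain_ids(model)[1]
  iv <- subsections[order(subsections$start), , drop = FALSE]
  sel <- function(a, b) residue_selection(model, chain = chain, resno = a:b)
  surf <- vapply(seq_len(nrow(iv)), function(i)
    surface_area(model, sel(iv$start[i], iv$end[i])), numeric(1))
  repeat {
    if (nrow(iv) < 2) break
    s <- rep(-Inf, nrow(iv) - 1)
    for (i in seq_len(nrow(iv) - 1)) {
      n <- contact_count(model, sel(iv$start[i], iv$end[i]),
                         sel(iv$start[i + 1], iv$end[i + 1]),
                         cutoff = config$contact_cutoff)
      s[i] <- merge_score(n, surf[i], surf[i + 1],
                          interval_len(iv[i, ]), interval_len(iv[i + 1, ]))
    }
    best <- which.max(s)          # which.max takes the first (lowest start)
    if (s[best] < config$tau_merge) break
    iv$end[best] <- iv$end[best + 1]
    iv <- iv[-(best + 1), , drop = FALSE]
    tailsurf <- if (best + 2 <= length(surf)) surf[(best + 2):length(surf)]
                else numeric()
    surf <- c(surf[seq_len(best - 1)],
              surface_area(model, sel(iv$start[best], iv$end[best])),
              tailsurf)
  }
  ## fold undersized intervals into the neighbor they contact most
  repeat {
    small <- which(interval_len(iv) < config$min_domain_len)
    if (!length(small) || nrow(iv) < 2) break
    i <- small[1]
    nb <- c(if (i > 1) i - 1, if (i < nrow(iv)) i + 1)
    cn <- vapply(nb, function(j) contact_count(
      model, sel(iv$start[i], iv$end[i]), sel(iv$start[j], iv$end[j]),
      cutoff = config$contact_cutoff), numeric(1))
    j <- nb[which.max(cn)]
    lo <- min(i, j); hi <- max(i, j)
    iv$end[lo] <- iv$end[hi]
    iv <- iv[-hi, , drop = FALSE]
    surf <- NULL  # lengths changed; surfaces no longer needed here
  }
  rownames(iv) <- NULL
  structure(list(intervals = iv, chain = chain), class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("domain_partition: %d domain(s) on chain %s\n",
              nrow(x$intervals), x$chain))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %d: %d-%d (%d aa)\n", i, x$intervals$start[i],
                x$intervals$end[i], interval_len(x$intervals[i, ])))
  invisible(x)
}

#' Refine domain boundaries by linker cropping
#'
#' For each domain boundary, candidate cut points are scanned across the
#' coil stretch containing the boundary; the cut minimizing the residue
#' contacts crossing it is chosen (ties resolve to the candidate nearest the
#' stretch midpoint).
#'
#' @param model a [structure_model] with SSE assigned.
#' @param partition a `domain_partition` with >= 2 domains.
#' @param config a [default_config()] list.
#' @return the cropped `domain_partition`.
#' @export
crop_linkers <- function(model, partition, config = default_config()) {
  iv <- partition$intervals
  if (nrow(iv) < 2) stop("crop_linkers needs >= 2 domains")
  chain <- partition$chain
  lab <- model$sse[[chain]]
  rn <- as.integer(names(lab))
  sel <- function(a, b) residue_selection(model, chain = chain, resno = a:b)
  for (b in seq_len(nrow(iv) - 1)) {
    bound <- iv$end[b]
    ## maximal coil run containing the boundary
    is_c <- lab == "C"
    i0 <- match(bound, rn)
    if (is.na(i0) || !is_c[i0]) {
      ## boundary not in coil: look one residue right
      i0 <- match(bound + 1, rn)
      if (is.na(i0) || !is_c[i0]) next        # zero-length linker
    }
    lo <- i0; while (lo > 1 && is_c[lo - 1]) lo <- lo - 1
    hi <- i0; while (hi < length(rn) && is_c[hi + 1]) hi <- hi + 1
    cand <- rn[lo:hi]
    cand <- cand[cand >= iv$start[b] & cand < iv$end[b + 1]]
    if (!length(cand)) next
    cross <- vapply(cand, function(cut) contact_count(
      model, sel(iv$start[b], cut), sel(cut + 1, iv$end[b + 1]),
      cutoff = config$contact_cutoff), numeric(1))
    mins <- cand[cross == min(cross)]
    mid <- (min(cand) + max(cand)) / 2
    cut <- mins[which.min(abs(mins - mid))]
    iv$end[b] <- cut; iv$start[b + 1] <- cut + 1
  }
  partition$intervals <- iv
  partition
}

#' Convenience wrapper: full domain identification
#'
#' [assign_sse()] + [initial_subsections()] + [merge_to_domains()] +
#' [crop_linkers()] on one chain.
#' @inheritParams initial_subsections
#' @return a `domain_partition`.
#' @export
identify_domains <- function(model, config = default_config(), chain = NULL) {
  if (is.null(model$sse)) model <- assign_sse(model)
  ss <- initial_subsections(model, config, chain)
  part <- merge_to_domains(model, ss, config, chain)
  if (nrow(part$intervals) >= 2) part <- crop_linkers(model, part, config)
  part
}

#' The five-subchain truncation scheme
#'
#' For a multi-domain protein, generates the full-length sequence, the chain
#' without the N-terminal domain, the chain without the C-terminal domain,
#' the first third of the domains and the last third of the domains
#' (third = ceiling(D/3) domains). Interval lengths are clamped to
#' `[subchain_min_len, subchain_max_len]` by extending or trimming toward
#' the anchored end; duplicate intervals collapse with a warning.
#'
#' @param partition a `domain_partition`.
#' @param chain_len chain length (defaults to the partition span).
#' @param config a [default_config()] list.
#' @return data.frame with `id`, `start`, `end`, `n_domains`; a
#'   single-domain protein yields only the full-length spec, flagged by the
#'   `single_domain` attribute.
#' @export
make_subchains <- function(partition, chain_len = NULL,
                           config = default_config()) {
  iv <- partition$intervals
  D <- nrow(iv)
  lo <- min(iv$start); hi <- max(iv$end)
  if (is.null(chain_len)) chain_len <- hi
  if (D == 1) {
    out <- data.frame(id = "full", start = lo, end = hi, n_domains = 1)
    attr(out, "single_domain") <- TRUE
    warning("single-domain protein: full-length subchain only")
    return(out)
  }
  third <- ceiling(D / 3)
  specs <- data.frame(
    id = c("full", "no_nterm", "no_cterm", "first_third", "last_third"),
    start = c(lo, iv$start[2], lo, lo, iv$start[D - third + 1]),
    end = c(hi, hi, iv$end[D - 1], iv$end[third], hi),
    n_domains = c(D, D - 1, D - 1, third, third),
    stringsAsFactors = FALSE)
  ## clamp lengths toward the anchored end
  for (i in seq_len(nrow(specs))) {
    len <- specs$end[i] - specs$start[i] + 1
    if (len < config$subchain_min_len) {
      if (specs$start[i] == lo)
        specs$end[i] <- min(hi, specs$start[i] + config$subchain_min_len - 1)
      else
        specs$start[i] <- max(lo, specs$end[i] - config$subchain_min_len + 1)
    } else if (len > config$subchain_max_len) {
      if (specs$start[i] == lo)
        specs$end[i] <- specs$start[i] + config$subchain_max_len - 1
      else
        specs$start[i] <- specs$end[i] - config$subchain_max_len + 1
    }
  }
  dup <- duplicated(specs[, c("start", "end")])
  if (any(dup)) {
    warning("duplicate subchain interval(s) collapsed: ",
            paste(specs$id[dup], collapse = ", "))
    specs <- specs[!dup, , drop = FALSE]
  }
  rownames(specs) <- NULL
  attr(specs, "single_domain") <- FALSE
  specs
}

#' Single-domain subchains for the p1 route
#'
#' One spec per domain (`single_domain:k`), sorted by start, exactly
#' matching the partition intervals.
#'
#' @param partition a `domain_partition` with >= 2 domains.
#' @return data.frame with `id`, `start`, `end`.
#' @export
p1_single_domains <- function(partition) {
  iv <- partition$intervals
  if (nrow(iv) < 2)
    stop("p1 route needs >= 2 domains; use the standard subchain scheme")
  iv <- iv[order(iv$start), , drop = FALSE]
  data.frame(id = paste0("single_domain:", seq_len(nrow(iv))),
             start = iv$start, end = iv$end, stringsAsFactors = FALSE)
}

#' Write the per-domain report (TSV)
#'
#' Columns: domain_id, start, end, len, mean_surface (surface area per
#' residue, A^2).
#' @param model a [structure_model].
#' @param partition a `domain_partition`.
#' @param path output TSV path.
#' @export
write_domain_report <- function(model, partition, path) {
  iv <- partition$intervals
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    sel <- residue_selection(model, chain = partition$chain,
                             resno = iv$start[i]:iv$end[i])
    area <- surface_area(model, sel)
    data.frame(domain_id = i, start = iv$start[i], end = iv$end[i],
               len = interval_len(iv[i, ]),
               mean_surface = area / interval_len(iv[i, ]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
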
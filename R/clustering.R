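## Interface-based clustering of symmetry complexes: distogram matrices,
## correlation-weighted graph, Louvain communities, and candidate-pair
## ranking for the lattice assembly.

#' Interface distogram of a symmetry complex
#'
#' Residue-by-residue minimum heavy-atom distances between the reference
#' monomer (first chain in angular order) and its +1 neighbor around the
#' axis, capped at `d_cap`, indexed in full-length residue numbering.
#'
#' @param complex a `symmetry_complex` from [detect_symmetry()].
#' @param config a [default_config()] list.
#' @return an `interface_matrix`: numeric matrix with full-length residue
#'   numbers as dimnames; attribute `subchain_id`.
#' @export
interface_matrix <- function(complex, config = default_config()) {
  model <- complex$oligomer$model
  off <- complex$oligomer$residue_offset
  ord <- complex$axis$chain_order
  ref <- ord[1]; succ <- ord[2]
  M <- residue_min_dist(model,
                        residue_selection(model, chain = ref),
                        residue_selection(model, chain = succ))
  if (is.null(M) || min(M) >= config$d_cap)
    stop(errorCondition(
      "no interface: no inter-chain atom pair under the distance cap",
      class = "no_interface"))
  M[M > config$d_cap] <- config$d_cap
  strip <- function(keys) as.integer(sub("^.*:", "", keys)) + off
  dimnames(M) <- list(strip(rownames(M)), strip(colnames(M)))
  M <- M[order(as.integer(rownames(M))), order(as.integer(colnames(M))),
         drop = FALSE]
  attr(M, "subchain_id") <- complex$oligomer$subchain_id
  class(M) <- c("interface_matrix", class(M))
  M
}

#' Correlation between two interface distograms
#'
#' Pearson correlation of the vectorized contact indicators (entry below the
#' contact cutoff) restricted to the residue index ranges shared by both
#' matrices.
#'
#' @param m1,m2 `interface_matrix` objects.
#' @param config a [default_config()] list.
#' @return coefficient in `[-1, 1]`; 0 with a warning when either indicator
#'   vector has zero variance.
#' @export
matrix_correlation <- function(m1, m2, config = default_config()) {
  rows <- intersect(rownames(m1), rownames(m2))
  cols <- intersect(colnames(m1), colnames(m2))
  if (length(rows) * length(cols) < 20)
    stop("fewer than 20 shared full-length positions")
  a <- (m1[rows, cols] < config$contact_cutoff) * 1
  b <- (m2[rows, cols] < config$contact_cutoff) * 1
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a contact-indicator vector; correlation 0")
    return(0)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Build the interface-similarity graph
#'
#' One node per symmetry complex; all pairs are evaluated and an undirected
#' edge is kept when the interface correlation exceeds `w_min`.
#'
#' @param complexes list of `symmetry_complex` objects.
#' @param config a [default_config()] list.
#' @return an `interface_graph`: list with `graph` (igraph) and `complexes`.
#' @export
build_graph <- function(complexes, config = default_config()) {
  stopifnot(length(complexes) >= 1)
  for (i in seq_along(complexes))
    if (is.null(complexes[[i]]$interface))
      complexes[[i]]$interface <- interface_matrix(complexes[[i]], config)
  n <- length(complexes)
  nm <- vapply(seq_len(n), function(i) {
    cx <- complexes[[i]]
    sprintf("%s.k%d.m%d.%03d", cx$oligomer$subchain_id, cx$axis$order_k,
            cx$axis$m, i)
  }, character(1))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  ed <- NULL; w <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ## pairs without enough shared positions simply get no edge
      co <- tryCatch(matrix_correlation(complexes[[i]]$interface,
                                        complexes[[j]]$interface, config),
                     warning = function(w2) 0,
                     error = function(e) -1)
      if (co > config$w_min) { ed <- c(ed, i, j); w <- c(w, co) }
    }
  }
  if (length(ed)) {
    g <- igraph::add_edges(g, ed)
    g <- igraph::set_edge_attr(g, "weight", value = w)
  }
  structure(list(graph = g, complexes = complexes), class = "interface_graph")
}

#' Partition the interface graph with the Louvain method
#'
#' Communities maximize modularity; the node order is canonicalized (sorted
#' by name) and the RNG seeded before clustering, so the partition is
#' deterministic and invariant to input permutation. Each community becomes
#' an axis cluster whose consensus order is a score-weighted vote among
#' members (ties to the higher order) and whose representative is the
#' highest-scoring member.
#'
#' @param igr an `interface_graph` from [build_graph()].
#' @param seed RNG seed (default: config `louvain_seed`).
#' @param config a [default_config()] list.
#' @return list of `axis_cluster` objects, ordered by representative score
#'   (descending).
#' @export
louvain_partition <- function(igr, seed = NULL, config = default_config()) {
  if (is.null(seed)) seed <- config$louvain_seed
  g <- igr$graph
  if (igraph::vcount(g) == 0) return(list())
  perm <- order(igraph::V(g)$name)
  g2 <- igraph::permute(g, match(seq_along(perm), perm))
  memb <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    igraph::membership(igraph::cluster_louvain(g2))
  })
  ## map membership back to original complex order
  memb_orig <- memb[match(igraph::V(g)$name, igraph::V(g2)$name)]
  clusters <- lapply(sort(unique(memb_orig)), function(cm) {
    idx <- which(memb_orig == cm)
    members <- igr$complexes[idx]
    scores <- vapply(members, function(cx) cx$oligomer$score$combined,
                     numeric(1))
    orders <- vapply(members, function(cx) cx$axis$order_k, numeric(1))
    vote <- tapply(scores, orders, sum)
    top <- as.numeric(names(vote)[vote == max(vote)])
    consensus <- max(top)                       # ties -> higher order
    rep_i <- which.max(scores)
    structure(list(members = members, consensus_order = consensus,
                   representative = members[[rep_i]],
                   rep_score = scores[rep_i],
                   support = sort(unique(vapply(members, function(cx)
                     cx$axis$m, numeric(1))))),
              class = "axis_cluster")
  })
  clusters[order(-vapply(clusters, `[[`, numeric(1), "rep_score"))]
}

#' @export
print.axis_cluster <- function(x, ...) {
  cat(sprintf(
    "axis_cluster: %d member(s), consensus %d-fold, representative score %.3f, molecule counts {%s}\n",
    length(x$members), x$consensus_order, x$rep_score,
    paste(x$support, collapse = ",")))
  invisible(x)
}

#' Rank cluster pairs for lattice assembly
#'
#' Pairs of axis clusters ordered by the smaller of the two representatives'
#' scores (descending; ties to the higher combined order). Fallback pairs of
#' lower-scored members are appended so that more pairs can be tested when
#' the top pair fails. Fewer than two clusters raise a `one_axis_only`
#' error: a single rotational axis cannot span a 2D layer.
#'
#' @param clusters list of `axis_cluster` objects.
#' @return data.frame with `cluster_a`, `cluster_b`, `member_a`, `member_b`
#'   (indices), `min_score`, `tier` (0 = representatives, 1 = fallback).
#' @export
rank_pairs <- function(clusters) {
  if (length(clusters) < 2)
    stop(errorCondition(
      "one axis cluster only: spanning a 2D layer is not possible",
      class = "one_axis_only"))
  rows <- list(); k <- 0
  for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
    ca <- clusters[[i]]; cb <- clusters[[j]]
    sa <- vapply(ca$members, function(cx) cx$oligomer$score$combined, numeric(1))
    sb <- vapply(cb$members, function(cx) cx$oligomer$score$combined, numeric(1))
    grid <- expand.grid(ma = order(-sa), mb = order(-sb))
    for (r in seq_len(nrow(grid))) {
      k <- k + 1
      tier <- as.integer(!(grid$ma[r] == which.max(sa) &&
                           grid$mb[r] == which.max(sb)))
      rows[[k]] <- data.frame(
        cluster_a = i, cluster_b = j, member_a = grid$ma[r],
        member_b = grid$mb[r],
        min_score = min(sa[grid$ma[r]], sb[grid$mb[r]]),
        order_sum = clusters[[i]]$consensus_order + clusters[[j]]$consensus_order,
        tier = tier)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tier, -out$min_score, -out$order_sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}
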
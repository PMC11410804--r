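cfg <- default_config()

touching_complex <- function(seed = 1, k = 3) {
  detect_symmetry(tiny_oligomer(k, k, seed = seed), "layer", cfg)
}

test_that("interface matrix captures the touching interface", {
  cx <- touching_complex()
  M <- interface_matrix(cx, cfg)
  expect_true(min(M) < 5)
  expect_true(all(M > 0 & M <= cfg$d_cap))
  ## entries equal a brute-force min-distance scan
  model <- cx$oligomer$model
  ord <- cx$axis$chain_order
  a <- model$atoms[!model$atoms$hydrogen & model$atoms$chain == ord[1], ]
  b <- model$atoms[!model$atoms$hydrogen & model$atoms$chain == ord[2], ]
  for (probe in 1:5) {
    ri <- sample(unique(a$resno), 1); rj <- sample(unique(b$resno), 1)
    pa <- as.matrix(a[a$resno == ri, c("x", "y", "z")])
    pb <- as.matrix(b[b$resno == rj, c("x", "y", "z")])
    dmin <- min(sqrt(symlattice:::dist2_matrix(pa, pb)))
    expect_equal(M[as.character(ri), as.character(rj)],
                 min(dmin, cfg$d_cap), tolerance = 1e-9)
  }
  ## far-apart chains: no interface error
  spread <- tiny_oligomer(3, 3, radius = 80)
  cx_far <- detect_symmetry(spread, "layer", cfg)
  expect_error(interface_matrix(cx_far, cfg), class = "no_interface")
})

test_that("identical interfaces correlate at 1, disjoint at or below 0", {
  cx <- touching_complex()
  M <- interface_matrix(cx, cfg)
  expect_equal(matrix_correlation(M, M, cfg), 1.0)
  ## shifted interface: anti-agreement on shared indices
  M2 <- M
  rn <- as.integer(rownames(M))
  dimnames(M2) <- list(rn + 6, as.integer(colnames(M)) + 6)
  class(M2) <- class(M)
  expect_lte(matrix_correlation(M, M2, cfg), 0.3)
  ## hand-computed Pearson on the 0/1 vectors
  rows <- intersect(rownames(M), rownames(M2))
  cols <- intersect(colnames(M), colnames(M2))
  a <- as.vector((M[rows, cols] < 5) * 1)
  b <- as.vector((M2[rows, cols] < 5) * 1)
  byhand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(matrix_correlation(M, M2, cfg), byhand, tolerance = 1e-12)
  ## zero-variance indicator: 0 with warning
  Mflat <- M; Mflat[] <- cfg$d_cap
  class(Mflat) <- class(M)
  expect_warning(z <- matrix_correlation(M, Mflat, cfg), "zero variance")
  expect_equal(z, 0)
  ## too little overlap is an error
  Msmall <- M[1:2, 1:2]
  dimnames(Msmall) <- list(c("1", "2"), c("1", "2"))
  expect_error(matrix_correlation(Msmall, Msmall, cfg), "20 shared")
})

test_that("graph construction keeps only edges above the weight floor", {
  cx <- touching_complex(1)
  g1 <- build_graph(list(cx), cfg)
  expect_equal(igraph::vcount(g1$graph), 1)
  expect_equal(igraph::ecount(g1$graph), 0)
  g2 <- build_graph(list(cx, cx), cfg)
  expect_equal(igraph::ecount(g2$graph), 1)
  expect_equal(igraph::E(g2$graph)$weight, 1.0)
})

test_that("louvain recovers planted interface clusters with purity 1", {
  ps <- planted_interface_set()
  expect_gte(length(ps$complexes), 6)
  g <- build_graph(ps$complexes, cfg)
  clusters <- louvain_partition(g, config = cfg)
  expect_equal(length(clusters), 2)
  ## purity: every cluster holds complexes of one planted interface only
  for (cl in clusters) {
    sides <- substr(vapply(cl$members, function(cx)
      cx$oligomer$subchain_id, character(1)), 1, 1)
    expect_equal(length(unique(sides)), 1)
  }
  ## permutation invariance: shuffled input, same communities
  perm <- rev(seq_along(ps$complexes))
  g2 <- build_graph(ps$complexes[perm], cfg)
  cl2 <- louvain_partition(g2, config = cfg)
  sig <- function(cls) sort(vapply(cls, function(cl)
    paste(sort(vapply(cl$members, function(cx) cx$oligomer$subchain_id,
                      character(1))), collapse = "|"), character(1)))
  expect_equal(sig(cl2), sig(clusters))
})

test_that("partial representations vote the consensus order up", {
  ## one interface seen as a trimer stepping 60 deg and as a full hexamer:
  ## the cluster's consensus order is 6
  hexa <- detect_symmetry(tiny_oligomer(6, 6, seed = 2), "layer", cfg)
  tri60 <- detect_symmetry(tiny_oligomer(6, 3, seed = 3), "layer", cfg)
  expect_equal(tri60$axis$order_k, 6)
  g <- build_graph(list(hexa, tri60), cfg)
  clusters <- louvain_partition(g, config = cfg)
  expect_equal(length(clusters), 1)
  expect_equal(clusters[[1]]$consensus_order, 6)
  expect_setequal(clusters[[1]]$support, c(3, 6))
  ## singleton node forms its own cluster
  solo <- louvain_partition(build_graph(list(hexa), cfg), config = cfg)
  expect_equal(length(solo), 1)
  expect_equal(length(solo[[1]]$members), 1)
})

test_that("pair ranking orders by the weaker representative score", {
  mk_cluster <- function(score, order) {
    cx <- touching_complex(seed = round(score * 100) %% 10 + 1)
    cx$oligomer$score$combined <- score
    cx$axis$order_k <- order
    structure(list(members = list(cx), consensus_order = order,
                   representative = cx, rep_score = score,
                   support = cx$axis$m), class = "axis_cluster")
  }
  cl <- list(mk_cluster(0.9, 4), mk_cluster(0.8, 4), mk_cluster(0.5, 3))
  pairs <- rank_pairs(cl)
  ## best pair: 0.9 with 0.8 (min 0.8) above 0.9 with 0.5 (min 0.5)
  expect_equal(unlist(pairs[1, c("cluster_a", "cluster_b")],
                      use.names = FALSE), c(1, 2))
  expect_true(all(diff(pairs$min_score[pairs$tier == 0]) <= 0))
  expect_error(rank_pairs(cl[1]), class = "one_axis_only")
  ## equal scores: higher combined order first
  cl2 <- list(mk_cluster(0.7, 2), mk_cluster(0.7, 4), mk_cluster(0.7, 6))
  p2 <- rank_pairs(cl2)
  expect_equal(p2$order_sum[1], 10)   # the 4+6 pair leads
})
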
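# Proportional thresholding and graph measures.

test_that("proportional threshold achieves the exact requested density", {
  set.seed(1)
  M <- matrix(rnorm(100 * 100), 100); M <- (M + t(M)) / 2; diag(M) <- 0
  g <- binarize_proportional(M, 0.2)
  expect_equal(sum(g$adjacency) / 2, ceiling(0.2 * 4950))
  expect_equal(sum(g$adjacency) / 2, 990)
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  # rank-based: invariant under monotone transforms
  expect_identical(binarize_proportional(tanh(M), 0.2)$adjacency, g$adjacency)
  # near-full density on distinct entries: complete minus the weakest pair
  n <- 8; Ms <- matrix(rnorm(n * n), n); Ms <- Ms + t(Ms); diag(Ms) <- 0
  P <- n * (n - 1) / 2
  gf <- binarize_proportional(Ms, (P - 1) / P - 1e-9)
  expect_equal(sum(gf$adjacency) / 2, P - 1)
  ut <- which(upper.tri(Ms), arr.ind = TRUE)
  weakest <- ut[which.min(Ms[ut]), ]
  expect_equal(gf$adjacency[weakest[1], weakest[2]], 0L)
  expect_error(binarize_proportional(matrix(1, 5, 5), 0.2), "equal")
  expect_error(binarize_proportional(Ms, 1.2), "density")
})

test_that("local metrics match closed forms and brute-force enumeration", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  lm5 <- local_metrics(make_graph(K5))
  expect_true(all(lm5$degree == 4))
  expect_true(all(lm5$clustering == 1))
  star <- matrix(0L, 4, 4); star[1, 2:4] <- 1L; star <- star + t(star)
  lms <- local_metrics(make_graph(star))
  expect_equal(lms$degree, c(3L, 1L, 1L, 1L))
  expect_true(all(lms$clustering == 0))
  # random 12-node graphs against triangle enumeration over all triples
  set.seed(2)
  for (rep in 1:5) {
    A <- matrix(rbinom(144, 1, 0.35), 12); A[lower.tri(A, TRUE)] <- 0
    A <- A + t(A)
    lm <- local_metrics(make_graph(A))
    tri <- oracle_triangles(A)
    k <- rowSums(A)
    cc_oracle <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
    expect_equal(lm$clustering, cc_oracle, tolerance = 1e-12)
    expect_equal(lm$degree, as.integer(k))
  }
})

test_that("global efficiency matches BFS enumeration, unreachable pairs give 0", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  g5 <- global_metrics(make_graph(K5))
  expect_equal(g5$global_clustering, 1)
  expect_equal(g5$global_efficiency, 1)
  # 4-node path: closed form
  P4 <- matrix(0L, 4, 4); P4[cbind(1:3, 2:4)] <- 1L; P4 <- P4 + t(P4)
  expect_equal(global_metrics(make_graph(P4))$global_efficiency,
               (1 + 1 + 1 + 0.5 + 0.5 + 1 / 3) / 6)
  # random graphs against the BFS oracle
  set.seed(3)
  for (rep in 1:4) {
    A <- matrix(rbinom(100, 1, 0.25), 10); A[lower.tri(A, TRUE)] <- 0
    A <- A + t(A)
    expect_equal(global_metrics(make_graph(A))$global_efficiency,
                 oracle_efficiency(A), tolerance = 1e-12)
  }
  # isolated node: efficiency < 1 and pairs to it contribute 0
  iso <- matrix(0L, 4, 4); iso[1, 2] <- iso[2, 1] <- 1L
  eff <- global_metrics(make_graph(iso))$global_efficiency
  expect_equal(eff, 1 / 6)
})

test_that("global clustering is the mean of nodal clustering", {
  set.seed(4)
  A <- matrix(rbinom(400, 1, 0.3), 20); A[lower.tri(A, TRUE)] <- 0
  A <- A + t(A)
  g <- make_graph(A)
  expect_equal(global_metrics(g)$global_clustering,
               mean(local_metrics(g)$clustering))
})

test_that("smallworldness separates lattice-like from random networks", {
  skip_if_not_installed("igraph")
  set.seed(5)
  ws <- igraph::sample_smallworld(1, 100, 3, 0.05)
  Aw <- as.matrix(igraph::as_adjacency_matrix(ws))
  sw <- smallworldness(make_graph(Aw), n_null = 10, seed = 5)
  expect_gt(sw$sigma, 1.5)
  er <- igraph::sample_gnp(100, 0.5)
  Ae <- as.matrix(igraph::as_adjacency_matrix(er))
  swr <- smallworldness(make_graph(Ae), n_null = 10, seed = 5)
  expect_gt(swr$sigma, 0.8); expect_lt(swr$sigma, 1.2)
  # rewired nulls preserve every node's degree: verified indirectly by
  # rewiring once with the same routine
  rg <- igraph::rewire(ws, igraph::keeping_degseq(niter = 20 * igraph::ecount(ws)))
  expect_equal(igraph::degree(rg), igraph::degree(ws))
  # heavily disconnected graph is an error
  frag <- matrix(0L, 10, 10)
  frag[1, 2] <- frag[2, 1] <- 1L; frag[3, 4] <- frag[4, 3] <- 1L
  expect_error(smallworldness(make_graph(frag)), "90%")
})

test_that("metrics are invariant to node relabelling", {
  set.seed(6)
  A <- matrix(rbinom(225, 1, 0.3), 15); A[lower.tri(A, TRUE)] <- 0
  A <- A + t(A)
  perm <- sample(15)
  Ap <- A[perm, perm]
  g <- global_metrics(make_graph(A)); gp <- global_metrics(make_graph(Ap))
  expect_equal(g$global_clustering, gp$global_clustering)
  expect_equal(g$global_efficiency, gp$global_efficiency)
  expect_equal(sort(local_metrics(make_graph(A))$degree),
               sort(local_metrics(make_graph(Ap))$degree))
})

test_that("efficiency and clustering do not decrease under edge addition", {
  set.seed(7)
  A <- matrix(rbinom(144, 1, 0.25), 12); A[lower.tri(A, TRUE)] <- 0
  A <- A + t(A)
  base_eff <- global_metrics(make_graph(A))$global_efficiency
  missing <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
  for (k in seq_len(min(5, nrow(missing)))) {
    A2 <- A
    A2[missing[k, 1], missing[k, 2]] <- A2[missing[k, 2], missing[k, 1]] <- 1L
    expect_gte(global_metrics(make_graph(A2))$global_efficiency, base_eff)
  }
})
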
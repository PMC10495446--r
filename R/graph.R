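# Feature stage 5: proportional thresholding/binarization and graph
# measures: nodal degree and clustering, global clustering, global
# efficiency, smallworldness against degree-preserving null networks.

#' Binarize a connectivity matrix by proportional thresholding
#'
#' Keeps the `ceiling(density * P)` strongest upper-triangle entries by
#' value (P = n(n-1)/2 pairs), breaking ties at the cutoff by (row, col)
#' lexical order, and symmetrizes. Rank-based, so invariant under monotone
#' transforms; negative entries rank below positive ones (no absolute
#' value is taken).
#'
#' @param M a `connectivity_matrix` or plain symmetric matrix
#' @param density fraction of pairs to keep, strictly in (0, 1)
#' @return a `binary_graph`: `adjacency` (0/1, zero diagonal), `density`
#'   (achieved), `threshold` (value of the weakest kept edge)
#' @export
binarize_proportional <- function(M, density = 0.2) {
  if (inherits(M, "connectivity_matrix")) M <- M$matrix
  if (density <= 0 || density >= 1) stop("density must lie strictly in (0, 1)")
  n <- nrow(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  if (max(vals) - min(vals) < .Machine$double.eps)
    stop("all connectivity values are equal; proportional threshold undefined")
  P <- nrow(ut)
  k <- ceiling(density * P)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, n, n)
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(M)
  structure(list(adjacency = A, density = k / P, threshold = min(vals[keep])),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (density %.3f, threshold %.4g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density, x$threshold))
  invisible(x)
}

#' Nodal degree and clustering coefficient
#'
#' Degree is the row sum of the adjacency; the clustering coefficient of
#' node i is `2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through i (taken as 0 when `k_i < 2`).
#'
#' @param g a `binary_graph`
#' @return data.frame with columns `node`, `degree`, `clustering`
#' @export
local_metrics <- function(g) {
  A <- g$adjacency
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  data.frame(node = rownames(A) %||% as.character(seq_len(nrow(A))),
             degree = as.integer(k), clustering = cc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global clustering coefficient and global efficiency
#'
#' Global clustering is the mean nodal clustering coefficient; global
#' efficiency is the mean inverse shortest path length over unordered node
#' pairs, unreachable pairs contributing 0.
#'
#' @param g a `binary_graph`
#' @return named list `global_clustering`, `global_efficiency`
#' @export
global_metrics <- function(g) {
  lm <- local_metrics(g)
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  D <- igraph::distances(ig)
  iv <- 1 / D[upper.tri(D)]
  iv[!is.finite(iv)] <- 0
  list(global_clustering = mean(lm$clustering),
       global_efficiency = mean(iv))
}

#' Smallworldness against degree-preserving random networks
#'
#' Humphries-Gurney sigma: `(C / C_null) / (L / L_null)` where C is the
#' global clustering coefficient, L the characteristic path length over
#' reachable pairs of the largest connected component, and the null values
#' are means over `n_null` degree-preserving edge-swap rewirings (20 * |E|
#' attempted swaps each, seeded). The graph must be connected on a largest
#' component covering at least 90% of nodes.
#'
#' @param g a `binary_graph`
#' @param n_null number of null networks
#' @param seed RNG seed for the rewiring
#' @return list `sigma`, `C`, `L`, `C_null`, `L_null`, `n_null`, `seed`
#' @export
smallworldness <- function(g, n_null = 10, seed = 2000L) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  comp <- igraph::components(ig)
  if (max(comp$csize) < 0.9 * igraph::vcount(ig))
    stop("largest component covers under 90% of nodes; increase graph density")
  cl_metrics <- function(gr) {
    A <- as.matrix(igraph::as_adjacency_matrix(gr))
    bg <- structure(list(adjacency = A), class = "binary_graph")
    C <- mean(local_metrics(bg)$clustering)
    main <- igraph::induced_subgraph(gr, which(comp_membership(gr) == 1L))
    D <- igraph::distances(main)
    dv <- D[upper.tri(D)]
    L <- mean(dv[is.finite(dv)])
    c(C = C, L = L)
  }
  obs <- cl_metrics(ig)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = 20 * igraph::ecount(ig)))
      cl_metrics(rg)
    }, numeric(2))
  })
  Cn <- mean(nulls["C", ]); Ln <- mean(nulls["L", ])
  list(sigma = (obs["C"] / Cn) / (obs["L"] / Ln),
       C = unname(obs["C"]), L = unname(obs["L"]),
       C_null = Cn, L_null = Ln, n_null = n_null, seed = seed)
}

comp_membership <- function(gr) {
  comp <- igraph::components(gr)
  # relabel so the largest component is 1
  big <- which.max(comp$csize)
  ifelse(comp$membership == big, 1L, comp$membership + 1L)
}

#' All graph metrics for one connectivity matrix
#'
#' Thresholds, binarizes and computes the nodal and global measures in one
#' call.
#'
#' @param M a `connectivity_matrix`
#' @param density proportional threshold
#' @param n_null null networks for smallworldness
#' @param seed rewiring seed
#' @return a `graph_metrics`: `local` (data.frame), `global` (list with
#'   clustering, efficiency, smallworldness), `graph`, `density`
#' @export
graph_metrics <- function(M, density = 0.2, n_null = 10, seed = 2000L) {
  g <- binarize_proportional(M, density)
  loc <- local_metrics(g)
  glob <- global_metrics(g)
  sw <- tryCatch(smallworldness(g, n_null, seed),
                 error = function(e) list(sigma = NA_real_, message = conditionMessage(e)))
  structure(list(local = loc,
                 global = list(global_clustering = glob$global_clustering,
                               global_efficiency = glob$global_efficiency,
                               smallworldness = unname(sw$sigma)),
                 null_model = list(n_null = n_null, seed = seed),
                 graph = g, density = density,
                 measure = if (inherits(M, "connectivity_matrix")) M$measure else NA,
                 band = if (inherits(M, "connectivity_matrix")) M$band else NA),
            class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("<graph_metrics> %s: C %.3f, Eff %.3f, sigma %s (density %.2f)\n",
              if (is.na(x$measure[1])) "graph" else x$measure,
              x$global$global_clustering, x$global$global_efficiency,
              format(x$global$smallworldness, digits = 3), x$density))
  invisible(x)
}
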
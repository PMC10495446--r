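# Group-level statistics: a 1-D cluster-based permutation test across
# frequency bins and the JZS default-prior Bayes-factor t-test.

#' Cluster-based permutation test across frequencies
#'
#' Per frequency bin a t statistic is computed (paired or two-sample);
#' bins with two-sided parametric p below `cluster_alpha` form clusters of
#' adjacent bins with the same sign, each cluster's statistic being the
#' sum of its t values. The null distribution of the maximum absolute
#' cluster statistic is built from `n_perm` sign-flip (paired) or
#' label-shuffling (unpaired) permutations, and each observed cluster gets
#' the Monte-Carlo p-value `(b + 1) / (n_perm + 1)` — so the smallest
#' attainable p at 500 randomizations is 1/501.
#'
#' @param specA,specB subjects x bins matrices (same subjects when paired)
#' @param freqs frequency of each bin (defaults to bin index)
#' @param paired dependent-samples test?
#' @param n_perm number of randomizations
#' @param cluster_alpha bin-level threshold for cluster formation
#' @param alpha cluster-level significance level
#' @param seed RNG seed for the permutations
#' @return a `cluster_test`: data.frame `clusters` (sign, start/end bin,
#'   freq range, statistic, p, significant), `t` per bin, `freqs`,
#'   `n_perm`
#' @export
cluster_perm_test <- function(specA, specB, freqs = NULL, paired = TRUE,
                              n_perm = 500, cluster_alpha = 0.05,
                              alpha = 0.05, seed = 1L) {
  specA <- as.matrix(specA); specB <- as.matrix(specB)
  if (ncol(specA) != ncol(specB)) stop("bin count differs between conditions")
  if (paired && nrow(specA) != nrow(specB))
    stop("paired test needs the same subjects in both conditions")
  if (min(nrow(specA), nrow(specB)) < 3) stop("need at least 3 subjects")
  nb <- ncol(specA)
  if (is.null(freqs)) freqs <- seq_len(nb)

  if (paired) {
    D <- specA - specB
    n <- nrow(D)
    tfun <- function(M) {
      mu <- colMeans(M)
      s <- sqrt((colSums(M^2) - n * mu^2) / (n - 1))
      mu / (s / sqrt(n) + 1e-300)
    }
    df <- n - 1
    t_obs <- tfun(D)
  } else {
    n1 <- nrow(specA); n2 <- nrow(specB)
    all <- rbind(specA, specB)
    tfun2 <- function(ia) {
      A <- all[ia, , drop = FALSE]; B <- all[-ia, , drop = FALSE]
      ma <- colMeans(A); mb <- colMeans(B)
      va <- (colSums(A^2) - n1 * ma^2) / (n1 - 1)
      vb <- (colSums(B^2) - n2 * mb^2) / (n2 - 1)
      sp <- sqrt(((n1 - 1) * va + (n2 - 1) * vb) / (n1 + n2 - 2))
      (ma - mb) / (sp * sqrt(1 / n1 + 1 / n2) + 1e-300)
    }
    df <- n1 + n2 - 2
    t_obs <- tfun2(seq_len(n1))
  }
  tcrit <- stats::qt(1 - cluster_alpha / 2, df)

  find_clusters <- function(tv) {
    supra <- abs(tv) > tcrit
    sgn <- sign(tv)
    out <- NULL
    i <- 1L
    while (i <= nb) {
      if (supra[i]) {
        j <- i
        while (j < nb && supra[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
        out <- rbind(out, c(start = i, end = j, stat = sum(tv[i:j]), sign = sgn[i]))
        i <- j + 1L
      } else i <- i + 1L
    }
    out
  }

  obs <- find_clusters(t_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      tv <- if (paired) {
        flip <- sample(c(-1, 1), nrow(specA), replace = TRUE)
        tfun(D * flip)
      } else {
        tfun2(sample(nrow(all), nrow(specA)))
      }
      cl <- find_clusters(tv)
      if (is.null(cl)) 0 else max(abs(cl[, "stat"]))
    }, numeric(1))
  })

  clusters <- if (is.null(obs)) {
    data.frame(sign = integer(), start_bin = integer(), end_bin = integer(),
               freq_lo = numeric(), freq_hi = numeric(),
               stat = numeric(), p = numeric(), significant = logical())
  } else {
    p <- vapply(obs[, "stat"], function(s)
      (sum(null_max >= abs(s)) + 1) / (n_perm + 1), numeric(1))
    data.frame(sign = as.integer(obs[, "sign"]),
               start_bin = as.integer(obs[, "start"]),
               end_bin = as.integer(obs[, "end"]),
               freq_lo = freqs[obs[, "start"]], freq_hi = freqs[obs[, "end"]],
               stat = obs[, "stat"], p = p, significant = p < alpha)
  }
  structure(list(clusters = clusters, t = t_obs, freqs = freqs,
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 alpha = alpha, paired = paired),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s, %d randomizations, %d cluster(s)\n",
              if (x$paired) "paired" else "independent", x$n_perm, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' JZS Bayes-factor t-test (two-sided, independent samples)
#'
#' Default-prior Bayes factor BF10 for a two-sample t-test: Cauchy prior
#' with scale `rscale` (default sqrt(2)/2) on the standardized effect
#' size, integrated against the noncentral-t likelihood of the observed t
#' statistic by adaptive quadrature. BF10 above 1 favors a group
#' difference; the conventional strong-evidence bounds are 30 and 1/30.
#'
#' @param x,y numeric samples (each n >= 2)
#' @param rscale Cauchy prior scale
#' @return a `bayes_ttest`: `bf10`, `t`, `n1`, `n2`, `rscale`
#' @export
jzs_bf_ttest <- function(x, y, rscale = sqrt(2) / 2) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance; t statistic undefined")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  bf <- jzs_bf_from_t(t, n1, n2, rscale)
  structure(list(bf10 = bf, t = t, n1 = n1, n2 = n2, rscale = rscale),
            class = "bayes_ttest")
}

#' JZS Bayes factor from a t statistic and group sizes
#'
#' @param t observed t statistic
#' @param n1,n2 group sizes
#' @param rscale Cauchy prior scale on the standardized effect
#' @return BF10 (positive scalar)
#' @export
jzs_bf_from_t <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  lik <- function(delta)
    suppressWarnings(stats::dt(t, df = nu, ncp = delta * sqrt(neff)))
  integrand <- function(delta) lik(delta) * stats::dcauchy(delta, scale = rscale)
  m1 <- stats::integrate(integrand, -Inf, 0, rel.tol = 1e-9)$value +
        stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  m0 <- stats::dt(t, df = nu)
  m1 / m0
}

#' @export
print.bayes_ttest <- function(x, ...) {
  cat(sprintf("<bayes_ttest> t = %.3f (n = %d/%d), BF10 = %.4g (Cauchy scale %.3f)\n",
              x$t, x$n1, x$n2, x$bf10, x$rscale))
  invisible(x)
}

#' Mass-univariate Bayes-factor comparison of connectivity matrices
#'
#' Loops [jzs_bf_ttest()] over the unordered ROI pairs of two groups of
#' connectivity matrices (one 100 x 100 matrix per subject), returning one
#' row per pair with t, BF10 and the conventional evidence category.
#'
#' @param matsA,matsB lists of `connectivity_matrix` objects or plain
#'   matrices (one per subject)
#' @param rscale Cauchy prior scale
#' @return data.frame: roi_a, roi_b, t, bf10, evidence
#' @export
bf_compare_connectivity <- function(matsA, matsB, rscale = sqrt(2) / 2) {
  getm <- function(m) if (inherits(m, "connectivity_matrix")) m$matrix else m
  A <- lapply(matsA, getm); B <- lapply(matsB, getm)
  n <- nrow(A[[1]])
  ut <- which(upper.tri(A[[1]]), arr.ind = TRUE)
  va <- vapply(A, function(m) m[ut], numeric(nrow(ut)))
  vb <- vapply(B, function(m) m[ut], numeric(nrow(ut)))
  rn <- rownames(A[[1]]) %||% as.character(seq_len(n))
  out <- data.frame(roi_a = rn[ut[, 1]], roi_b = rn[ut[, 2]],
                    t = NA_real_, bf10 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ut))) {
    bt <- jzs_bf_ttest(va[i, ], vb[i, ], rscale)
    out$t[i] <- bt$t; out$bf10[i] <- bt$bf10
  }
  out$evidence <- cut(out$bf10, c(0, 1 / 30, 1 / 3, 3, 30, Inf),
                      labels = c("strong H0", "substantial H0", "inconclusive",
                                 "substantial H1", "strong H1"))
  out
}
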
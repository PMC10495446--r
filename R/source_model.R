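# Source model (100-ROI centroid atlas) and the analytic 3-shell spherical
# EEG forward solution.

#' Load a source-model centroid table
#'
#' With no path, the packaged SYNTHETIC 100-ROI table is used: 100 centroid
#' coordinates on a cortical shell with the seven canonical network labels
#' (Visual, Somato-Motor, Dorsal attention, Salience-Ventral attention,
#' Limbic, Control, Default). It is a stand-in with the same shape and
#' interface as a real 100-parcel/7-network atlas; any TSV with columns
#' `roi_index, roi_name, network, x, y, z` (head RAS, meters) is accepted.
#'
#' @param path optional path to a centroid TSV
#' @return data.frame of ROI centroids
#' @export
load_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atlas100_synthetic.tsv", package = "resteeg")
  at <- read_tsv_plain(path)
  need <- c("roi_index", "roi_name", "network", "x", "y", "z")
  if (!all(need %in% names(at)))
    stop("atlas table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(at$roi_name)) stop("atlas ROI names must be unique")
  at
}

#' Analytic 3-shell concentric-sphere EEG lead field
#'
#' Solves the Poisson boundary-value problem for a current dipole inside
#' three concentric shells (brain/skull/scalp, conductivities
#' 0.33/0.0042/0.33 S/m) by a truncated Legendre series (default 60
#' terms), the per-degree radial coefficients coming from the 5x5 interface
#' linear system. The scalp radius is fit to the electrode cloud by
#' least squares; brain and skull radii are 0.87 and 0.92 of it.
#' Electrodes are projected onto the scalp sphere. Gains are returned
#' average-referenced (each dipole's gain sums to zero over electrodes).
#'
#' @param atlas centroid table from [load_atlas()]
#' @param channels channel table (EEG rows with positions are used)
#' @param conductivities brain/skull/scalp conductivities in S/m
#' @param radii_frac brain and skull radii as fractions of the scalp radius
#' @param n_terms Legendre series truncation
#' @return a `lead_field`: `gain` (ROI x channel x 3 array, volts per unit
#'   dipole moment, average-referenced), `channel_names`, `atlas`,
#'   `center`, `radius`
#' @export
build_spherical_leadfield <- function(atlas, channels,
                                      conductivities = c(0.33, 0.0042, 0.33),
                                      radii_frac = c(0.87, 0.92),
                                      n_terms = 60) {
  ch <- as.data.frame(channels, stringsAsFactors = FALSE)
  ch <- ch[ch$type == "EEG" & !is.na(ch$x), , drop = FALSE]
  if (nrow(ch) < 4) stop("need at least 4 positioned EEG electrodes")
  P <- as.matrix(ch[, c("x", "y", "z")])
  # algebraic sphere fit: |p|^2 = 2 p.c + (R^2 - |c|^2)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  if (kappa(crossprod(A)) > 1e10)
    stop("electrode cloud cannot be fit to a sphere (degenerate geometry)")
  beta <- solve(crossprod(A), crossprod(A, b))
  center <- beta[1:3]
  R <- sqrt(beta[4] + sum(center^2))
  Pu <- sweep(P, 2, center)
  Pu <- Pu / sqrt(rowSums(Pu^2))          # unit directions, electrodes on scalp sphere
  r1 <- radii_frac[1] * R; r2 <- radii_frac[2] * R
  sig <- conductivities

  src <- sweep(as.matrix(atlas[, c("x", "y", "z")]), 2, center)
  rr <- sqrt(rowSums(src^2))
  if (any(rr >= r1 * 0.99)) {
    warning("rescaling ", sum(rr >= r1 * 0.99), " centroid(s) into the brain shell")
    bad <- rr >= r1 * 0.99
    src[bad, ] <- src[bad, ] * (0.95 * r1 / rr[bad])
    rr <- sqrt(rowSums(src^2))
  }

  # per-degree outer-surface radial transfer V_n for the dipole expansion;
  # solved in radius-normalized units (x = r/R in (0, 1]) so the powers
  # x^n and x^-(n+1) stay well-conditioned up to high degree
  nvec <- seq_len(n_terms)
  x1 <- radii_frac[1]; x2 <- radii_frac[2]
  radial_coef <- function(b_r) {
    cn <- (b_r / R)^(nvec - 1) / (4 * pi * sig[1] * R^2)
    out <- numeric(n_terms)
    for (j in nvec) {
      n <- j
      M <- matrix(0, 5, 5)
      rhs <- numeric(5)
      # unknowns: A1, A2, B2, A3, B3 (normalized-radius coefficients)
      M[1, ] <- c(x1^n, -x1^n, -x1^(-(n + 1)), 0, 0)
      rhs[1] <- -cn[j] * x1^(-(n + 1))
      M[2, ] <- c(sig[1] * n * x1^(n - 1),
                  -sig[2] * n * x1^(n - 1), sig[2] * (n + 1) * x1^(-(n + 2)), 0, 0)
      rhs[2] <- cn[j] * sig[1] * (n + 1) * x1^(-(n + 2))
      M[3, ] <- c(0, x2^n, x2^(-(n + 1)), -x2^n, -x2^(-(n + 1)))
      M[4, ] <- c(0, sig[2] * n * x2^(n - 1), -sig[2] * (n + 1) * x2^(-(n + 2)),
                  -sig[3] * n * x2^(n - 1), sig[3] * (n + 1) * x2^(-(n + 2)))
      M[5, ] <- c(0, 0, 0, n, -(n + 1))
      sol <- solve(M, rhs)
      out[j] <- sol[4] + sol[5]
    }
    out
  }

  nch <- nrow(Pu); nroi <- nrow(src)
  gain <- array(0, dim = c(nroi, nch, 3))
  for (q in seq_len(nroi)) {
    b_r <- rr[q]
    bu <- src[q, ] / b_r
    Vn <- radial_coef(b_r)
    cg <- pmin(pmax(Pu %*% bu, -1), 1)    # cos(gamma) per electrode
    Pn <- legendre_table(as.vector(cg), n_terms)        # n_terms x nch
    Pn0 <- rbind(rep(1, nch), Pn[-n_terms, , drop = FALSE])  # P_{n-1}
    sing <- sqrt(pmax(1 - as.vector(cg)^2, 0))
    # associated Legendre P_n^1 = -n (x P_n - P_{n-1}) / sin(gamma)
    Pn1 <- matrix(0, n_terms, nch)
    ok <- sing > 1e-9
    if (any(ok)) {
      xg <- as.vector(cg)[ok]
      Pn1[, ok] <- -sweep(sweep(Pn[, ok, drop = FALSE], 2, xg, "*") - Pn0[, ok, drop = FALSE],
                          1, nvec, "*") / rep(sing[ok], each = n_terms)
    }
    # tangential unit vector from dipole axis toward each electrode
    chat <- Pu - as.vector(cg) %*% t(bu)
    nrm <- sqrt(rowSums(chat^2))
    chat[nrm > 1e-9, ] <- chat[nrm > 1e-9, ] / nrm[nrm > 1e-9]
    chat[nrm <= 1e-9, ] <- 0
    rad_part <- as.vector(crossprod(Pn, Vn * nvec))     # nch, for unit radial moment
    tan_part <- as.vector(crossprod(Pn1, Vn))           # nch, for unit tangential moment
    for (d in 1:3) {
      e <- c(0, 0, 0); e[d] <- 1
      qr <- sum(e * bu)
      qc <- chat %*% e                                  # tangential component toward each electrode
      gain[q, , d] <- rad_part * qr + tan_part * as.vector(qc)
    }
  }
  # average-reference projection
  for (d in 1:3) {
    gd <- matrix(gain[, , d], nrow = nroi)
    gain[, , d] <- gd - rowMeans(gd)
  }
  structure(list(gain = gain, channel_names = ch$name, atlas = atlas,
                 center = center, radius = R),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d ROIs x %d channels x 3 (scalp radius %.3f m)\n",
              dim(x$gain)[1], dim(x$gain)[2], x$radius))
  invisible(x)
}

#' Read a user-supplied lead field from HDF5
#'
#' Expects a dataset `leadfield` of shape ROI x channel x 3 and a dataset
#' or attribute `channel_names`.
#'
#' @param path HDF5 file path
#' @param atlas centroid table to attach
#' @return a `lead_field`
#' @export
read_leadfield_h5 <- function(path, atlas) {
  g <- rhdf5::h5read(path, "leadfield")
  cn <- as.character(rhdf5::h5read(path, "channel_names"))
  if (length(dim(g)) != 3 || dim(g)[3] != 3)
    stop("dataset 'leadfield' must be ROI x channel x 3")
  if (dim(g)[2] != length(cn)) stop("channel_names length mismatch")
  structure(list(gain = g, channel_names = cn, atlas = atlas,
                 center = c(0, 0, 0), radius = NA_real_),
            class = "lead_field")
}
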
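#' Oxygen-oxygen radial distribution function
#'
#' Standard pair-count g(r) on minimum-image distances of wrapped hydroxyl-O
#' coordinates, normalised by the ideal-gas shell count at the system's
#' average number density and averaged over frames. Bins are half-open
#' [r, r + dr).
#'
#' @param traj A [trajectory()]; molecule positions are the hydroxyl-O sites
#'   (all sites if no topology is attached).
#' @param bin_width Bin width dr in nm.
#' @param r_max Histogram range in nm; must not exceed L/2 of the smallest
#'   frame box (minimum-image validity).
#' @return An `rdf_curve` data.frame with columns `r` (bin centers), `g`,
#'   `stderr` (frame-to-frame standard error), `count` (mean pairs per bin),
#'   and attributes `bin_width`, `rho` (nm^-3), `r_max`.
#' @export
compute_rdf <- function(traj, bin_width = 0.01, r_max = NULL) {
  pos <- oxygen_positions(traj)
  L <- vapply(traj$frames, `[[`, numeric(1), "box_edge")
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-12)
    stop("r_max must be <= L/2 (minimum-image validity)")
  n_bins <- ceiling(r_max / bin_width)
  N <- nrow(pos[[1]])
  g_frames <- matrix(0, n_bins, length(pos))
  cnt_frames <- matrix(0, n_bins, length(pos))
  rho_frames <- N / L^3
  for (fi in seq_along(pos)) {
    p <- wrap_positions(pos[[fi]], L[fi])
    d <- minimum_image_dist_matrix(p, L[fi])
    d <- d[upper.tri(d)]
    idx <- floor(d / bin_width) + 1L
    keep <- idx >= 1L & idx <= n_bins
    counts <- tabulate(idx[keep], nbins = n_bins)
    edges <- bin_width * (0:n_bins)
    shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
    ideal <- N * (N - 1) / 2 * shell_vol / L[fi]^3
    g_frames[, fi] <- counts / ideal
    cnt_frames[, fi] <- counts
  }
  g <- rowMeans(g_frames)
  se <- if (ncol(g_frames) > 1)
    apply(g_frames, 1, stats::sd) / sqrt(ncol(g_frames)) else rep(NA_real_, n_bins)
  out <- data.frame(r = bin_width * (seq_len(n_bins) - 0.5), g = g,
                    stderr = se, count = rowMeans(cnt_frames))
  structure(out, class = c("rdf_curve", "data.frame"),
            bin_width = bin_width, rho = mean(rho_frames), r_max = r_max)
}

# Full minimum-image distance matrix (nm) for an n x 3 coordinate set.
minimum_image_dist_matrix <- function(p, L) {
  dsq <- 0
  for (a in 1:3) {
    d <- outer(p[, a], p[, a], "-")
    d <- d - L * floor(d / L + 0.5)
    dsq <- dsq + d * d
  }
  sqrt(dsq)
}

#' Static structure factor by direct reciprocal-lattice summation
#'
#' Evaluates S(k) = <|sum_j exp(-i k . r_j)|^2 / N> on the reciprocal lattice
#' k = 2 pi (n_x, n_y, n_z) / L for every nonzero integer triple with
#' max(|n|) <= n_max, deduplicated by the k -> -k symmetry (each half-space
#' vector counts its mirror in the shell multiplicity). Vectors are grouped
#' into shells by the exact integer norm n_x^2 + n_y^2 + n_z^2, which keeps
#' shells well defined when the box edge fluctuates across frames; reported
#' |k| uses the mean box edge. The squared-modulus single-sum form is
#' algebraically identical to the double sum over pairs.
#'
#' @param traj A [trajectory()]; particle positions are the hydroxyl-O sites.
#' @param n_max Maximum integer component of the lattice vectors (default 70).
#' @return An `sk_curve` data.frame with columns `k` (nm^-1), `S`, `stderr`
#'   (frame-to-frame standard error of the shell value), `count` (lattice
#'   vectors per shell, mirror images included), `nsq` (integer norm); and
#'   attributes `k_min` (= 2 pi / mean L) and `n_max`.
#' @export
structure_factor_direct <- function(traj, n_max = 70) {
  if (n_max < 1) stop("n_max must be >= 1")
  pos <- oxygen_positions(traj)
  if (nrow(pos[[1]]) < 1L) stop("empty particle selection")
  L <- vapply(traj$frames, `[[`, numeric(1), "box_edge")
  nsq_max <- 3L * n_max^2
  n_frames <- length(pos)
  shell_sum <- matrix(0, nsq_max, n_frames)  # sum of |.|^2/N over half-space
  shell_cnt <- integer(nsq_max)               # half-space vector count per nsq
  nvals <- -n_max:n_max
  for (fi in seq_len(n_frames)) {
    p <- pos[[fi]]
    N <- nrow(p)
    tf <- -2i * pi / L[fi]
    Ex <- exp(tf * outer(nvals, p[, 1]))
    Ey <- exp(tf * outer(nvals, p[, 2]))
    Ezp <- exp(tf * outer(seq_len(n_max), p[, 3]))  # n_z = 1..n_max
    count_this <- fi == 1L
    # group A: n_z >= 1, full (n_x, n_y) plane
    for (iy in seq_along(nvals)) {
      W <- Ex * rep(Ey[iy, ], each = length(nvals))   # (2n+1) x N
      Sz <- W %*% t(Ezp)                              # (2n+1) x n_max sums
      s2 <- (Mod(Sz)^2) / N
      nsq <- outer(nvals^2 + nvals[iy]^2, seq_len(n_max)^2, "+")
      acc <- rowsum(as.vector(s2), as.vector(nsq))
      ks <- as.integer(rownames(acc))
      shell_sum[ks, fi] <- shell_sum[ks, fi] + acc[, 1]
      if (count_this)
        shell_cnt[ks] <- shell_cnt[ks] + tabulate(as.vector(nsq), nsq_max)[ks]
    }
    # group B: n_z = 0, n_y >= 1, full n_x
    for (iy in which(nvals >= 1L)) {
      sums <- Ex %*% Ey[iy, ]
      s2 <- (Mod(sums)^2) / N
      nsq <- nvals^2 + nvals[iy]^2
      acc <- rowsum(as.vector(s2), nsq)
      ks <- as.integer(rownames(acc))
      shell_sum[ks, fi] <- shell_sum[ks, fi] + acc[, 1]
      if (count_this)
        shell_cnt[ks] <- shell_cnt[ks] + tabulate(nsq, nsq_max)[ks]
    }
    # group C: n_z = 0, n_y = 0, n_x >= 1
    sums <- rowSums(Ex[nvals >= 1L, , drop = FALSE])
    s2 <- (Mod(sums)^2) / N
    nsq <- nvals[nvals >= 1L]^2
    shell_sum[nsq, fi] <- shell_sum[nsq, fi] + s2
    if (count_this) shell_cnt[nsq] <- shell_cnt[nsq] + 1L
  }
  occ <- which(shell_cnt > 0L)
  S_frames <- shell_sum[occ, , drop = FALSE] / shell_cnt[occ]
  S <- rowMeans(S_frames)
  se <- if (n_frames > 1)
    apply(S_frames, 1, stats::sd) / sqrt(n_frames) else rep(NA_real_, length(occ))
  k <- 2 * pi * sqrt(occ) / mean(L)
  out <- data.frame(k = k, S = S, stderr = se,
                    count = 2L * shell_cnt[occ], nsq = occ)
  structure(out[order(out$k), ], class = c("sk_curve", "data.frame"),
            k_min = 2 * pi / mean(L), n_max = n_max)
}

#' Structure factor from the radial distribution function
#'
#' Fourier-transform route: S(k) = 1 + 4 pi rho \int_0^{r_max} dr r^2
#' sin(kr)/(kr) (g(r) - 1), evaluated by trapezoidal quadrature on the RDF
#' grid and truncated at r_max. Provided for cross-checking the direct
#' reciprocal-lattice route; values at k < 2 pi / r_max are flagged as
#' truncation-sensitive.
#'
#' @param rdf An `rdf_curve` from [compute_rdf()], or any data.frame with
#'   columns `r`, `g` plus a `rho` attribute.
#' @param k Numeric vector of wavenumbers (nm^-1), all positive.
#' @param rho Number density in nm^-3; defaults to the curve's attribute.
#' @return An `sk_curve` data.frame with columns `k`, `S` and
#'   `truncation_sensitive` (logical).
#' @export
structure_factor_from_rdf <- function(rdf, k, rho = attr(rdf, "rho")) {
  if (any(k <= 0)) stop("all k must be positive")
  if (is.null(rho)) stop("rho must be supplied (nm^-3)")
  r <- rdf$r
  h <- rdf$g - 1
  S <- vapply(k, function(kk) {
    f <- r^2 * sin(kk * r) / (kk * r) * h
    1 + 4 * pi * rho * trapz(r, f)
  }, numeric(1))
  r_max <- max(r)
  out <- data.frame(k = k, S = S,
                    truncation_sensitive = k < 2 * pi / r_max)
  structure(out, class = c("sk_curve", "data.frame"), rho = rho,
            r_max = r_max)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Isothermal compressibility from the k -> 0 limit of S(k)
#'
#' The long-wavelength limit of the structure factor of a homogeneous liquid
#' equals rho k_B T kappa_T; in practice S is evaluated at the smallest
#' reciprocal-lattice wavenumber k_min = 2 pi / L, valid while k_min is well
#' below 2 pi over the correlation length.
#'
#' @param S_at_kmin Structure-factor value at k_min (dimensionless, > 0).
#' @param rho Number density in nm^-3.
#' @param temperature Temperature in K.
#' @return List with `kappa_Pa` (Pa^-1), `kappa_bar` (bar^-1) and `chi`
#'   (the dimensionless rho k_B T kappa_T, i.e. the input S).
#' @export
kappa_from_sk <- function(S_at_kmin, rho, temperature) {
  if (S_at_kmin <= 0 || rho <= 0 || temperature <= 0)
    stop("S_at_kmin, rho and temperature must be positive")
  kPa <- S_at_kmin /
    (rho * fluct_constants$per_nm3_to_per_m3 * fluct_constants$kB * temperature)
  list(kappa_Pa = kPa, kappa_bar = kPa * fluct_constants$Pa_per_bar,
       chi = S_at_kmin)
}

#' Smallest reciprocal-lattice wavenumber of a cubic box
#'
#' @param L Cubic box edge in nm.
#' @return k_min = 2 pi / L in nm^-1.
#' @export
kmin_for_box <- function(L) {
  if (any(L <= 0)) stop("L must be positive")
  2 * pi / L
}

#' Export a curve as TSV with a comment header
#'
#' @param curve A data.frame (`rdf_curve`, `sk_curve`, `fluct_curve`).
#' @param path Output path.
#' @param comment Header comment lines (without the leading `#`).
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path, comment = character(0)) {
  hdr <- c(paste0("# ", comment),
           paste0("# columns: ", paste(names(curve), collapse = "\t")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
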
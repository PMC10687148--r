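# Spatial block analysis: number fluctuations in subvolumes of a closed box
# extrapolated to the bulk (open-system) limit.

# Run code under a private RNG stream; the caller's .Random.seed survives.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Subvolume number fluctuations chi_T(lambda)
#'
#' For each block ratio lambda = (V/V0)^(1/3), cubic subvolumes of edge
#' lambda * L are placed uniformly at random in the periodically wrapped box
#' of each frame; molecule counts (hydroxyl-O positions) accumulate the
#' variance-to-mean ratio chi = (<N^2> - <N>^2) / <N> for that subvolume
#' size. At lambda = 1 every placement contains all molecules, so chi is 0
#' exactly for a fixed-N trajectory. Under a fluctuating box the subvolume
#' edge tracks L(t) per frame, keeping lambda strictly relative.
#'
#' @param traj A [trajectory()].
#' @param lambda Block-ratio grid, values in (0, 1]. Default 24 points
#'   uniform on [0.05, 1].
#' @param placements Random subvolume placements per frame per lambda.
#' @param seed Integer seed; same seed and inputs give bit-identical output.
#' @param grid Logical; if TRUE, placements are a deterministic cubic grid of
#'   ceiling(placements^(1/3))^3 origins instead of random draws (exact
#'   reproducibility without a seed, used by tests).
#' @param n_blocks Frame blocks for the standard-error estimate.
#' @return A `fluct_curve` data.frame with columns `lambda`, `chi`, `stderr`,
#'   `mean_N`; attributes `V0` (mean box volume, nm^3), `rho` (nm^-3),
#'   `placements`, `seed`.
#' @export
subvolume_fluctuations <- function(traj, lambda = seq(0.05, 1, length.out = 24),
                                   placements = 64, seed = 1, grid = FALSE,
                                   n_blocks = 10) {
  if (any(lambda <= 0 | lambda > 1))
    stop("lambda values must lie in (0, 1]")
  if (placements < 1) stop("placements must be >= 1")
  pos <- oxygen_positions(traj)
  L <- vapply(traj$frames, `[[`, numeric(1), "box_edge")
  n_frames <- length(pos)
  N_per_frame <- vapply(pos, nrow, integer(1))
  counts <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fi) {
      p <- wrap_positions(pos[[fi]], L[fi])
      org <- if (grid) grid_origins(placements, L[fi])
             else matrix(stats::runif(3 * placements, 0, L[fi]), ncol = 3)
      # particle is inside a cubic subvolume of edge a anchored at the
      # origin iff its largest wrapped axis offset is below a
      d <- outer(p[, 1], org[, 1], "-")
      dmax <- d - L[fi] * floor(d / L[fi])
      for (ax in 2:3) {
        d <- outer(p[, ax], org[, ax], "-")
        dmax <- pmax(dmax, d - L[fi] * floor(d / L[fi]))
      }
      m <- sapply(seq_along(lambda), function(li) {
        if (lambda[li] == 1) return(rep(nrow(p), nrow(org)))
        colSums(dmax < lambda[li] * L[fi])
      })
      matrix(m, nrow = nrow(org))  # placements x n_lambda
    })
  })
  # counts[[frame]] is placements x n_lambda
  all_counts <- do.call(rbind, counts)
  mean_N <- colMeans(all_counts)
  var_N <- colMeans(all_counts^2) - mean_N^2
  chi <- ifelse(mean_N > 0, var_N / mean_N, 0)
  chi[lambda == 1] <- 0
  se <- block_se_chi(counts, lambda, n_blocks)
  out <- data.frame(lambda = lambda, chi = chi, stderr = se, mean_N = mean_N)
  structure(out, class = c("fluct_curve", "data.frame"),
            V0 = mean(L^3), rho = mean(N_per_frame / L^3),
            placements = placements, seed = seed)
}

grid_origins <- function(placements, L) {
  n <- max(1L, ceiling(placements^(1 / 3) - 1e-9))
  s <- (seq_len(n) - 1) * L / n
  as.matrix(expand.grid(x = s, y = s, z = s))
}

block_se_chi <- function(counts, lambda, n_blocks) {
  n_frames <- length(counts)
  if (n_frames < 2) return(rep(NA_real_, length(lambda)))
  n_blocks <- max(2L, min(n_blocks, n_frames))
  blk <- cut(seq_len(n_frames), n_blocks, labels = FALSE)
  chi_blk <- sapply(seq_len(n_blocks), function(b) {
    m <- do.call(rbind, counts[blk == b])
    mu <- colMeans(m)
    v <- colMeans(m^2) - mu^2
    ifelse(mu > 0, v / mu, 0)
  })  # n_lambda x n_blocks
  apply(chi_blk, 1, stats::sd) / sqrt(n_blocks)
}

#' Finite-size extrapolation of the bulk fluctuation level (SBA fit)
#'
#' Fits the finite-size model lambda * chi(lambda) =
#' chi_inf * (1 - lambda^3) * lambda + rho * alpha / V0^(1/3) by ordinary
#' least squares of y = lambda * chi against the model's exact regressor
#' x = lambda * (1 - lambda^3) on a small-lambda window (where x ~ lambda),
#' so the slope estimates the bulk value chi_inf = rho k_B T kappa_T and the
#' intercept the intensive surface term. Grid points with mean subvolume
#' count below `min_count` are excluded
#' (counting noise dominates); the exclusion is reported, not silent.
#'
#' @param curve A `fluct_curve` from [subvolume_fluctuations()].
#' @param window Fit window `c(lambda_lo, lambda_hi)`, a subset of (0, 1).
#'   Default c(0.05, 0.30), where lambda^3 <= 0.027.
#' @param temperature Temperature in K for the compressibility conversion
#'   (NA skips it).
#' @param min_count Minimum mean subvolume occupancy for a point to enter
#'   the fit.
#' @return An `sba_fit` list: `chi_inf`, `alpha` (nm, intercept *
#'   V0^(1/3) / rho), `intercept`, `window`, `n_points`, `excluded_low_count`,
#'   `r_squared`, `kappa_Pa`, `kappa_bar`, `temperature`, `rho`, `V0`,
#'   `flagged` (TRUE when the fitted slope is negative), and `prediction`,
#'   the full-curve model chi(lambda) = chi_inf (1 - lambda^3) +
#'   rho alpha / (V0^(1/3) lambda) evaluated on the curve's grid for the
#'   whole-range overlap diagnostic.
#' @export
sba_fit <- function(curve, window = c(0.05, 0.30), temperature = NA_real_,
                    min_count = 5) {
  stopifnot(inherits(curve, "fluct_curve"))
  if (window[1] <= 0 || window[2] >= 1 || window[1] >= window[2])
    stop("fit window must satisfy 0 < lambda_lo < lambda_hi < 1")
  inw <- curve$lambda >= window[1] & curve$lambda <= window[2]
  low <- inw & curve$mean_N < min_count
  if (any(low))
    message(sum(low), " lambda point(s) excluded from SBA fit: mean count < ",
            min_count)
  use <- inw & !low
  if (sum(use) < 3)
    stop("SBA fit needs at least 3 usable lambda points inside the window")
  x <- curve$lambda[use] * (1 - curve$lambda[use]^3)
  y <- curve$lambda[use] * curve$chi[use]
  fit <- stats::lm(y ~ x)
  chi_inf <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  flagged <- chi_inf < 0
  if (flagged)
    warning("SBA fit returned a negative slope (chi_inf < 0); ",
            "result flagged — inspect the fluctuation curve")
  rho <- attr(curve, "rho")
  V0 <- attr(curve, "V0")
  alpha <- intercept * V0^(1 / 3) / rho
  kappa <- if (is.finite(temperature) && chi_inf > 0)
    kappa_from_sk(chi_inf, rho, temperature)
  else list(kappa_Pa = NA_real_, kappa_bar = NA_real_)
  pred <- data.frame(
    lambda = curve$lambda,
    chi = chi_inf * (1 - curve$lambda^3) +
      intercept / curve$lambda
  )
  structure(list(
    chi_inf = chi_inf, alpha = alpha, intercept = intercept,
    window = window, n_points = sum(use), excluded_low_count = sum(low),
    r_squared = summary(fit)$r.squared,
    chi_inf_se = summary(fit)$coefficients[2, 2],
    kappa_Pa = kappa$kappa_Pa, kappa_bar = kappa$kappa_bar,
    temperature = temperature, rho = rho, V0 = V0,
    flagged = flagged, prediction = pred
  ), class = "sba_fit")
}

#' @export
print.sba_fit <- function(x, ...) {
  cat(sprintf("SBA fit on lambda in [%.3g, %.3g] (%d points)\n",
              x$window[1], x$window[2], x$n_points))
  cat(sprintf("  chi_inf = %.6g +- %.2g   alpha = %.4g nm   R^2 = %.4f\n",
              x$chi_inf, x$chi_inf_se, x$alpha, x$r_squared))
  if (is.finite(x$kappa_Pa))
    cat(sprintf("  kappa_T = %.4g Pa^-1 (%.4g bar^-1) at T = %g K\n",
                x$kappa_Pa, x$kappa_bar, x$temperature))
  if (x$flagged) cat("  [flagged: negative fitted slope]\n")
  invisible(x)
}

#' Isothermal compressibility from NPT volume fluctuations
#'
#' kappa_T = (<V0^2> - <V0>^2) / (k_B T <V0>) on a volume time series from a
#' constant-pressure ensemble, with a block-averaged standard error. A
#' constant series gives kappa_T = 0 (valid, not an error).
#'
#' @param volumes Numeric vector of box volumes in nm^3 (>= 2 samples).
#' @param temperature Temperature in K.
#' @param n_blocks Blocks for the standard-error estimate.
#' @return List with `kappa_Pa`, `kappa_bar`, `stderr_Pa`, `mean_V`,
#'   `var_V` (population variance, nm^6).
#' @export
kappa_from_volume_fluctuations <- function(volumes, temperature,
                                           n_blocks = 10) {
  if (length(volumes) < 2) stop("need at least 2 volume samples")
  if (temperature <= 0) stop("temperature must be positive")
  mu <- mean(volumes)
  v <- mean(volumes^2) - mu^2
  to_Pa <- fluct_constants$nm3_to_m3 /
    (fluct_constants$kB * temperature)
  kappa <- v / mu * to_Pa
  n_blocks <- max(2L, min(n_blocks, length(volumes) %/% 2L))
  blk <- cut(seq_along(volumes), n_blocks, labels = FALSE)
  kb <- vapply(seq_len(n_blocks), function(b) {
    vb <- volumes[blk == b]
    (mean(vb^2) - mean(vb)^2) / mean(vb) * to_Pa
  }, numeric(1))
  list(kappa_Pa = kappa, kappa_bar = kappa * fluct_constants$Pa_per_bar,
       stderr_Pa = stats::sd(kb) / sqrt(n_blocks),
       mean_V = mu, var_V = v)
}
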
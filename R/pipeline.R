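# Temperature-series orchestration: run every estimator on a set of
# trajectories labelled by temperature and collect one summary row per T,
# mirroring a cooling study (S(k_min), kappa_T by SBA and by volume
# fluctuations, n_H, cluster sizes, modularity).

#' Default analysis parameters for a temperature-series run
#'
#' Values follow the study conventions where stated (n_max = 70 lattice
#' components, H-bond cutoffs 0.35 nm and 30 degrees, pressure label 1 bar);
#' the rest are package defaults, all recorded in the run log.
#'
#' @return Named list of defaults.
#' @export
default_run_params <- function() {
  list(n_max = 70, bin_width = 0.02, r_max = NA_real_,
       lambda = seq(0.05, 1, length.out = 24), fit_window = c(0.05, 0.30),
       placements = 64, d_max = 0.35, theta_max = 30,
       seed = 1, stride = 1, discard = 0)
}

#' Read a YAML run configuration
#'
#' Layout: a `temperatures` list of `{temperature, path, format}` entries,
#' an optional `params` block overriding [default_run_params()], and
#' `output_dir`.
#'
#' @param path YAML file.
#' @return A run-config list accepted by [run_temperature_series()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$temperatures)) stop("config needs a 'temperatures' list")
  if (!is.null(cfg$params$fit_window))
    cfg$params$fit_window <- as.numeric(cfg$params$fit_window)
  if (!is.null(cfg$params$lambda))
    cfg$params$lambda <- as.numeric(cfg$params$lambda)
  cfg
}

#' Run the full analysis over a temperature series
#'
#' For each `{temperature, path|trajectory}` entry: read the trajectory,
#' apply frame discard/stride, then compute the RDF, the direct structure
#' factor and S(k_min) with its compressibility, the subvolume fluctuation
#' curve and SBA fit, the volume-fluctuation estimate (when the box
#' fluctuates), and the H-bond network report (when a hydroxyl topology is
#' present). Per-temperature curves and fit results are written under
#' `output_dir`; one summary row per temperature is returned. A failure in
#' one temperature is recorded in its row and the run continues; the result
#' carries `attr(, "n_failed")` so callers can exit nonzero.
#'
#' Given identical config (including seed) and input files, every output
#' byte is reproducible: per-temperature placement seeds are derived as
#' `seed + entry index`.
#'
#' @param config List with `temperatures` (list of entries with
#'   `temperature` and `path` + `format`, or an in-memory `trajectory`),
#'   optional `params` overriding [default_run_params()], and `output_dir`.
#' @return A `data.frame` of summary rows (class `run_summary`), sorted by
#'   temperature descending.
#' @export
run_temperature_series <- function(config) {
  prm <- utils::modifyList(default_run_params(), config$params %||% list())
  outdir <- config$output_dir %||% stop("config needs output_dir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  entries <- config$temperatures
  temps <- vapply(entries, function(e) as.numeric(e$temperature), numeric(1))
  if (anyDuplicated(temps)) stop("temperatures must be distinct")
  log_lines <- c(sprintf("fluctnet temperature-series run"),
                 sprintf("parameters: %s",
                         jsonlite::toJSON(prm, auto_unbox = TRUE, digits = NA)))
  rows <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    rows[[i]] <- tryCatch(
      analyze_one_temperature(e, prm, seed = prm$seed + i, outdir = outdir),
      error = function(err) {
        data.frame(temperature = as.numeric(e$temperature), status = "error",
                   error = conditionMessage(err), rho = NA_real_,
                   S_kmin = NA_real_, S_kmin_se = NA_real_,
                   kappa_sk_Pa = NA_real_, chi_inf = NA_real_,
                   chi_inf_se = NA_real_, kappa_sba_Pa = NA_real_,
                   kappa_vol_Pa = NA_real_, kappa_vol_se = NA_real_,
                   n_H = NA_real_, mean_largest = NA_real_, Q = NA_real_)
      })
    log_lines <- c(log_lines,
                   sprintf("T=%g K: %s", temps[i], rows[[i]]$status[1]))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$temperature), , drop = FALSE]
  rownames(tab) <- NULL
  for (i in seq_len(nrow(tab))) {
    jsonlite::write_json(as.list(tab[i, , drop = FALSE]),
                         file.path(outdir,
                                   sprintf("row_T%g.json", tab$temperature[i])),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  writeLines(log_lines, file.path(outdir, "run.log"))
  n_failed <- sum(tab$status == "error")
  structure(tab, class = c("run_summary", class(tab)), n_failed = n_failed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_one_temperature <- function(entry, prm, seed, outdir) {
  temp <- as.numeric(entry$temperature)
  traj <- if (!is.null(entry$trajectory)) entry$trajectory
          else read_trajectory(entry$path, format = entry$format %||% "gro",
                               temperature = temp)
  keep <- seq_along(traj$frames)
  if (prm$discard > 0) keep <- keep[keep > prm$discard]
  keep <- keep[seq(1, length(keep), by = prm$stride)]
  if (length(keep) < 1) stop("no frames left after discard/stride")
  traj <- trajectory(traj$frames[keep], topology = traj$topology,
                     temperature = temp, pressure = traj$pressure)
  L <- vapply(traj$frames, `[[`, numeric(1), "box_edge")
  pos <- oxygen_positions(traj)
  rho <- mean(vapply(pos, nrow, integer(1)) / L^3)
  tag <- sprintf("T%g", temp)

  r_max <- if (is.finite(prm$r_max)) prm$r_max else min(L) / 2
  rdf <- compute_rdf(traj, bin_width = prm$bin_width, r_max = r_max)
  write_curve_tsv(rdf, file.path(outdir, paste0("rdf_", tag, ".tsv")),
                  comment = sprintf("g(r), T=%g K, rho=%g nm^-3", temp, rho))

  sk <- structure_factor_direct(traj, n_max = prm$n_max)
  write_curve_tsv(sk, file.path(outdir, paste0("sk_", tag, ".tsv")),
                  comment = sprintf("S(k), T=%g K, k_min=%g nm^-1",
                                    temp, attr(sk, "k_min")))
  S_kmin <- sk$S[1]
  S_kmin_se <- sk$stderr[1]
  kappa_sk <- kappa_from_sk(S_kmin, rho, temp)

  fc <- subvolume_fluctuations(traj, lambda = prm$lambda,
                               placements = prm$placements, seed = seed)
  write_curve_tsv(fc, file.path(outdir, paste0("chi_", tag, ".tsv")),
                  comment = sprintf("chi_T(lambda), T=%g K", temp))
  fit <- sba_fit(fc, window = prm$fit_window, temperature = temp)
  jsonlite::write_json(unclass(fit)[setdiff(names(unclass(fit)), "prediction")],
                       file.path(outdir, paste0("sba_", tag, ".json")),
                       auto_unbox = TRUE, digits = NA)

  kv <- list(kappa_Pa = NA_real_, stderr_Pa = NA_real_)
  if (length(L) > 1 && stats::sd(L) > 0)
    kv <- kappa_from_volume_fluctuations(L^3, temp)

  n_H <- NA_real_; mean_largest <- NA_real_; Q <- NA_real_
  if (!is.null(traj$topology)) {
    hb <- analyze_hbond_network(traj, d_max = prm$d_max,
                                theta_max = prm$theta_max)
    n_H <- hb$n_H
    mean_largest <- hb$clusters$mean_largest
    Q <- hb$Q
    jsonlite::write_json(
      list(n_H = hb$n_H, Q = hb$Q, regime = hb$regime,
           mean_largest = hb$clusters$mean_largest,
           mean_degree_bonded = hb$mean_degree_bonded,
           size_distribution = hb$clusters$size_distribution),
      file.path(outdir, paste0("hbond_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  data.frame(temperature = temp, status = "ok", error = "",
             rho = rho, S_kmin = S_kmin, S_kmin_se = S_kmin_se,
             kappa_sk_Pa = kappa_sk$kappa_Pa,
             chi_inf = fit$chi_inf, chi_inf_se = fit$chi_inf_se,
             kappa_sba_Pa = fit$kappa_Pa,
             kappa_vol_Pa = kv$kappa_Pa, kappa_vol_se = kv$stderr_Pa,
             n_H = n_H, mean_largest = mean_largest, Q = Q)
}

#' Consolidate a completed run directory into one summary table
#'
#' Merges the per-temperature row files written by
#' [run_temperature_series()], sorted by temperature descending (the cooling
#' direction). Failed temperatures are kept and flagged by their `status`
#' column, never dropped silently; missing rows only raise a warning.
#'
#' @param output_dir Run directory.
#' @return The merged summary data.frame; also written to `summary.tsv` and
#'   `summary.json` inside `output_dir`.
#' @export
summarize_run <- function(output_dir) {
  files <- sort(list.files(output_dir, pattern = "^row_T.*\\.json$",
                           full.names = TRUE))
  if (length(files) == 0) {
    warning("no summary rows found in ", output_dir)
    return(invisible(NULL))
  }
  rows <- lapply(files, function(f)
    as.data.frame(jsonlite::read_json(f, simplifyVector = TRUE)))
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$temperature), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$status == "error"))
    warning(sum(tab$status == "error"), " temperature(s) failed; ",
            "rows flagged in the summary")
  utils::write.table(tab, file.path(output_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(tab, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tab
}
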
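#' Default study configuration
#'
#' Configuration for a full simulate-and-analyze run emulating the barrel
#' study: three toast levels, daily ECI over days 0-90 with the reference
#' kinetic parameters, the four-phase trajectory (late ramp after day
#' 60), one representative DPV scan per level, and one stave image per
#' level. All randomness flows from the single `seed`.
#'
#' @param seed Integer master seed.
#' @param days Measurement days.
#' @param replicates ECI replicates per day.
#' @param noise_sd ECI measurement noise (uA/V).
#' @param late_slope,late_onset Late linear-rise parameters (uA/V/day,
#'   day).
#' @param fit_window Kinetic fitting window (days).
#' @param dpv_days Days at which a voltammogram is also written.
#' @param image_size Stave image side length (pixels).
#' @return A list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L, days = 0:90, replicates = 1L,
                           noise_sd = 0.02, late_slope = 0.002,
                           late_onset = 60, fit_window = c(0, 90),
                           dpv_days = 7, image_size = 128L) {
  ref <- reference_kinetics()
  kin <- lapply(seq_len(nrow(ref)), function(i) {
    list(eci_eq = ref$ECI_eq[i], a1_mag = ref$A1[i], k1 = ref$k1[i],
         a2_mag = ref$A2[i], k2 = ref$k2[i])
  })
  names(kin) <- ref$toast_level
  structure(
    list(seed = seed, days = days, replicates = replicates,
         noise_sd = noise_sd, late_slope = late_slope,
         late_onset = late_onset, fit_window = fit_window,
         dpv_days = dpv_days, image_size = image_size,
         toast_levels = ref$toast_level, kinetics = kin),
    class = "run_config")
}

#' Validate a study configuration
#'
#' Checks invariants (positive rate constants, non-negative noise,
#' integer seed, known toast levels) before any file is written.
#'
#' @param config A [default_config()]-style list.
#' @return The config, invisibly; errors on the first violation.
#' @export
validate_config <- function(config) {
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      config$seed != round(config$seed)) {
    stop("config: `seed` must be a single integer", call. = FALSE)
  }
  if (any(config$days < 0)) stop("config: days must be non-negative",
                                 call. = FALSE)
  if (config$noise_sd < 0) stop("config: `noise_sd` must be >= 0",
                                call. = FALSE)
  for (lev in config$toast_levels) {
    k <- config$kinetics[[lev]]
    if (is.null(k)) {
      stop(sprintf("config: no kinetic scenario for toast level '%s'",
                   lev), call. = FALSE)
    }
    if (k$k1 <= 0 || k$k2 <= 0) {
      stop(sprintf("config: rate constants for '%s' must be positive",
                   lev), call. = FALSE)
    }
    if (k$a1_mag < 0 || k$a2_mag < 0) {
      stop(sprintf("config: amplitude magnitudes for '%s' must be >= 0",
                   lev), call. = FALSE)
    }
  }
  invisible(config)
}

#' Simulate the study inputs to disk
#'
#' Writes, per toast level, the simulated ECI series CSV
#' (`eci_<level>.csv`), representative voltammogram CSVs
#' (`voltammogram_<level>_day<d>.csv`) and a stave image PNG
#' (`texture_<level>.png`), plus a `config.json` echo of the scenario.
#' The configuration is validated before anything is written; identical
#' configurations produce byte-identical data files.
#'
#' @param config A [default_config()]-style list.
#' @param dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the vector of files written.
#' @export
simulate_study <- function(config = default_config(), dir, quiet = TRUE) {
  validate_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  with_seed(config$seed, {
    for (lev in config$toast_levels) {
      k <- config$kinetics[[lev]]
      sc <- kinetic_scenario(k$eci_eq, k$a1_mag, k$k1, k$a2_mag, k$k2,
                             late_slope = config$late_slope,
                             late_onset = config$late_onset,
                             noise_sd = config$noise_sd)
      s <- gen_eci_series(sc, config$days, config$replicates, lev)
      f <- file.path(dir, sprintf("eci_%s.csv", lev))
      write_eci_series(s, f)
      files <- c(files, f)
      vs <- gen_voltammogram_series(sc, days = config$dpv_days,
                                    toast_level = lev)
      for (ix in seq_along(vs)) {
        f <- file.path(dir, sprintf("voltammogram_%s_day%g.csv", lev,
                                    config$dpv_days[ix]))
        write_voltammogram(vs[[ix]], f)
        files <- c(files, f)
      }
      img <- gen_texture_image(texture_preset(lev,
                                              image_size =
                                                config$image_size))
      f <- file.path(dir, sprintf("texture_%s.png", lev))
      write_gray_png(img, f)
      files <- c(files, f)
      if (!quiet) message("simulated toast level: ", lev)
    }
  })
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, "config.json"))
  invisible(files)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Analyze simulated or measured study inputs
#'
#' Runs the analysis stages over the files written by [simulate_study()]
#' (or equivalently formatted measured data): `eci` loads the ECI series
#' (and recomputes the index from any voltammogram CSVs present), `fit`
#' fits the bi-exponential kinetic model per toast level and writes a
#' parameter table, `phases` segments the four kinetic phases, `texture`
#' computes direction-averaged GLCM metrics of the stave images, and
#' `multivariate` assembles the feature matrix and runs PCA, Spearman
#' correlations and the across-level ANOVA. A run log with package
#' version, seed and stage timings is always written.
#'
#' @param dir Directory holding the input files.
#' @param stages Subset of `c("eci", "fit", "phases", "texture",
#'   "multivariate")`.
#' @param fit_window Kinetic fitting window (days).
#' @param out_dir Output directory (defaults to `dir`).
#' @return Invisibly, a list with the stage results (`series`, `fits`,
#'   `parameters`, `phases`, `texture`, `pca`, `spearman`, `anova`).
#' @export
analyze_study <- function(dir,
                          stages = c("eci", "fit", "phases", "texture",
                                     "multivariate"),
                          fit_window = c(0, 90), out_dir = dir) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("ecikinetics %s | R %s",
                         as.character(utils::packageVersion("ecikinetics")),
                         paste(R.version$major, R.version$minor,
                               sep = ".")),
                 sprintf("input: %s", dir),
                 sprintf("stages: %s", paste(stages, collapse = ",")))
  res <- list()

  lev_files <- list.files(dir, pattern = "^eci_.*\\.csv$",
                          full.names = TRUE)
  if ("eci" %in% stages) {
    res$series <- run_stage("eci", {
      if (length(lev_files) == 0L) {
        stop(sprintf("no ECI series CSVs (eci_*.csv) found in %s", dir))
      }
      parts <- lapply(lev_files, read_eci_series)
      all <- do.call(rbind, lapply(parts, as.data.frame))
      vfiles <- list.files(dir, pattern = "^voltammogram_.*\\.csv$",
                           full.names = TRUE)
      if (length(vfiles) > 0L) {
        vs <- lapply(vfiles, read_voltammogram)
        dpv <- eci_timeseries(vs)
        write_eci_series(dpv, file.path(out_dir, "eci_from_dpv.csv"))
      }
      eci_series(all$day, all$eci, all$toast_level, all$replicate)
    })
  }

  if ("fit" %in% stages) {
    res$fits <- run_stage("fit", {
      if (is.null(res$series)) stop("stage 'eci' must run before 'fit'")
      levs <- unique(res$series$toast_level)
      fits <- lapply(levs, function(lev) {
        fit_kinetics(res$series[res$series$toast_level == lev, ],
                     window = fit_window)
      })
      names(fits) <- levs
      fits
    })
    res$parameters <- do.call(rbind, lapply(names(res$fits), function(l) {
      p <- res$fits[[l]]$params
      data.frame(toast_level = l, ECI_eq = p$eci_eq, A1 = abs(p$a1),
                 k1 = p$k1, A2 = abs(p$a2), k2 = p$k2, R2 = p$r2)
    }))
    utils::write.csv(res$parameters,
                     file.path(out_dir, "kinetic_parameters.csv"),
                     row.names = FALSE)
  }

  if ("phases" %in% stages) {
    res$phases <- run_stage("phases", {
      if (is.null(res$series)) stop("stage 'eci' must run before 'phases'")
      levs <- unique(res$series$toast_level)
      ph <- lapply(levs, function(lev) {
        sg <- segment_phases(res$series[res$series$toast_level == lev, ])
        list(breakpoints = sg$breakpoints,
             slopes = as.list(sg$slopes), sse = sg$sse,
             pattern_ok = sg$pattern_ok,
             no_structure = sg$no_structure)
      })
      names(ph) <- levs
      jsonlite::write_json(ph, file.path(out_dir, "phases.json"),
                           auto_unbox = TRUE, digits = NA)
      ph
    })
  }

  if ("texture" %in% stages) {
    res$texture <- run_stage("texture", {
      ifiles <- list.files(dir, pattern = "^texture_.*\\.png$",
                           full.names = TRUE)
      if (length(ifiles) == 0L) {
        stop(sprintf("no stave images (texture_*.png) found in %s", dir))
      }
      rows <- lapply(ifiles, function(f) {
        lev <- sub("^texture_(.*)\\.png$", "\\1", basename(f))
        m <- glcm_features(read_gray_png(f))$average
        data.frame(toast_level = lev, Contrast = m$contrast,
                   Entropy = m$entropy, Homogeneity = m$homogeneity,
                   Energy = m$energy, Correlation = m$correlation)
      })
      tex <- do.call(rbind, rows)
      utils::write.csv(tex, file.path(out_dir, "texture_metrics.csv"),
                       row.names = FALSE)
      tex
    })
  }

  if ("multivariate" %in% stages) {
    res <- run_stage("multivariate", {
      if (is.null(res$parameters)) {
        stop("stage 'fit' must run before 'multivariate'")
      }
      desc <- default_descriptors()
      if (!is.null(res$texture) &&
          all(res$parameters$toast_level %in% res$texture$toast_level)) {
        ix <- match(desc$toast_level, res$texture$toast_level)
        ok <- !is.na(ix)
        desc$Contrast[ok] <- res$texture$Contrast[ix[ok]]
        desc$Entropy[ok] <- res$texture$Entropy[ix[ok]]
        desc$Homogeneity[ok] <- res$texture$Homogeneity[ix[ok]]
      }
      fm <- assemble_feature_matrix(res$parameters, desc)
      pca <- run_pca(fm)
      utils::write.csv(data.frame(variable = rownames(pca$loadings),
                                  pca$loadings),
                       file.path(out_dir, "pca_loadings.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(toast_level = rownames(pca$scores),
                                  pca$scores),
                       file.path(out_dir, "pca_scores.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(explained_pct = pca$explained_pct),
                           file.path(out_dir, "pca.json"),
                           auto_unbox = FALSE, digits = NA)
      pairs <- list(c("A1", "A2"), c("A1", "k1"), c("A1", "Raman_G"),
                    c("k1", "Raman_G"), c("FTIR_OH", "Contrast"),
                    c("FTIR_CO", "Raman_G"))
      sp <- do.call(rbind, lapply(pairs, function(pr) {
        data.frame(var1 = pr[1], var2 = pr[2],
                   rho = spearman_rho(fm[, pr[1]], fm[, pr[2]]))
      }))
      utils::write.csv(sp, file.path(out_dir,
                                     "spearman_correlations.csv"),
                       row.names = FALSE)
      an <- NULL
      if (!is.null(res$series)) {
        groups <- split(res$series$eci, res$series$toast_level)
        if (length(groups) >= 2L && all(lengths(groups) >= 2L)) {
          an <- one_way_anova(groups)
          jsonlite::write_json(
            list(f_stat = an$f_stat, df_between = an$df_between,
                 df_within = an$df_within, p_value = an$p_value),
            file.path(out_dir, "anova.json"), auto_unbox = TRUE,
            digits = NA)
        }
      }
      c(res, list(feature_matrix = fm, pca = pca, spearman = sp,
                  anova = an))
    })
  }

  log_lines <- c(log_lines,
                 sprintf("elapsed: %.2f s",
                         as.numeric(difftime(Sys.time(), t0,
                                             units = "secs"))))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
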
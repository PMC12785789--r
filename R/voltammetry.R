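#' Differential-pulse voltammogram
#'
#' A voltammogram is a sampled current-versus-potential curve recorded by
#' differential pulse voltammetry (DPV) against a saturated Ag/AgCl
#' reference electrode. Potentials are in volts and must be strictly
#' increasing; currents are in microamperes.
#'
#' @param potential Numeric vector of potentials (V vs Ag/AgCl(sat)),
#'   strictly increasing, length >= 2.
#' @param current Numeric vector of currents (uA), same length.
#' @param sample_id Optional sample identifier.
#' @param day Optional maturation day the scan was taken.
#' @param toast_level Optional barrel toast level ("light", "medium",
#'   "intense").
#' @param replicate Optional replicate id.
#' @return An object of class `"voltammogram"`.
#' @export
voltammogram <- function(potential, current, sample_id = NA_character_,
                         day = NA_real_, toast_level = NA_character_,
                         replicate = NA_integer_) {
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) < 2L) {
    stop("a voltammogram needs at least 2 points", call. = FALSE)
  }
  if (length(potential) != length(current)) {
    stop("`potential` and `current` must have the same length", call. = FALSE)
  }
  if (anyNA(potential) || anyNA(current) || any(!is.finite(potential)) ||
      any(!is.finite(current))) {
    stop("potentials and currents must be finite", call. = FALSE)
  }
  if (any(diff(potential) <= 0)) {
    stop("`potential` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(potential = potential, current = current,
         sample_id = as.character(sample_id), day = as.numeric(day),
         toast_level = as.character(toast_level),
         replicate = replicate),
    class = "voltammogram"
  )
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf(
    "DPV voltammogram: %d points, %.3f to %.3f V vs Ag/AgCl(sat)\n",
    length(x$potential), min(x$potential), max(x$potential)))
  if (!is.na(x$day) || !is.na(x$toast_level)) {
    cat(sprintf("  day %s, toast level %s, replicate %s\n",
                format(x$day), x$toast_level, format(x$replicate)))
  }
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, ...) {
  graphics::plot(x$potential, x$current, type = "l",
                 xlab = "E (V vs Ag/AgCl(sat))", ylab = "i (uA)", ...)
  invisible(x)
}

#' Oxidation peak pair entering the Electrochemical Color Index
#'
#' Holds the two anodic peaks used by the index: the polyphenol peak near
#' 0.34 V and the flavonoid peak near 0.50 V (potentials vs Ag/AgCl(sat)).
#'
#' @param e1,i1 Potential (V) and current (uA) of the lower-potential peak.
#' @param e2,i2 Potential (V) and current (uA) of the higher-potential peak.
#' @param present1,present2 Logical flags; `FALSE` marks a peak that was not
#'   found above the baseline (its current is forced to 0).
#' @return An object of class `"peak_set"`.
#' @export
peak_set <- function(e1, i1, e2, i2, present1 = TRUE, present2 = TRUE) {
  for (nm in c("e1", "i1", "e2", "i2")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (e1 <= 0 || e2 <= 0) {
    stop("peak potentials must be positive", call. = FALSE)
  }
  if (e1 >= e2) {
    stop("`e1` must be smaller than `e2`", call. = FALSE)
  }
  if (i1 < 0 || i2 < 0) {
    stop("peak currents must be non-negative", call. = FALSE)
  }
  structure(list(e1 = e1, i1 = i1, e2 = e2, i2 = i2,
                 present1 = isTRUE(present1), present2 = isTRUE(present2)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak 1: E = %.3f V, i = %.4g uA%s\n", x$e1, x$i1,
              if (x$present1) "" else " (absent)"))
  cat(sprintf("peak 2: E = %.3f V, i = %.4g uA%s\n", x$e2, x$i2,
              if (x$present2) "" else " (absent)"))
  invisible(x)
}

#' Locate the two ECI oxidation peaks in a voltammogram
#'
#' Searches a window around each nominal peak potential (defaults 0.34 and
#' 0.50 V, the polyphenol and flavonoid oxidation signals) and reports the
#' grid point of maximum current within each window. No sub-grid
#' interpolation is performed: the 5 mV DPV step resolves the index
#' adequately. With `baseline = "linear"` a straight line is first fitted to
#' the scan regions far from both targets (farther than `exclusion`) and
#' subtracted, which makes the heights invariant to linear drift and
#' constant offsets.
#'
#' A window whose maximum (after any baseline correction) is not positive is
#' flagged absent and its current set to 0.
#'
#' @param v A [voltammogram()].
#' @param targets Two nominal peak potentials (V), increasing.
#' @param window Half-width (V) of the search window around each target.
#' @param baseline `"none"` (raw currents, the default) or `"linear"`.
#' @param exclusion Distance (V) from a target beyond which points are used
#'   for the linear baseline fit. Defaults to `3 * window`.
#' @return A [peak_set()].
#' @export
detect_peaks <- function(v, targets = c(0.34, 0.50), window = 0.06,
                         baseline = c("none", "linear"),
                         exclusion = 3 * window) {
  stopifnot(inherits(v, "voltammogram"))
  baseline <- match.arg(baseline)
  targets <- sort(as.numeric(targets))
  if (length(targets) != 2L) {
    stop("`targets` must name exactly two peak potentials", call. = FALSE)
  }
  stop_if_not_scalar_number(window, "window")
  rng <- range(v$potential)
  for (tg in targets) {
    if (tg - window < rng[1] || tg + window > rng[2]) {
      stop(sprintf("search window %.3f +/- %.3f V lies outside the scan range",
                   tg, window), call. = FALSE)
    }
  }
  cur <- v$current
  if (baseline == "linear") {
    far <- abs(v$potential - targets[1]) > exclusion &
      abs(v$potential - targets[2]) > exclusion
    if (sum(far) < 2L) {
      stop("too few baseline points outside the peak exclusion zones",
           call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, v$potential[far]), cur[far])
    cur <- cur - (fit$coefficients[1] + fit$coefficients[2] * v$potential)
  }
  one <- function(tg) {
    sel <- which(abs(v$potential - tg) <= window + 1e-12)
    k <- sel[which.max(cur[sel])]
    h <- cur[k]
    list(e = v$potential[k], i = max(h, 0), present = h > 0)
  }
  p1 <- one(targets[1])
  p2 <- one(targets[2])
  peak_set(p1$e, p1$i, p2$e, p2$i, p1$present, p2$present)
}

#' Electrochemical Color Index from a peak pair
#'
#' The ECI condenses a DPV scan into one scalar: the sum over the two
#' oxidation peaks of peak current divided by peak potential,
#' `ECI = i1/E1 + i2/E2` (uA/V). Each ratio weights the amount of
#' electroactive phenolics (peak current) by their oxidation ease (peak
#' potential), so the index tracks the global chromophore load of the
#' distillate.
#'
#' @param p A [peak_set()].
#' @return The index in uA/V (non-negative).
#' @export
compute_eci <- function(p) {
  stopifnot(inherits(p, "peak_set"))
  if (p$e1 <= 0 || p$e2 <= 0) {
    stop("peak potentials must be positive to form the index", call. = FALSE)
  }
  p$i1 / p$e1 + p$i2 / p$e2
}

#' ECI time series
#'
#' A tidy table of daily ECI measurements: one row per (toast level, day,
#' replicate). Days must be non-negative.
#'
#' @param day Numeric vector of maturation days (>= 0).
#' @param eci Numeric vector of index values (uA/V).
#' @param toast_level Character vector of toast levels.
#' @param replicate Replicate ids (defaults to 1).
#' @return A data frame of class `"eci_series"` sorted by toast level, day
#'   and replicate.
#' @export
eci_series <- function(day, eci, toast_level = "sample", replicate = 1L) {
  day <- as.numeric(day)
  eci <- as.numeric(eci)
  n <- length(day)
  if (length(eci) != n) {
    stop("`day` and `eci` must have the same length", call. = FALSE)
  }
  if (n > 0 && (anyNA(day) || any(day < 0))) {
    stop("days must be non-negative", call. = FALSE)
  }
  if (n > 0 && any(!is.finite(eci))) {
    stop("ECI values must be finite", call. = FALSE)
  }
  out <- data.frame(day = day, eci = eci,
                    toast_level = rep_len(as.character(toast_level), n),
                    replicate = rep_len(replicate, n))
  out <- out[order(out$toast_level, out$day, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eci_series", "data.frame")
  out
}

#' Build an ECI time series from a set of voltammograms
#'
#' Runs peak detection and the index on every scan, carrying the `day`,
#' `toast_level` and `replicate` metadata along. Duplicate
#' (toast level, day, replicate) triples are rejected.
#'
#' @param voltammograms List of [voltammogram()] objects with `day`
#'   metadata.
#' @param ... Passed to [detect_peaks()].
#' @return An [eci_series()].
#' @export
eci_timeseries <- function(voltammograms, ...) {
  if (length(voltammograms) == 0L) {
    return(eci_series(numeric(0), numeric(0), character(0), integer(0)))
  }
  stopifnot(all(vapply(voltammograms, inherits, logical(1), "voltammogram")))
  day <- vapply(voltammograms, function(v) v$day, numeric(1))
  if (anyNA(day)) {
    stop("every voltammogram needs `day` metadata", call. = FALSE)
  }
  lev <- vapply(voltammograms, function(v) v$toast_level, character(1))
  rep_ <- vapply(voltammograms, function(v) as.integer(v$replicate),
                 integer(1))
  key <- paste(lev, day, rep_, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (toast_level, day, replicate) measurements", call. = FALSE)
  }
  vals <- vapply(voltammograms,
                 function(v) compute_eci(detect_peaks(v, ...)), numeric(1))
  eci_series(day, vals, lev, rep_)
}

#' Read and write voltammogram CSV files
#'
#' The on-disk format is a plain CSV with columns `potential_V` and
#' `current_uA`; metadata travel as constant extra columns (`sample_id`,
#' `day`, `toast_level`, `replicate`).
#'
#' @param v A [voltammogram()].
#' @param path File path.
#' @return `write_voltammogram()` returns `path` invisibly;
#'   `read_voltammogram()` returns a [voltammogram()].
#' @export
write_voltammogram <- function(v, path) {
  stopifnot(inherits(v, "voltammogram"))
  df <- data.frame(potential_V = v$potential, current_uA = v$current,
                   sample_id = v$sample_id, day = v$day,
                   toast_level = v$toast_level, replicate = v$replicate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltammogram
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("voltammogram file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  voltammogram(df$potential_V, df$current_uA,
               sample_id = df$sample_id[1], day = df$day[1],
               toast_level = df$toast_level[1], replicate = df$replicate[1])
}

#' Read and write ECI series CSV files
#'
#' Columns: `day,eci,toast_level,replicate`.
#'
#' @param s An [eci_series()].
#' @param path File path.
#' @return `write_eci_series()` returns `path` invisibly;
#'   `read_eci_series()` returns an [eci_series()].
#' @export
write_eci_series <- function(s, path) {
  stopifnot(inherits(s, "eci_series"))
  utils::write.csv(as.data.frame(s)[c("day", "eci", "toast_level",
                                      "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eci_series
#' @export
read_eci_series <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("ECI series file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path)
  eci_series(df$day, df$eci, df$toast_level, df$replicate)
}
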
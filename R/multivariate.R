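#' Canonical feature-matrix variable names
#'
#' The eleven structural and kinetic descriptors relating stave surface
#' chemistry/texture to extraction kinetics, in canonical column order:
#' FTIR O-H band (3547 cm-1) and C=O band (1666 cm-1) intensities, Raman G
#' band (1588 cm-1) intensity, GLCM contrast, entropy and homogeneity of
#' the stave image, and the kinetic parameters A1, A2, k1, k2 and ECI_eq.
#'
#' @return Character vector of length 11.
#' @export
feature_variables <- function() {
  c("FTIR_OH", "FTIR_CO", "Raman_G", "Contrast", "Entropy", "Homogeneity",
    "A1", "A2", "k1", "k2", "ECI_eq")
}

#' Default structural descriptors per toast level
#'
#' Published scalar descriptors of the toasted staves: Raman G band
#' intensity and the direction-averaged GLCM contrast, entropy and
#' homogeneity of the stave photographs. The two FTIR band intensities
#' were not published as numbers; the defaults are synthetic placeholders
#' chosen to follow the reported qualitative trends (O-H decreases with
#' toasting as hydroxyls are degraded, C=O increases as carbonyls form)
#' and should be replaced with measured values when available.
#'
#' @param ftir_oh,ftir_co Length-3 numeric vectors (light, medium,
#'   intense) overriding the placeholder FTIR band intensities.
#' @return Data frame with `toast_level` plus the six structural
#'   descriptor columns.
#' @export
default_descriptors <- function(ftir_oh = c(1.00, 0.75, 0.50),
                                ftir_co = c(0.40, 0.70, 1.00)) {
  stopifnot(length(ftir_oh) == 3L, length(ftir_co) == 3L)
  data.frame(
    toast_level = c("light", "medium", "intense"),
    FTIR_OH = as.numeric(ftir_oh),
    FTIR_CO = as.numeric(ftir_co),
    Raman_G = c(1.14, 1.09, 4.32),
    Contrast = c(252.73, 236.06, 307.06),
    Entropy = c(12.32, 11.92, 12.16),
    Homogeneity = c(0.1824, 0.2043, 0.1717),
    stringsAsFactors = FALSE
  )
}

#' Assemble the toast-level feature matrix
#'
#' Joins the kinetic parameter table (columns `A1`, `A2`, `k1`, `k2`,
#' `ECI_eq`, magnitudes) with the structural descriptor table on
#' `toast_level` and returns the 3 x 11 matrix in canonical variable order
#' (rows light, medium, intense).
#'
#' @param kinetics Data frame with `toast_level` and the five kinetic
#'   columns; defaults to [reference_kinetics()].
#' @param descriptors Data frame with `toast_level` and the six structural
#'   columns; defaults to [default_descriptors()].
#' @return A numeric matrix of class `"feature_matrix"`.
#' @export
assemble_feature_matrix <- function(kinetics = reference_kinetics(),
                                    descriptors = default_descriptors()) {
  for (df in list(kinetics, descriptors)) {
    if (!"toast_level" %in% names(df)) {
      stop("both tables need a `toast_level` column", call. = FALSE)
    }
  }
  if (!setequal(kinetics$toast_level, descriptors$toast_level)) {
    stop("kinetics and descriptors must cover the same toast levels",
         call. = FALSE)
  }
  merged <- merge(descriptors, kinetics, by = "toast_level")
  missing <- setdiff(feature_variables(), names(merged))
  if (length(missing) > 0L) {
    stop(sprintf("missing feature variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lev_order <- intersect(c("light", "medium", "intense"),
                         merged$toast_level)
  if (length(lev_order) == 0L) lev_order <- merged$toast_level
  merged <- merged[match(lev_order, merged$toast_level), , drop = FALSE]
  m <- as.matrix(merged[, feature_variables(), drop = FALSE])
  if (anyNA(m)) stop("feature matrix contains missing values",
                     call. = FALSE)
  rownames(m) <- merged$toast_level
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Standardize feature columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). A zero-spread column cannot be scaled and raises
#' an error naming it.
#'
#' @param m Numeric matrix (observations x variables).
#' @return The standardized matrix.
#' @export
standardize_features <- function(m) {
  m <- unclass(as.matrix(m))
  sds <- apply(m, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0L) {
    stop(sprintf("zero-spread column(s): %s",
                 paste(colnames(m)[bad], collapse = ", ")), call. = FALSE)
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Principal component analysis of a standardized feature matrix
#'
#' Singular value decomposition of the column-standardized matrix.
#' Explained percentages come from the squared singular values; loading
#' columns are unit-norm and sign-fixed so that each column's
#' largest-magnitude entry is positive (PCA signs are otherwise
#' arbitrary). With `n` observations at most `n - 1` components are
#' non-null; only those are returned.
#'
#' @param m Numeric matrix (observations x variables), e.g. a
#'   [assemble_feature_matrix()] result.
#' @param standardize Standardize columns first (default TRUE; set FALSE
#'   if `m` is already standardized).
#' @return An object of class `"eci_pca"`: `loadings` (variables x
#'   components), `scores` (observations x components), `explained_pct`,
#'   `sdev`.
#' @export
run_pca <- function(m, standardize = TRUE) {
  X <- unclass(as.matrix(m))
  if (nrow(X) < 2L) stop("PCA needs at least 2 observations",
                         call. = FALSE)
  X <- if (standardize) standardize_features(X) else
    scale(X, scale = FALSE)
  sv <- svd(X)
  k <- min(nrow(X) - 1L, ncol(X))
  load <- sv$v[, seq_len(k), drop = FALSE]
  # fix the arbitrary component signs deterministically
  for (j in seq_len(k)) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) load[, j] <- -load[, j]
  }
  scores <- X %*% load
  expl <- 100 * sv$d^2 / sum(sv$d^2)
  dimnames(load) <- list(colnames(m), paste0("PC", seq_len(k)))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(k)))
  structure(
    list(loadings = load, scores = scores,
         explained_pct = expl[seq_len(k)],
         sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(X) - 1))),
    class = "eci_pca")
}

#' @export
print.eci_pca <- function(x, ...) {
  k <- length(x$explained_pct)
  cat(sprintf("Standardized PCA: %d component(s)\n", k))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  cat("  scores:\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank);
#' +/-1 exactly when the association is strictly monotone. With a handful
#' of ordered observations this is a descriptor of monotone trend, not an
#' inferential statistic, so no p-value is attached. If either argument
#' has no rank variation the coefficient is undefined and `NA` is
#' returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    warning("zero rank variance: Spearman rho undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' One-way analysis of variance across toast levels
#'
#' Classical between/within decomposition via [stats::aov()], returning
#' the F statistic, its degrees of freedom and the upper-tail p-value.
#' When the within-group variance is exactly zero (while group means
#' differ) the F statistic is infinite; this degenerate case is flagged
#' rather than reported as a plain number.
#'
#' @param groups List of numeric vectors, one per group, each holding at
#'   least 2 values.
#' @return An object of class `"anova_result"`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  df_b <- length(groups) - 1L
  df_w <- length(value) - length(groups)
  ss_within <- sum(unlist(lapply(groups,
                                 function(v) sum((v - mean(v))^2))))
  if (ss_within == 0) {
    degenerate <- any(vapply(groups, mean, numeric(1)) !=
                        mean(value))
    return(structure(
      list(f_stat = if (degenerate) Inf else 0,
           df_between = df_b, df_within = df_w,
           p_value = if (degenerate) 0 else 1, degenerate = degenerate),
      class = "anova_result"))
  }
  tab <- stats::anova(stats::aov(value ~ g))
  structure(
    list(f_stat = tab[["F value"]][1], df_between = tab[["Df"]][1],
         df_within = tab[["Df"]][2], p_value = tab[["Pr(>F)"]][1],
         degenerate = FALSE),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d,%d) = %.5g, p = %.5g%s\n",
              x$df_between, x$df_within, x$f_stat, x$p_value,
              if (x$degenerate) " (degenerate: zero within-group variance)"
              else ""))
  invisible(x)
}
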
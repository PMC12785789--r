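# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive double loops / direct formulas and share no
# code with the package internals.

# Direct evaluation of the five GLCM texture metrics over every (i, j)
# cell of a normalized co-occurrence matrix.
oracle_texture_metrics <- function(P) {
  L <- nrow(P)
  ent <- 0; hom <- 0; en <- 0; con <- 0
  mui <- 0; muj <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      p <- P[i, j]
      if (p > 0) ent <- ent - p * log2(p)
      hom <- hom + p / (1 + abs(i - j))
      en <- en + p * p
      con <- con + (i - j)^2 * p
      mui <- mui + (i - 1) * p
      muj <- muj + (j - 1) * p
    }
  }
  si <- 0; sj <- 0; cov <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      p <- P[i, j]
      si <- si + (i - 1 - mui)^2 * p
      sj <- sj + (j - 1 - muj)^2 * p
      cov <- cov + (i - 1 - mui) * (j - 1 - muj) * p
    }
  }
  corr <- if (si == 0 || sj == 0) NA_real_ else cov / sqrt(si * sj)
  list(contrast = con, entropy = ent, homogeneity = hom, energy = en,
       correlation = corr)
}

# Windowed sample standard deviation with mirror padding, pixel by pixel.
oracle_local_sd <- function(img, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(ix, n) {
    ix <- ifelse(ix < 1, 1 - ix, ix)        # 0 -> 1, -1 -> 2 (edge mirrored)
    ifelse(ix > n, 2 * n + 1 - ix, ix)      # n+1 -> n, n+2 -> n-1
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rs <- reflect((r - h):(r + h), nr)
      cs <- reflect((c - h):(c + h), nc)
      out[r, c] <- stats::sd(as.vector(img[rs, cs]))
    }
  }
  out
}

# Spearman's rho from first principles: mean ranks for ties, then the
# plain Pearson formula on the ranks.
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }, numeric(1))
  }
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Admissible random bi-exponential parameter draw with separated rates,
# for self-consistency fitting checks.
draw_kinetic_truth <- function() {
  repeat {
    k <- sort(stats::runif(2, 0.06, 1.4))
    if (k[2] - k[1] >= 0.05) break
  }
  amps <- stats::runif(2, 0.5, 25) * sample(c(-1, 1), 2, replace = TRUE)
  list(eci_eq = stats::runif(1, 0.1, 1),
       a_fast = amps[1], k_fast = k[2], a_slow = amps[2], k_slow = k[1])
}

# Apply the package's term-labelling rule (negative amplitude first, then
# faster rate) to a truth draw so fitted and true labels are comparable.
label_truth <- function(tr) {
  terms <- data.frame(a = c(tr$a_fast, tr$a_slow),
                      k = c(tr$k_fast, tr$k_slow))
  o <- if (sign(terms$a[1]) == sign(terms$a[2])) order(-terms$k) else
    order(terms$a)
  terms <- terms[o, ]
  c(eci_eq = tr$eci_eq, a1 = terms$a[1], k1 = terms$k[1],
    a2 = terms$a[2], k2 = terms$k[2])
}
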
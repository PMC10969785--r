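# Independent brute-force oracles, kept deliberately naive: each one
# re-derives its quantity from the mathematical definition, with none of the
# package's code paths.

# Erosion from the set definition: a pixel survives iff every active offset
# of the structuring element lands on foreground (outside the image counts
# as background).
oracleErode <- function(m, se) {
  nr <- nrow(m); nc <- ncol(m)
  ar <- (nrow(se) + 1) %/% 2; ac <- (ncol(se) + 1) %/% 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    keep <- TRUE
    for (si in seq_len(nrow(se))) for (sj in seq_len(ncol(se))) {
      if (!se[si, sj]) next
      ii <- i + si - ar; jj <- j + sj - ac
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !m[ii, jj]) keep <- FALSE
    }
    out[i, j] <- keep
  }
  out
}

# Dilation as the Minkowski sum: union of the element translated to every
# foreground pixel.
oracleDilate <- function(m, se) {
  nr <- nrow(m); nc <- ncol(m)
  ar <- (nrow(se) + 1) %/% 2; ac <- (ncol(se) + 1) %/% 2
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!m[i, j]) next
    for (si in seq_len(nrow(se))) for (sj in seq_len(ncol(se))) {
      if (!se[si, sj]) next
      ii <- i + si - ar; jj <- j + sj - ac
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) out[ii, jj] <- TRUE
    }
  }
  out
}

# Stack-based flood fill over an allowed-pixel set.
oracleFlood <- function(allowed, seed, connectivity = 8) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  out <- matrix(FALSE, nr, nc)
  if (!allowed[seed[1], seed[2]]) return(out)
  stack <- list(seed)
  out[seed[1], seed[2]] <- TRUE
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (k in seq_len(nrow(nb))) {
      ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          allowed[ii, jj] && !out[ii, jj]) {
        out[ii, jj] <- TRUE
        stack[[length(stack) + 1L]] <- c(ii, jj)
      }
    }
  }
  out
}

# Region-growing fill oracle: grow from the seed across foreground pixels
# and enclosed background (background not flood-reachable from the border).
oracleRegionFill <- function(m, seed, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  exterior <- matrix(FALSE, nr, nc)
  border <- rbind(cbind(1, seq_len(nc)), cbind(nr, seq_len(nc)),
                  cbind(seq_len(nr), 1), cbind(seq_len(nr), nc))
  for (k in seq_len(nrow(border))) {
    b <- border[k, ]
    if (!m[b[1], b[2]] && !exterior[b[1], b[2]])
      exterior <- exterior | oracleFlood(!m, b, connectivity)
  }
  allowed <- m | (!m & !exterior)
  oracleFlood(allowed, seed, connectivity)
}

# Exhaustive Otsu: scan midpoints between consecutive distinct values and
# minimize the weighted within-class sum of squares.
oracleOtsu <- function(values) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  wss <- vapply(cand, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  cand[which.min(wss)]
}

# Closed-form OLS via the normal equations.
oracleOls <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Random binary grid for property tests.
randomGrid <- function(maxSide = 16, pFg = NULL) {
  nr <- sample(2:maxSide, 1); nc <- sample(2:maxSide, 1)
  if (is.null(pFg)) pFg <- runif(1, 0.2, 0.8)
  matrix(runif(nr * nc) < pFg, nr, nc)
}
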
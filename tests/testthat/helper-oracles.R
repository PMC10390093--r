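# Brute-force reference implementations used as independent oracles, plus
# small random-fixture generators.  These deliberately use naive loops and
# first-principles definitions, never the package's own code paths.

# random connected-ish blob on an n x n canvas (may have several components)
randomBlobMask <- function(n = 20, density = 0.35, nSeeds = 2) {
  z <- matrix(FALSE, n, n)
  for (b in seq_len(nSeeds)) {
    r0 <- sample(3:(n - 2), 1)
    c0 <- sample(3:(n - 2), 1)
    k <- rpois(1, density * n * n / nSeeds) + 5
    rr <- pmax(1, pmin(n, r0 + sample(-4:4, k, replace = TRUE)))
    cc <- pmax(1, pmin(n, c0 + sample(-4:4, k, replace = TRUE)))
    z[cbind(rr, cc)] <- TRUE
  }
  z
}

# exhaustive tiling: count boxes of side s (grid anchored at index 1)
# containing at least one set pixel
bruteBoxCount <- function(m, s) {
  d <- dim(m)
  cnt <- 0L
  for (br in seq_len(ceiling(d[1] / s))) {
    for (bc in seq_len(ceiling(d[2] / s))) {
      rows <- ((br - 1) * s + 1):min(br * s, d[1])
      cols <- ((bc - 1) * s + 1):min(bc * s, d[2])
      if (any(m[rows, cols])) cnt <- cnt + 1L
    }
  }
  cnt
}

# per-pixel neighbour scan for the face-connectivity boundary
bruteBoundary2d <- function(m) {
  d <- dim(m)
  out <- matrix(FALSE, d[1], d[2])
  at <- function(r, c) r >= 1 && c >= 1 && r <= d[1] && c <= d[2] && m[r, c]
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      if (!m[r, c]) next
      if (!at(r - 1, c) || !at(r + 1, c) || !at(r, c - 1) || !at(r, c + 1))
        out[r, c] <- TRUE
    }
  }
  out
}

# direct pair enumeration GLCM (values 0-based, offset = c(dr, dc))
bruteGLCM <- function(vals, mask, offset, symmetric, levels) {
  d <- dim(vals)
  tab <- matrix(0, levels, levels)
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      r2 <- r + offset[1]
      c2 <- c + offset[2]
      if (r2 < 1 || c2 < 1 || r2 > d[1] || c2 > d[2]) next
      if (!mask[r, c] || !mask[r2, c2]) next
      i <- vals[r, c] + 1L
      j <- vals[r2, c2] + 1L
      tab[i, j] <- tab[i, j] + 1
      if (symmetric) tab[j, i] <- tab[j, i] + 1
    }
  }
  tab / sum(tab)
}

# all-pairs AUC with half credit for ties
bruteAUC <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Benjamini-Hochberg from the step-up definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# any fully-set 2x2 block?
has2x2Block <- function(m) {
  d <- dim(m)
  if (d[1] < 2 || d[2] < 2) return(FALSE)
  any(m[-d[1], -d[2]] & m[-1, -d[2]] & m[-d[1], -1] & m[-1, -1])
}
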
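## Independent brute-force oracles: written as plain per-element loops so
## they share no code path with the vectorized implementation.

naiveMembership <- function(d, m) {
  cc <- nrow(d); n <- ncol(d)
  u <- matrix(0, cc, n)
  for (k in seq_len(n)) {
    hk <- which(d[, k] == 0)
    if (length(hk)) {
      u[hk, k] <- 1 / length(hk)
    } else {
      for (i in seq_len(cc)) {
        s <- 0
        for (j in seq_len(cc)) s <- s + (d[i, k] / d[j, k])^(2 / (m - 1))
        u[i, k] <- 1 / s
      }
    }
  }
  u
}

naiveCenters <- function(x, u, m) {
  cc <- nrow(u)
  v <- numeric(cc)
  for (i in seq_len(cc)) {
    num <- 0; den <- 0
    for (k in seq_along(x)) {
      num <- num + u[i, k]^m * x[k]
      den <- den + u[i, k]^m
    }
    v[i] <- num / den
  }
  v
}

naiveObjective <- function(u, d, m) {
  s <- 0
  for (i in seq_len(nrow(u)))
    for (k in seq_len(ncol(u)))
      s <- s + u[i, k]^m * d[i, k]^2
  s
}

reflectIdx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

naiveNeighborOffsets <- function(radius, includeCenter = FALSE) {
  off <- NULL
  for (dc in -radius:radius)
    for (dr in -radius:radius)
      if (includeCenter || dr != 0 || dc != 0)
        off <- rbind(off, c(dr, dc))
  off
}

naiveWeight <- function(img, r, c, dr, dc, sigmaG) {
  rr <- reflectIdx(r + dr, nrow(img))
  cc <- reflectIdx(c + dc, ncol(img))
  exp(-((img[r, c] - img[rr, cc])^2) / sigmaG^2)
}

## per-pixel loop evaluation of the blended distance formula
naiveEffectiveDistance <- function(d, img, radius, sigmaG, beta,
                                   includeCenter = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  off <- naiveNeighborOffsets(radius, includeCenter)
  out <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d))) {
    d2img <- matrix(d[i, ]^2, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      num <- 0; den <- 0
      for (j in seq_len(nrow(off))) {
        w <- naiveWeight(img, r, c, off[j, 1], off[j, 2], sigmaG)
        rr <- reflectIdx(r + off[j, 1], nr)
        cc <- reflectIdx(c + off[j, 2], nc)
        num <- num + w * d2img[rr, cc]
        den <- den + w
      }
      k <- r + (c - 1) * nr
      out[i, k] <- sqrt((1 - beta) * d[i, k]^2 + beta * num / den)
    }
  }
  out
}

naiveReconstruct <- function(u, v, m) {
  n <- ncol(u)
  out <- numeric(n)
  for (k in seq_len(n)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(u))) {
      num <- num + u[i, k]^m * v[i]
      den <- den + u[i, k]^m
    }
    out[k] <- num / den
  }
  out
}

## SB by exhaustive search over label permutations, coded independently
naiveSB <- function(pred, truth, cc) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  perms <- gtoolsPerms(cc)
  best <- 0
  for (p in seq_len(nrow(perms))) {
    hits <- sum(perms[p, pred] == truth)
    if (hits > best) best <- hits
  }
  best / length(pred)
}

gtoolsPerms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- gtoolsPerms(k - 1)
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}

naiveWRE <- function(orig, recon) {
  s <- 0
  for (k in seq_along(orig)) s <- s + (recon[k] - orig[k])^2
  s / length(orig)
}

naiveMedian3 <- function(img, size = 3) {
  r <- (size - 1) / 2
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r)
      vals <- c(vals, img[reflectIdx(i + di, nrow(img)),
                          reflectIdx(j + dj, ncol(img))])
    out[i, j] <- median(vals)
  }
  out
}

## Independent alternate-optimization FCM loop (scalar loops throughout).
referenceFcmLoop <- function(x, cc, m, v0, maxIter = 500, eps = 1e-10) {
  v <- sort(v0)
  u <- NULL
  for (e in seq_len(maxIter)) {
    d <- matrix(0, cc, length(x))
    for (i in seq_len(cc)) for (k in seq_along(x))
      d[i, k] <- abs(v[i] - x[k])
    uNew <- naiveMembership(d, m)
    if (!is.null(u) && max(abs(u - uNew)) < eps) { u <- uNew; break }
    u <- uNew
    v <- naiveCenters(x, u, m)
  }
  list(centers = sort(v), u = u)
}
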
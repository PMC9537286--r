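# Independent brute-force oracles.  Deliberately naive implementations,
# structured differently from the package code paths they check.

# connected zones of equal grey level, 26-connectivity, plain-R BFS
oracleZones <- function(disc) {
  d <- dim(disc)
  seen <- array(FALSE, d)
  nbh <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nbh <- nbh[rowSums(abs(nbh)) > 0, ]
  res <- NULL
  for (start in which(!is.na(disc))) {
    if (seen[start]) next
    lev <- disc[start]
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(nbh))) {
        co <- ci + nbh[r, ]
        if (any(co < 1) || any(co > d)) next
        fl <- co[1] + (co[2] - 1) * d[1] + (co[3] - 1) * d[1] * d[2]
        if (!seen[fl] && !is.na(disc[fl]) && disc[fl] == lev) {
          seen[fl] <- TRUE
          queue <- c(queue, fl)
        }
      }
    }
    res <- rbind(res, c(lev, size))
  }
  res
}

oracleGlnu <- function(zones) {
  sum(as.numeric(table(zones[, 1]))^2) / nrow(zones)
}

# symmetric co-occurrence counts by explicit pair enumeration
oracleGlcm <- function(disc, offset, nLevels) {
  d <- dim(disc)
  m <- matrix(0L, nLevels, nLevels)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    a <- disc[i, j, k]
    if (is.na(a)) next
    co <- c(i, j, k) + offset
    if (any(co < 1) || any(co > d)) next
    b <- disc[co[1], co[2], co[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1L
    m[b, a] <- m[b, a] + 1L
  }
  m
}

# one-way ANOVA ICC written straight from the sum-of-squares definitions
oracleIcc <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- sum(tab) / (n * k)
  ssb <- k * sum((apply(tab, 1, sum) / k - grand)^2)
  ssw <- 0
  for (i in 1:n) for (j in 1:k) ssw <- ssw + (tab[i, j] - mean(tab[i, ]))^2
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}

# step-by-step GSVA: kernel CDF, decreasing rank, weighted random walk
oracleGsva <- function(expr, geneSet, tau = 1) {
  sds <- apply(expr, 1, stats::sd)
  expr <- expr[sds > 0, , drop = FALSE]
  p <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, p, n)
  for (i in 1:p) {
    h <- stats::sd(expr[i, ]) / 4
    for (j in 1:n) z[i, j] <- mean(stats::pnorm((expr[i, j] - expr[i, ]) / h))
  }
  set <- intersect(geneSet, rownames(expr))
  m <- length(set)
  scores <- numeric(n)
  for (j in 1:n) {
    ord <- order(z[, j], decreasing = TRUE)
    inSet <- rownames(expr)[ord] %in% set
    wAll <- abs(seq_len(p) - (p + 1) / 2)
    denom <- sum(wAll[inSet]^tau)
    walk <- 0; best <- 0
    for (l in 1:p) {
      walk <- walk + if (inSet[l]) wAll[l]^tau / denom else -1 / (p - m)
      if (abs(walk) > abs(best)) best <- walk
    }
    scores[j] <- best
  }
  scores
}

# equal-frequency binning + table-based mutual information, written
# independently for the MRMR criterion oracle
oracleBin <- function(x, nBins = 4) {
  qs <- unique(stats::quantile(x, seq(0, 1, length.out = nBins + 1),
                               type = 7, names = FALSE))
  if (length(qs) < 2) return(rep(1L, length(x)))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  as.integer(cut(x, qs, labels = FALSE, include.lowest = TRUE))
}

oracleMi <- function(a, b) {
  tb <- table(a, b) / length(a)
  mi <- 0
  for (i in seq_len(nrow(tb))) for (j in seq_len(ncol(tb))) {
    if (tb[i, j] > 0)
      mi <- mi + tb[i, j] * log(tb[i, j] / (sum(tb[i, ]) * sum(tb[, j])))
  }
  mi
}

# exhaustive evaluation of the MRMR quotient criterion along a greedy path
oracleMrmrGreedy <- function(X, y, nSelect) {
  feats <- sort(colnames(X))
  D <- sapply(feats, function(f) oracleBin(X[, f]))
  yd <- if (is.numeric(y) && length(unique(y)) > 8) oracleBin(y)
        else as.integer(factor(y))
  rel <- sapply(feats, function(f) oracleMi(D[, f], yd))
  sel <- character(0)
  while (length(sel) < nSelect) {
    avail <- setdiff(feats, sel)
    crit <- sapply(avail, function(f) {
      if (!length(sel)) return(rel[f])
      red <- mean(sapply(sel, function(s) oracleMi(D[, f], D[, s])))
      rel[f] / max(red, 1e-12)
    })
    sel <- c(sel, avail[which.max(crit)])
  }
  sel
}

# naive agglomerative complete linkage cut at height h
oracleCompleteLinkageCut <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cd <- max(D[clusters[[i]], clusters[[j]]])
      if (cd < best) { best <- cd; bi <- i; bj <- j }
    }
    if (!is.finite(best) || best > h) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# small helpers for building fixtures
makeSphereMask <- function(radiusVox, dimLen = 2 * radiusVox + 5) {
  d <- rep(dimLen, 3)
  ctr <- (d + 1) / 2
  g <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  m <- array(sqrt((g$i - ctr[1])^2 + (g$j - ctr[2])^2 +
                    (g$k - ctr[3])^2) <= radiusVox, d)
  m
}
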
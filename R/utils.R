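# Internal helpers shared across modules.

# Derive a reproducible substream seed from a root seed and a stream name.
# Keeps results independent across streams while everything flows from one
# root; stays below 2^31 - 1.
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# quantile type 7 percentile used throughout for p10/p90 etc.
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

roundHalfUp <- function(x) floor(x + 0.5)

# stable equal-frequency discretisation into up to nBins levels
equalFreqBins <- function(x, nBins = 4L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  br[1] <- -Inf
  br[length(br)] <- Inf
  as.integer(cut(x, breaks = br, labels = FALSE, include.lowest = TRUE))
}

# discrete mutual information between two integer codes
mutualInfo <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
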
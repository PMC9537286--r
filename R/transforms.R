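# Yeo-Johnson power transform with maximum-likelihood lambda, followed by
# z-standardisation.  Parameters are estimated on the discovery cohort only
# and transferred frozen to validation.

#' Yeo-Johnson transform
#'
#' For x >= 0: ((x+1)^lambda - 1)/lambda (log(x+1) when lambda = 0); for
#' x < 0: -(((-x+1)^(2-lambda) - 1)/(2-lambda)) (-log(-x+1) when
#' lambda = 2).
#'
#' @param x numeric vector.
#' @param lambda transform parameter.
#' @return transformed vector.
#' @export
yeoJohnson <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -(((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda))
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

#' Inverse Yeo-Johnson transform
#' @param y transformed values.
#' @param lambda transform parameter.
#' @return raw-scale values.
#' @export
yeoJohnsonInverse <- function(y, lambda) {
  pos <- y >= 0
  out <- numeric(length(y))
  if (abs(lambda) > 1e-10) {
    out[pos] <- (y[pos] * lambda + 1)^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(y[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- 1 - (1 - (2 - lambda) * y[!pos])^(1 / (2 - lambda))
  } else {
    out[!pos] <- 1 - exp(-y[!pos])
  }
  out
}

yjLogLik <- function(x, lambda) {
  y <- yeoJohnson(x, lambda)
  s2 <- mean((y - mean(y))^2)
  if (s2 <= 0) return(-Inf)
  -length(x) / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

fitYeoJohnson <- function(x, range = c(-3, 3)) {
  grid <- seq(range[1], range[2], by = 0.25)
  ll <- vapply(grid, yjLogLik, numeric(1), x = x)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  gr <- (sqrt(5) - 1) / 2                       # golden-section refinement
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- yjLogLik(x, x1); f2 <- yjLogLik(x, x2)
  for (it in 1:60) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- yjLogLik(x, x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- yjLogLik(x, x1)
    }
    if (b - a < 1e-5) break
  }
  (a + b) / 2
}

#' Fit Yeo-Johnson and z-transform parameters on the discovery cohort
#'
#' Lambda is chosen by maximum likelihood (coarse grid over [-3, 3] with
#' golden-section refinement); z-shift and z-scale are the mean and SD of
#' the transformed discovery values.
#'
#' @param features patients x features numeric matrix or data.frame
#'   (discovery cohort only).
#' @return data.frame(feature, lambda, shift, scale) of class
#'   "TransformParams".
#' @export
fitTransforms <- function(features) {
  X <- as.matrix(features)
  rows <- lapply(colnames(X), function(f) {
    x <- X[, f]
    lam <- fitYeoJohnson(x)
    y <- yeoJohnson(x, lam)
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0)
      stop("zero discovery SD after transform for feature ", f)
    data.frame(feature = f, lambda = lam, shift = mean(y), scale = s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TransformParams", "data.frame")
  out
}

#' Apply frozen transform parameters
#'
#' Pure function: Yeo-Johnson with the stored lambda, then
#' (y - shift)/scale.  Usable on any cohort.
#'
#' @param features patients x features matrix/data.frame; must contain
#'   every feature in \code{params}.
#' @param params a \code{\link{fitTransforms}} result (or any data.frame
#'   with feature/lambda/shift/scale columns, e.g. printed model tables).
#' @return transformed matrix restricted to the parametrised features.
#' @export
applyTransforms <- function(features, params) {
  X <- as.matrix(features)
  miss <- setdiff(params$feature, colnames(X))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  out <- sapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    (yeoJohnson(X[, p$feature], p$lambda) - p$shift) / p$scale
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(X))
  colnames(out) <- params$feature
  rownames(out) <- rownames(X)
  out
}

#' Invert a z-score back to the raw feature scale
#'
#' @param z z-scores.
#' @param lambda,shift,scale the frozen transform parameters.
#' @return raw feature values.
#' @export
inverseTransform <- function(z, lambda, shift, scale) {
  yeoJohnsonInverse(z * scale + shift, lambda)
}
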
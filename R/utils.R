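# Internal helpers shared across modules.

#' Signal a validation error
#'
#' Input-validation failures carry the condition class
#' \code{"rp_validation_error"} so callers (and the command-line wrapper)
#' can distinguish bad inputs (exit code 2) from computation failures
#' (exit code 3).
#' @noRd
rpStop <- function(..., class = "rp_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so seeded generation never
#' perturbs the caller's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rpStop("'seed' must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream index.
subSeed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 190000) * 10000 + (k %% 10000))
}

# ---- interval utilities ------------------------------------------------
# Intervals are two-column matrices (start, end) in seconds, half-open on
# the right for membership unless noted.

asIntervalMatrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), ncol = 2L))
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  if (is.data.frame(x) && all(c("start", "end") %in% names(x))) {
    return(cbind(x$start, x$end))
  }
  if (is.numeric(x) && length(x) == 2L) return(matrix(x, ncol = 2L))
  if (is.list(x)) return(do.call(rbind, lapply(x, function(p) matrix(p, ncol = 2L))))
  rpStop("cannot interpret intervals; supply a 2-column (start, end) matrix")
}

validateIntervals <- function(iv, what = "intervals") {
  iv <- asIntervalMatrix(iv)
  if (nrow(iv) == 0L) return(iv)
  if (any(!is.finite(iv))) rpStop(what, " contain non-finite values")
  if (any(iv[, 2L] <= iv[, 1L])) rpStop(what, " must have end > start")
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
    rpStop(what, " must be disjoint")
  }
  iv
}

intervalTotal <- function(iv) {
  iv <- asIntervalMatrix(iv)
  if (nrow(iv) == 0L) return(0)
  sum(iv[, 2L] - iv[, 1L])
}

# Membership of times in a union of intervals (closed [start, end]).
inIntervals <- function(t, iv) {
  iv <- asIntervalMatrix(iv)
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  idx <- findInterval(t, iv[, 1L])
  ends <- c(-Inf, iv[, 2L])[idx + 1L]   # idx 0 -> before first interval
  idx > 0L & t <= ends
}

# Map absolute times to a concatenated within-interval coordinate [0, T).
# Times outside the intervals map to NA.
toConcatTime <- function(t, iv) {
  iv <- asIntervalMatrix(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  offs <- c(0, cumsum(iv[, 2L] - iv[, 1L]))
  idx <- findInterval(t, iv[, 1L])
  out <- rep(NA_real_, length(t))
  ends <- c(-Inf, iv[, 2L])[idx + 1L]
  ok <- idx > 0L & t <= ends
  out[ok] <- offs[idx[ok]] + (t[ok] - iv[idx[ok], 1L])
  out
}

# Inverse of toConcatTime for u in [0, T).
fromConcatTime <- function(u, iv) {
  iv <- asIntervalMatrix(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  lens <- iv[, 2L] - iv[, 1L]
  offs <- c(0, cumsum(lens))
  idx <- findInterval(u, offs, rightmost.closed = FALSE)
  idx[idx > nrow(iv)] <- nrow(iv)
  iv[idx, 1L] + (u - offs[idx])
}

# ---- spectral helpers --------------------------------------------------

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector; its modulus is the
#' instantaneous amplitude envelope and its argument the analytic phase.
#' @noRd
analyticSignal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase filtering: forward-backward application of an ARMA filter with
# odd-reflection padding.  The two pass orders (forward-then-backward and
# backward-then-forward) are averaged: they differ only in edge transients,
# and the average is exactly symmetric under time reversal —
# rev(zeroPhaseFilter(f, rev(x))) equals zeroPhaseFilter(f, x) bitwise.
zeroPhaseFilter <- function(filt, x, padLen) {
  n <- length(x)
  p <- max(0L, min(as.integer(padLen), n - 1L))
  if (p > 0L) {
    pre <- 2 * x[1L] - x[(p + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - p)]
    y <- c(pre, x, post)
  } else {
    y <- x
  }
  fwd <- function(v) as.numeric(signal::filter(filt, v))
  y1 <- rev(fwd(rev(fwd(y))))
  y2 <- fwd(rev(fwd(rev(y))))
  out <- (y1 + y2) / 2
  if (p > 0L) out[(p + 1L):(p + n)] else out
}

# Circular helpers (degrees).
degToRad <- function(d) d * pi / 180
radToDeg <- function(r) r * 180 / pi

wrapDeg <- function(d) ((d %% 360) + 360) %% 360

circularMeanDeg <- function(phasesDeg) {
  th <- degToRad(phasesDeg)
  wrapDeg(radToDeg(atan2(mean(sin(th)), mean(cos(th)))))
}

circularRbar <- function(phasesDeg) {
  th <- degToRad(phasesDeg)
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

# Circular standard deviation in degrees, sqrt(-2 log rbar).
circularSDDeg <- function(phasesDeg) {
  r <- circularRbar(phasesDeg)
  if (r <= 0) return(Inf)
  radToDeg(sqrt(-2 * log(r)))
}

# Mean resultant length of a von Mises distribution, A(kappa) = I1/I0.
besselRatio <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Maximum-likelihood kappa from a mean resultant length (Fisher 1993).
kappaFromRbar <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}
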
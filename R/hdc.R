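#' Dilation scheme for a stack of dilated convolutions
#'
#' @param rates Ordered positive integer dilation rates, default c(1, 2, 5).
#' @param kernel Odd kernel size >= 3, default 3.
#' @return Object of class `dilation_scheme`.
#' @export
dilation_scheme <- function(rates = c(1L, 2L, 5L), kernel = 3L) {
  rates <- as.integer(rates); kernel <- as.integer(kernel)
  if (!length(rates)) stop("rates must be non-empty")
  if (any(rates < 1L)) stop("all dilation rates must be >= 1")
  if (kernel < 3L || kernel %% 2L == 0L) stop("kernel must be odd and >= 3")
  structure(list(rates = rates, kernel = kernel), class = "dilation_scheme")
}

#' Validate a dilation scheme against the hybrid dilated convolution rules
#'
#' Two conditions guarantee hole-free coverage when dilated convolutions are
#' stacked. First, no pair of rates may share a common divisor greater than 1
#' (pairs involving rate 1 always pass). Second, the maximum distance between
#' two nonzero taps, computed backward through the stack as
#' \deqn{M_i = \max(M_{i+1} - 2 r_i,\; 2 r_i - M_{i+1},\; r_i)}
#' with \eqn{M_n = r_n}, must satisfy \eqn{M_i < K} for every layer before
#' the last, where K is the kernel size.
#'
#' @param scheme A [dilation_scheme()].
#' @return Object of class `hdc_report` with fields `max_distances`,
#'   `coprime_ok`, `distance_ok` and `valid` (= coprime_ok & distance_ok).
#' @export
validate_hdc <- function(scheme) {
  stopifnot(inherits(scheme, "dilation_scheme"))
  r <- scheme$rates; K <- scheme$kernel; n <- length(r)
  M <- integer(n)
  M[n] <- r[n]
  if (n > 1) for (i in (n - 1):1)
    M[i] <- max(M[i + 1] - 2L * r[i], 2L * r[i] - M[i + 1], r[i])
  gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
  coprime_ok <- TRUE
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (r[i] > 1L && r[j] > 1L && gcd2(r[i], r[j]) > 1L) coprime_ok <- FALSE
    }
  }
  distance_ok <- if (n > 1) all(M[1:(n - 1)] < K) else TRUE
  structure(list(max_distances = M, coprime_ok = coprime_ok,
                 distance_ok = distance_ok,
                 valid = coprime_ok && distance_ok,
                 rates = r, kernel = K),
            class = "hdc_report")
}

#' @export
print.hdc_report <- function(x, ...) {
  cat("HDC report for rates (", paste(x$rates, collapse = ", "),
      "), kernel ", x$kernel, "\n", sep = "")
  cat("  max distances M_i:", paste(x$max_distances, collapse = ", "), "\n")
  cat("  coprime rates:    ", x$coprime_ok, "\n")
  cat("  distances < K:    ", x$distance_ok, "\n")
  cat("  valid:            ", x$valid, "\n")
  invisible(x)
}

#' Brute-force 1-D tap coverage of a dilated convolution stack
#'
#' Independent oracle for the gridding effect: composes the 1-D tap sets of
#' each dilated kernel (offsets -r(K-1)/2 .. +r(K-1)/2 in steps of r) by
#' Minkowski sum and returns every covered offset. The stack is hole-free
#' iff the coverage is a contiguous integer interval.
#'
#' @param scheme A [dilation_scheme()].
#' @return Sorted integer vector of covered offsets.
#' @export
gridding_coverage <- function(scheme) {
  stopifnot(inherits(scheme, "dilation_scheme"))
  half <- (scheme$kernel - 1L) %/% 2L
  cov <- 0L
  for (r in scheme$rates) {
    taps <- seq(-half * r, half * r, by = r)
    cov <- sort(unique(as.vector(outer(cov, taps, `+`))))
  }
  cov
}

#' Is a dilation scheme free of gridding holes?
#'
#' @param scheme A [dilation_scheme()].
#' @return TRUE iff [gridding_coverage()] is a contiguous interval.
#' @export
is_hole_free <- function(scheme) {
  cov <- gridding_coverage(scheme)
  identical(cov, seq(min(cov), max(cov), by = 1L))
}

#' Analytic receptive field of a layer stack
#'
#' For a stack of convolutions described by (kernel, dilation, stride) per
#' layer, the receptive-field span per axis is
#' RF = 1 + sum over layers of (K - 1) * r * (product of preceding strides).
#'
#' @param layers List of lists/vectors with elements `kernel`, `dilation`,
#'   `stride` (missing entries default to dilation 1, stride 1).
#' @return Integer receptive-field span.
#' @export
receptive_field <- function(layers) {
  rf <- 1
  jump <- 1
  for (l in layers) {
    K <- l$kernel
    r <- if (is.null(l$dilation)) 1 else l$dilation
    s <- if (is.null(l$stride)) 1 else l$stride
    rf <- rf + (K - 1) * r * jump
    jump <- jump * s
  }
  as.integer(rf)
}

#' Receptive field of the standard block types
#'
#' Convenience wrappers: an RnD block is three serial kernel-3 dilated
#' convolutions at the scheme's rates; a residual block is two kernel-3
#' convolutions.
#'
#' @param scheme A [dilation_scheme()].
#' @return Integer span.
#' @export
rnd_receptive_field <- function(scheme = dilation_scheme()) {
  receptive_field(lapply(scheme$rates, function(r)
    list(kernel = scheme$kernel, dilation = r, stride = 1)))
}

#' @rdname rnd_receptive_field
#' @export
residual_receptive_field <- function() {
  receptive_field(list(list(kernel = 3), list(kernel = 3)))
}
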
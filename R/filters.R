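## M-band orthogonal filter banks.
##
## A bank consists of M finite tap sequences h_0 .. h_{M-1} of a common length
## L (a multiple of M): one low-pass scaling filter h_0 and M-1 band-pass
## wavelet filters. Orthogonality of the implied transform requires
##   sum_t h_i[t] h_j[t + M s] = delta_ij delta_s0   for all i, j, s
## and the scaling filter sums to sqrt(M) so that a constant signal is carried
## entirely by the approximation channel.

## Daubechies scaling filters (2-band). db2 is exact closed form; db3/db4 are
## the standard published minimal-phase coefficients.
.db_scaling <- list(
  db1 = c(1, 1) / sqrt(2),
  db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db3 = c(0.33267055295008263, 0.80689150931109250, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.23037781330889650, 0.71484657055291570, 0.63088076792985890,
          -0.02798376941685985, -0.18703481171909309, 0.03084138183556076,
          0.03288301166688520, -0.01059740178506903)
)

## Quadrature-mirror wavelet filter for a 2-band scaling filter h:
## g[t] = (-1)^t h[L-1-t].
.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

## Modulated-cosine (DCT-II) block bank of length M: the classical orthogonal
## block transform, h_0 flat and h_j[t] = sqrt(2/M) cos(pi j (t + 1/2) / M).
## Reduces to the Haar pair at M = 2.
.mcos_bank <- function(M) {
  t <- seq_len(M) - 1
  taps <- lapply(seq_len(M) - 1, function(j) {
    if (j == 0) rep(1 / sqrt(M), M) else sqrt(2 / M) * cos(pi * j * (t + 0.5) / M)
  })
  taps
}

.supported_families <- function(M) {
  switch(as.character(M),
    "2" = c("db2", "haar", "db1", "db3", "db4", "mcos"),
    "3" = "mcos",
    "4" = "mcos",
    character()
  )
}

#' Construct an M-band orthogonal filter bank
#'
#' Builds the M tap sequences of an orthogonal M-band filter bank: one
#' scaling (low-pass) filter and M-1 wavelet (band-pass) filters. Every bank
#' is validated at construction against the orthogonality conditions
#' (unit norm, cross/shift orthogonality at shifts of M, scaling sum
#' \eqn{\sqrt{M}}) and construction fails if any condition is violated.
#'
#' @param M Band count; one of 2, 3, 4.
#' @param family Filter family. For `M = 2`: `"db2"` (default, Daubechies
#'   4-tap), `"haar"` (alias `"db1"`), `"db3"`, `"db4"`, or `"mcos"`.
#'   For `M = 3` and `M = 4` the modulated-cosine block bank `"mcos"`
#'   (the default) is shipped. `NULL` selects the default for `M`.
#' @return An object of class `wmc_filter_bank`: a list with elements `M`,
#'   `family`, `taps` (list of M numeric tap sequences) and `L` (tap length).
#' @examples
#' fb <- build_filter_bank(2, "haar")
#' fb$taps[[1]] # 1/sqrt(2), 1/sqrt(2)
#' @export
build_filter_bank <- function(M, family = NULL) {
  if (!is.numeric(M) || length(M) != 1 || !(M %in% c(2, 3, 4))) {
    stop("unsupported configuration: band count M must be 2, 3 or 4 (got ",
         deparse(substitute(M)), " = ", paste(M, collapse = ","), ")")
  }
  M <- as.integer(M)
  if (is.null(family)) family <- if (M == 2L) "db2" else "mcos"
  family <- tolower(family)
  if (family == "haar") family <- if (M == 2L) "db1" else "mcos"
  if (!family %in% .supported_families(M)) {
    stop("unsupported configuration: family '", family,
         "' is not available for M = ", M,
         " (supported: ", paste(.supported_families(M), collapse = ", "), ")")
  }
  taps <- if (M == 2L && family != "mcos") {
    h <- .db_scaling[[family]]
    list(h, .qmf(h))
  } else {
    .mcos_bank(M)
  }
  fb <- structure(list(M = M, family = family, taps = taps,
                       L = length(taps[[1]])),
                  class = "wmc_filter_bank")
  validate_filter_bank(fb)
  fb
}

#' Validate the orthogonality conditions of a filter bank
#'
#' Checks unit l2-norm of every tap sequence, cross- and shift-orthogonality
#' at all shifts by multiples of M, and that the scaling filter sums to
#' \eqn{\sqrt{M}}. Called automatically by [build_filter_bank()].
#'
#' @param fb A `wmc_filter_bank`.
#' @param tol Absolute tolerance.
#' @return `fb`, invisibly; errors if any condition fails.
#' @export
validate_filter_bank <- function(fb, tol = wmc_tol$abs) {
  stopifnot(inherits(fb, "wmc_filter_bank"))
  M <- fb$M
  L <- fb$L
  if (length(fb$taps) != M) stop("filter bank must have M tap sequences")
  if (any(vapply(fb$taps, length, 1L) != L)) stop("tap sequences differ in length")
  if (L %% M != 0) stop("tap length must be a multiple of M")
  if (abs(sum(fb$taps[[1]]) - sqrt(M)) > tol) {
    stop("scaling filter does not sum to sqrt(M)")
  }
  shifts <- seq(-(L %/% M), L %/% M)
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      for (s in shifts) {
        t1 <- seq_len(L)
        t2 <- t1 + M * s
        ok <- t2 >= 1 & t2 <= L
        val <- sum(fb$taps[[i]][t1[ok]] * fb$taps[[j]][t2[ok]])
        target <- if (i == j && s == 0) 1 else 0
        if (abs(val - target) > tol) {
          stop(sprintf(
            "filter bank fails orthogonality: <h_%d, shift(h_%d, %d)> = %.3g",
            i - 1, j - 1, M * s, val))
        }
      }
    }
  }
  invisible(fb)
}

#' @export
print.wmc_filter_bank <- function(x, ...) {
  cat(sprintf("<wmc_filter_bank> M = %d, family = '%s', %d taps per filter\n",
              x$M, x$family, x$L))
  invisible(x)
}
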
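#' Dynamic fixed-point matrices
#'
#' A `dfp` matrix stores signed integer mantissas with one power-of-two
#' scaling exponent per row: entry (i, j) has real value
#' `mantissa[i,j] * 2^(row_exp[i] - F)` with `F` fractional bits.  After
#' normalisation every non-zero row has its largest magnitude in `[0.5, 1)`,
#' so nearly all mantissa bits carry signal; all-zero rows carry the reserved
#' exponent [dfp_exp_zero].  Mantissas are bounded by 2^53 so they cross the
#' R/C++ boundary exactly; arithmetic runs on 64-bit integers with 128-bit
#' products.
#'
#' @param x numeric matrix (or vector, treated as one row).
#' @param frac_bits fractional bits F of the mantissa (default 50).
#' @return An object of class `dfp`.
#' @export
dfp <- function(x, frac_bits = 50L) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  r <- dfp_from_real_cpp(as.matrix(x), as.integer(frac_bits))
  structure(list(m = r$m, e = as.integer(r$e), frac_bits = as.integer(frac_bits)),
            class = "dfp")
}

# internal constructor from kernel output
.dfp_wrap <- function(r, frac_bits) {
  m <- r$m
  if (is.null(dim(m))) m <- matrix(as.numeric(m), nrow = 1L)
  structure(list(m = m, e = as.integer(r$e), frac_bits = as.integer(frac_bits)),
            class = "dfp")
}

#' Reserved exponent marking an all-zero row
#' @export
dfp_exp_zero <- function() dfp_exp_zero_cpp()

#' Evaluate a dfp matrix back to double precision
#' @param m a [dfp] object.
#' @return A numeric matrix (exact evaluation of the representation formula).
#' @export
to_real <- function(m) {
  stopifnot(inherits(m, "dfp"))
  dfp_to_real_cpp(m$m, m$e, m$frac_bits)
}

#' @export
print.dfp <- function(x, ...) {
  cat(sprintf("<dfp> %d x %d, F = %d\n", nrow(x$m), ncol(x$m), x$frac_bits))
  print(to_real(x))
  invisible(x)
}

#' @export
dim.dfp <- function(x) dim(x$m)

#' Renormalise rows so each non-zero row's maximum lies in [0.5, 1)
#'
#' The scaling factor of each row is the power of two that brings the largest
#' magnitude into `[0.5, 1)`; it is applied by bit shifts (right shifts
#' truncate toward zero, at most 1 ulp per entry).  Idempotent; all-zero rows
#' get the reserved exponent.
#'
#' @param m a [dfp] object.
#' @return A normalised [dfp].
#' @export
normalize_rows <- function(m) {
  stopifnot(inherits(m, "dfp"))
  .dfp_wrap(dfp_normalize_cpp(m$m, m$e, m$frac_bits), m$frac_bits)
}

.check_shapes <- function(a, b) {
  if (!identical(dim(a$m), dim(b$m))) stop("shape mismatch")
  if (a$frac_bits != b$frac_bits) stop("frac_bits mismatch")
}

#' Row-wise dfp addition
#'
#' Both operands are shifted to the larger of the two row exponents plus one
#' headroom bit (overflow-safe, branch-free), mantissas added, rows
#' renormalised.
#'
#' @param a,b [dfp] matrices of equal shape.
#' @return A [dfp].
#' @export
dfp_add <- function(a, b) {
  .check_shapes(a, b)
  .dfp_wrap(dfp_add_cpp(a$m, a$e, b$m, b$e, a$frac_bits), a$frac_bits)
}

#' Element-wise dfp multiplication
#'
#' Double-width mantissa products shifted down by F; row exponents summed;
#' rows renormalised.
#'
#' @inheritParams dfp_add
#' @return A [dfp].
#' @export
dfp_mul <- function(a, b) {
  .check_shapes(a, b)
  .dfp_wrap(dfp_mul_cpp(a$m, a$e, b$m, b$e, a$frac_bits), a$frac_bits)
}

#' Column sums of a dfp matrix
#'
#' All rows are brought to the highest row scale (minimising precision loss)
#' and summed column-wise in 64-bit integers, whose headroom above the
#' 53-bit mantissas makes overflow impossible; the result is renormalised.
#'
#' @param m a [dfp] matrix.
#' @return A one-row [dfp] vector.
#' @export
dfp_col_sum <- function(m) {
  stopifnot(inherits(m, "dfp"))
  .dfp_wrap(dfp_col_sum_cpp(m$m, m$e, m$frac_bits), m$frac_bits)
}

#' Weighted row combination (forward-pass pattern)
#'
#' `dfp_matvec(m, v)` computes `y_j = sum_i v_i m[i,j]` as the composition of
#' per-row scaling by `v_i` and a column sum.
#'
#' @param m a [dfp] matrix.
#' @param v a one-row [dfp] with `ncol(v) == nrow(m)`.
#' @return A one-row [dfp].
#' @export
dfp_matvec <- function(m, v) {
  stopifnot(inherits(m, "dfp"), inherits(v, "dfp"), nrow(v$m) == 1L,
            ncol(v$m) == nrow(m$m), v$frac_bits == m$frac_bits)
  .dfp_wrap(dfp_matvec_cpp(m$m, m$e, as.numeric(v$m), v$e[1], m$frac_bits),
            m$frac_bits)
}

#' Renormalise a nonnegative dfp vector into a probability distribution
#'
#' Entries are divided by their sum through a constant-time reciprocal
#' (restoring long division with a fixed iteration schedule) followed by a
#' branch-free elementwise multiply, so entries sum to 1 within `n * 2^-F`.
#' The all-zero vector maps to the uniform distribution `1/n` by convention,
#' which keeps the downstream sampling stage total.
#'
#' @param v a one-row [dfp] with nonnegative entries.
#' @return A one-row [dfp] distribution.
#' @export
renormalize_distribution <- function(v) {
  stopifnot(inherits(v, "dfp"), nrow(v$m) == 1L)
  .dfp_wrap(dfp_renorm_dist_cpp(as.numeric(v$m), v$e[1], v$frac_bits),
            v$frac_bits)
}

#' Dynamic versus static fixed point under repeated scaling
#'
#' Runs a forward-algorithm-like chain: a vector of row values is multiplied
#' `steps` times by a small constant factor (about 2^-10 by default).  Under
#' dynamic scaling the per-row exponents absorb the shrinkage and the relative
#' ordering of the rows survives; under a conventional static fixed point at
#' `static_frac_bits` fractional bits the values truncate to exact zero after
#' a handful of steps, the mechanism by which entire distributions collapse
#' to uniform in a fixed-point phasing pipeline.
#'
#' @param v0 starting values (one per row).
#' @param factor per-step multiplier.
#' @param steps number of multiplications.
#' @param frac_bits dynamic mantissa fractional bits.
#' @param static_frac_bits fractional bits of the static baseline (52, the
#'   most accurate static setting for 64-bit integers).
#' @return A list with the dynamic trajectory (`dynamic`, values per step),
#'   the static trajectory (`static`), and summary flags
#'   `dynamic_order_preserved` and `static_collapsed`.
#' @export
dfp_chain_demo <- function(v0 = c(0.9, 0.5, 0.2, 0.05), factor = 2^-10,
                           steps = 200L, frac_bits = 50L,
                           static_frac_bits = 52L) {
  dyn <- matrix(NA_real_, steps + 1L, length(v0))
  cur <- dfp(matrix(v0, ncol = 1L), frac_bits) # one row per value
  dyn[1L, ] <- as.numeric(to_real(cur))
  fac <- dfp(matrix(rep(factor, length(v0)), ncol = 1L), frac_bits)
  ord0 <- order(v0, decreasing = TRUE)
  ord_ok <- TRUE
  for (t in seq_len(steps)) {
    cur <- dfp_mul(cur, fac)      # includes normalize_rows
    dyn[t + 1L, ] <- as.numeric(to_real(cur))
    # relative ordering must survive; exponents carry the magnitude
    ranks <- order(cur$e + log2(pmax(abs(as.numeric(cur$m)), 1)), decreasing = TRUE)
    if (!identical(ranks, ord0)) ord_ok <- FALSE
  }
  st <- dfp_static_chain_cpp(v0, factor, as.integer(steps),
                             as.integer(static_frac_bits))
  list(dynamic = dyn, static = st,
       dynamic_order_preserved = ord_ok,
       static_collapsed = all(st[steps + 1L, ] == 0))
}
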
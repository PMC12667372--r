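#' Tag a value as secret
#'
#' Secret values model data derived from user input.  Arithmetic and
#' comparisons involving a secret yield secrets; a secret may only index an
#' array through [oblivious_read]/[oblivious_write], and must be exposed
#' explicitly with [declassify].  Direct subscripting with a secret fails by
#' construction (the wrapper is not a valid subscript).
#'
#' @param x a value (integer, index, logical, or fixed-point mantissa).
#' @return An object of class `obli_secret`.
#' @export
secret <- function(x) structure(list(value = x), class = "obli_secret")

#' @rdname secret
#' @export
is_secret <- function(x) inherits(x, "obli_secret")

#' @rdname secret
#' @export
declassify <- function(x) {
  stopifnot(is_secret(x))
  x$value
}

# internal accessor: secrets and plain values both flow into primitives
sv <- function(x) if (is_secret(x)) x$value else x

#' @export
Ops.obli_secret <- function(e1, e2) {
  if (missing(e2)) {
    secret(get(.Generic)(sv(e1)))
  } else {
    secret(get(.Generic)(sv(e1), sv(e2)))
  }
}

#' @export
print.obli_secret <- function(x, ...) {
  cat("<secret>\n")
  invisible(x)
}

#' @export
as.integer.obli_secret <- function(x, ...)
  stop("secret value used in a non-oblivious context; use declassify() or oblivious_read()")

#' @export
as.numeric.obli_secret <- function(x, ...)
  stop("secret value used in a non-oblivious context; use declassify() or oblivious_read()")

#' Linear-scan oblivious read
#'
#' Reads `arr[idx]` while touching every slot of `arr` in fixed ascending
#' order, so the access trace is independent of `idx`.  An out-of-range index
#' yields the `NA` sentinel rather than an error (a data-dependent exception
#' would itself be a side channel).
#'
#' @param arr numeric vector (public shape, possibly secret contents).
#' @param idx 1-based index, plain or [secret].
#' @param label integer label identifying the array in captured traces.
#' @return A [secret] scalar.
#' @export
oblivious_read <- function(arr, idx, label = 0L) {
  secret(ob_read_cpp(as.numeric(arr), as.integer(sv(idx)) - 1L, as.integer(label)))
}

#' Linear-scan oblivious write
#'
#' Writes `v` at position `idx`, rewriting every slot (unchanged values
#' included) so the trace covers all indices.
#'
#' @inheritParams oblivious_read
#' @param v value to store, plain or [secret].
#' @return The updated numeric vector.
#' @export
oblivious_write <- function(arr, idx, v, label = 0L) {
  ob_write_cpp(as.numeric(arr), as.integer(sv(idx)) - 1L, as.numeric(sv(v)),
               as.integer(label))
}

#' Deterministic multiplexer
#'
#' Returns `a` if `c` else `b`; both operands are materialised and no branch
#' on `c` appears in the captured trace.
#'
#' @param c condition, plain or [secret] logical/0-1.
#' @param a,b alternatives.
#' @return A [secret] holding the selected value.
#' @export
cond_select <- function(c, a, b) {
  cv <- as.logical(sv(c))
  av <- sv(a)
  bv <- sv(b)
  if (is.numeric(av) && is.numeric(bv) && length(av) == 1L && length(bv) == 1L) {
    secret(ob_select_cpp(as.integer(cv), av, bv))
  } else {
    secret((list(bv, av))[[cv + 1L]])
  }
}

#' Bitonic sorting network
#'
#' Sorts ascending through a compare-exchange network whose structure depends
#' only on the input length (padded to the next power of two with +Inf
#' sentinels).  Stability is enforced with a composite (key, original index)
#' comparison.  Keys must be finite: the maximal value is reserved for the
#' padding sentinel.
#'
#' @param x vector (or list) to sort.
#' @param key optional numeric key vector or key function; defaults to `x`.
#' @param label trace label.
#' @return Sorted `x`, with attribute `ncomparisons` (network size) and
#'   `order` (the permutation applied).
#' @export
bitonic_sort <- function(x, key = NULL, label = 0L) {
  k <- if (is.null(key)) as.numeric(x) else if (is.function(key))
    vapply(x, function(e) as.numeric(key(e)), 0.0) else as.numeric(key)
  stopifnot(all(is.finite(k)))
  perm <- bitonic_sort_cpp(k, as.integer(label))
  out <- x[as.integer(perm)]
  attr(out, "ncomparisons") <- attr(perm, "ncomparisons")
  attr(out, "order") <- as.integer(perm)
  out
}

#' Oblivious filter to a fixed public size
#'
#' Routes elements with `mask == 1` to the front by sorting the composite key
#' `(1 - mask, index)` through the bitonic network, then truncates to the
#' public length `out_len`.  Selected elements keep their relative order;
#' unused output slots hold the `NA` sentinel.  Selected elements beyond
#' `out_len` are dropped deterministically in index order.
#'
#' @param items vector or list of elements.
#' @param mask 0/1 selection mask (plain or secret values).
#' @param out_len public output length.
#' @param label trace label.
#' @return Length-`out_len` vector (or list) with `NA` sentinels.
#' @export
oblivious_filter <- function(items, mask, out_len, label = 0L) {
  mv <- as.numeric(vapply(mask, function(m) as.numeric(sv(m)), 0.0))
  stopifnot(length(mv) == length(items), out_len >= 0)
  idx <- oblivious_filter_idx_cpp(mv, as.integer(out_len), as.integer(label))
  if (is.list(items)) {
    lapply(seq_len(out_len), function(i) if (is.na(idx[i])) NA else items[[idx[i]]])
  } else {
    out <- items[ifelse(is.na(idx), NA_integer_, idx)]
    out
  }
}

#' Constant-time integer division
#'
#' Restoring long division with exactly `width` iterations regardless of the
#' operands.  `den == 0` yields the all-ones sentinel of the width (never a
#' trap).  Operands must be exact integers below 2^53 in magnitude.
#'
#' @param num numerator (plain or [secret]).
#' @param den denominator, `> 0` expected.
#' @param width bit width of the division schedule.
#' @return A [secret] holding `trunc(num / den)`.
#' @export
ct_divide <- function(num, den, width = 64L) {
  n <- as.numeric(sv(num))
  d <- as.numeric(sv(den))
  if (length(n) > 1L || length(d) > 1L) {
    m <- max(length(n), length(d))
    secret(ct_divide_vec_cpp(rep_len(n, m), rep_len(d, m), as.integer(width)))
  } else {
    secret(ct_divide_cpp(n, d, as.integer(width)))
  }
}

#' Capture the access trace of an oblivious computation
#'
#' Runs `expr` with the recorder enabled and returns the ordered event stream
#' (op, label, index).  For fixed public shapes the trace must be identical
#' across secret inputs; [traces_identical] compares two captures.
#'
#' @param expr expression to evaluate.
#' @return An `access_trace`: a list with `events` (data.frame) and `value`.
#' @export
trace_capture <- function(expr) {
  trace_start_cpp()
  ok <- FALSE
  val <- tryCatch({
    v <- force(expr)
    ok <- TRUE
    v
  }, finally = if (!ok) trace_stop_cpp())
  ev <- trace_stop_cpp()
  structure(list(events = data.frame(op = ev$op, label = ev$label,
                                     index = ev$index),
                 value = val),
            class = "access_trace")
}

#' @rdname trace_capture
#' @param a,b two `access_trace` objects.
#' @export
traces_identical <- function(a, b) identical(a$events, b$events)

#' @export
print.access_trace <- function(x, ...) {
  cat(sprintf("<access_trace> %d events\n", nrow(x$events)))
  invisible(x)
}
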
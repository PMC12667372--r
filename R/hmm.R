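#' Li-Stephens HMM parameters
#'
#' Per-interval recombination probabilities follow the standard Li-Stephens
#' convention `rho_i = 1 - exp(-0.04 * Ne * d_i / K)` with `d_i` the
#' inter-site genetic distance in cM (from a genetic map, or a constant
#' 0.01 cM fallback), `Ne` an effective-population-size proxy and `K` the
#' public conditioned-panel capacity; `eps` is the allele-copy error.
#'
#' @param n_sites window width.
#' @param K conditioned-panel capacity.
#' @param cm optional cumulative genetic-map positions (cM) per site.
#' @param Ne effective population size proxy.
#' @param eps allele mis-copy probability.
#' @param frac_bits fixed-point fractional bits.
#' @return An `hmm_params` list with per-site `rho`.
#' @export
hmm_params <- function(n_sites, K, cm = NULL, Ne = 15000, eps = 1e-4,
                       frac_bits = 50L) {
  d <- if (is.null(cm)) rep(0.01, n_sites) else c(0.01, pmax(diff(cm), 1e-6))
  rho <- 1 - exp(-0.04 * Ne * d / K)
  rho <- pmin(pmax(rho, 1e-9), 1 - 1e-9)
  stopifnot(eps > 0, eps < 0.5)
  structure(list(rho = rho, eps = eps, Ne = Ne, K = K,
                 frac_bits = as.integer(frac_bits)),
            class = "hmm_params")
}

# build the C++ kernel inputs from a graph
.hmm_inputs <- function(graph) {
  nseg <- length(graph$segments)
  nopt <- vapply(graph$segments, function(s) nrow(s$options), 1L)
  maxopt <- max(nopt)
  L <- graph$n_sites
  g <- graph$genotypes
  base <- as.integer(g %/% 2L)
  hapA <- matrix(rep(base, each = maxopt), maxopt, L)
  for (s in seq_len(nseg)) {
    seg <- graph$segments[[s]]
    for (t in seq_along(seg$het)) {
      site <- seg$het[t]
      hapA[seq_len(nopt[s]), site] <- seg$options[, t]
    }
  }
  hapB <- matrix(rep(g, each = maxopt), maxopt, L) - hapA
  list(segid = graph$seg_of_site - 1L, nopt = nopt, hapA = hapA, hapB = hapB)
}

#' Diploid forward-backward over the conditioned panel
#'
#' Runs the fixed-point diploid Li-Stephens forward-backward: the site-level
#' state is (k1, k2, segment option), haplotype copies switch with
#' probability `rho` per interval, emissions are `1 - eps` on match and
#' `eps` on mismatch, option transitions at segment boundaries carry a
#' uniform prior, and the state distribution is renormalised at every site.
#' Padding rows of the conditioned panel carry zero weight.
#'
#' @param graph a `genotype_graph`.
#' @param cond_panel a `conditioned_panel`.
#' @param params an [hmm_params].
#' @param dynamic_scaling use dynamic per-site rescaling (default); `FALSE`
#'   runs a conventional static fixed-point pipeline for comparison.
#' @return A `transition_posterior`: per-segment option marginals and
#'   per-boundary joint option posteriors as [dfp] vectors/matrices, plus the
#'   data log2-likelihood.
#' @export
forward_backward <- function(graph, cond_panel, params, dynamic_scaling = TRUE) {
  inp <- .hmm_inputs(graph)
  F <- params$frac_bits
  r <- hmm_fb_cpp(cond_panel$alleles, cond_panel$valid, inp$segid, inp$nopt,
                  inp$hapA, inp$hapB, params$rho, params$eps, F,
                  dynamic_scaling)
  nseg <- length(inp$nopt)
  marg <- lapply(seq_len(nseg), function(s)
    .dfp_wrap(list(m = matrix(r$marg[[s]], 1L), e = r$marg_e[s]), F))
  joint <- if (nseg > 1L) lapply(seq_len(nseg - 1L), function(b)
    .dfp_wrap(list(m = r$tp[[b]], e = rep(r$tp_e[b], nrow(r$tp[[b]]))), F))
  else list()
  structure(list(marg = marg, joint = joint, loglik = r$loglik,
                 nopt = inp$nopt, frac_bits = F),
            class = "transition_posterior")
}

#' @export
print.transition_posterior <- function(x, ...) {
  cat(sprintf("<transition_posterior> %d segments, log2-lik %.2f\n",
              length(x$marg), x$loglik))
  invisible(x)
}

# inverse-CDF draw from fixed-point mantissas (exact integer cumsum below
# 2^53); the comparison-count form of the selection touches every entry
.sample_fp <- function(mantissas) {
  m <- pmax(as.numeric(mantissas), 0)
  cum <- cumsum(m)
  tot <- cum[length(cum)]
  if (tot <= 0) return(sample.int(length(m), 1L))
  thr <- floor(runif(1) * tot)
  sum(cum <= thr) + 1L
}

#' Sample a phase path from the transition posteriors
#'
#' Backward sampling over the chain of boundary posteriors: the last
#' segment's option is drawn from its marginal, then each previous option
#' from the joint posterior column conditioned on the draw.  Inverse-CDF
#' sampling runs on fixed-point cumulative sums; seed-deterministic.
#'
#' @param post a `transition_posterior`.
#' @param graph the `genotype_graph` it was computed on.
#' @return A `phase_estimate`.
#' @export
sample_path <- function(post, graph) {
  nseg <- length(post$marg)
  opt <- integer(nseg)
  opt[nseg] <- .sample_fp(post$marg[[nseg]]$m)
  if (nseg > 1L) {
    for (s in (nseg - 1L):1L) {
      w <- post$joint[[s]]$m[, opt[s + 1L]]
      opt[s] <- .sample_fp(w)
    }
  }
  .expand_phase(graph, opt)
}

#' Merge confidently phased adjacent segments
#'
#' The joint boundary posterior is folded over the global haplotype-swap
#' symmetry (an option pair and its complement pair describe the same
#' relative phase); when the best folded transition exceeds `threshold`, the
#' two segments are fused keeping only that transition (and its complement),
#' shrinking the option space to 2.  Merged segments are never re-split.
#'
#' @param graph a `genotype_graph`.
#' @param post a `transition_posterior` computed on `graph`.
#' @param threshold merge confidence in (0.5, 1).
#' @return The pruned `genotype_graph`.
#' @export
prune <- function(graph, post, threshold = 0.999) {
  stopifnot(threshold > 0.5, threshold < 1)
  nseg <- length(graph$segments)
  if (nseg < 2L) return(graph)
  segs <- graph$segments
  out <- list()
  merges <- 0L
  s <- 1L
  while (s <= nseg) {
    if (s < nseg) {
      jp <- to_real(post$joint[[s]])
      compA <- .complement_options(segs[[s]])
      compB <- .complement_options(segs[[s + 1L]])
      folded <- jp
      best <- -Inf
      bo <- c(1L, 1L)
      for (o in seq_len(nrow(jp))) for (op in seq_len(ncol(jp))) {
        f <- jp[o, op]
        ca <- compA[o]; cb <- compB[op]
        if (!is.na(ca) && !is.na(cb)) f <- f + jp[ca, cb]
        if (f > best) { best <- f; bo <- c(o, op) }
      }
      if (best > threshold) {
        a <- segs[[s]]; b <- segs[[s + 1L]]
        o1 <- bo[1L]; o2 <- bo[2L]
        r1 <- c(a$options[o1, ], b$options[o2, ])
        ca <- compA[o1]; cb <- compB[o2]
        opts <- if (!is.na(ca) && !is.na(cb))
          rbind(r1, c(a$options[ca, ], b$options[cb, ])) else rbind(r1, 1L - r1)
        dimnames(opts) <- NULL
        storage.mode(opts) <- "integer"
        out[[length(out) + 1L]] <- list(het = c(a$het, b$het), options = opts)
        merges <- merges + 1L
        s <- s + 2L
        next
      }
    }
    out[[length(out) + 1L]] <- segs[[s]]
    s <- s + 1L
  }
  n <- graph$n_sites
  last_het <- vapply(out, function(sg)
    if (length(sg$het)) max(sg$het) else n, 1L)
  nsg <- length(out)
  b <- last_het[-nsg]
  seg_of_site <- 1L + findInterval(seq_len(n) - 1L, if (nsg > 1L) b else numeric(0))
  graph$segments <- out
  graph$seg_of_site <- as.integer(seg_of_site)
  graph$n_merges <- graph$n_merges + merges
  graph
}

#' Viterbi decoding of the maximum-likelihood phase
#'
#' Max-product analogue of [forward_backward]; fixed-point max/argmax with
#' deterministic tie-breaking, returning the argmax option path expanded to a
#' haplotype pair.
#'
#' @inheritParams forward_backward
#' @return A `phase_estimate` with attribute `loglik` (log2-likelihood of
#'   the decoded path).
#' @export
viterbi_decode <- function(graph, cond_panel, params) {
  inp <- .hmm_inputs(graph)
  r <- hmm_vit_cpp(cond_panel$alleles, cond_panel$valid, inp$segid, inp$nopt,
                   inp$hapA, inp$hapB, params$rho, params$eps,
                   params$frac_bits)
  est <- .expand_phase(graph, r$path + 1L)
  attr(est, "loglik") <- r$loglik
  est
}
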
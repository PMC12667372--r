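#' Build the genotype graph of an unphased sample
#'
#' Heterozygous sites are partitioned, in order, into consecutive segments of
#' at most `H_seg` sites; a segment with `h` het sites enumerates all `2^h`
#' phase options (the haplotype-A pattern over its het sites; haplotype B is
#' the complement at het sites and both equal the genotype at homozygous
#' sites).  Every consistent phased haplotype pair is a path through the
#' segment options.
#'
#' @param genotypes vector of dosages in `{0, 1, 2}`, no missing values.
#' @param H_seg maximum heterozygous sites per segment (default 3).
#' @return A `genotype_graph`.
#' @export
build_genotype_graph <- function(genotypes, H_seg = 3L) {
  g <- as.integer(genotypes)
  if (any(is.na(g)) || !all(g %in% 0:2)) stop("genotypes must be 0/1/2, no missing")
  n <- length(g)
  het <- which(g == 1L)
  if (length(het) == 0L) {
    segments <- list(list(het = integer(0), options = matrix(0L, 1L, 0L)))
  } else {
    chunks <- split(het, ceiling(seq_along(het) / H_seg))
    segments <- lapply(chunks, function(h) {
      k <- length(h)
      opts <- as.matrix(expand.grid(rep(list(0:1), k)))[, seq_len(k), drop = FALSE]
      storage.mode(opts) <- "integer"
      dimnames(opts) <- NULL
      list(het = as.integer(h), options = opts)
    })
    names(segments) <- NULL
  }
  nseg <- length(segments)
  last_het <- vapply(segments, function(s)
    if (length(s$het)) max(s$het) else n, 1L)
  b <- last_het[-nseg]
  seg_of_site <- 1L + findInterval(seq_len(n) - 1L, if (nseg > 1L) b else numeric(0))
  structure(list(genotypes = g, H_seg = as.integer(H_seg), segments = segments,
                 seg_of_site = as.integer(seg_of_site), n_sites = n,
                 n_merges = 0L),
            class = "genotype_graph")
}

#' @export
print.genotype_graph <- function(x, ...) {
  cat(sprintf("<genotype_graph> %d sites, %d het, %d segments (%d merges)\n",
              x$n_sites, sum(x$genotypes == 1L), length(x$segments), x$n_merges))
  invisible(x)
}

# expand segment options into a full haplotype pair
.expand_phase <- function(graph, opt_idx) {
  g <- graph$genotypes
  hapA <- as.integer(g %/% 2L) # hom sites; het overwritten below
  for (s in seq_along(graph$segments)) {
    seg <- graph$segments[[s]]
    if (length(seg$het)) hapA[seg$het] <- seg$options[opt_idx[s], ]
  }
  hapB <- g - hapA
  structure(list(hapA = hapA, hapB = hapB, opt = as.integer(opt_idx)),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("<phase_estimate> %d sites\n", length(x$hapA)))
  invisible(x)
}

# recover option indices of an existing haplotype pair under a (possibly
# pruned) graph; used to carry the estimate across pruning
.estimate_options <- function(graph, hapA) {
  vapply(graph$segments, function(seg) {
    if (!length(seg$het)) return(1L)
    pat <- hapA[seg$het]
    idx <- which(apply(seg$options, 1L, function(r) all(r == pat)))
    if (!length(idx)) 1L else idx[1L]
  }, 1L)
}

# complement option index per segment (global haplotype swap symmetry)
.complement_options <- function(seg) {
  vapply(seq_len(nrow(seg$options)), function(o) {
    comp <- 1L - seg$options[o, ]
    idx <- which(apply(seg$options, 1L, function(r) all(r == comp)))
    if (length(idx)) idx[1L] else NA_integer_
  }, 1L)
}

#' Initial phase guess
#'
#' Draws a uniform random phase option per segment (seed-deterministic).
#'
#' @param graph a `genotype_graph`.
#' @return A `phase_estimate`.
#' @export
init_phase <- function(graph) {
  opt <- vapply(graph$segments, function(s) sample.int(nrow(s$options), 1L), 1L)
  .expand_phase(graph, opt)
}
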
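# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: string sorts, direct scans, double-precision
# probability calculations.

# random haplotype panel
rand_panel <- function(n_hap, n_sites, p = 0.5) {
  haplotype_panel(matrix(rbinom(n_hap * n_sites, 1L, p), n_hap, n_sites))
}

# --- PBWT oracles -----------------------------------------------------------

# positional prefix order by reversed prefix, as a string sort
naive_prefix_order <- function(U, col) {
  if (col == 0L) return(seq_len(nrow(U)))
  keys <- apply(U[, col:1, drop = FALSE], 1L, paste0, collapse = "")
  order(keys, seq_len(nrow(U)))
}

# divergence (match start) between adjacent rows of the naive order
naive_divergence <- function(U, col) {
  ord <- naive_prefix_order(U, col)
  n <- nrow(U)
  d <- integer(n)
  d[1] <- col
  if (n > 1L) for (i in 2:n) {
    a <- U[ord[i], ]; b <- U[ord[i - 1L], ]
    m <- col
    while (m > 0L && a[m] == b[m]) m <- m - 1L
    d[i] <- m
  }
  d
}

# top-S haplotypes by suffix-match length with z ending before 0-based p0,
# ties to the smaller id
brute_top_s <- function(al, z, p0, S) {
  L <- apply(al, 1L, function(h) {
    l <- 0L
    while (l < p0 && h[p0 - l] == z[p0 - l]) l <- l + 1L
    l
  })
  ord <- order(-L, seq_len(nrow(al)))
  sort(ord[seq_len(S)])
}

# naive insertion rank of z at prefix length col (target before equal keys)
naive_rank <- function(U, z, col) {
  if (col == 0L) return(0L)
  rev_key <- function(v) paste0(v[col:1], collapse = "")
  zk <- rev_key(z)
  sum(vapply(seq_len(nrow(U)), function(i) rev_key(U[i, ]) < zk, TRUE))
}

# --- float HMM oracles ------------------------------------------------------

# double-precision diploid forward-backward, independent implementation
float_fb <- function(panel, valid, graph, rho, eps) {
  K <- nrow(panel); L <- ncol(panel)
  segs <- graph$segments; nseg <- length(segs)
  nopt <- vapply(segs, function(s) nrow(s$options), 1L)
  sos <- graph$seg_of_site
  Kv <- sum(valid); jump <- valid / Kv
  em <- function(s, t) {
    E <- array(0, c(nopt[s], K, K))
    for (o in seq_len(nopt[s])) {
      e <- obliphase:::.expand_phase(graph, replace(rep(1L, nseg), s, o))
      e1 <- ifelse(panel[, t] == e$hapA[t], 1 - eps, eps)
      e2 <- ifelse(panel[, t] == e$hapB[t], 1 - eps, eps)
      E[o, , ] <- outer(e1, e2)
    }
    E
  }
  ktr <- function(M, r) {
    M1 <- (1 - r) * M + r * outer(jump, colSums(M))
    (1 - r) * M1 + r * outer(rowSums(M1), jump)
  }
  ktr_rev <- function(M, r) {
    M1 <- (1 - r) * M + r * matrix(colSums(M * jump), K, K, byrow = TRUE)
    (1 - r) * M1 + r * matrix(rowSums(t(t(M1) * jump)), K, K)
  }
  Fs <- vector("list", L)
  s <- sos[1]
  f <- array(0, c(nopt[s], K, K))
  E <- em(s, 1)
  for (o in seq_len(nopt[s])) f[o, , ] <- outer(valid, valid) * E[o, , ]
  f <- f / sum(f); Fs[[1]] <- f
  if (L > 1) for (t in 2:L) {
    s <- sos[t]; sp <- sos[t - 1]
    if (s != sp) {
      g <- apply(f, c(2, 3), sum)
      f <- array(0, c(nopt[s], K, K))
      for (o in seq_len(nopt[s])) f[o, , ] <- g / nopt[s]
    }
    for (o in seq_len(dim(f)[1])) f[o, , ] <- ktr(matrix(f[o, , ], K, K), rho[t])
    f <- f * em(s, t)
    f <- f / sum(f)
    Fs[[t]] <- f
  }
  marg <- vector("list", nseg)
  joint <- vector("list", max(nseg - 1L, 0L))
  s <- sos[L]
  b <- array(1, c(nopt[s], K, K))
  m <- apply(Fs[[L]] * b, 1, sum)
  marg[[s]] <- m / sum(m)
  if (L > 1) for (t in L:2) {
    s <- sos[t]; sp <- sos[t - 1]
    be <- b * em(s, t)
    if (s != sp) {
      J <- matrix(0, nopt[sp], nopt[s])
      for (o in seq_len(nopt[sp])) {
        gp <- ktr(matrix(Fs[[t - 1]][o, , ], K, K), rho[t])
        for (op in seq_len(nopt[s])) J[o, op] <- sum(gp * be[op, , ])
      }
      joint[[sp]] <- J / sum(J)
    }
    n <- array(0, dim(be))
    for (o in seq_len(dim(be)[1])) n[o, , ] <- ktr_rev(matrix(be[o, , ], K, K), rho[t])
    if (s != sp) {
      g <- apply(n, c(2, 3), sum)
      b <- array(0, c(nopt[sp], K, K))
      for (o in seq_len(nopt[sp])) b[o, , ] <- g
    } else b <- n
    b <- b / max(b)
    if (s != sp) {
      m <- apply(Fs[[t - 1]] * b, 1, sum)
      marg[[sp]] <- m / sum(m)
    }
  }
  list(marg = marg, joint = joint)
}

# exhaustive option-path Viterbi (max over k paths per option path, in logs)
float_vit <- function(panel, valid, graph, rho, eps) {
  K <- nrow(panel); L <- ncol(panel)
  segs <- graph$segments
  nopt <- vapply(segs, function(s) nrow(s$options), 1L)
  Kv <- sum(valid); jump <- valid / Kv
  paths <- as.matrix(expand.grid(lapply(nopt, seq_len)))
  best <- -Inf; bestpath <- NULL
  for (pi in seq_len(nrow(paths))) {
    opt <- as.integer(paths[pi, ])
    e <- obliphase:::.expand_phase(graph, opt)
    V <- log(outer(valid, valid))
    for (t in seq_len(L)) {
      if (t > 1) {
        r <- rho[t]
        cm <- apply(V, 2, max)
        V1 <- pmax(log(1 - r) + V,
                   log(r) + matrix(log(jump), K, K) + matrix(cm, K, K, byrow = TRUE))
        rm <- apply(V1, 1, max)
        V <- pmax(log(1 - r) + V1,
                  log(r) + matrix(log(jump), K, K, byrow = TRUE) + matrix(rm, K, K))
      }
      e1 <- ifelse(panel[, t] == e$hapA[t], 1 - eps, eps)
      e2 <- ifelse(panel[, t] == e$hapB[t], 1 - eps, eps)
      V <- V + log(outer(e1, e2))
    }
    m <- max(V)
    if (m > best) { best <- m; bestpath <- opt }
  }
  list(ll2 = best / log(2), opt = bestpath)
}

# random small HMM test instance
rand_hmm_instance <- function(Kmax = 4L, Lmax = 12L, H_seg = 2L) {
  K <- sample(2:Kmax, 1L)
  L <- sample(6:Lmax, 1L)
  panel <- matrix(rbinom(K * L, 1L, 0.5), K, L)
  g <- pmin(rbinom(L, 1L, 0.6) + rbinom(L, 1L, 0.3), 2L)
  if (sum(g == 1L) == 0L) g[sample.int(L, 2L)] <- 1L
  graph <- build_genotype_graph(g, H_seg = H_seg)
  rho <- runif(L, 0.01, 0.2)
  cond <- structure(list(alleles = panel, valid = rep(1L, K)),
                    class = "conditioned_panel")
  params <- structure(list(rho = rho, eps = 1e-3, frac_bits = 50L),
                      class = "hmm_params")
  list(panel = panel, graph = graph, rho = rho, cond = cond, params = params,
       eps = 1e-3)
}
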
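test_that("forward-backward matches the float oracle on small instances", {
  set.seed(89)
  for (i in 1:25) {
    inst <- rand_hmm_instance()
    orc <- float_fb(inst$panel, rep(1, nrow(inst$panel)), inst$graph,
                    inst$rho, inst$eps)
    post <- forward_backward(inst$graph, inst$cond, inst$params)
    for (s in seq_along(orc$marg)) {
      tv <- 0.5 * sum(abs(as.numeric(to_real(post$marg[[s]])) - orc$marg[[s]]))
      expect_lt(tv, 1e-3)
    }
    for (b in seq_along(orc$joint)) {
      tv <- 0.5 * sum(abs(to_real(post$joint[[b]]) - orc$joint[[b]]))
      expect_lt(tv, 1e-3)
    }
    # posteriors are normalised distributions
    for (s in seq_along(post$marg))
      expect_lt(abs(sum(to_real(post$marg[[s]])) - 1), 1e-10)
    for (b in seq_along(post$joint))
      expect_lt(abs(sum(to_real(post$joint[[b]])) - 1), 1e-10)
  }
})

test_that("posterior concentrates on the truth in forced settings", {
  # a K = 1 panel carries no relative-phase information: both options of a
  # het site are emission-symmetric, so the posterior is exactly uniform
  # (verified against the enumeration oracle)
  g <- c(1, 0, 1)
  graph <- build_genotype_graph(g, H_seg = 1L)
  panel <- matrix(c(1L, 0L, 1L), 1, 3)
  cond <- structure(list(alleles = panel, valid = 1L),
                    class = "conditioned_panel")
  params <- structure(list(rho = rep(0.01, 3), eps = 1e-6, frac_bits = 50L),
                      class = "hmm_params")
  post <- forward_backward(graph, cond, params)
  orc <- float_fb(panel, 1, graph, params$rho, params$eps)
  expect_equal(to_real(post$joint[[1]]), orc$joint[[1]], tolerance = 1e-9)
  expect_equal(as.numeric(to_real(post$marg[[1]])), c(0.5, 0.5),
               tolerance = 1e-9)
  # with the true haplotype pair in the panel and rho -> 0, the posterior
  # concentrates on the true relative phase (folded over the swap symmetry)
  set.seed(95)
  hA <- c(1L, 0L, 0L, 1L, 1L, 0L); hB <- c(0L, 0L, 1L, 1L, 0L, 1L)
  gt <- hA + hB
  grapht <- build_genotype_graph(gt, H_seg = 1L)
  condt <- structure(list(alleles = rbind(hA, hB), valid = c(1L, 1L)),
                     class = "conditioned_panel")
  paramst <- structure(list(rho = rep(1e-7, 6), eps = 1e-6, frac_bits = 50L),
                       class = "hmm_params")
  postt <- forward_backward(grapht, condt, paramst)
  truth_opt <- obliphase:::.estimate_options(grapht, hA)
  for (b in seq_along(postt$joint)) {
    jp <- to_real(postt$joint[[b]])
    o <- truth_opt[b]; op <- truth_opt[b + 1]
    expect_gt(jp[o, op] + jp[3 - o, 3 - op], 0.99)
  }
  # rho -> 0 with the true pair in the panel: posterior nails the phase
  set.seed(97)
  hapA <- rbinom(8, 1, 0.5); hapB <- rbinom(8, 1, 0.5)
  g2 <- hapA + hapB
  graph2 <- build_genotype_graph(g2)
  cond2 <- structure(list(alleles = rbind(hapA, hapB), valid = c(1L, 1L)),
                     class = "conditioned_panel")
  params2 <- structure(list(rho = rep(1e-7, 8), eps = 1e-6, frac_bits = 50L),
                       class = "hmm_params")
  vit <- viterbi_decode(graph2, cond2, params2)
  ok <- identical(vit$hapA, as.integer(hapA)) ||
    identical(vit$hapA, as.integer(hapB))
  expect_true(ok)
})

test_that("viterbi agrees with exhaustive path enumeration", {
  set.seed(101)
  for (i in 1:25) {
    inst <- rand_hmm_instance()
    orc <- float_vit(inst$panel, rep(1, nrow(inst$panel)), inst$graph,
                     inst$rho, inst$eps)
    vit <- viterbi_decode(inst$graph, inst$cond, inst$params)
    oe <- obliphase:::.expand_phase(inst$graph, orc$opt)
    same <- identical(vit$hapA, oe$hapA) && identical(vit$hapB, oe$hapB)
    swap <- identical(vit$hapA, oe$hapB) && identical(vit$hapB, oe$hapA)
    expect_true(same || swap ||
                  abs(attr(vit, "loglik") - orc$ll2) < 1e-3) # exact-tie path
    expect_lt(abs(attr(vit, "loglik") - orc$ll2), 1e-3)
  }
})

test_that("viterbi likelihood dominates sampled paths", {
  set.seed(103)
  inst <- rand_hmm_instance(Kmax = 4L, Lmax = 12L)
  post <- forward_backward(inst$graph, inst$cond, inst$params)
  vit <- viterbi_decode(inst$graph, inst$cond, inst$params)
  # score any option path in double precision
  ll_path <- function(opt) {
    e <- obliphase:::.expand_phase(inst$graph, opt)
    K <- nrow(inst$panel); L <- ncol(inst$panel)
    jump <- rep(1 / K, K)
    V <- log(matrix(1, K, K))
    for (t in 1:L) {
      if (t > 1) {
        r <- inst$rho[t]
        cm <- apply(V, 2, max)
        V1 <- pmax(log(1 - r) + V, log(r) + log(1 / K) + matrix(cm, K, K, byrow = TRUE))
        rm <- apply(V1, 1, max)
        V <- pmax(log(1 - r) + V1, log(r) + log(1 / K) + matrix(rm, K, K))
      }
      e1 <- ifelse(inst$panel[, t] == e$hapA[t], 1 - inst$eps, inst$eps)
      e2 <- ifelse(inst$panel[, t] == e$hapB[t], 1 - inst$eps, inst$eps)
      V <- V + log(outer(e1, e2))
    }
    max(V) / log(2)
  }
  vll <- ll_path(vit$opt)
  for (r in 1:100) {
    sp <- sample_path(post, inst$graph)
    expect_lte(ll_path(sp$opt), vll + 1e-9)
  }
})

test_that("path sampling follows the posterior and is seed-deterministic", {
  # degenerate posterior: single forced option
  g <- c(2, 0, 2)
  graph <- build_genotype_graph(g)
  cond <- structure(list(alleles = matrix(1L, 2, 3), valid = c(1L, 1L)),
                    class = "conditioned_panel")
  params <- structure(list(rho = rep(0.05, 3), eps = 1e-4, frac_bits = 50L),
                      class = "hmm_params")
  post <- forward_backward(graph, cond, params)
  for (i in 1:5) expect_equal(sample_path(post, graph)$opt, 1L)
  # uniform posterior over 2 options: frequencies 0.5 +- 0.02
  graph1 <- build_genotype_graph(c(1, 0, 0), H_seg = 1L)
  condu <- structure(list(alleles = matrix(c(0L, 1L), 2, 3), valid = c(1L, 1L)),
                     class = "conditioned_panel")
  postu <- forward_backward(graph1, condu, params)
  expect_equal(as.numeric(to_real(postu$marg[[1]])), c(0.5, 0.5),
               tolerance = 1e-6)
  set.seed(7)
  draws <- replicate(10000, sample_path(postu, graph1)$opt)
  expect_lt(abs(mean(draws == 1) - 0.5), 0.02)
  set.seed(11); p1 <- replicate(20, sample_path(postu, graph1)$opt)
  set.seed(11); p2 <- replicate(20, sample_path(postu, graph1)$opt)
  expect_identical(p1, p2)
})

test_that("pruning merges confident boundaries and never re-splits", {
  set.seed(107)
  # target equals a panel row pair: boundaries become confident
  hapA <- rbinom(12, 1, 0.5); hapB <- rbinom(12, 1, 0.5)
  g <- hapA + hapB
  if (sum(g == 1) < 4) { hapA[1:4] <- 0:1; hapB[1:4] <- 1:0; g <- hapA + hapB }
  graph <- build_genotype_graph(g, H_seg = 2L)
  cond <- structure(list(alleles = rbind(hapA, hapB), valid = c(1L, 1L)),
                    class = "conditioned_panel")
  params <- structure(list(rho = rep(1e-6, 12), eps = 1e-6, frac_bits = 50L),
                      class = "hmm_params")
  post <- forward_backward(graph, cond, params)
  pruned <- prune(graph, post, 0.999)
  expect_lt(length(pruned$segments), length(graph$segments))
  expect_gt(pruned$n_merges, 0L)
  # merged segments expose exactly the two swap-symmetric options
  for (s in pruned$segments) {
    if (length(s$het) > graph$H_seg) expect_equal(nrow(s$options), 2L)
  }
  # uniform posterior: nothing merges
  graphu <- build_genotype_graph(c(1, 0, 1), H_seg = 1L)
  condu <- structure(list(alleles = matrix(c(0L, 1L), 2, 3), valid = c(1L, 1L)),
                     class = "conditioned_panel")
  postu <- forward_backward(graphu, condu,
                            structure(list(rho = rep(0.5, 3), eps = 0.25,
                                           frac_bits = 50L),
                                      class = "hmm_params"))
  expect_equal(length(prune(graphu, postu, 0.999)$segments), 2L)
  # merge count equals a direct threshold scan on the folded posteriors
  folded_max <- function(post, graph, b) {
    jp <- to_real(post$joint[[b]])
    ca <- obliphase:::.complement_options(graph$segments[[b]])
    cb <- obliphase:::.complement_options(graph$segments[[b + 1]])
    m <- -Inf
    for (o in seq_len(nrow(jp))) for (op in seq_len(ncol(jp))) {
      f <- jp[o, op] + if (!is.na(ca[o]) && !is.na(cb[op])) jp[ca[o], cb[op]] else 0
      m <- max(m, f)
    }
    m
  }
  n_confident <- sum(vapply(seq_len(length(graph$segments) - 1), function(b)
    folded_max(post, graph, b) > 0.999, TRUE))
  expect_equal(pruned$n_merges,
               length(graph$segments) - length(pruned$segments))
  expect_gte(n_confident, pruned$n_merges)
})
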
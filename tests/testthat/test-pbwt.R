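test_that("prefix-tree order and divergences match the naive PBWT", {
  # two complementary single-site haplotypes
  b <- compress_block(haplotype_panel(matrix(c(0L, 1L), 2, 1)), 0, 1)
  tr <- build_prefix_tree(b)
  expect_equal(tr$ord[2, ] + 1L, c(1L, 2L))
  # a single unique row gives one node chain with full-length matches
  b1 <- compress_block(haplotype_panel(matrix(1L, 4, 6)), 0, 6)
  tr1 <- build_prefix_tree(b1)
  expect_equal(tr1$n_unique, 1L)
  set.seed(47)
  for (i in 1:25) {
    n <- sample(2:12, 1); w <- sample(2:10, 1)
    pan <- rand_panel(n, w)
    b <- compress_block(pan, 0, w)
    tr <- build_prefix_tree(b)
    for (col in 0:w) {
      expect_equal(tr$ord[col + 1, ] + 1L, naive_prefix_order(b$uniques, col))
      expect_equal(tr$div[col + 1, ], naive_divergence(b$uniques, col))
    }
  }
})

test_that("tree nodes group identical prefixes and link to children", {
  pan <- haplotype_panel(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(0L, 0L)))
  tr <- build_prefix_tree(compress_block(pan, 0, 2))
  n0 <- tree_nodes(tr, 0)
  expect_equal(nrow(n0), 1L) # all prefixes empty
  expect_equal(n0$n_hap, 4L)
  n1 <- tree_nodes(tr, 1)
  expect_equal(nrow(n1), 2L) # prefixes 0 and 1
  expect_false(any(is.na(c(n0$child0, n0$child1))))
  n2 <- tree_nodes(tr, 2)
  expect_equal(nrow(n2), 3L) # three unique rows
})

test_that("oblivious insertion reproduces naive PBWT ranks and divergences", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(2:12, 1); w <- sample(2:10, 1)
    pan <- rand_panel(n, w)
    b <- compress_block(pan, 0, w)
    tr <- build_prefix_tree(b)
    trees <- build_prefix_trees(compress_panel(pan, max_width = w,
                                               max_uniques = 2^w))
    z <- rbinom(w, 1, 0.5)
    ins <- insert_estimate(trees, z)$blocks[[1]]
    for (col in 0:w) {
      expect_equal(ins$rank[col + 1], naive_rank(b$uniques, z, col))
      r <- ins$rank[col + 1]
      ord <- naive_prefix_order(b$uniques, col)
      ms <- function(u) { # brute-force match start of z vs unique u
        m <- col
        while (m > 0 && b$uniques[u, m] == z[m]) m <- m - 1
        m
      }
      expect_equal(ins$dzu[col + 1], if (r > 0) ms(ord[r]) else col)
      expect_equal(ins$dzd[col + 1], if (r < nrow(b$uniques)) ms(ord[r + 1]) else col)
    }
  }
  # a target equal to a reference row matches it over the full block
  pan <- rand_panel(6, 8)
  trees <- build_prefix_trees(compress_panel(pan, max_width = 8))
  ins <- insert_estimate(trees, pan$alleles[3, ])$blocks[[1]]
  u3 <- trees$trees[[1]]$index_map[3]
  expect_equal(ins$end_lcs[u3], 8L)
  # the complement of every row diverges everywhere
  insc <- insert_estimate(trees, 1L - pan$alleles[3, ])$blocks[[1]]
  expect_equal(insc$end_lcs[u3], 0L)
})

test_that("candidate search returns a superset of the block-level top-S", {
  set.seed(59)
  for (i in 1:20) {
    n <- sample(4:16, 1); w <- sample(3:10, 1)
    pan <- rand_panel(n, w)
    trees <- build_prefix_trees(compress_panel(pan, max_width = w,
                                               max_uniques = 2^w))
    tr <- trees$trees[[1]]
    z <- rbinom(w, 1, 0.5)
    ins <- insert_estimate(trees, z)$blocks[[1]]
    col <- sample(0:w, 1)
    S <- sample(1:min(4, n), 1)
    cands <- candidate_search(tr, ins, col, S)
    expect_gte(cands$n_hap, S)
    # block-level LCS oracle over original haplotypes
    lcs_true <- apply(pan$alleles, 1, function(h) {
      l <- 0
      while (l < col && h[col - l] == z[col - l]) l <- l + 1
      l
    })
    top <- sort(lcs_true, decreasing = TRUE)[S]
    cand_haps <- which(tr$index_map %in% cands$uniques)
    expect_true(all(which(lcs_true > top) %in% cand_haps))
    # candidates' LCS values are exact
    lcs_map <- setNames(cands$lcs, cands$uniques)
    expect_equal(unname(lcs_map[as.character(tr$index_map[cand_haps])]),
                 unname(lcs_true[cand_haps]))
  }
  expect_error(candidate_search(build_prefix_tree(
    compress_block(rand_panel(3, 4), 0, 4)),
    NULL, 0, 10), "S exceeds")
})

test_that("global LCS carryover equals a direct scan on the uncompressed panel", {
  set.seed(61)
  for (i in 1:15) {
    pan <- rand_panel(sample(4:16, 1), sample(20:60, 1))
    trees <- build_prefix_trees(compress_panel(pan, max_width = 7,
                                               max_uniques = 12))
    z <- rbinom(ncol(pan$alleles), 1, 0.5)
    ins <- insert_estimate(trees, z)
    for (b in seq_along(trees$trees)) {
      start <- trees$trees[[b]]$start
      g <- global_lcs_at_block_start(trees, ins, b)
      want <- apply(pan$alleles, 1, function(h) {
        l <- 0
        while (l < start && h[start - l] == z[start - l]) l <- l + 1
        l
      })
      expect_equal(g, as.integer(want))
    }
  }
  # block 1 start: all zeros; identical target: cumulative width
  pan <- rand_panel(5, 24)
  trees <- build_prefix_trees(compress_panel(pan, max_width = 6))
  ins <- insert_estimate(trees, pan$alleles[2, ])
  for (b in seq_along(trees$trees)) {
    g <- global_lcs_at_block_start(trees, ins, b)
    expect_equal(g[2], trees$trees[[b]]$start)
  }
  expect_equal(global_lcs_at_block_start(trees, ins, 1), integer(5))
})

test_that("end-to-end neighbour selection equals the brute-force top-S scan", {
  set.seed(67)
  for (i in 1:40) {
    nh <- sample(4:24, 1); ns <- sample(10:80, 1)
    pan <- rand_panel(nh, ns)
    trees <- build_prefix_trees(compress_panel(pan, max_width = 8,
                                               max_uniques = 16))
    z <- rbinom(ns, 1, 0.5)
    ins <- insert_estimate(trees, z)
    for (S in c(1, 2, 4)) {
      if (S > nh) next
      pos <- sample(ns, 3)
      nss <- select_neighbors(trees, ins, pos, S)
      for (k in seq_along(pos)) {
        expect_equal(sort(as.integer(nss[[k]])),
                     brute_top_s(pan$alleles, z, pos[k] - 1, S))
      }
    }
  }
  # the candidate-walk + subset-ranking path agrees with the full ranking
  for (i in 1:15) {
    nh <- sample(4:16, 1); ns <- sample(10:40, 1)
    pan <- rand_panel(nh, ns)
    trees <- build_prefix_trees(compress_panel(pan, max_width = 8,
                                               max_uniques = 16))
    z <- rbinom(ns, 1, 0.5)
    ins <- insert_estimate(trees, z)
    p <- sample(ns, 1)
    S <- sample(1:min(4, nh), 1)
    p0 <- p - 1L
    b <- max(1L, min(findInterval(p0, trees$starts), length(trees$trees)))
    tr <- trees$trees[[b]]
    col <- p0 - tr$start
    cands <- candidate_search(tr, ins$blocks[[b]], col, S)
    g <- global_lcs_at_block_start(trees, ins, b)
    via_cands <- sort(as.integer(rank_neighbors(cands, g, tr, col, S)))
    full <- sort(as.integer(select_neighbors(trees, ins, p, S)[[1]]))
    expect_identical(via_cands, full)
  }
  # a target equal to panel row h ranks h first everywhere
  pan <- rand_panel(8, 30)
  trees <- build_prefix_trees(compress_panel(pan, max_width = 8))
  ins <- insert_estimate(trees, pan$alleles[5, ])
  ns <- select_neighbors(trees, ins, c(10, 20, 30), 1)
  for (s in ns) expect_equal(as.integer(s), 5L)
})

test_that("neighbour selection traces are identical across random targets", {
  set.seed(71)
  pan <- rand_panel(12, 40)
  trees <- build_prefix_trees(compress_panel(pan, max_width = 8,
                                             max_uniques = 16))
  run <- function(z) {
    ins <- insert_estimate(trees, z)
    ns <- select_neighbors(trees, ins, c(15, 33), 2)
    build_conditioned_panel(ns, trees, 4)
  }
  tr1 <- trace_capture(run(rbinom(40, 1, 0.5)))
  tr2 <- trace_capture(run(rbinom(40, 1, 0.5)))
  tr3 <- trace_capture(run(rep(0L, 40)))
  expect_gt(nrow(tr1$events), 0)
  expect_true(traces_identical(tr1, tr2))
  expect_true(traces_identical(tr1, tr3))
})

test_that("prefix trees are bit-identical when rebuilt (public data reuse)", {
  set.seed(73)
  pan <- rand_panel(10, 30)
  cp <- compress_panel(pan, max_width = 8)
  t1 <- build_prefix_trees(cp)
  t2 <- build_prefix_trees(cp)
  expect_identical(t1$trees, t2$trees)
})

test_that("conditioned panel equals plain set union with sentinel padding", {
  set.seed(79)
  pan <- rand_panel(10, 12)
  trees <- build_prefix_trees(compress_panel(pan, max_width = 6))
  ns1 <- structure(c(3L, 5L), class = "neighbor_set")
  ns2 <- structure(c(5L, 7L), class = "neighbor_set")
  condp <- build_conditioned_panel(list(ns1, ns2), trees, 4)
  expect_equal(sum(condp$bitmap), 3) # union {3,5,7}
  expect_equal(condp$ids, c(3L, 5L, 7L, 3L)) # padded with first selected
  expect_equal(condp$valid, c(1L, 1L, 1L, 0L))
  expect_equal(condp$alleles[1, ], pan$alleles[3, ])
  for (i in 1:20) {
    sets <- lapply(1:3, function(j)
      structure(sample(10, 2), class = "neighbor_set"))
    K <- 6
    condp <- build_conditioned_panel(sets, trees, K)
    want <- sort(unique(unlist(sets)))
    expect_equal(sort(unique(condp$ids[condp$valid == 1])), want)
    expect_equal(sum(condp$valid), length(want))
  }
})
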
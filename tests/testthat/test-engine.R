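small_cfg <- function(seed = NULL, ...) {
  phase_config(seed = seed, max_positions = 4L,
               schedule = c("b", "b", "b", "p", "b", "p", "m", "m"),
               window_min_segments = 10L, ...)
}

test_that("targets present verbatim in the panel are phased without switch errors", {
  cfg <- sim_config(seed = 8L, n_hap = 60L, n_sites = 150L,
                    target_recombs = 0L, genotype_error = 0)
  pan <- simulate_panel(cfg)
  set.seed(8)
  tr <- make_target(pan, cfg)
  est <- mcmc_run(tr$genotypes, pan, small_cfg(seed = 80L))
  expect_equal(as.numeric(switch_error_rate(est, tr)), 0)
  expect_equal(est$hapA + est$hapB, tr$genotypes)
})

test_that("zero-het targets return immediately with the forced phase", {
  pan <- rand_panel(10, 30)
  g <- 2L * pan$alleles[1, ]
  est <- mcmc_run(g, pan, small_cfg(seed = 1L))
  expect_equal(est$hapA, pan$alleles[1, ])
  expect_equal(est$hapB, pan$alleles[1, ])
})

test_that("a fixed seed yields byte-identical phased VCF output", {
  cfg <- sim_config(seed = 9L, n_hap = 50L, n_sites = 120L)
  pan <- simulate_panel(cfg)
  set.seed(9)
  tr <- make_target(pan, cfg)
  run_once <- function() {
    est <- mcmc_run(tr$genotypes, pan, small_cfg(seed = 99L))
    path <- tempfile(fileext = ".vcf")
    write_phased_vcf(path, est, pan$site_ids)
    readBin(path, "raw", file.size(path))
  }
  expect_identical(run_once(), run_once())
})

test_that("segment count never increases across pruning iterations", {
  cfg <- sim_config(seed = 10L, n_hap = 60L, n_sites = 150L)
  pan <- simulate_panel(cfg)
  set.seed(10)
  tr <- make_target(pan, cfg)
  cp <- compress_panel(pan)
  trees <- build_prefix_trees(cp)
  pcfg <- small_cfg()
  set.seed(123)
  graph <- build_genotype_graph(tr$genotypes, pcfg$H_seg)
  est <- init_phase(graph)
  nsegs <- length(graph$segments)
  for (i in 1:4) {
    cond <- obliphase:::.iteration_panel(est, graph, trees, pcfg)
    params <- hmm_params(length(tr$genotypes), nrow(cond$alleles),
                         eps = pcfg$eps, frac_bits = pcfg$frac_bits)
    post <- forward_backward(graph, cond, params)
    graph <- prune(graph, post, 0.99)
    expect_lte(length(graph$segments), nsegs)
    nsegs <- length(graph$segments)
    est <- sample_path(post = forward_backward(graph,
                                               obliphase:::.iteration_panel(est, graph, trees, pcfg),
                                               params), graph)
  }
})

test_that("window stitching flips and joins deterministically", {
  # identical overlap: no flip
  e1 <- structure(list(hapA = c(0L, 1L, 1L, 0L), hapB = c(1L, 0L, 0L, 1L)),
                  class = "phase_estimate")
  e2 <- structure(list(hapA = c(1L, 0L, 0L, 1L), hapB = c(0L, 1L, 1L, 0L)),
                  class = "phase_estimate")
  # windows 1:4 and 3:6; e2's overlap (sites 3,4) equals e1's
  e2b <- structure(list(hapA = c(1L, 0L, 1L, 1L), hapB = c(0L, 1L, 0L, 0L)),
                   class = "phase_estimate")
  st <- stitch_windows(list(e1, e2b), list(c(1L, 4L), c(3L, 6L)), 6L)
  expect_equal(st$hapA[1:4], e1$hapA)
  expect_equal(st$hapA + st$hapB, c(e1$hapA + e1$hapB, e2b$hapA[3:4] + e2b$hapB[3:4]))
  # fully complementary overlap: flip
  e3 <- structure(list(hapA = c(0L, 1L, 1L, 1L), hapB = c(1L, 0L, 0L, 0L)),
                  class = "phase_estimate")
  stf <- stitch_windows(list(e1, e3), list(c(1L, 4L), c(3L, 6L)), 6L)
  # after flipping, the relative phase across the join is consistent
  expect_equal(stf$hapA[3], e1$hapA[3])
  # random windows: het agreement after stitching is at least as good as raw
  set.seed(113)
  for (i in 1:10) {
    hapA <- rbinom(12, 1, 0.5); hapB <- rbinom(12, 1, 0.5)
    w1 <- structure(list(hapA = hapA[1:8], hapB = hapB[1:8]),
                    class = "phase_estimate")
    flip <- sample(c(TRUE, FALSE), 1)
    w2 <- structure(list(hapA = (if (flip) hapB else hapA)[5:12],
                         hapB = (if (flip) hapA else hapB)[5:12]),
                    class = "phase_estimate")
    st <- stitch_windows(list(w1, w2), list(c(1L, 8L), c(5L, 12L)), 12L)
    het <- which(hapA != hapB)
    agree <- sum(st$hapA[het] == hapA[het])
    expect_true(agree == length(het) || agree == 0) # single global orientation
  }
})

test_that("multi-window runs stitch into a consistent estimate", {
  cfg <- sim_config(seed = 12L, n_hap = 60L, n_sites = 260L,
                    target_recombs = 0L, genotype_error = 0)
  pan <- simulate_panel(cfg)
  set.seed(12)
  tr <- make_target(pan, cfg)
  pcfg <- phase_config(seed = 14L, max_positions = 4L,
                       schedule = c("b", "b", "p", "m", "m"),
                       window_min_segments = 6L, window_overlap = 30L)
  est <- mcmc_run(tr$genotypes, pan, pcfg)
  expect_equal(est$hapA + est$hapB, tr$genotypes)
  expect_lte(as.numeric(switch_error_rate(est, tr)), 0.05)
})

test_that("config validation rejects unknown keys and bad schedules", {
  expect_error(phase_config(schedule = c("b", "x")), "schedule")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 3", "S: 2", "bogus_key: 1"), path)
  expect_error(phase_config_from_yaml(path), "unknown config keys")
  writeLines(c("seed: 3", "S: 2", "max_positions: 4"), path)
  cfg <- phase_config_from_yaml(path)
  expect_equal(cfg$S, 2L)
  expect_equal(cfg$seed, 3)
})

test_that("target/panel site mismatch errors at ingest", {
  pan <- rand_panel(6, 20)
  expect_error(mcmc_run(rep(1L, 19), pan, small_cfg(seed = 2L)),
               "different site sets")
})
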
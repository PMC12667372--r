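#' Simulation configuration
#'
#' Defaults describe a desk-scale panel with Li-Stephens mosaic structure:
#' 200 haplotypes over 500 biallelic sites derived from 20 founders, targets
#' built as panel mosaics with 3 recombinations and 0.2% genotype error.
#'
#' @param n_founders founder haplotypes drawn site-wise from the allele
#'   frequencies.
#' @param n_hap total panel haplotypes (founders plus mosaics).
#' @param n_sites biallelic sites.
#' @param maf_range range of per-site minor-allele frequencies.
#' @param recomb_per_site founder-switch probability per interval for panel
#'   mosaics.
#' @param mutation_per_site allele-flip probability for panel mosaics.
#' @param target_recombs exact number of switch points per target haplotype.
#' @param genotype_error dosage-resampling rate on the target.
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_founders = 20L, n_hap = 200L, n_sites = 500L,
                       maf_range = c(0.05, 0.5), recomb_per_site = 0.01,
                       mutation_per_site = 0.001, target_recombs = 3L,
                       genotype_error = 0.002, seed = 1L) {
  stopifnot(n_founders <= n_hap, recomb_per_site >= 0, recomb_per_site < 1,
            mutation_per_site >= 0, mutation_per_site < 1,
            genotype_error >= 0, genotype_error < 1)
  structure(list(n_founders = as.integer(n_founders), n_hap = as.integer(n_hap),
                 n_sites = as.integer(n_sites), maf_range = maf_range,
                 recomb_per_site = recomb_per_site,
                 mutation_per_site = mutation_per_site,
                 target_recombs = as.integer(target_recombs),
                 genotype_error = genotype_error, seed = as.integer(seed)),
            class = "sim_config")
}

# one mosaic of the rows of `mat`, switching source with prob r per interval
.mosaic <- function(mat, r) {
  n <- ncol(mat)
  src <- integer(n)
  cur <- sample.int(nrow(mat), 1L)
  for (j in seq_len(n)) {
    if (j > 1L && runif(1) < r) cur <- sample.int(nrow(mat), 1L)
    src[j] <- cur
  }
  mat[cbind(src, seq_len(n))]
}

#' Simulate a reference panel with mosaic sharing structure
#'
#' Founders are drawn per site as Bernoulli(maf) with maf ~
#' Uniform(`maf_range`); the remaining haplotypes are founder mosaics
#' (random founder copy, switching founders with probability
#' `recomb_per_site` per interval) with alleles flipped at
#' `mutation_per_site`.  Seed-deterministic.
#'
#' @param cfg a [sim_config].
#' @return A [haplotype_panel].
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  maf <- runif(cfg$n_sites, cfg$maf_range[1], cfg$maf_range[2])
  founders <- matrix(rbinom(cfg$n_founders * cfg$n_sites, 1L,
                            rep(maf, each = cfg$n_founders)),
                     cfg$n_founders, cfg$n_sites)
  al <- matrix(0L, cfg$n_hap, cfg$n_sites)
  al[seq_len(cfg$n_founders), ] <- founders
  if (cfg$n_hap > cfg$n_founders) {
    for (h in (cfg$n_founders + 1L):cfg$n_hap) {
      row <- .mosaic(founders, cfg$recomb_per_site)
      flip <- runif(cfg$n_sites) < cfg$mutation_per_site
      row[flip] <- 1L - row[flip]
      al[h, ] <- row
    }
  }
  haplotype_panel(al)
}

#' Build a ground-truth diploid target from a panel
#'
#' Each true haplotype is a mosaic of panel rows with exactly
#' `target_recombs` uniformly placed switch points.  Genotype errors are
#' applied at rate `genotype_error` by resampling the dosage; the truth
#' haplotype pair is adjusted at error sites (a resulting heterozygote gets a
#' random split) so the dosage identity `genotypes = hapA + hapB` holds
#' everywhere and error-created heterozygotes are scored like any other.
#'
#' @param panel a [haplotype_panel].
#' @param cfg a [sim_config].
#' @return A `truth_set`: `hapA`, `hapB`, `genotypes`, `n_errors`, and the
#'   switch positions used (`switchesA`, `switchesB`).
#' @export
make_target <- function(panel, cfg) {
  al <- panel$alleles
  n <- ncol(al)
  draw_mosaic <- function() {
    k <- cfg$target_recombs
    cuts <- if (k > 0) sort(sample(seq_len(n - 1L), k)) else integer(0)
    bounds <- c(0L, cuts, n)
    hap <- integer(n)
    for (i in seq_len(length(bounds) - 1L)) {
      src <- sample.int(nrow(al), 1L)
      hap[(bounds[i] + 1L):bounds[i + 1L]] <- al[src, (bounds[i] + 1L):bounds[i + 1L]]
    }
    list(hap = hap, cuts = cuts)
  }
  a <- draw_mosaic()
  b <- draw_mosaic()
  hapA <- a$hap
  hapB <- b$hap
  err <- which(runif(n) < cfg$genotype_error)
  for (j in err) {
    d <- sample(0:2, 1L)
    if (d == 0L) { hapA[j] <- 0L; hapB[j] <- 0L }
    else if (d == 2L) { hapA[j] <- 1L; hapB[j] <- 1L }
    else { hapA[j] <- sample(0:1, 1L); hapB[j] <- 1L - hapA[j] }
  }
  structure(list(hapA = hapA, hapB = hapB, genotypes = hapA + hapB,
                 n_errors = length(err), switchesA = a$cuts,
                 switchesB = b$cuts),
            class = "truth_set")
}

#' Switch error rate
#'
#' The proportion of consecutive heterozygous site pairs whose relative
#' phase (same-versus-opposite assignment of the two het alleles to
#' haplotype A) differs between estimate and truth.  Invariant to globally
#' swapping the estimated haplotype pair.  With fewer than two het sites the
#' rate is undefined and 0 is returned with attribute `undefined = TRUE`.
#'
#' @param est a `phase_estimate`.
#' @param truth a `truth_set` (or any list with `hapA`/`hapB`).
#' @return Error rate in `[0, 1]`; attribute `n_pairs` gives the
#'   denominator.
#' @export
switch_error_rate <- function(est, truth) {
  ge <- est$hapA + est$hapB
  gt <- truth$hapA + truth$hapB
  if (!identical(as.integer(ge), as.integer(gt)))
    stop("estimate and truth disagree on genotypes")
  het <- which(gt == 1L)
  if (length(het) < 2L) {
    r <- 0
    attr(r, "undefined") <- TRUE
    attr(r, "n_pairs") <- 0L
    return(r)
  }
  eh <- est$hapA[het]
  th <- truth$hapA[het]
  same_e <- eh[-1L] == eh[-length(eh)]
  same_t <- th[-1L] == th[-length(th)]
  errs <- xor(same_e, same_t)
  r <- mean(errs)
  attr(r, "n_pairs") <- length(errs)
  r
}

#' Benchmark phasing accuracy over a configuration grid
#'
#' For each row of the grid, simulates panels/targets over the given seeds,
#' phases with dynamic fixed point and (for comparison) with the static
#' fixed-point pipeline, and reports mean switch error rates with 95%
#' confidence intervals.
#'
#' @param grid data.frame of [sim_config] overrides (one scenario per row;
#'   columns must be sim_config argument names).
#' @param seeds integer vector of simulation seeds per scenario.
#' @param config a [phase_config] used for phasing.
#' @param static also run the static fixed-point pipeline (default TRUE).
#' @param out_tsv optional path for a TSV report.
#' @return data.frame with one row per scenario: mean SER, CI bounds, and
#'   the static-pipeline column.
#' @export
benchmark_run <- function(grid = data.frame(n_hap = c(50L, 200L)),
                          seeds = 1:3, config = phase_config(),
                          static = TRUE, out_tsv = NULL) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    sers <- numeric(0)
    sers_static <- numeric(0)
    for (sd in seeds) {
      cfg <- do.call(sim_config, c(args, list(seed = sd)))
      pan <- simulate_panel(cfg)
      tr <- make_target(pan, cfg)
      config$seed <- sd + 10000L
      est <- mcmc_run(tr$genotypes, pan, config)
      sers <- c(sers, as.numeric(switch_error_rate(est, tr)))
      if (static) {
        cs <- config
        cs$dynamic_scaling <- FALSE
        cs$seed <- sd + 10000L
        es <- mcmc_run(tr$genotypes, pan, cs)
        sers_static <- c(sers_static, as.numeric(switch_error_rate(es, tr)))
      }
    }
    ci <- if (length(sers) > 1L)
      qt(0.975, length(sers) - 1L) * sd(sers) / sqrt(length(sers)) else 0
    data.frame(grid[i, , drop = FALSE],
               mean_ser = mean(sers), ci_lo = mean(sers) - ci,
               ci_hi = mean(sers) + ci,
               mean_ser_static = if (static) mean(sers_static) else NA_real_,
               n_seeds = length(seeds))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_tsv))
    write.table(out, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
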
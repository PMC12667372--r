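#' Phasing configuration
#'
#' Defaults follow a SHAPEIT4-style schedule: burn-in iterations interleaved
#' with pruning stages, then main iterations decoded by Viterbi, keeping the
#' best-likelihood decode.
#'
#' @param seed optional RNG seed applied by [mcmc_run].
#' @param S nearest neighbours per search position.
#' @param H_seg het sites per genotype-graph segment.
#' @param Ne effective population size proxy.
#' @param eps allele mis-copy probability.
#' @param prune_threshold boundary-posterior confidence for merging.
#' @param schedule character vector over `"b"` (burn-in), `"p"` (prune),
#'   `"m"` (main).
#' @param window_min_segments minimum expected segments per phasing window.
#' @param min_het_rate minimum heterozygosity rate used to size windows.
#' @param window_overlap sites of overlap between adjacent windows.
#' @param max_positions cap on search positions per haplotype per iteration;
#'   the conditioned-panel capacity is `2 * max_positions * S`.
#' @param frac_bits fixed-point fractional bits.
#' @param dynamic_scaling use dynamic per-site rescaling (default `TRUE`).
#' @param static_frac_bits fractional bits when `dynamic_scaling = FALSE`.
#' @param max_width,max_uniques panel-compression caps.
#' @return A `phase_config` list.
#' @export
phase_config <- function(seed = NULL, S = 4L, H_seg = 3L, Ne = 15000,
                         eps = 1e-4, prune_threshold = 0.999,
                         schedule = c("b", "b", "b", "b", "b", "p", "b", "p",
                                      "b", "p", "m", "m", "m", "m", "m"),
                         window_min_segments = 20L, min_het_rate = 0.10,
                         window_overlap = 60L, max_positions = 8L,
                         frac_bits = 50L, dynamic_scaling = TRUE,
                         static_frac_bits = 52L,
                         max_width = 32L, max_uniques = 256L) {
  stopifnot(all(schedule %in% c("b", "p", "m")), S >= 1, H_seg >= 1,
            min_het_rate > 0, min_het_rate <= 1)
  structure(list(seed = seed, S = as.integer(S), H_seg = as.integer(H_seg),
                 Ne = Ne, eps = eps, prune_threshold = prune_threshold,
                 schedule = schedule,
                 window_min_segments = as.integer(window_min_segments),
                 min_het_rate = min_het_rate,
                 window_overlap = as.integer(window_overlap),
                 max_positions = as.integer(max_positions),
                 frac_bits = as.integer(frac_bits),
                 dynamic_scaling = isTRUE(dynamic_scaling),
                 static_frac_bits = as.integer(static_frac_bits),
                 max_width = as.integer(max_width),
                 max_uniques = as.integer(max_uniques)),
            class = "phase_config")
}

#' Read a phasing configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `phase_config`.
#' @export
phase_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phase_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(phase_config, vals)
}

# one MCMC iteration's conditioned panel for the current estimate
.iteration_panel <- function(est, graph, trees, cfg) {
  pos <- select_search_positions(graph, cfg$max_positions)
  if (length(pos) == 0L) pos <- 1L
  K_cap <- min(2L * cfg$max_positions * cfg$S, trees$cp$n_hap)
  insA <- insert_estimate(trees, est$hapA)
  insB <- insert_estimate(trees, est$hapB)
  nsA <- select_neighbors(trees, insA, pos, cfg$S)
  nsB <- select_neighbors(trees, insB, pos, cfg$S)
  build_conditioned_panel(c(nsA, nsB), trees, K_cap)
}

# phase one window
.run_window <- function(genotypes, trees, cfg, cm = NULL) {
  graph <- build_genotype_graph(genotypes, cfg$H_seg)
  if (sum(genotypes == 1L) == 0L) {
    return(.expand_phase(graph, rep(1L, length(graph$segments))))
  }
  est <- init_phase(graph)
  fbits <- if (cfg$dynamic_scaling) cfg$frac_bits else cfg$static_frac_bits
  best <- NULL
  best_ll <- -Inf
  for (stage in cfg$schedule) {
    cond <- .iteration_panel(est, graph, trees, cfg)
    params <- hmm_params(length(genotypes), nrow(cond$alleles),
                         cm = cm, Ne = cfg$Ne, eps = cfg$eps,
                         frac_bits = fbits)
    if (stage == "b") {
      post <- forward_backward(graph, cond, params, cfg$dynamic_scaling)
      est <- sample_path(post, graph)
    } else if (stage == "p") {
      post <- forward_backward(graph, cond, params, cfg$dynamic_scaling)
      graph <- prune(graph, post, cfg$prune_threshold)
      est <- .expand_phase(graph, .estimate_options(graph, est$hapA))
    } else {
      vit <- viterbi_decode(graph, cond, params)
      ll <- attr(vit, "loglik")
      if (ll > best_ll) {
        best_ll <- ll
        best <- vit
      }
      est <- vit
    }
  }
  if (is.null(best)) est else best
}

#' Stitch phased windows into one estimate
#'
#' Adjacent windows overlap by a margin; the next window's haplotype pair is
#' flipped when that increases heterozygous-phase agreement over the overlap,
#' then the windows are joined at the overlap midpoint.  Deterministic.
#'
#' @param estimates list of `phase_estimate`s.
#' @param ranges list of `c(first, last)` 1-based site ranges per window.
#' @param n_sites total window width.
#' @return A combined `phase_estimate`.
#' @export
stitch_windows <- function(estimates, ranges, n_sites) {
  hapA <- integer(n_sites)
  hapB <- integer(n_sites)
  r1 <- ranges[[1L]]
  hapA[r1[1]:r1[2]] <- estimates[[1L]]$hapA
  hapB[r1[1]:r1[2]] <- estimates[[1L]]$hapB
  filled <- r1[2]
  for (w in seq_along(estimates)[-1L]) {
    r <- ranges[[w]]
    e <- estimates[[w]]
    ov <- r[1]:min(filled, r[2])
    loc <- ov - r[1] + 1L
    het <- ov[hapA[ov] != hapB[ov] & e$hapA[loc] != e$hapB[loc]]
    flip <- FALSE
    if (length(het)) {
      lh <- het - r[1] + 1L
      agree <- sum(hapA[het] == e$hapA[lh])
      flip <- agree < length(het) - agree
    }
    a <- if (flip) e$hapB else e$hapA
    b <- if (flip) e$hapA else e$hapB
    mid <- if (length(ov)) ov[ceiling(length(ov) / 2)] else r[1] - 1L
    take <- (mid + 1L):r[2]
    hapA[take] <- a[take - r[1] + 1L]
    hapB[take] <- b[take - r[1] + 1L]
    filled <- r[2]
  }
  structure(list(hapA = hapA, hapB = hapB, opt = NULL),
            class = "phase_estimate")
}

#' Phase one sample against a reference panel
#'
#' The full MCMC pipeline: the panel is block-compressed and indexed once;
#' fixed-size phasing windows are processed independently (each running the
#' configured schedule of burn-in, pruning and main iterations, with a fresh
#' conditioned reference panel selected through the compressed PBWT in every
#' iteration) and stitched.  Window size is chosen so the expected
#' heterozygous-site count at `min_het_rate` covers
#' `H_seg * window_min_segments` sites.
#'
#' @param genotypes dosage vector in `{0, 1, 2}` over the panel's sites.
#' @param panel a [haplotype_panel].
#' @param config a [phase_config].
#' @param cm optional cumulative genetic-map cM per site.
#' @return A `phase_estimate`.
#' @export
mcmc_run <- function(genotypes, panel, config = phase_config(), cm = NULL) {
  g <- as.integer(genotypes)
  if (length(g) != ncol(panel$alleles))
    stop("target and panel cover different site sets")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- length(g)
  wsz <- ceiling(config$H_seg * config$window_min_segments / config$min_het_rate)
  if (n <= wsz) {
    cp <- compress_panel(panel, config$max_width, config$max_uniques)
    trees <- build_prefix_trees(cp)
    return(.run_window(g, trees, config, cm))
  }
  step <- wsz - config$window_overlap
  starts <- seq(1L, n - config$window_overlap, by = step)
  starts <- starts[starts + config$window_overlap <= n | starts == starts[1]]
  ranges <- lapply(starts, function(s) c(s, min(s + wsz - 1L, n)))
  # drop a final fully-contained window
  keep <- vapply(seq_along(ranges), function(i)
    i == 1L || ranges[[i]][2] > ranges[[i - 1L]][2], TRUE)
  ranges <- ranges[keep]
  ests <- lapply(ranges, function(r) {
    sub <- haplotype_panel(panel$alleles[, r[1]:r[2], drop = FALSE],
                           panel$positions[r[1]:r[2]],
                           panel$site_ids[r[1]:r[2], , drop = FALSE])
    cp <- compress_panel(sub, config$max_width, config$max_uniques)
    trees <- build_prefix_trees(cp)
    .run_window(g[r[1]:r[2]], trees, config,
                if (is.null(cm)) NULL else cm[r[1]:r[2]])
  })
  stitch_windows(ests, ranges, n)
}

#' Phase one or more samples
#'
#' @param targets matrix of dosages (samples in columns) or a single vector.
#' @param panel a [haplotype_panel].
#' @param config a [phase_config].
#' @param cm optional genetic-map cM per site.
#' @return A list of `phase_estimate`s (one per sample), or a single
#'   estimate for a vector input.
#' @export
phase <- function(targets, panel, config = phase_config(), cm = NULL) {
  if (is.null(dim(targets))) return(mcmc_run(targets, panel, config, cm))
  out <- lapply(seq_len(ncol(targets)), function(j)
    mcmc_run(targets[, j], panel, config, cm))
  names(out) <- colnames(targets)
  out
}
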
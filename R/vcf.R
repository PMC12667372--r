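# vcfR drops single-row results to vectors; restore matrix shape
.as_fix_matrix <- function(fix) {
  if (is.null(dim(fix))) matrix(fix, nrow = 1L,
                                dimnames = list(NULL, names(fix))) else fix
}
.as_gt_matrix <- function(gt) {
  if (is.null(dim(gt))) matrix(gt, nrow = 1L,
                               dimnames = list(NULL, names(gt))) else gt
}

#' Read a phased reference panel from VCF
#'
#' All genotypes must be phased (`|` separator), biallelic, and non-missing;
#' violations name the offending site and sample.  Each sample contributes
#' two haplotype rows in file order (first allele, then second).
#'
#' @param path VCF path (plain text or gzipped, v4.x, GT field).
#' @return A [haplotype_panel].
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- .as_gt_matrix(vcfR::extract.gt(v, element = "GT"))
  fix <- .as_fix_matrix(vcfR::getFIX(v))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic site at ", fix[which(multi)[1], "POS"])
  n_sites <- nrow(gt)
  n_samp <- ncol(gt)
  al <- matrix(0L, 2L * n_samp, n_sites)
  for (s in seq_len(n_samp)) {
    g <- gt[, s]
    bad <- which(is.na(g) | !grepl("^[01]\\|[01]$", g))
    if (length(bad))
      stop(sprintf("unphased or missing GT at site %s, sample %s",
                   fix[bad[1], "POS"], colnames(gt)[s]))
    al[2L * s - 1L, ] <- as.integer(substr(g, 1L, 1L))
    al[2L * s, ] <- as.integer(substr(g, 3L, 3L))
  }
  site_ids <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = alt,
                         stringsAsFactors = FALSE)
  haplotype_panel(al, site_ids$pos, site_ids)
}

#' Read unphased target genotypes from VCF
#'
#' Missing genotypes are dropped (with a logged count), and sites are
#' intersected with the panel by exact (chrom, pos, ref, alt) match;
#' non-shared sites are dropped with counts reported.  Allele swaps and
#' strand flips are rejected rather than repaired.
#'
#' @param path VCF path.
#' @param panel a [haplotype_panel] defining the shared site set.
#' @return list with `genotypes` (matrix, samples in columns), `site_index`
#'   (1-based panel columns used), `n_missing_dropped`, `n_unshared_dropped`.
#' @export
read_target_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- .as_gt_matrix(vcfR::extract.gt(v, element = "GT"))
  fix <- .as_fix_matrix(vcfR::getFIX(v))
  if (any(grepl(",", fix[, "ALT"]))) stop("multiallelic site in target VCF")
  key <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"])
  pkey <- paste(panel$site_ids$chrom, panel$site_ids$pos,
                panel$site_ids$ref, panel$site_ids$alt)
  miss <- apply(gt, 1L, function(r) any(is.na(r) | grepl("\\.", r)))
  shared <- key %in% pkey & !miss
  n_unshared <- sum(!(key %in% pkey))
  n_missing <- sum(miss & (key %in% pkey))
  if (!any(shared)) stop("zero shared sites between target and panel")
  message(sprintf("dropped %d missing and %d unshared sites", n_missing,
                  n_unshared))
  gt <- gt[shared, , drop = FALSE]
  dosage <- apply(gt, 2L, function(g) {
    a1 <- as.integer(substr(g, 1L, 1L))
    a2 <- as.integer(substr(g, 3L, 3L))
    a1 + a2
  })
  dosage <- matrix(as.integer(dosage), nrow = sum(shared))
  colnames(dosage) <- colnames(gt)
  list(genotypes = dosage, site_index = match(key[shared], pkey),
       n_missing_dropped = n_missing, n_unshared_dropped = n_unshared)
}

#' Write phased haplotypes as VCF
#'
#' Deterministic byte output given identical inputs: fixed header (no
#' timestamps), GT written with the `|` separator.
#'
#' @param path output path.
#' @param estimates a `phase_estimate` or list of them (samples).
#' @param site_ids data.frame with chrom, pos, ref, alt.
#' @param sample_names optional sample names.
#' @export
write_phased_vcf <- function(path, estimates, site_ids,
                             sample_names = NULL) {
  if (inherits(estimates, "phase_estimate")) estimates <- list(estimates)
  n_samp <- length(estimates)
  if (is.null(sample_names))
    sample_names <- sprintf("SAMPLE%d", seq_len(n_samp))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=obliphase",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names), collapse = "\t"))
  writeLines(hdr, con, sep = "\n")
  n_sites <- nrow(site_ids)
  gts <- vapply(estimates, function(e)
    paste0(e$hapA, "|", e$hapB), character(n_sites))
  gts <- matrix(gts, nrow = n_sites)
  lines <- paste(site_ids$chrom, site_ids$pos, ".", site_ids$ref,
                 site_ids$alt, ".", "PASS", ".", "GT",
                 apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a genetic map and interpolate cM positions
#'
#' The map is a TSV with columns `pos` and `cM` (monotone non-decreasing);
#' site positions are linearly interpolated, extrapolating flat beyond the
#' map ends.  With `path = NULL` a constant-rate fallback of 0.01 cM per
#' interval is returned.
#'
#' @param path TSV path or NULL.
#' @param positions physical site positions.
#' @return Numeric vector of cumulative cM per site.
#' @export
read_genetic_map <- function(path, positions) {
  if (is.null(path)) return(cumsum(rep(0.01, length(positions))))
  map <- read.table(path, header = TRUE)
  if (!all(c("pos", "cM") %in% names(map))) stop("map needs pos and cM columns")
  if (any(diff(map$cM) < 0) || any(diff(map$pos) <= 0))
    stop("genetic map must be monotone")
  approx(map$pos, map$cM, xout = positions, rule = 2)$y
}
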
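#' Construct a haplotype reference panel
#'
#' A haplotype panel is a binary allele matrix (haplotypes in rows, biallelic
#' sites in columns).  Rows are individual haplotypes, not individuals, so an
#' odd number of rows is allowed.
#'
#' @param alleles integer matrix of 0/1 alleles, `n_hap x n_sites`.
#' @param positions 1-based physical positions, strictly increasing; defaults
#'   to `1:n_sites`.
#' @param site_ids optional data.frame with columns chrom, pos, ref, alt.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions = NULL, site_ids = NULL) {
  alleles <- as.matrix(alleles)
  if (length(alleles) == 0L) stop("empty panel")
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1 (biallelic only)")
  storage.mode(alleles) <- "integer"
  n_sites <- ncol(alleles)
  if (is.null(positions)) positions <- seq_len(n_sites)
  if (length(positions) != n_sites) stop("positions length mismatch")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (is.null(site_ids)) {
    site_ids <- data.frame(chrom = "1", pos = positions,
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  structure(list(alleles = alleles, positions = positions, site_ids = site_ids),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$alleles)

# per-site running count of distinct row-prefixes, used by the greedy
# partitioner
.prefix_keys <- function(alleles, keys, j) paste0(keys, alleles[, j])

#' Partition panel sites into compression blocks
#'
#' Greedy tiling of `[0, n_sites)`: each block is grown site by site until
#' adding the next site would exceed `max_width` sites or push the number of
#' distinct haplotype prefixes in the block above `max_uniques`.
#'
#' @param panel a [haplotype_panel].
#' @param max_width maximum block width in sites.
#' @param max_uniques maximum number of unique haplotypes per block.
#' @return A list of `c(start, end)` pairs, 0-based half-open site ranges.
#' @export
partition_blocks <- function(panel, max_width = 32L, max_uniques = 256L) {
  stopifnot(inherits(panel, "haplotype_panel"), max_width >= 1, max_uniques >= 1)
  al <- panel$alleles
  n_sites <- ncol(al)
  if (n_sites == 0L) stop("empty panel")
  blocks <- list()
  start <- 0L
  keys <- rep("", nrow(al))
  for (s in 0:(n_sites - 1L)) {
    cand <- .prefix_keys(al, keys, s + 1L)
    width_new <- s - start + 1L
    over <- (width_new > max_width) || (length(unique(cand)) > max_uniques)
    if (over && s > start) { # close [start, s), begin a fresh block at s
      blocks[[length(blocks) + 1L]] <- c(start, s)
      start <- s
      keys <- as.character(al[, s + 1L])
    } else {
      keys <- cand
    }
  }
  blocks[[length(blocks) + 1L]] <- c(start, n_sites)
  blocks
}

#' Compress one block to its unique haplotypes
#'
#' @param panel a [haplotype_panel].
#' @param start,end 0-based half-open site range.
#' @return A `compressed_block`: unique rows in first-appearance order plus an
#'   index map from each original haplotype to its unique row (1-based).
#' @export
compress_block <- function(panel, start, end) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_sites <- ncol(panel$alleles)
  if (!(start >= 0 && start < end && end <= n_sites)) stop("invalid block range")
  sub <- panel$alleles[, (start + 1L):end, drop = FALSE]
  keys <- apply(sub, 1L, paste0, collapse = "")
  first <- !duplicated(keys)
  uniques <- sub[first, , drop = FALSE]
  index_map <- match(keys, keys[first])
  structure(list(start = as.integer(start), end = as.integer(end),
                 uniques = uniques, index_map = as.integer(index_map)),
            class = "compressed_block")
}

#' Compress a haplotype panel into M3VCF-style blocks
#'
#' The panel is tiled into contiguous blocks ([partition_blocks]) and each
#' block keeps only the unique haplotypes observed within it
#' ([compress_block]).
#'
#' @inheritParams partition_blocks
#' @return A `compressed_panel`.
#' @export
compress_panel <- function(panel, max_width = 32L, max_uniques = 256L) {
  ranges <- partition_blocks(panel, max_width, max_uniques)
  blocks <- lapply(ranges, function(r) compress_block(panel, r[1], r[2]))
  structure(list(blocks = blocks, n_hap = nrow(panel$alleles),
                 n_sites = ncol(panel$alleles), positions = panel$positions,
                 site_ids = panel$site_ids),
            class = "compressed_panel")
}

#' @export
print.compressed_panel <- function(x, ...) {
  nu <- sum(vapply(x$blocks, function(b) nrow(b$uniques), 1L))
  cat(sprintf("<compressed_panel> %d haplotypes x %d sites, %d blocks, %d unique rows total\n",
              x$n_hap, x$n_sites, length(x$blocks), nu))
  invisible(x)
}

#' Reconstruct the original panel from its compressed form
#'
#' @param cp a `compressed_panel`.
#' @return A [haplotype_panel] identical to the panel that was compressed.
#' @export
decompress <- function(cp) {
  stopifnot(inherits(cp, "compressed_panel"))
  if (length(cp$blocks) == 0L) stop("empty block list")
  al <- matrix(0L, cp$n_hap, cp$n_sites)
  for (b in cp$blocks) {
    if (length(b$index_map) != cp$n_hap) stop("inconsistent index_map length")
    al[, (b$start + 1L):b$end] <- b$uniques[b$index_map, , drop = FALSE]
  }
  haplotype_panel(al, cp$positions, cp$site_ids)
}

#' Write a compressed panel in the package's plain-text block format
#'
#' One header line per block (`start end n_unique`, 0-based half-open range),
#' then the unique rows as 0/1 strings, then the index map (1-based) on one
#' line.  The file begins with a line `n_hap n_sites`.
#'
#' @param cp a `compressed_panel`.
#' @param path output file path.
#' @export
write_compressed_panel <- function(cp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", cp$n_hap, cp$n_sites), con)
  for (b in cp$blocks) {
    writeLines(sprintf("%d %d %d", b$start, b$end, nrow(b$uniques)), con)
    writeLines(apply(b$uniques, 1L, paste0, collapse = ""), con)
    writeLines(paste(b$index_map, collapse = " "), con)
  }
  invisible(path)
}

#' Read a compressed panel written by [write_compressed_panel]
#' @param path file path.
#' @return A `compressed_panel`.
#' @export
read_compressed_panel <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1], " ")[[1]])
  n_hap <- hd[1]; n_sites <- hd[2]
  i <- 2L
  blocks <- list()
  while (i <= length(lines)) {
    h <- as.integer(strsplit(lines[i], " ")[[1]])
    start <- h[1]; end <- h[2]; nu <- h[3]
    rows <- lines[(i + 1L):(i + nu)]
    uniques <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
    index_map <- as.integer(strsplit(lines[i + nu + 1L], " ")[[1]])
    blocks[[length(blocks) + 1L]] <-
      structure(list(start = start, end = end, uniques = uniques,
                     index_map = index_map), class = "compressed_block")
    i <- i + nu + 2L
  }
  structure(list(blocks = blocks, n_hap = n_hap, n_sites = n_sites,
                 positions = seq_len(n_sites),
                 site_ids = data.frame(chrom = "1", pos = seq_len(n_sites),
                                       ref = "A", alt = "C",
                                       stringsAsFactors = FALSE)),
            class = "compressed_panel")
}
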
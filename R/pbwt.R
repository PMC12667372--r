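#' Build the PBWT prefix tree of one compressed block
#'
#' Computes, for every column of the block, the positional prefix order of
#' the unique haplotypes (lexicographic by reversed prefix) together with the
#' divergence values (start position of the longest match between adjacent
#' haplotypes in that order).  Runs of zero divergence delimit the prefix-tree
#' nodes: groups of haplotypes sharing the full prefix up to that column.
#' Built from public panel data only, so it is reused across MCMC iterations
#' and target samples.
#'
#' @param block a `compressed_block`.
#' @return A `prefix_tree`.
#' @export
build_prefix_tree <- function(block) {
  stopifnot(inherits(block, "compressed_block"))
  bp <- pbwt_build_cpp(block$uniques)
  counts <- tabulate(block$index_map, nbins = nrow(block$uniques))
  structure(list(ord = bp$ord, div = bp$div, uniques = block$uniques,
                 index_map = block$index_map, counts = counts,
                 start = block$start, end = block$end,
                 n_unique = nrow(block$uniques)),
            class = "prefix_tree")
}

#' Prefix-tree nodes at one column
#'
#' Nodes group unique haplotypes with identical prefixes of length `col`
#' (0-based column within the block); they are maximal runs of zero
#' divergence in positional prefix order.  Child links connect each node to
#' the nodes at the next column obtained by extending the prefix with allele
#' 0 or 1.
#'
#' @param tree a `prefix_tree`.
#' @param col column, `0..width`.
#' @return data.frame with one row per node: first/last rank, member count
#'   (unique rows), original-haplotype count, and (for `col < width`) the ids
#'   of the allele-0 and allele-1 child nodes at column `col + 1` (NA if
#'   absent).
#' @export
tree_nodes <- function(tree, col) {
  stopifnot(inherits(tree, "prefix_tree"), col >= 0, col <= ncol(tree$uniques))
  n <- tree$n_unique
  d <- tree$div[col + 1L, ]
  starts <- which(c(TRUE, d[-1L] > 0L))
  ends <- c(starts[-1L] - 1L, n)
  nodes <- data.frame(node = seq_along(starts), first = starts, last = ends)
  nodes$n_unique <- nodes$last - nodes$first + 1L
  nodes$n_hap <- vapply(seq_len(nrow(nodes)), function(i) {
    ids <- tree$ord[col + 1L, nodes$first[i]:nodes$last[i]] + 1L
    sum(tree$counts[ids])
  }, 1L)
  w <- ncol(tree$uniques)
  if (col < w) {
    nxt <- tree_node_ids <- .node_of_rank(tree, col + 1L)
    child0 <- child1 <- rep(NA_integer_, nrow(nodes))
    ordc <- tree$ord[col + 1L, ] + 1L
    for (i in seq_len(nrow(nodes))) {
      ids <- ordc[nodes$first[i]:nodes$last[i]]
      al <- tree$uniques[ids, col + 1L]
      rank_next <- match(ids, tree$ord[col + 2L, ] + 1L)
      ch <- unique(nxt[rank_next])
      a0 <- unique(nxt[rank_next[al == 0L]])
      a1 <- unique(nxt[rank_next[al == 1L]])
      if (length(a0)) child0[i] <- a0[1L]
      if (length(a1)) child1[i] <- a1[1L]
    }
    nodes$child0 <- child0
    nodes$child1 <- child1
  }
  nodes
}

# node id of each rank position at a column
.node_of_rank <- function(tree, col) {
  d <- tree$div[col + 1L, ]
  cumsum(c(TRUE, d[-1L] > 0L))
}

#' Build prefix trees for all blocks of a compressed panel
#'
#' @param cp a `compressed_panel`.
#' @return A `prefix_tree_set` (also caches the decompressed allele matrix,
#'   which is public panel data).
#' @export
build_prefix_trees <- function(cp) {
  trees <- lapply(cp$blocks, build_prefix_tree)
  structure(list(trees = trees, cp = cp,
                 full = decompress(cp)$alleles,
                 starts = vapply(cp$blocks, function(b) b$start, 1L),
                 ends = vapply(cp$blocks, function(b) b$end, 1L)),
            class = "prefix_tree_set")
}

#' Obliviously insert a phase estimate into the prefix trees
#'
#' The estimated haplotype is split into block regions and inserted into each
#' block's positional prefix order; per column the insertion rank and the
#' divergences to the neighbours above/below are computed through fixed
#' linear scans (trace depends only on the public tree shape).  The
#' block-level LCS of the target against every unique haplotype at the block
#' end is retained for the global-LCS carryover.
#'
#' @param trees a `prefix_tree_set`.
#' @param hap target haplotype over the whole window (0/1 vector, plain or
#'   [secret]).
#' @return An `inserted_target`: one record per block.
#' @export
insert_estimate <- function(trees, hap) {
  stopifnot(inherits(trees, "prefix_tree_set"))
  h <- as.integer(sv(hap))
  if (length(h) != trees$cp$n_sites) stop("hap length must equal window width")
  recs <- lapply(seq_along(trees$trees), function(b) {
    tr <- trees$trees[[b]]
    z <- h[(tr$start + 1L):tr$end]
    r <- pbwt_insert_cpp(tr$uniques, tr$ord, z, as.integer(b))
    list(rank = r$rank, dzu = r$dzu, dzd = r$dzd, end_lcs = r$end_lcs)
  })
  structure(list(blocks = recs, hap = h), class = "inserted_target")
}

#' Nearest-neighbour candidate search at one column
#'
#' Walks outward from the insertion rank over prefix-tree nodes, accumulating
#' group sizes (in original-haplotype counts) until at least `S` candidates
#' are gathered; ties at the smallest included block-level LCS are extended so
#' the candidate set is always a superset of the true top-`S` by block-level
#' LCS.  Node LCS values are reconstructed on the fly from the divergences.
#'
#' @param tree a `prefix_tree`.
#' @param ins the per-block insertion record (element of
#'   `insert_estimate(...)$blocks`).
#' @param col block-local column (0-based; the LCS counts matching sites
#'   ending immediately before this column).
#' @param S number of neighbours sought.
#' @return list with `uniques` (candidate unique-row ids, 1-based), `lcs`
#'   (block-level LCS per candidate), `n_hap` (original haplotypes covered).
#' @export
candidate_search <- function(tree, ins, col, S) {
  stopifnot(inherits(tree, "prefix_tree"), S >= 1)
  n_hap_total <- sum(tree$counts)
  if (S > n_hap_total) stop("S exceeds the panel size")
  n <- tree$n_unique
  lcs_u <- pbwt_lcs_at_col_cpp(tree$ord, tree$div, col,
                               ins$rank[col + 1L], ins$dzu[col + 1L],
                               ins$dzd[col + 1L], 0L)
  # group ranks into nodes and walk outward from the insertion point
  nid <- .node_of_rank(tree, col)
  ordc <- tree$ord[col + 1L, ] + 1L
  node_lcs <- tapply(lcs_u[ordc], nid, function(v) v[1L])
  node_cnt <- tapply(tree$counts[ordc], nid, sum)
  nn <- length(node_lcs)
  r <- ins$rank[col + 1L]
  up <- if (r > 0) nid[r] else 0L          # last node above the insertion
  dn <- if (r < n) nid[r + 1L] else nn + 1L # first node at/below
  take <- logical(nn)
  cnt <- 0L
  repeat {
    lu <- if (up >= 1L) node_lcs[[up]] else -1L
    ld <- if (dn <= nn) node_lcs[[dn]] else -1L
    if (lu < 0L && ld < 0L) break
    min_in <- if (cnt > 0L) min(node_lcs[take]) else Inf
    if (cnt >= S && max(lu, ld) < min_in) break
    if (lu >= ld) {
      take[up] <- TRUE
      cnt <- cnt + node_cnt[[up]]
      up <- up - 1L
    } else {
      take[dn] <- TRUE
      cnt <- cnt + node_cnt[[dn]]
      dn <- dn + 1L
    }
  }
  sel <- which(nid %in% which(take))
  list(uniques = ordc[sel], lcs = lcs_u[ordc[sel]], n_hap = cnt)
}

#' Global LCS of the target at a block start
#'
#' For every original haplotype, the length of its longest common suffix with
#' the target ending at the start of block `block_idx`, computed recursively:
#' a haplotype whose block-level LCS spans a full preceding block carries its
#' running total forward, otherwise the total restarts at the block-level
#' value.
#'
#' @param trees a `prefix_tree_set`.
#' @param ins an `inserted_target`.
#' @param block_idx block index (1-based).
#' @return Integer vector of length `n_hap`.
#' @export
global_lcs_at_block_start <- function(trees, ins, block_idx) {
  n_hap <- trees$cp$n_hap
  g <- integer(n_hap)
  if (block_idx <= 1L) return(g)
  for (b in seq_len(block_idx - 1L)) {
    tr <- trees$trees[[b]]
    w <- tr$end - tr$start
    lcs_h <- ins$blocks[[b]]$end_lcs[tr$index_map]
    g <- ifelse(lcs_h == w, g + w, lcs_h)
  }
  as.integer(g)
}

#' Rank candidates into the S nearest neighbours
#'
#' Candidates are ranked by their total match length with the target ending
#' at the search position: the block-level LCS, extended by the global
#' carryover when the whole block prefix matches.  Ties break toward the
#' smaller haplotype id.  Ranking runs through the oblivious sorting network.
#'
#' @param cands output of [candidate_search].
#' @param global_lcs output of [global_lcs_at_block_start].
#' @param tree the block's `prefix_tree`.
#' @param col block-local column used in the search.
#' @param S neighbours to keep.
#' @return A `neighbor_set`: integer vector of `S` haplotype ids (1-based)
#'   with attribute `lcs` holding their total match lengths.
#' @export
rank_neighbors <- function(cands, global_lcs, tree, col, S) {
  # expand candidate uniques to original haplotype ids
  hap_ids <- which(tree$index_map %in% cands$uniques)
  lcs_blk <- integer(length(hap_ids))
  lcs_map <- setNames(cands$lcs, cands$uniques)
  lcs_blk <- lcs_map[as.character(tree$index_map[hap_ids])]
  total <- ifelse(lcs_blk == col, global_lcs[hap_ids] + col, lcs_blk)
  if (length(hap_ids) < S) stop("fewer candidates than S")
  n_all <- length(global_lcs)
  key <- -(total * (n_all + 1)) + hap_ids # descending total, ascending id
  sorted <- bitonic_sort(seq_along(hap_ids), key = key, label = 1L)
  pick <- sorted[seq_len(S)]
  structure(as.integer(hap_ids[pick]), lcs = as.numeric(total[pick]),
            class = "neighbor_set")
}

#' Choose search positions from the genotype graph
#'
#' One search position per chosen segment, uniformly among the segment's
#' heterozygous sites; when the graph has more segments than `max_positions`,
#' that many segments are sampled without replacement.  Deterministic under a
#' fixed RNG seed.
#'
#' @param graph a `genotype_graph`.
#' @param max_positions cap on the number of positions.
#' @return Sorted integer vector of 1-based site indices.
#' @export
select_search_positions <- function(graph, max_positions = 8L) {
  segs <- Filter(function(s) length(s$het) > 0L, graph$segments)
  if (length(segs) == 0L) return(integer(0))
  if (length(segs) > max_positions) {
    segs <- segs[sort(sample.int(length(segs), max_positions))]
  }
  pos <- vapply(segs, function(s) {
    h <- s$het
    h[sample.int(length(h), 1L)]
  }, 1L)
  sort(as.integer(pos))
}

#' End-to-end neighbour selection for one inserted haplotype
#'
#' For each search position: locate the covering block, reconstruct the
#' block-level LCS of every node at the column from the divergences, extend
#' by the global carryover where the full block prefix matches, and take the
#' top `S` through the oblivious sorting network.  All per-node match lengths
#' are ranked and the winners selected obliviously, so the trace shape is
#' fixed by the (public) panel; the candidate walk of [candidate_search] is
#' the large-panel shortcut and yields the same set.
#'
#' @param trees a `prefix_tree_set`.
#' @param ins an `inserted_target`.
#' @param positions 1-based site indices; the match ends immediately before
#'   each position.
#' @param S neighbours per position.
#' @return List of `neighbor_set`s.
#' @export
select_neighbors <- function(trees, ins, positions, S) {
  n_hap <- trees$cp$n_hap
  if (S > n_hap) stop("S exceeds the panel size")
  lapply(positions, function(p) {
    p0 <- p - 1L # 0-based site index
    b <- findInterval(p0, trees$starts)
    b <- max(1L, min(b, length(trees$trees)))
    tr <- trees$trees[[b]]
    col <- p0 - tr$start
    insb <- ins$blocks[[b]]
    lcs_u <- pbwt_lcs_at_col_cpp(tr$ord, tr$div, col, insb$rank[col + 1L],
                                 insb$dzu[col + 1L], insb$dzd[col + 1L], 1L)
    g <- global_lcs_at_block_start(trees, ins, b)
    lcs_h <- lcs_u[tr$index_map]
    total <- ifelse(lcs_h == col, g + col, lcs_h)
    key <- -(total * (n_hap + 1)) + seq_len(n_hap) # ties to smaller id
    sorted <- bitonic_sort(seq_len(n_hap), key = key, label = 1L)
    pick <- sorted[seq_len(S)]
    structure(as.integer(pick), lcs = as.numeric(total[pick]),
              class = "neighbor_set")
  })
}

#' Build the conditioned reference panel from neighbour sets
#'
#' Membership is an `n_hap` bitmap whose bits are set through linear-scan
#' oblivious writes; the panel is then reduced to the fixed public capacity
#' `K_cap` with the oblivious filter.  When the union is smaller than
#' `K_cap`, the remaining rows are sentinel copies of the first selected
#' haplotype, flagged invalid so the HMM gives them zero weight — the public
#' panel size never reveals the true union cardinality.
#'
#' @param neighbor_sets list of `neighbor_set`s.
#' @param trees a `prefix_tree_set` (provides the allele matrix).
#' @param K_cap public capacity of the conditioned panel.
#' @return A `conditioned_panel`: alleles (`K_cap x n_sites`), `valid` flags,
#'   selected `ids`, and the membership `bitmap`.
#' @export
build_conditioned_panel <- function(neighbor_sets, trees, K_cap) {
  n_hap <- trees$cp$n_hap
  bitmap <- numeric(n_hap)
  for (ns in neighbor_sets) {
    for (id in ns) bitmap <- ob_write_cpp(bitmap, id - 1L, 1, 2L)
  }
  idx <- oblivious_filter_idx_cpp(bitmap, as.integer(K_cap), 2L)
  valid <- as.integer(!is.na(idx))
  first <- idx[1L]
  if (is.na(first)) stop("no haplotypes selected")
  ids <- ifelse(is.na(idx), first, idx)
  structure(list(alleles = trees$full[ids, , drop = FALSE],
                 valid = valid, ids = as.integer(ids), bitmap = bitmap),
            class = "conditioned_panel")
}
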
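# Offset-based coordinate systems on sequence graphs.
#
# A coordinate system is obtained by partitioning the graph into
# non-overlapping linear runs of blocks ("region paths"); a coordinate is a
# (region-path id, offset) pair with the offset counted from the start of
# the region path. Two partitionings are provided:
#
#  * hierarchical: one region path per chromosome main path per layer; each
#    alternative locus is its own region path. Backward compatible by
#    construction: adding a path never changes existing coordinates.
#  * sequential: main paths are additionally divided wherever an alternative
#    path attaches or detaches, giving spatially coherent coordinates at the
#    cost of an explicit update mapping for backward compatibility.
#
# Offsets are 0-based; intervals are half-open [start, end).

#' Create an offset-based position
#'
#' @param region_path Region-path id.
#' @param offset Non-negative 0-based offset from the region-path start.
#' @return An object of class `obg_position`.
#' @examples
#' position("chr14", 150e6)
#' @export
position <- function(region_path, offset) {
  if (!is.character(region_path) || length(region_path) != 1L) {
    obg_stop("region_path must be a string", "obg_coordinate_error")
  }
  if (!is.numeric(offset) || length(offset) != 1L || is.na(offset) || offset < 0) {
    obg_stop("offset must be a non-negative number", "obg_coordinate_error")
  }
  structure(list(region_path = region_path, offset = as.numeric(offset)),
            class = "obg_position")
}

#' @export
print.obg_position <- function(x, ...) {
  cat(format_position(x), "\n")
  invisible(x)
}

#' @export
format.obg_position <- function(x, ...) format_position(x)

#' Format a position as `<name>:<offset>`
#' @param pos An `obg_position`.
#' @param names Optional id -> display-name map (from [assign_names()]).
#' @return Character scalar, e.g. `"chr14:150000000"`.
#' @export
format_position <- function(pos, names = NULL) {
  nm <- if (!is.null(names) && !is.na(names[pos$region_path])) {
    names[[pos$region_path]]
  } else pos$region_path
  paste0(nm, ":", fmt_int(pos$offset))
}

#' Parse a position token
#'
#' Accepts `"<name>:<offset>"` with optional SI-style suffixes on the offset:
#' `k` = 1e3, `m` = 1e6, `g` = 1e9 (so `"chr14:150m"` is offset 150,000,000).
#'
#' @param text Character scalar.
#' @return An `obg_position`.
#' @export
parse_position <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^(.+):([0-9]+(?:\\.[0-9]+)?)([kmgKMG]?)$", text))[[1]]
  if (length(m) == 0L) {
    obg_stop(sprintf("cannot parse position '%s'", text), "obg_parse_error")
  }
  mult <- c(k = 1e3, m = 1e6, g = 1e9)[tolower(m[4])]
  if (is.na(mult)) mult <- 1
  off <- as.numeric(m[3]) * mult
  if (off != round(off)) {
    obg_stop(sprintf("position '%s' is not an integral base offset", text),
             "obg_parse_error")
  }
  position(m[2], off)
}

#' Construct a region-path partition (coordinate system)
#'
#' Low-level constructor; most users build partitions with
#' [hierarchical_partition()] or [sequential_partition()]. Validates the
#' partition property: every block of the graph belongs to exactly one
#' region path and each region path is a directed path in the edge set.
#'
#' @param graph A `sequence_graph`.
#' @param region_paths Named list of block-id vectors.
#' @param kind One of `"hierarchical"`, `"sequential"`, `"custom"`.
#' @return An object of class `region_partition`.
#' @export
region_partition <- function(graph, region_paths, kind = "custom") {
  if (is.null(names(region_paths)) || any(!nzchar(names(region_paths)))) {
    obg_stop("region paths must be named", "obg_partition_error")
  }
  if (anyDuplicated(names(region_paths))) {
    obg_stop("region path names must be unique", "obg_partition_error")
  }
  covered <- unlist(region_paths, use.names = FALSE)
  if (anyDuplicated(covered)) {
    obg_stop(sprintf("blocks in more than one region path: %s",
                     paste(unique(covered[duplicated(covered)]), collapse = ", ")),
             "obg_partition_error")
  }
  missing <- setdiff(block_ids(graph), covered)
  if (length(missing)) {
    obg_stop(sprintf("blocks not covered by any region path: %s",
                     paste(missing, collapse = ", ")), "obg_partition_error")
  }
  if (length(extra <- setdiff(covered, block_ids(graph)))) {
    obg_stop(sprintf("region paths reference unknown blocks: %s",
                     paste(extra, collapse = ", ")), "obg_partition_error")
  }
  for (nm in names(region_paths)) {
    rp <- region_paths[[nm]]
    if (length(rp) > 1L) {
      for (i in seq_len(length(rp) - 1L)) {
        if (!has_edge(graph, rp[i], rp[i + 1L])) {
          obg_stop(sprintf("region path '%s' is not a directed path (%s -> %s)",
                           nm, rp[i], rp[i + 1L]), "obg_partition_error")
        }
      }
    }
  }
  index <- new.env(parent = emptyenv())
  rp_length <- numeric(0)
  for (nm in names(region_paths)) {
    rp <- region_paths[[nm]]
    lens <- vapply(rp, function(id) block_length(graph, id), 0)
    starts <- cumsum(c(0, lens[-length(lens)]))
    for (i in seq_along(rp)) {
      assign(rp[i], list(rp = nm, start = starts[i]), envir = index)
    }
    rp_length[nm] <- sum(lens)
  }
  structure(list(kind = kind, region_paths = region_paths, graph = graph,
                 index = index, rp_length = rp_length),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition kind=%s: %d region path(s) over %d blocks>\n",
              x$kind, length(x$region_paths), length(block_ids(x$graph))))
  invisible(x)
}

# Position -> (block id, intra-block offset). For is_end = TRUE the offset
# may equal a boundary; boundary offsets resolve to the *preceding* block
# with intra == length, except offset 0 which is the first block at 0.
position_to_block <- function(p, pos, is_end = FALSE) {
  rp <- p$region_paths[[pos$region_path]]
  if (is.null(rp)) {
    obg_stop(sprintf("unknown region path '%s'", pos$region_path),
             "obg_coordinate_error")
  }
  total <- p$rp_length[[pos$region_path]]
  off <- pos$offset
  if (is_end) {
    if (off < 0 || off > total) {
      obg_stop(sprintf("offset %s out of range for region path '%s' (length %s)",
                       fmt_int(off), pos$region_path, fmt_int(total)),
               "obg_coordinate_error")
    }
    if (off == 0) return(list(block = rp[1L], intra = 0))
    lens <- vapply(rp, function(id) block_length(p$graph, id), 0)
    cum <- cumsum(lens)
    i <- which(off <= cum)[1L]
    return(list(block = rp[i], intra = unname(off - (cum[i] - lens[i]))))
  }
  if (off < 0 || off >= total) {
    obg_stop(sprintf("offset %s out of range for region path '%s' (length %s)",
                     fmt_int(off), pos$region_path, fmt_int(total)),
             "obg_coordinate_error")
  }
  lens <- vapply(rp, function(id) block_length(p$graph, id), 0)
  cum <- cumsum(lens)
  i <- which(off < cum)[1L]
  list(block = rp[i], intra = unname(off - (cum[i] - lens[i])))
}

# (block id, intra-block offset) -> Position in partition p.
block_to_position <- function(p, block, intra) {
  e <- get0(block, envir = p$index, inherits = FALSE)
  if (is.null(e)) {
    obg_stop(sprintf("block '%s' not covered by partition", block),
             "obg_coordinate_error")
  }
  position(e$rp, e$start + intra)
}

rp_of_block <- function(p, block) {
  e <- get0(block, envir = p$index, inherits = FALSE)
  if (is.null(e)) {
    obg_stop(sprintf("block '%s' not covered by partition", block),
             "obg_coordinate_error")
  }
  e$rp
}

# Infer alternative region paths: weakly-connected components of the
# subgraph induced on non-main blocks must each be a simple directed chain.
infer_alt_paths <- function(g) {
  main_blocks <- unique(unlist(g$main_paths, use.names = FALSE))
  rest <- setdiff(block_ids(g), main_blocks)
  if (!length(rest)) return(stats::setNames(list(), character(0)))
  sub_edges <- g$edges[g$edges[, 1] %in% rest & g$edges[, 2] %in% rest, , drop = FALSE]
  comp <- stats::setNames(seq_along(rest), rest)
  repeat {
    changed <- FALSE
    if (nrow(sub_edges)) {
      for (i in seq_len(nrow(sub_edges))) {
        a <- sub_edges[i, 1]; b <- sub_edges[i, 2]
        m <- min(comp[[a]], comp[[b]])
        if (comp[[a]] != m || comp[[b]] != m) {
          comp[comp == comp[[a]] | comp == comp[[b]]] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  alts <- list()
  for (cid in sort(unique(comp))) {
    members <- names(comp)[comp == cid]
    ce <- sub_edges[sub_edges[, 1] %in% members, , drop = FALSE]
    outdeg <- table(factor(ce[, 1], levels = members))
    indeg <- table(factor(ce[, 2], levels = members))
    starts <- members[indeg[members] == 0L]
    if (length(starts) != 1L || any(outdeg > 1L) || any(indeg > 1L)) {
      obg_stop(paste0("cannot infer alternative region paths: non-chain ",
                      "alternative structure; pass alt_paths explicitly"),
               "obg_partition_error")
    }
    chain <- starts
    repeat {
      nxt <- ce[ce[, 1] == chain[length(chain)], 2]
      if (!length(nxt)) break
      chain <- c(chain, nxt)
    }
    if (length(chain) != length(members)) {
      obg_stop("cannot infer alternative region paths: disconnected chain",
               "obg_partition_error")
    }
    alts[[chain[1L]]] <- chain
  }
  alts[order(names(alts))]
}

resolve_alt_paths <- function(g, alt_paths) {
  if (is.null(alt_paths)) {
    alt_paths <- g$meta$alt_region_paths %||% infer_alt_paths(g)
  }
  main_blocks <- unique(unlist(g$main_paths, use.names = FALSE))
  for (nm in names(alt_paths)) {
    if (length(shared <- intersect(alt_paths[[nm]], main_blocks))) {
      obg_stop(sprintf("alternative path '%s' shares blocks with a main path: %s",
                       nm, paste(shared, collapse = ", ")), "obg_partition_error")
    }
  }
  alt_paths
}

#' Hierarchical partitioning
#'
#' One region path per chromosome main path; each alternative locus
#' (recursively, alternative loci of alternative loci) is its own region
#' path. The resulting coordinate system is the one in common use for
#' assemblies with alt loci, and is backward compatible: adding a new path
#' never changes existing coordinates.
#'
#' @param g A `sequence_graph`.
#' @param alt_paths Named list of block-id chains, one per alternative locus
#'   (any layer). When `NULL`, taken from the builder metadata if present,
#'   otherwise inferred — inference only succeeds when the non-main blocks
#'   form simple chains; layered or branching alternatives must be designated
#'   explicitly by the caller.
#' @return A `region_partition` of kind `"hierarchical"`.
#' @export
hierarchical_partition <- function(g, alt_paths = NULL) {
  alt_paths <- resolve_alt_paths(g, alt_paths)
  region_partition(g, c(g$main_paths, alt_paths), kind = "hierarchical")
}

#' Sequential partitioning
#'
#' Like the hierarchical partitioning, but every region path is additionally
#' divided wherever an alternative path starts or stops. Adding one
#' alternative path to a region path therefore yields three new region paths
#' (before, parallel to, and after it); [apply_update()] returns the
#' [update_mapping()] needed to keep old coordinates resolvable.
#'
#' Main-path pieces are named `<parent>-<k>` with `k` increasing along the
#' genome; a region path that is not split keeps its name.
#'
#' @inheritParams hierarchical_partition
#' @return A `region_partition` of kind `"sequential"`.
#' @export
sequential_partition <- function(g, alt_paths = NULL) {
  alt_paths <- resolve_alt_paths(g, alt_paths)
  base <- c(g$main_paths, alt_paths)
  firsts <- vapply(base, `[`, "", 1L)
  lasts <- vapply(base, function(x) x[length(x)], "")
  # block u such that some other region path attaches right after u
  attach_after <- g$edges[g$edges[, 2] %in% firsts, 1]
  # block v such that some other region path detaches right before v
  detach_before <- g$edges[g$edges[, 1] %in% lasts, 2]

  out <- list()
  parents <- character(0)
  offsets <- numeric(0)
  for (nm in names(base)) {
    rp <- base[[nm]]
    n <- length(rp)
    cuts <- logical(max(n - 1L, 0L))   # cut between i and i+1
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        if (rp[i] %in% attach_after || rp[i + 1L] %in% detach_before) {
          # only cuts caused by *other* region paths
          others_attach <- any(g$edges[, 1] == rp[i] &
                                 g$edges[, 2] %in% setdiff(firsts[names(base) != nm], rp))
        others_detach <- any(g$edges[, 2] == rp[i + 1L] &
                               g$edges[, 1] %in% setdiff(lasts[names(base) != nm], rp))
          cuts[i] <- others_attach || others_detach
        }
      }
    }
    if (!any(cuts)) {
      out[[nm]] <- rp
      parents[nm] <- nm
      offsets[nm] <- 0
      next
    }
    piece_id <- cumsum(c(0L, cuts))
    lens <- vapply(rp, function(id) block_length(g, id), 0)
    for (k in unique(piece_id)) {
      blocks_k <- rp[piece_id == k]
      pname <- paste0(nm, "-", k)
      out[[pname]] <- blocks_k
      parents[pname] <- nm
      offsets[pname] <- sum(lens[seq_along(rp) < which(piece_id == k)[1L]])
    }
  }
  p <- region_partition(g, out, kind = "sequential")
  p$parents <- parents
  p$parent_offsets <- offsets
  p
}

#' Assign display names to region paths
#'
#' Naming aims at three (partly conflicting) criteria: vertical spatiality
#' (variants of the same region have related names), horizontal spatiality
#' (nearby region paths have similar names) and monotonicity (names increase
#' along the genome). The default policy keeps chromosome/locus names under
#' the hierarchical partitioning; under the sequential partitioning,
#' main-path pieces are named `<chrom>-<k>` with `k` increasing along the
#' genome and each alternative path is named `<parallel main piece>-alt<j>`.
#'
#' @param p A `region_partition`.
#' @param policy `"default"`, or a function `function(p)` returning a named
#'   character vector (id -> display name).
#' @return Named character vector mapping region-path ids to display names.
#' @export
assign_names <- function(p, policy = "default") {
  if (is.function(policy)) {
    nms <- policy(p)
    if (anyDuplicated(nms)) {
      obg_stop("naming policy produced duplicate names", "obg_naming_error")
    }
    return(nms)
  }
  ids <- names(p$region_paths)
  nms <- stats::setNames(ids, ids)
  if (p$kind != "sequential") return(nms)
  g <- p$graph
  main_blocks <- unique(unlist(g$main_paths, use.names = FALSE))
  is_alt <- vapply(ids, function(nm) !any(p$region_paths[[nm]] %in% main_blocks),
                   TRUE)
  # name alternatives after the main piece they run parallel to
  alt_counter <- list()
  for (nm in ids[is_alt]) {
    rp <- p$region_paths[[nm]]
    pred <- predecessors(g, rp[1L])
    parallel <- NA_character_
    if (length(pred)) {
      before <- rp_of_block(p, pred[1L])
      # the parallel piece is the one following `before` on its parent path
      parent <- p$parents[[before]] %||% before
      sibs <- ids[vapply(ids, function(x) identical(p$parents[[x]] %||% x, parent), TRUE)]
      sibs <- sibs[order(p$parent_offsets[sibs])]
      i <- match(before, sibs)
      if (!is.na(i) && i < length(sibs)) parallel <- sibs[i + 1L]
    }
    if (is.na(parallel)) {
      succ <- successors(g, rp[length(rp)])
      if (length(succ)) {
        after <- rp_of_block(p, succ[1L])
        parent <- p$parents[[after]] %||% after
        sibs <- ids[vapply(ids, function(x) identical(p$parents[[x]] %||% x, parent), TRUE)]
        sibs <- sibs[order(p$parent_offsets[sibs])]
        i <- match(after, sibs)
        if (!is.na(i) && i > 1L) parallel <- sibs[i - 1L]
      }
    }
    if (is.na(parallel)) {
      nms[nm] <- nm
    } else {
      j <- (alt_counter[[parallel]] %||% 0L) + 1L
      alt_counter[[parallel]] <- j
      nms[nm] <- paste0(nms[[parallel]], "-alt", j)
    }
  }
  if (anyDuplicated(nms)) {
    obg_stop("naming policy produced duplicate names", "obg_naming_error")
  }
  nms
}

#' Translate a position between coordinate systems
#'
#' Both partitions must be over the same underlying graph; the returned
#' position identifies the identical base (same block, same intra-block
#' offset), making translation a bijection on base positions.
#'
#' @param pos An `obg_position` valid in `from`.
#' @param from,to `region_partition`s over the same graph.
#' @param is_end Treat `pos` as an exclusive interval end (offset equal to
#'   the region-path length is then permitted).
#' @return An `obg_position` in `to`.
#' @export
translate_position <- function(pos, from, to, is_end = FALSE) {
  if (!setequal(block_ids(from$graph), block_ids(to$graph))) {
    obg_stop("partitions are not over the same underlying graph",
             "obg_coordinate_error")
  }
  loc <- position_to_block(from, pos, is_end = is_end)
  if (is_end && loc$intra == 0 && loc$block == p_first_block(to, loc$block)) {
    # offset-0 end stays an offset-0 end in the target system
    return(block_to_position(to, loc$block, 0))
  }
  block_to_position(to, loc$block, loc$intra)
}

p_first_block <- function(p, block) {
  rp <- rp_of_block(p, block)
  p$region_paths[[rp]][1L]
}
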
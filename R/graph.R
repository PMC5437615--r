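# Core sequence-graph data model: blocks, edges, main paths.
#
# A sequence graph is a directed acyclic graph whose vertices ("blocks") each
# represent a DNA segment of one or more base pairs and whose edges connect
# consecutive segments.  One or more designated main paths (one per
# chromosome) identify the primary assembly walk through the graph.

#' Create a sequence block
#'
#' A block is a named linear DNA segment, the unit of offset-based
#' addressing. Blocks may carry an explicit length without sequence so that
#' coordinate arithmetic works on topology alone; operations that need bases
#' fail loudly if the sequence is absent.
#'
#' @param id Character scalar, unique block identifier.
#' @param length Positive integer length in base pairs. May be omitted when
#'   `sequence` is given.
#' @param sequence Optional DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return An object of class `obg_block`.
#' @examples
#' block("chr1", sequence = "ACGT")
#' block("big", length = 1e6)
#' @export
block <- function(id, length = NULL, sequence = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    obg_stop("block id must be a non-empty string", "obg_validation_error")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (grepl("[^ACGTN]", sequence)) {
      obg_stop(sprintf("block '%s': sequence contains non-ACGTN characters", id),
               "obg_validation_error")
    }
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length) {
      obg_stop(sprintf("block '%s': sequence length %d != declared length %s",
                       id, nchar(sequence), fmt_int(length)),
               "obg_validation_error")
    }
  }
  if (is.null(length) || is.na(length) || length < 1) {
    obg_stop(sprintf("block '%s': length must be a positive integer", id),
             "obg_validation_error")
  }
  structure(list(id = id, length = as.numeric(length), sequence = sequence),
            class = "obg_block")
}

#' @export
print.obg_block <- function(x, ...) {
  cat(sprintf("<block %s len=%s%s>\n", x$id, fmt_int(x$length),
              if (is.null(x$sequence)) "" else " seq"))
  invisible(x)
}

#' Build and validate a sequence graph
#'
#' Assembles blocks, edges and main paths into a validated directed acyclic
#' sequence graph. Validation enforces unique block ids, edge endpoints that
#' name existing blocks, no duplicate edges, acyclicity, and that every main
#' path is a connected directed path in the edge set.
#'
#' @param blocks List of [block()] objects.
#' @param edges List of length-2 character vectors `c(from, to)`, or a
#'   two-column character matrix.
#' @param main_paths List of character vectors of block ids, one per
#'   chromosome. Names are used as chromosome names; unnamed paths are named
#'   after their first block.
#' @param meta Optional list of builder metadata (kept verbatim).
#' @return An object of class `sequence_graph` with elements `blocks`
#'   (named list), `edges` (two-column character matrix), `main_paths`
#'   (named list) and `meta`.
#' @examples
#' g <- build_graph(
#'   list(block("A", 3), block("B", 2), block("C", 4)),
#'   list(c("A", "B"), c("B", "C")),
#'   list(chr1 = c("A", "B", "C"))
#' )
#' @export
build_graph <- function(blocks, edges = list(), main_paths = list(), meta = list()) {
  if (inherits(blocks, "obg_block")) blocks <- list(blocks)
  ids <- vapply(blocks, function(b) b$id, "")
  if (anyDuplicated(ids)) {
    obg_stop(sprintf("duplicate block ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "obg_validation_error")
  }
  names(blocks) <- ids

  if (is.matrix(edges)) {
    em <- edges
  } else if (length(edges) == 0L) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2L) obg_stop("each edge must be a (from, to) pair",
                                    "obg_validation_error")
      as.character(e)
    }))
  }
  colnames(em) <- c("from", "to")
  bad <- setdiff(c(em), ids)
  if (length(bad)) {
    obg_stop(sprintf("edge references unknown block id(s): %s",
                     paste(sort(unique(bad)), collapse = ", ")),
             "obg_reference_error")
  }
  key <- paste(em[, 1], em[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    obg_stop("duplicate edges are not allowed", "obg_validation_error")
  }
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]

  if (length(main_paths) && is.null(names(main_paths))) {
    names(main_paths) <- vapply(main_paths, `[`, "", 1L)
  }
  g <- structure(list(blocks = blocks, edges = em,
                      main_paths = lapply(main_paths, as.character),
                      meta = meta),
                 class = "sequence_graph")

  topo_sort(g)  # errors on cycles
  for (nm in names(g$main_paths)) {
    mp <- g$main_paths[[nm]]
    if (length(bad2 <- setdiff(mp, ids))) {
      obg_stop(sprintf("main path '%s' references unknown block(s): %s",
                       nm, paste(bad2, collapse = ", ")), "obg_reference_error")
    }
    if (length(mp) > 1L) {
      for (i in seq_len(length(mp) - 1L)) {
        if (!has_edge(g, mp[i], mp[i + 1L])) {
          obg_stop(sprintf("main path '%s' is not connected: no edge %s -> %s",
                           nm, mp[i], mp[i + 1L]), "obg_validation_error")
        }
      }
    }
  }
  g
}

#' @export
print.sequence_graph <- function(x, ...) {
  cat(sprintf("<sequence_graph: %d blocks, %d edges, %d main path(s)>\n",
              length(x$blocks), nrow(x$edges), length(x$main_paths)))
  invisible(x)
}

has_edge <- function(g, from, to) {
  any(g$edges[, 1] == from & g$edges[, 2] == to)
}

successors <- function(g, id) {
  sort(g$edges[g$edges[, 1] == id, 2])
}

predecessors <- function(g, id) {
  sort(g$edges[g$edges[, 2] == id, 1])
}

block_length <- function(g, id) g$blocks[[id]]$length

block_ids <- function(g) names(g$blocks)

#' Topological order of a sequence graph
#'
#' Kahn's algorithm with lexicographic tie-breaking, so the order is
#' deterministic. Errors with class `obg_validation_error` if the graph is
#' cyclic.
#' @param g A `sequence_graph`.
#' @return Character vector of block ids in topological order.
#' @export
topo_sort <- function(g) {
  ids <- sort(block_ids(g))
  indeg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(g$edges)) {
    tab <- table(g$edges[, 2])
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    for (s in successors(g, v)) {
      indeg[[s]] <- indeg[[s]] - 1L
      if (indeg[[s]] == 0L) avail <- sort(c(avail, s))
    }
  }
  if (length(out) != length(ids)) {
    obg_stop("graph contains a cycle", "obg_validation_error")
  }
  out
}

# Set of block ids from which `target` is reachable (including target).
reachable_to <- function(g, target) {
  seen <- target
  frontier <- target
  while (length(frontier)) {
    preds <- unique(g$edges[g$edges[, 2] %in% frontier, 1])
    frontier <- setdiff(preds, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Enumerate directed paths between two blocks
#'
#' Depth-first enumeration of every directed block path from `start` to
#' `end`, in lexicographic order by block id. Exceeding `max_paths` raises an
#' error of class `obg_overflow_error` rather than silently truncating.
#'
#' @param g A `sequence_graph`.
#' @param start,end Block ids.
#' @param max_paths Maximum number of paths to return.
#' @return List of character vectors (block-id paths). Empty if `end` is not
#'   reachable from `start`.
#' @export
enumerate_paths <- function(g, start, end, max_paths = 1000L) {
  for (id in c(start, end)) {
    if (is.null(g$blocks[[id]])) {
      obg_stop(sprintf("unknown block id '%s'", id), "obg_reference_error")
    }
  }
  can_reach <- reachable_to(g, end)
  if (!(start %in% can_reach)) return(list())
  acc <- new.env(parent = emptyenv())
  acc$paths <- vector("list", 0L)
  walk <- function(prefix, v) {
    if (v == end) {
      if (length(acc$paths) >= max_paths) {
        obg_stop(sprintf("more than max_paths = %d paths from %s to %s",
                         max_paths, start, end), "obg_overflow_error")
      }
      acc$paths[[length(acc$paths) + 1L]] <- c(prefix, v)
      return(invisible())
    }
    for (s in intersect(successors(g, v), can_reach)) {
      walk(c(prefix, v), s)
    }
  }
  walk(character(0), start)
  acc$paths
}

#' Spell the sequence along a block path
#'
#' Concatenates block sequences along `path`, slicing the first block from
#' `start_offset` and the last block up to `end_offset` (0-based, half-open).
#' All blocks on the path must carry sequence.
#'
#' @param g A `sequence_graph`.
#' @param path Character vector of block ids forming a directed path.
#' @param start_offset Offset into the first block (default 0).
#' @param end_offset Offset into the last block (default: its full length).
#' @return A DNA string.
#' @export
path_sequence <- function(g, path, start_offset = 0, end_offset = NULL) {
  if (length(path) == 0L) return("")
  for (id in path) {
    b <- g$blocks[[id]]
    if (is.null(b)) obg_stop(sprintf("unknown block id '%s'", id), "obg_reference_error")
    if (is.null(b$sequence)) {
      obg_stop(sprintf("block '%s' carries no sequence", id), "obg_sequence_error")
    }
  }
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      if (!has_edge(g, path[i], path[i + 1L])) {
        obg_stop(sprintf("not a path: no edge %s -> %s", path[i], path[i + 1L]),
                 "obg_path_error")
      }
    }
  }
  last <- path[length(path)]
  if (is.null(end_offset)) end_offset <- block_length(g, last)
  if (start_offset < 0 || start_offset > block_length(g, path[1L])) {
    obg_stop("start_offset out of range", "obg_coordinate_error")
  }
  if (end_offset < 0 || end_offset > block_length(g, last)) {
    obg_stop("end_offset out of range", "obg_coordinate_error")
  }
  seqs <- unname(vapply(path, function(id) g$blocks[[id]]$sequence, ""))
  if (length(path) == 1L) {
    if (end_offset < start_offset) obg_stop("end_offset < start_offset on single block",
                                            "obg_coordinate_error")
    return(substr(seqs[1L], start_offset + 1L, end_offset))
  }
  seqs[1L] <- substr(seqs[1L], start_offset + 1L, nchar(seqs[1L]))
  seqs[length(seqs)] <- substr(seqs[length(seqs)], 1L, end_offset)
  paste(seqs, collapse = "")
}

#' Total base-pair length along a block path with endpoint offsets
#' @noRd
path_span_length <- function(g, path, start_offset, end_offset) {
  lens <- vapply(path, function(id) block_length(g, id), 0)
  if (length(path) == 1L) return(unname(end_offset - start_offset))
  unname(sum(lens) - start_offset - (lens[length(lens)] - end_offset))
}
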
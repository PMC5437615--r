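# Backward-compatible graph updates.
#
# Adding an alternative path under the hierarchical partitioning leaves all
# existing coordinates valid verbatim. Under the sequential partitioning the
# affected region path is replaced by up to three new region paths (before,
# parallel to, and after the new alternative); an update mapping records
# which region path each new piece comes from so that old coordinates can be
# resolved on the new system.

#' Create an update mapping
#'
#' @param records Named list; for each new region-path id, a
#'   `list(parent = <old id>, offset = <start of the new path within the old
#'   one>)`.
#' @return An object of class `update_mapping`.
#' @export
update_mapping <- function(records = list()) {
  for (r in records) {
    if (is.null(r$parent) || is.null(r$offset) || r$offset < 0) {
      obg_stop("update mapping records need a parent and a non-negative offset",
               "obg_validation_error")
    }
  }
  # images of new paths within one old path must be disjoint and ordered;
  # with start offsets only, require strictly increasing offsets per parent
  if (length(records)) {
    parents <- vapply(records, function(r) r$parent, "")
    offs <- vapply(records, function(r) r$offset, 0)
    for (pp in unique(parents)) {
      o <- offs[parents == pp]
      if (anyDuplicated(o)) {
        obg_stop(sprintf("overlapping images within old region path '%s'", pp),
                 "obg_validation_error")
      }
    }
  }
  structure(list(records = records), class = "update_mapping")
}

#' @export
print.update_mapping <- function(x, ...) {
  cat(sprintf("<update_mapping: %d record(s)>\n", length(x$records)))
  for (nm in names(x$records)) {
    r <- x$records[[nm]]
    cat(sprintf("  %s <- (%s, %s)\n", nm, r$parent, fmt_int(r$offset)))
  }
  invisible(x)
}

# Split block `id` of graph g at intra-block offset `at` (0 < at < length)
# into `<id>.1` / `<id>.2`, rewiring edges, main paths and builder metadata.
split_block <- function(g, id, at) {
  b <- g$blocks[[id]]
  if (is.null(b)) obg_stop(sprintf("unknown block '%s'", id), "obg_reference_error")
  if (at <= 0 || at >= b$length) {
    obg_stop("split offset must be strictly inside the block", "obg_coordinate_error")
  }
  id1 <- paste0(id, ".1")
  id2 <- paste0(id, ".2")
  if (!is.null(g$blocks[[id1]]) || !is.null(g$blocks[[id2]])) {
    obg_stop(sprintf("split would collide with existing block ids %s/%s", id1, id2),
             "obg_validation_error")
  }
  s1 <- if (is.null(b$sequence)) NULL else substr(b$sequence, 1, at)
  s2 <- if (is.null(b$sequence)) NULL else substr(b$sequence, at + 1, b$length)
  blocks <- g$blocks[setdiff(names(g$blocks), id)]
  blocks[[id1]] <- block(id1, at, s1)
  blocks[[id2]] <- block(id2, b$length - at, s2)

  em <- g$edges
  em[em[, 1] == id, 1] <- id2
  em[em[, 2] == id, 2] <- id1
  em <- rbind(em, c(id1, id2))

  replace_in <- function(path) {
    i <- match(id, path)
    if (is.na(i)) return(path)
    append(path[-i], c(id1, id2), after = i - 1L)
  }
  main_paths <- lapply(g$main_paths, replace_in)
  meta <- g$meta
  for (f in c("source_paths", "alt_region_paths")) {
    if (!is.null(meta[[f]])) meta[[f]] <- lapply(meta[[f]], replace_in)
  }
  build_graph(unname(blocks), em, main_paths, meta = meta)
}

# Locate the block boundary at absolute offset `at` within region path
# blocks `rp` of graph g, splitting a block if `at` falls inside one.
# Returns list(graph, rp) with rp updated for any split.
ensure_boundary <- function(g, rp, at) {
  lens <- vapply(rp, function(id) block_length(g, id), 0)
  cum <- cumsum(lens)
  total <- sum(lens)
  if (at < 0 || at > total) {
    obg_stop("attachment offset out of range", "obg_coordinate_error")
  }
  if (at == 0 || at == total || at %in% cum) return(list(graph = g, rp = rp))
  i <- which(at < cum)[1L]
  intra <- at - (cum[i] - lens[i])
  g2 <- split_block(g, rp[i], intra)
  rp2 <- append(rp[-i], paste0(rp[i], c(".1", ".2")), after = i - 1L)
  list(graph = g2, rp = rp2)
}

#' Add an alternative path to a partitioned graph
#'
#' Attaches a new chain of blocks in parallel to the span `[attach, detach)`
#' of one existing region path, then re-derives the partition. Under the
#' hierarchical kind all existing region paths keep their ids and offsets
#' and the mapping is empty; under the sequential kind the affected region
#' path is replaced by up to three pieces and the returned
#' [update_mapping()] records each piece's parent and start offset.
#'
#' Attachment offsets falling inside a block cause the block to be split
#' first; region-path ids and offsets are unaffected by block splits.
#'
#' @param p A `region_partition` (hierarchical or sequential).
#' @param new_alt A list with elements `name` (region-path id for the new
#'   alternative), `blocks` (list of [block()]s, ids not yet in the graph),
#'   `attach` and `detach` ([position()]s on the same existing region path,
#'   `attach$offset <= detach$offset`).
#' @return A list with elements `partition` (the new `region_partition`),
#'   `mapping` (an `update_mapping`) and `graph` (the updated graph).
#' @export
apply_update <- function(p, new_alt) {
  stopifnot(inherits(p, "region_partition"))
  for (f in c("name", "blocks", "attach", "detach")) {
    if (is.null(new_alt[[f]])) {
      obg_stop(sprintf("new_alt is missing '%s'", f), "obg_validation_error")
    }
  }
  R <- new_alt$attach$region_path
  if (!identical(R, new_alt$detach$region_path)) {
    obg_stop("attach and detach must lie on the same region path",
             "obg_validation_error")
  }
  rp <- p$region_paths[[R]]
  if (is.null(rp)) obg_stop(sprintf("unknown region path '%s'", R),
                            "obg_coordinate_error")
  a <- new_alt$attach$offset
  b <- new_alt$detach$offset
  total <- p$rp_length[[R]]
  if (a < 0 || b > total || a > b) {
    obg_stop("attachment offsets out of range", "obg_coordinate_error")
  }
  g <- p$graph
  newids <- vapply(new_alt$blocks, function(x) x$id, "")
  if (length(clash <- intersect(newids, block_ids(g)))) {
    obg_stop(sprintf("new block ids already exist: %s", paste(clash, collapse = ", ")),
             "obg_validation_error")
  }
  if (!is.null(g$blocks[[new_alt$name]]) || new_alt$name %in% names(p$region_paths)) {
    obg_stop(sprintf("region path name '%s' already in use", new_alt$name),
             "obg_validation_error")
  }

  res <- ensure_boundary(g, rp, a)
  res <- ensure_boundary(res$graph, res$rp, b)
  g <- res$graph
  rp <- res$rp

  lens <- vapply(rp, function(id) block_length(g, id), 0)
  cum <- cumsum(lens)
  blocks <- c(unname(g$blocks), new_alt$blocks)
  em <- g$edges
  chain <- newids
  if (length(chain) > 1L) {
    em <- rbind(em, cbind(chain[-length(chain)], chain[-1L]))
  }
  if (a > 0) {
    up <- rp[which(cum == a)[1L]]
    em <- rbind(em, c(up, chain[1L]))
  } else {
    for (pr in predecessors(g, rp[1L])) em <- rbind(em, c(pr, chain[1L]))
  }
  if (b < total) {
    down <- rp[which(cum - lens == b)[1L]]
    em <- rbind(em, c(chain[length(chain)], down))
  } else {
    for (su in successors(g, rp[length(rp)])) em <- rbind(em, c(chain[length(chain)], su))
  }
  meta <- g$meta
  meta$alt_region_paths <- c(meta$alt_region_paths %||% list(),
                             stats::setNames(list(chain), new_alt$name))
  g2 <- build_graph(blocks, em, g$main_paths, meta = meta)

  # rebuild region paths, carrying over any block splits
  expand_id <- function(id) {
    if (!is.null(g2$blocks[[id]])) return(id)
    if (is.null(g2$blocks[[paste0(id, ".1")]]) &&
        is.null(g2$blocks[[paste0(id, ".1.1")]])) {
      obg_stop(sprintf("block '%s' vanished during update", id), "obg_validation_error")
    }
    # a block may have been split repeatedly; expand recursively
    c(expand_id(paste0(id, ".1")), expand_id(paste0(id, ".2")))
  }
  carry <- function(old_rp_name) {
    unlist(lapply(p$region_paths[[old_rp_name]], expand_id), use.names = FALSE)
  }
  if (p$kind == "hierarchical" || p$kind == "custom") {
    rps <- lapply(stats::setNames(names(p$region_paths), names(p$region_paths)), carry)
    rps[[new_alt$name]] <- chain
    p2 <- region_partition(g2, rps, kind = p$kind)
    p2$parents <- p$parents
    p2$parent_offsets <- p$parent_offsets
    return(list(partition = p2, mapping = update_mapping(), graph = g2))
  }

  # sequential: replace R by pieces [0,a), [a,b), [b,total)
  rps <- lapply(stats::setNames(setdiff(names(p$region_paths), R),
                                setdiff(names(p$region_paths), R)), carry)
  rpR <- carry(R)
  lensR <- vapply(rpR, function(id) block_length(g2, id), 0)
  cumR <- cumsum(c(0, lensR))
  piece_bounds <- unique(c(0, a, b, total))
  records <- list()
  k <- 0L
  piece_names <- character(0)
  for (i in seq_len(length(piece_bounds) - 1L)) {
    lo <- piece_bounds[i]; hi <- piece_bounds[i + 1L]
    sel <- rpR[cumR[-length(cumR)] >= lo & cumR[-1L] <= hi]
    pname <- paste0(R, "-", k)
    while (pname %in% c(names(rps), new_alt$name)) {
      k <- k + 1L
      pname <- paste0(R, "-", k)
    }
    rps[[pname]] <- sel
    records[[pname]] <- list(parent = R, offset = lo)
    piece_names <- c(piece_names, pname)
    k <- k + 1L
  }
  rps[[new_alt$name]] <- chain
  p2 <- region_partition(g2, rps, kind = "sequential")
  p2$parents <- c(p$parents[setdiff(names(p$parents), R)],
                  stats::setNames(rep(p$parents[[R]] %||% R, length(piece_names)),
                                  piece_names),
                  stats::setNames(new_alt$name, new_alt$name))
  off0 <- p$parent_offsets[[R]] %||% 0
  p2$parent_offsets <- c(p$parent_offsets[setdiff(names(p$parent_offsets), R)],
                         stats::setNames(off0 + vapply(records, function(r) r$offset, 0),
                                         piece_names),
                         stats::setNames(0, new_alt$name))
  list(partition = p2, mapping = update_mapping(records), graph = g2)
}

#' Resolve a legacy coordinate through a chain of updates
#'
#' Maps a position expressed in an old coordinate system through an ordered
#' chain of [update_mapping()]s (oldest first) to the current system. The
#' result addresses the same underlying base as the input did before the
#' updates.
#'
#' @param pos An `obg_position` valid in the oldest system.
#' @param chain List of `update_mapping`s, ordered oldest to newest.
#' @param p Optional current `region_partition`; when given, the resolved
#'   region path is checked to exist in it.
#' @return An `obg_position` in the newest system.
#' @export
resolve_legacy <- function(pos, chain, p = NULL) {
  cur <- pos
  for (m in chain) {
    stopifnot(inherits(m, "update_mapping"))
    recs <- m$records
    parents <- vapply(recs, function(r) r$parent, "")
    hit <- names(recs)[parents == cur$region_path]
    if (!length(hit)) next
    offs <- vapply(recs[hit], function(r) r$offset, 0)
    ord <- order(offs)
    hit <- hit[ord]; offs <- offs[ord]
    i <- findInterval(cur$offset, offs)
    if (i == 0L) {
      obg_stop(sprintf("offset %s precedes every piece of '%s'",
                       fmt_int(cur$offset), cur$region_path), "obg_coordinate_error")
    }
    cur <- position(hit[i], cur$offset - offs[i])
  }
  if (!is.null(p) && is.null(p$region_paths[[cur$region_path]])) {
    obg_stop(sprintf("region path '%s' unknown after resolving chain",
                     cur$region_path), "obg_coordinate_error")
  }
  cur
}
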
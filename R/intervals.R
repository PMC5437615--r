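# Single-path intervals.
#
# A single-path interval is a start and an end coordinate plus the ordered
# list of region paths the interval traverses, which resolves all path
# ambiguity on the graph. Internally the full form is stored: the
# region-path identifier appears every time the identifier changes along the
# walk. Two text styles exist:
#   minimal: inner region paths are printed only where the walk is ambiguous
#            (at a divergence with more than one viable successor);
#   full:    every identifier change is printed.
# Offsets are 0-based and the end is exclusive; an end written `F:0` is
# legal — it contributes zero bases of F while F still terminates the list.

new_interval <- function(p, block_path, start_intra, end_intra) {
  rp_full <- unname(rle(vapply(block_path, function(b) rp_of_block(p, b), ""))$values)
  start <- block_to_position(p, block_path[1L], start_intra)
  endb <- block_path[length(block_path)]
  end <- block_to_position(p, endb, end_intra)
  structure(list(start = start, end = end, region_paths = rp_full,
                 block_path = unname(block_path),
                 start_intra = start_intra, end_intra = end_intra,
                 partition = p),
            class = "single_path_interval")
}

#' @export
print.single_path_interval <- function(x, ...) {
  cat(format_interval(x, "full"), "\n")
  invisible(x)
}

# candidate block paths consistent with (start, via, end)
candidate_paths <- function(p, start, end, via, max_paths = 10000L) {
  sloc <- position_to_block(p, start, is_end = FALSE)
  eloc <- position_to_block(p, end, is_end = TRUE)
  paths <- enumerate_paths(p$graph, sloc$block, eloc$block, max_paths = max_paths)
  keep <- list()
  for (bp in paths) {
    if (length(bp) == 1L && eloc$intra < sloc$intra) next
    rp_full <- rle(vapply(bp, function(b) rp_of_block(p, b), ""))$values
    if (rp_full[1L] != start$region_path) next
    if (rp_full[length(rp_full)] != end$region_path) next
    inner <- if (length(rp_full) > 2L) rp_full[2L:(length(rp_full) - 1L)] else character(0)
    if (!is_subsequence(via, inner)) next
    keep[[length(keep) + 1L]] <- list(block_path = bp, rp_full = rp_full,
                                      sloc = sloc, eloc = eloc)
  }
  keep
}

#' Construct a single-path interval
#'
#' Resolves the unique block-level path consistent with the start and end
#' coordinates and the `via` region paths, and stores the full region-path
#' form. If `via` underdetermines the path an ambiguity error listing the
#' candidates is raised; if no consistent path exists, a path error.
#'
#' @param start,end [position()]s; the end offset is exclusive (an end at
#'   offset 0 of a region path contributes zero bases of it).
#' @param via Ordered character vector of region-path ids the interval
#'   passes through (may be empty; inner ids in either minimal or full form).
#' @param p A `region_partition`.
#' @param max_paths Path-enumeration bound.
#' @return A `single_path_interval`.
#' @export
make_interval <- function(start, end, via = character(0), p, max_paths = 10000L) {
  stopifnot(inherits(p, "region_partition"))
  cand <- candidate_paths(p, start, end, as.character(via), max_paths)
  if (length(cand) == 0L) {
    obg_stop(sprintf("no path consistent with (%s via [%s] %s)",
                     format_position(start), paste(via, collapse = " "),
                     format_position(end)), "obg_path_error")
  }
  if (length(cand) > 1L) {
    # full-form input: an exact inner match outranks subsequence matches
    # (a full list is also a subsequence of longer walks)
    exact <- Filter(function(cc) {
      inner <- if (length(cc$rp_full) > 2L) {
        cc$rp_full[2L:(length(cc$rp_full) - 1L)]
      } else character(0)
      identical(unname(inner), unname(as.character(via)))
    }, cand)
    if (length(exact) == 1L) cand <- exact
  }
  if (length(cand) > 1L) {
    forms <- vapply(cand, function(cc) paste(cc$rp_full, collapse = " "), "")
    obg_stop(sprintf("ambiguous interval; candidates: %s",
                     paste(forms, collapse = "; ")), "obg_ambiguity_error")
  }
  cc <- cand[[1L]]
  new_interval(p, cc$block_path, cc$sloc$intra, cc$eloc$intra)
}

# inner region-path ids to print under the minimal style: a run is emitted
# iff at its entry point the previous block has more than one successor from
# which the interval's end block remains reachable.
minimal_inner <- function(i) {
  p <- i$partition
  g <- p$graph
  bp <- i$block_path
  rpb <- vapply(bp, function(b) rp_of_block(p, b), "")
  runs <- rle(rpb)
  if (length(runs$values) <= 2L) return(character(0))
  ends <- cumsum(runs$lengths)
  can_reach <- reachable_to(g, bp[length(bp)])
  out <- character(0)
  for (k in 2L:(length(runs$values) - 1L)) {
    u <- bp[ends[k - 1L]]                     # last block of previous run
    viable <- intersect(successors(g, u), can_reach)
    if (length(viable) > 1L) out <- c(out, runs$values[k])
  }
  out
}

#' Format a single-path interval
#'
#' @param i A `single_path_interval`.
#' @param style `"minimal"` (inner region paths only where the walk is
#'   ambiguous) or `"full"` (every identifier change).
#' @param names Optional id -> display-name map from [assign_names()].
#' @return Character scalar such as `"(A:1 D C F:0)"`.
#' @export
format_interval <- function(i, style = c("full", "minimal"), names = NULL) {
  style <- match.arg(style)
  disp <- function(id) {
    if (!is.null(names) && !is.na(names[id])) names[[id]] else id
  }
  full_inner <- if (length(i$region_paths) > 2L) {
    i$region_paths[2L:(length(i$region_paths) - 1L)]
  } else character(0)
  inner <- if (style == "full") full_inner else minimal_inner(i)
  if (style == "minimal" && !identical(inner, full_inner)) {
    # region-path names alone may fail to disambiguate (e.g. an edge that
    # skips blocks within one region path); fall back to the full form then
    ok <- tryCatch({
      j <- make_interval(i$start, i$end, inner, i$partition)
      identical(j$block_path, i$block_path)
    }, obg_error = function(e) FALSE)
    if (!ok) inner <- full_inner
  }
  toks <- c(format_position(i$start, names),
            vapply(inner, disp, ""),
            format_position(i$end, names))
  paste0("(", paste(toks, collapse = " "), ")")
}

#' Parse a single-path interval from text
#'
#' Accepts both the space-separated and comma-separated dialects, e.g.
#' `"(A:1 D C F:0)"` or `"(chr14:100, IGH-alt1, chr14, SERPIN-alt1,
#' chr14:150m)"`. Minimal-style input is expanded to full form during
#' construction; ambiguous input raises an ambiguity error.
#'
#' @param text Character scalar.
#' @param p A `region_partition`.
#' @param max_paths Path-enumeration bound.
#' @return A `single_path_interval`.
#' @export
parse_interval <- function(text, p, max_paths = 10000L) {
  s <- trimws(text)
  if (!grepl("^\\(.*\\)$", s)) {
    obg_stop(sprintf("malformed interval '%s': missing parentheses", text),
             "obg_parse_error")
  }
  s <- substr(s, 2L, nchar(s) - 1L)
  toks <- strsplit(s, "[,[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2L) {
    obg_stop(sprintf("malformed interval '%s': need start and end", text),
             "obg_parse_error")
  }
  start <- parse_position(toks[1L])
  end <- parse_position(toks[length(toks)])
  via <- if (length(toks) > 2L) toks[2L:(length(toks) - 1L)] else character(0)
  for (nm in c(start$region_path, end$region_path, via)) {
    if (is.null(p$region_paths[[nm]])) {
      obg_stop(sprintf("unknown region path '%s' in interval '%s'", nm, text),
               "obg_parse_error")
    }
  }
  make_interval(start, end, via, p, max_paths = max_paths)
}

#' Length of a single-path interval in base pairs
#'
#' Sum of traversed block lengths minus the start offset into the first
#' block and the unused tail of the last block (half-open semantics).
#'
#' @param i A `single_path_interval`.
#' @return Non-negative number of base pairs.
#' @export
interval_length <- function(i) {
  path_span_length(i$partition$graph, i$block_path, i$start_intra, i$end_intra)
}

#' Spell the DNA sequence covered by an interval
#'
#' @param i A `single_path_interval` on a sequence-bearing graph.
#' @return DNA string of length [interval_length()].
#' @export
interval_sequence <- function(i) {
  path_sequence(i$partition$graph, i$block_path, i$start_intra, i$end_intra)
}

#' Translate an interval between coordinate systems
#'
#' The underlying block path and base span are preserved; endpoints are
#' re-expressed and the region-path list rewritten under the target
#' partition.
#'
#' @param i A `single_path_interval`.
#' @param to A `region_partition` over the same graph.
#' @return A `single_path_interval` in `to`.
#' @export
translate_interval <- function(i, to) {
  if (!setequal(block_ids(i$partition$graph), block_ids(to$graph))) {
    obg_stop("partitions are not over the same underlying graph",
             "obg_coordinate_error")
  }
  new_interval(to, i$block_path, i$start_intra, i$end_intra)
}

#' Export an interval as a BED3 line
#'
#' Only intervals lying within a single region path have a linear BED
#' representation; multi-region-path intervals are refused with an explicit
#' error.
#'
#' @param i A `single_path_interval`.
#' @param names Optional id -> display-name map.
#' @return Character scalar `"chrom\tstart\tend"`.
#' @export
interval_to_bed <- function(i, names = NULL) {
  if (length(i$region_paths) != 1L) {
    obg_stop("interval spans multiple region paths and cannot be expressed in linear BED",
             "obg_format_error")
  }
  nm <- i$start$region_path
  if (!is.null(names) && !is.na(names[nm])) nm <- names[[nm]]
  paste(nm, fmt_int(i$start$offset), fmt_int(i$end$offset), sep = "\t")
}

# structural equality of intervals (same block path and endpoint offsets)
interval_identical <- function(a, b) {
  identical(a$block_path, b$block_path) &&
    a$start_intra == b$start_intra && a$end_intra == b$end_intra
}
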
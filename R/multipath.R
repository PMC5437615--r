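# Multipath intervals: representations denoting a *set* of single-path
# intervals between two coordinates.
#
# Two forms are provided:
#  * critical subpaths: all start->end paths that traverse every critical
#    subpath (contiguously). An empty critical set is the implicit form —
#    all paths between the endpoints.
#  * fuzzy path: a central single-path interval plus an edit-distance
#    threshold; denotes all paths whose spelled sequence deviates from the
#    central one by strictly less than the threshold. The distance is either
#    the global edit distance over the full spelled sequences, or the
#    maximum of local edit distances over maximal diverging segments
#    (anchored by the region paths shared with the central path).

#' Unit-cost edit (Levenshtein) distance
#'
#' @param a,b Character scalars.
#' @return Non-negative integer; zero iff the strings are equal.
#' @examples
#' edit_distance("ACGT", "AGT")
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b)[1, 1])
}

#' Critical-subpaths multipath interval
#'
#' @param start,end [position()]s shared by every denoted path.
#' @param critical List of character vectors; each is an ordered region-path
#'   id list that every denoted path must traverse contiguously. An empty
#'   list denotes all paths between the endpoints.
#' @return An object of class `critical_interval`.
#' @export
critical_interval <- function(start, end, critical = list()) {
  stopifnot(inherits(start, "obg_position"), inherits(end, "obg_position"))
  critical <- lapply(critical, as.character)
  structure(list(start = start, end = end, critical = critical),
            class = c("critical_interval", "multipath_interval"))
}

#' Fuzzy-path multipath interval
#'
#' @param central A `single_path_interval` on a sequence-bearing graph.
#' @param threshold Positive integer; member paths deviate from the central
#'   path by strictly less than this many edit operations.
#' @param mode `"global"` (edit distance over the full spelled sequences) or
#'   `"max_local"` (maximum over maximal diverging segments).
#' @return An object of class `fuzzy_interval`.
#' @export
fuzzy_interval <- function(central, threshold, mode = c("global", "max_local")) {
  stopifnot(inherits(central, "single_path_interval"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold < 1) {
    obg_stop("threshold must be a positive integer", "obg_validation_error")
  }
  structure(list(central = central, start = central$start, end = central$end,
                 threshold = as.integer(threshold), mode = mode),
            class = c("fuzzy_interval", "multipath_interval"))
}

#' @export
print.multipath_interval <- function(x, ...) {
  cat(format_multipath(x), "\n")
  invisible(x)
}

#' Format a multipath interval
#'
#' Text dialect of this package (the field defines none): critical form
#' `"(A:0 E:0 critical=C|B,D)"` ('|'-separated subpaths, ','-joined ids);
#' fuzzy form `"(A:0 E:0 fuzzy=<central inner ids> t=2 mode=global)"`.
#'
#' @param m A multipath interval.
#' @return Character scalar.
#' @export
format_multipath <- function(m) {
  a <- format_position(m$start)
  b <- format_position(m$end)
  if (inherits(m, "critical_interval")) {
    spec <- paste(vapply(m$critical, paste, "", collapse = ","), collapse = "|")
    sprintf("(%s %s critical=%s)", a, b, spec)
  } else {
    k <- length(m$central$region_paths)
    inner <- if (k > 2L) paste(m$central$region_paths[2L:(k - 1L)], collapse = ",") else ""
    sprintf("(%s %s fuzzy=%s t=%d mode=%s)", a, b, inner, m$threshold, m$mode)
  }
}

#' Parse a multipath interval
#'
#' Inverse of [format_multipath()].
#'
#' @param text Character scalar.
#' @param p A `region_partition` (needed to reconstruct a fuzzy central
#'   path).
#' @return A multipath interval.
#' @export
parse_multipath <- function(text, p) {
  s <- trimws(text)
  if (!grepl("^\\(.*\\)$", s)) {
    obg_stop(sprintf("malformed multipath interval '%s'", text), "obg_parse_error")
  }
  s <- substr(s, 2L, nchar(s) - 1L)
  toks <- strsplit(s, "[[:space:]]+")[[1]]
  if (length(toks) < 3L) {
    obg_stop(sprintf("malformed multipath interval '%s'", text), "obg_parse_error")
  }
  start <- parse_position(toks[1L])
  end <- parse_position(toks[2L])
  kv <- toks[-(1:2)]
  get_kv <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  crit <- get_kv("critical")
  if (!is.null(crit)) {
    critical <- if (nzchar(crit)) {
      lapply(strsplit(crit, "|", fixed = TRUE)[[1]],
             function(x) strsplit(x, ",", fixed = TRUE)[[1]])
    } else list()
    return(critical_interval(start, end, critical))
  }
  fz <- get_kv("fuzzy")
  if (is.null(fz)) {
    obg_stop(sprintf("multipath interval '%s' has neither critical= nor fuzzy=", text),
             "obg_parse_error")
  }
  via <- if (nzchar(fz)) strsplit(fz, ",", fixed = TRUE)[[1]] else character(0)
  central <- make_interval(start, end, via, p)
  fuzzy_interval(central, as.integer(get_kv("t") %||% 1L),
                 get_kv("mode") %||% "global")
}

# --- membership -------------------------------------------------------------

# distance between candidate interval i and central interval under
# max-local mode: the blocks shared between the two paths anchor maximal
# diverging segments (both paths share start and end blocks, so diverging
# segments are interior and consist of whole blocks); each candidate
# segment is compared against the central segment it replaces and the
# maximum edit distance is taken.
max_local_distance <- function(i, central) {
  g <- i$partition$graph
  bp_a <- i$block_path
  bp_c <- central$block_path
  anchors <- lcs_pairs(bp_a, bp_c)
  if (nrow(anchors) == 0L || anchors[1, 1] != 1L || anchors[1, 2] != 1L) {
    anchors <- rbind(c(1L, 1L), anchors)
  }
  last <- anchors[nrow(anchors), ]
  if (last[1] != length(bp_a) || last[2] != length(bp_c)) {
    anchors <- rbind(anchors, c(length(bp_a), length(bp_c)))
  }
  spell <- function(bp, x1, x2) {
    if (x1 > x2) "" else path_sequence(g, bp[x1:x2])
  }
  dmax <- 0L
  for (k in seq_len(nrow(anchors) - 1L)) {
    a1 <- anchors[k, 1] + 1L; a2 <- anchors[k + 1L, 1] - 1L
    c1 <- anchors[k, 2] + 1L; c2 <- anchors[k + 1L, 2] - 1L
    if (a1 > a2 && c1 > c2) next
    dmax <- max(dmax, edit_distance(spell(bp_a, a1, a2), spell(bp_c, c1, c2)))
  }
  dmax
}

#' Multipath membership test
#'
#' Decides whether a single-path interval is denoted by a multipath
#' interval. The single-path interval must share the multipath interval's
#' start and end positions (contract error otherwise).
#'
#' Critical form: true iff every critical subpath occurs as a contiguous
#' sublist of the interval's region-path list. Fuzzy form: true iff the
#' distance to the central path is strictly less than the threshold, under
#' the interval's distance mode.
#'
#' @param m A `critical_interval` or `fuzzy_interval`.
#' @param i A `single_path_interval`.
#' @return Logical scalar.
#' @export
contains <- function(m, i) {
  stopifnot(inherits(m, "multipath_interval"),
            inherits(i, "single_path_interval"))
  same_pos <- function(x, y) {
    identical(x$region_path, y$region_path) && x$offset == y$offset
  }
  if (!same_pos(m$start, i$start) || !same_pos(m$end, i$end)) {
    obg_stop("interval does not share the multipath interval's endpoints",
             "obg_contract_error")
  }
  if (inherits(m, "critical_interval")) {
    return(all(vapply(m$critical, is_contiguous_sublist, TRUE,
                      vec = i$region_paths)))
  }
  d <- if (m$mode == "global") {
    edit_distance(interval_sequence(i), interval_sequence(m$central))
  } else {
    max_local_distance(i, m$central)
  }
  d < m$threshold
}

#' Expand a multipath interval into its single-path members
#'
#' Enumerates every start-to-end block path and keeps those denoted by the
#' multipath interval. Intended for desk-scale verification; [contains()] is
#' the scalable membership API. Exceeding `max_paths` raises an
#' `obg_overflow_error`.
#'
#' @param m A multipath interval.
#' @param p A `region_partition` over the graph.
#' @param max_paths Enumeration bound.
#' @return List of `single_path_interval`s, in lexicographic block-path
#'   order.
#' @export
expand_multipath <- function(m, p, max_paths = 1000L) {
  stopifnot(inherits(m, "multipath_interval"), inherits(p, "region_partition"))
  sloc <- position_to_block(p, m$start, is_end = FALSE)
  eloc <- position_to_block(p, m$end, is_end = TRUE)
  paths <- enumerate_paths(p$graph, sloc$block, eloc$block, max_paths = max_paths)
  out <- list()
  for (bp in paths) {
    if (length(bp) == 1L && eloc$intra < sloc$intra) next
    i <- new_interval(p, bp, sloc$intra, eloc$intra)
    # expansion is defined for intervals sharing the endpoints exactly
    if (!identical(i$start$region_path, m$start$region_path) ||
        i$start$offset != m$start$offset ||
        !identical(i$end$region_path, m$end$region_path) ||
        i$end$offset != m$end$offset) next
    if (contains(m, i)) out[[length(out) + 1L]] <- i
  }
  out
}

#' Extensional equality of multipath intervals
#'
#' True iff both denote the same set of single-path intervals. Decided by
#' expansion when the graph is small enough to enumerate; when enumeration
#' overflows `max_paths`, falls back to canonical representation comparison
#' (equal endpoints and equal critical sets / equal central path, threshold
#' and mode) and flags the result with `attr(, "method") = "canonical"`.
#'
#' @param a,b Multipath intervals.
#' @param p A `region_partition`.
#' @param max_paths Enumeration bound before falling back.
#' @return Logical scalar with attribute `method` (`"expansion"` or
#'   `"canonical"`).
#' @export
multipath_equal <- function(a, b, p, max_paths = 1000L) {
  res <- tryCatch({
    ea <- expand_multipath(a, p, max_paths = max_paths)
    eb <- expand_multipath(b, p, max_paths = max_paths)
    key <- function(i) paste(i$block_path, collapse = "\r")
    structure(setequal(vapply(ea, key, ""), vapply(eb, key, "")),
              method = "expansion")
  }, obg_overflow_error = function(e) NULL)
  if (!is.null(res)) return(res)
  same_pos <- function(x, y) {
    identical(x$region_path, y$region_path) && x$offset == y$offset
  }
  eqp <- same_pos(a$start, b$start) && same_pos(a$end, b$end)
  val <- if (!eqp) {
    FALSE
  } else if (inherits(a, "critical_interval") && inherits(b, "critical_interval")) {
    ka <- vapply(a$critical, paste, "", collapse = ",")
    kb <- vapply(b$critical, paste, "", collapse = ",")
    setequal(ka, kb)
  } else if (inherits(a, "fuzzy_interval") && inherits(b, "fuzzy_interval")) {
    identical(a$central$block_path, b$central$block_path) &&
      a$threshold == b$threshold && identical(a$mode, b$mode)
  } else {
    FALSE
  }
  structure(val, method = "canonical")
}
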
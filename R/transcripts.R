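# Transcript projection and alt-locus transcript categorization.
#
# Transcripts annotated on a chromosome or on an alt locus are projected
# onto graph coordinates: each exon becomes a single-path interval (so
# exons spanning region-path borders get multi-entry region-path lists).
# Alt-locus transcripts with a same-id main-path counterpart are then
# classified, on the flank-trimmed graph, into five categories:
#   A: wholly on flank-derived shared blocks, counterpart span identical;
#   B: wholly on the varying region, counterpart within the parallel main
#      segment;
#   C: partly on flanks and partly on the varying region, with a parallel
#      counterpart;
#   D: on shared blocks with a counterpart elsewhere on the main path
#      (disjoint from the alt placement);
#   E: on shared blocks with a counterpart extending outside the placement;
#   none: no counterpart, or no rule fires.
# Rules are evaluated in order A..E; the first match wins.

#' Read a BED12 annotation
#'
#' Headerless 12-column BED: chrom, chromStart, chromEnd, name, score,
#' strand, thickStart, thickEnd, itemRgb, blockCount, blockSizes,
#' blockStarts (0-based half-open; exon blocks relative to chromStart).
#'
#' @param file Path to the BED file.
#' @return A data frame with the twelve standard columns.
#' @export
read_bed12 <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12L) {
    obg_stop("BED12 requires 12 columns", "obg_format_error")
  }
  names(df)[1:12] <- c("chrom", "chromStart", "chromEnd", "name", "score",
                       "strand", "thickStart", "thickEnd", "itemRgb",
                       "blockCount", "blockSizes", "blockStarts")
  df[1:12]
}

#' Read a genePred annotation table
#'
#' Standard genePred columns: name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (0-based half-open, absolute exon
#' coordinates). Converted to the BED12 layout used internally.
#'
#' @param file Path to the genePred TSV (headerless).
#' @return A data frame in BED12 layout.
#' @export
read_genepred <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 10L) {
    obg_stop("genePred requires at least 10 columns", "obg_format_error")
  }
  names(df)[1:10] <- c("name", "chrom", "strand", "txStart", "txEnd",
                       "cdsStart", "cdsEnd", "exonCount", "exonStarts",
                       "exonEnds")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    es <- as.numeric(strsplit(df$exonStarts[i], ",")[[1]])
    ee <- as.numeric(strsplit(df$exonEnds[i], ",")[[1]])
    data.frame(chrom = df$chrom[i], chromStart = df$txStart[i],
               chromEnd = df$txEnd[i], name = df$name[i], score = 0L,
               strand = df$strand[i], thickStart = df$cdsStart[i],
               thickEnd = df$cdsEnd[i], itemRgb = "0",
               blockCount = length(es),
               blockSizes = paste0(paste(fmt_int(ee - es), collapse = ","), ","),
               blockStarts = paste0(paste(fmt_int(es - df$txStart[i]),
                                          collapse = ","), ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# exon (start, stop) matrix in source coordinates for one annotation row
annotation_exons <- function(row) {
  sizes <- as.numeric(strsplit(row$blockSizes, ",")[[1]])
  starts <- as.numeric(strsplit(row$blockStarts, ",")[[1]])
  cbind(start = row$chromStart + starts, stop = row$chromStart + starts + sizes)
}

# project a half-open source-coordinate span onto a single-path interval
# along the source path `sp` (block ids whose lengths tile the source)
project_span <- function(p, sp, s, e) {
  g <- p$graph
  lens <- vapply(sp, function(id) block_length(g, id), 0)
  cum <- cumsum(lens)
  total <- sum(lens)
  if (s < 0 || e > total || s >= e) {
    obg_stop(sprintf("span [%s, %s) outside source of length %s",
                     fmt_int(s), fmt_int(e), fmt_int(total)),
             "obg_coordinate_error")
  }
  i <- which(s < cum)[1L]
  j <- which(e <= cum)[1L]
  new_interval(p, sp[i:j], s - (cum[i] - lens[i]), e - (cum[j] - lens[j]))
}

#' Project a transcript annotation onto graph coordinates
#'
#' Each annotation row names its source sequence (a chromosome or an alt
#' locus) in the `chrom` column; exons are mapped along the source's block
#' path recorded by the graph builder, becoming single-path intervals in
#' partition `p`. Rows with out-of-range coordinates (or unknown sources)
#' are collected as record-level errors and do not stop the remaining rows.
#'
#' @param records BED12-layout data frame ([read_bed12()]/[read_genepred()]).
#' @param p A `region_partition` over a builder-produced graph.
#' @return List of `obg_transcript` objects, with a data frame of per-record
#'   failures in `attr(, "errors")`.
#' @export
project_annotation <- function(records, p) {
  g <- p$graph
  sps <- g$meta$source_paths
  if (is.null(sps)) {
    obg_stop("graph carries no source paths; build it with a graph builder",
             "obg_validation_error")
  }
  out <- list()
  errs <- list()
  for (r in seq_len(nrow(records))) {
    row <- records[r, ]
    res <- tryCatch({
      sp <- sps[[row$chrom]]
      if (is.null(sp)) {
        obg_stop(sprintf("unknown source sequence '%s'", row$chrom),
                 "obg_reference_error")
      }
      ex <- annotation_exons(row)
      if (any(diff(as.vector(t(ex))) < 0)) {
        obg_stop(sprintf("record '%s': exons overlap or are unordered", row$name),
                 "obg_validation_error")
      }
      exons <- lapply(seq_len(nrow(ex)), function(k) {
        project_span(p, sp, ex[k, 1], ex[k, 2])
      })
      span <- project_span(p, sp, row$chromStart, row$chromEnd)
      main_sources <- names(g$main_paths)
      structure(list(transcript_id = row$name, source = row$chrom,
                     source_kind = if (row$chrom %in% main_sources) "main" else "alt",
                     start = row$chromStart, end = row$chromEnd,
                     exons = exons, span = span),
                class = "obg_transcript")
    }, obg_error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(row = r, name = row$name,
                                              message = conditionMessage(res),
                                              stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  errdf <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), name = character(0), message = character(0))
  if (nrow(errdf)) {
    message(sprintf("project_annotation: %d record(s) failed", nrow(errdf)))
  }
  structure(out, errors = errdf)
}

#' @export
print.obg_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s on %s: %d exon(s), span %s>\n", x$transcript_id,
              x$source, length(x$exons), format_interval(x$span, "full")))
  invisible(x)
}

# blocks covered by any exon of a transcript
transcript_blocks <- function(t) {
  unique(unlist(lapply(t$exons, function(i) i$block_path), use.names = FALSE))
}

# chromosome-coordinate span of a transcript whose blocks all lie on the
# main path of `chrom`; NULL otherwise
main_span_of <- function(p, t, chrom) {
  g <- p$graph
  mp <- g$main_paths[[chrom]]
  bp <- t$span$block_path
  if (!all(bp %in% mp)) return(NULL)
  lens <- vapply(mp, function(id) block_length(g, id), 0)
  cum <- cumsum(c(0, lens))
  i <- match(bp[1L], mp)
  j <- match(bp[length(bp)], mp)
  c(cum[i] + t$span$start_intra, cum[j] + t$span$end_intra)
}

#' Categorize one alt-locus transcript
#'
#' Applies the category rules (see the module header above) on a
#' flank-trimmed graph. Always returns a label; `"none"` when the
#' transcript has no same-id main-path counterpart or no rule fires.
#'
#' @param alt_t An alt-locus `obg_transcript`.
#' @param main_ts List of main-path `obg_transcript`s (any ids; filtered to
#'   `alt_t$transcript_id` internally).
#' @param p The `region_partition` the transcripts were projected in, over a
#'   trimmed-mode graph.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"none"`.
#' @export
categorize <- function(alt_t, main_ts, p) {
  g <- p$graph
  if (!identical(g$meta$mode, "trimmed")) {
    obg_stop("categorization requires a trimmed-mode graph", "obg_validation_error")
  }
  am <- g$meta$alts[[alt_t$source]]
  if (is.null(am)) {
    obg_stop(sprintf("'%s' is not an alt locus of this graph", alt_t$source),
             "obg_validation_error")
  }
  mates <- Filter(function(t) identical(t$transcript_id, alt_t$transcript_id) &&
                    identical(t$source, am$chrom), main_ts)
  if (!length(mates)) return("none")

  mp <- g$main_paths[[am$chrom]]
  blocks <- transcript_blocks(alt_t)
  on_shared <- all(blocks %in% mp)
  on_varying <- all(blocks %in% am$varying_blocks)
  mixed <- !on_shared && !on_varying &&
    all(blocks %in% c(mp, am$varying_blocks))
  alt_span <- main_span_of(p, alt_t, am$chrom)   # NULL unless all-shared

  for (mate in mates) {
    ms <- c(mate$start, mate$end)
    placed <- ms[1] >= am$chrom_start && ms[2] <= am$chrom_stop
    parallel_seg <- ms[1] >= am$var_start && ms[2] <= am$var_stop
    disjoint <- ms[2] <= am$chrom_start || ms[1] >= am$chrom_stop
    extends <- !placed && !disjoint
    if (on_shared && !is.null(alt_span) &&
        alt_span[1] == ms[1] && alt_span[2] == ms[2]) return("A")
    if (on_varying && parallel_seg) return("B")
    if (mixed && placed) return("C")
    if (on_shared && disjoint) return("D")
    if (on_shared && extends) return("E")
  }
  "none"
}

#' Categorize all alt-locus transcripts
#'
#' @param alt_ts List of alt-locus `obg_transcript`s.
#' @param main_ts List of main-path `obg_transcript`s.
#' @param p Partition over a trimmed-mode graph.
#' @return Data frame with columns `category` (A, B, C, D, E, none) and
#'   `count`; counts sum to `length(alt_ts)`.
#' @export
categorize_all <- function(alt_ts, main_ts, p) {
  labels <- vapply(alt_ts, categorize, "", main_ts = main_ts, p = p)
  lv <- c("A", "B", "C", "D", "E", "none")
  data.frame(category = lv,
             count = as.integer(table(factor(labels, levels = lv))),
             stringsAsFactors = FALSE)
}

#' Convert a transcript to a multipath interval
#'
#' Critical mode: the transcript's span endpoints become the interval
#' endpoints and each exon's region-path list becomes a critical subpath —
#' the gene is then all paths through its exonic regions. Fuzzy mode: the
#' transcript's own single path is the central path.
#'
#' @param t An `obg_transcript` projected on a merged-mode graph.
#' @param mode `"critical"` or `"fuzzy"`.
#' @param fuzzy_threshold Threshold for fuzzy mode (required there).
#' @param distance_mode `"global"` or `"max_local"` for fuzzy mode.
#' @return A multipath interval.
#' @export
to_multipath <- function(t, mode = c("critical", "fuzzy"), fuzzy_threshold = NULL,
                         distance_mode = "global") {
  mode <- match.arg(mode)
  if (mode == "critical") {
    return(critical_interval(t$span$start, t$span$end,
                             lapply(t$exons, function(i) i$region_paths)))
  }
  if (is.null(fuzzy_threshold)) {
    obg_stop("fuzzy mode requires fuzzy_threshold", "obg_validation_error")
  }
  if (any(vapply(t$span$block_path,
                 function(b) is.null(t$span$partition$graph$blocks[[b]]$sequence),
                 TRUE))) {
    obg_stop("fuzzy mode requires block sequences", "obg_sequence_error")
  }
  fuzzy_interval(t$span, fuzzy_threshold, distance_mode)
}

#' Count alt-locus transcripts sharing a multipath representation
#'
#' Number of alt-locus transcripts for which some same-id main-path
#' transcript has an extensionally equal multipath representation
#' ([multipath_equal()]).
#'
#' @param alt_ts,main_ts Lists of `obg_transcript`s projected on a
#'   merged-mode graph.
#' @param p The projection partition.
#' @param mode `"critical"` or `"fuzzy"`.
#' @param fuzzy_threshold,distance_mode Passed to [to_multipath()] in fuzzy
#'   mode.
#' @param max_paths Expansion bound for [multipath_equal()].
#' @return Integer count.
#' @export
count_multipath_matches <- function(alt_ts, main_ts, p, mode = "critical",
                                    fuzzy_threshold = NULL,
                                    distance_mode = "global",
                                    max_paths = 1000L) {
  n <- 0L
  for (at in alt_ts) {
    mates <- Filter(function(t) identical(t$transcript_id, at$transcript_id),
                    main_ts)
    if (!length(mates)) next
    ma <- tryCatch(to_multipath(at, mode, fuzzy_threshold, distance_mode),
                   obg_error = function(e) NULL)
    if (is.null(ma)) next
    hit <- FALSE
    for (mt in mates) {
      mb <- tryCatch(to_multipath(mt, mode, fuzzy_threshold, distance_mode),
                     obg_error = function(e) NULL)
      if (is.null(mb)) next
      eq <- tryCatch(multipath_equal(ma, mb, p, max_paths = max_paths),
                     obg_contract_error = function(e) FALSE,
                     obg_error = function(e) FALSE)
      if (isTRUE(as.logical(eq))) { hit <- TRUE; break }
    }
    if (hit) n <- n + 1L
  }
  n
}
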
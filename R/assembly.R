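# Graph construction from assembly-style inputs.
#
# Inputs mirror the structure of an assembly report: a placement table
# locating each alternative locus on its chromosome, FASTA sequences, and
# (for the merged graph) alignment records partitioning each alt locus into
# identity and variant segments. Three builders of increasing detail:
#
#  * build_simple_graph:  each alt locus is one block connected in parallel
#    to the chromosome span it is placed on.
#  * build_trimmed_graph: flanking regions (leading/trailing alt-locus
#    sequence identical to the main path) are removed; only the varying
#    region is connected, so flank bases live on shared main blocks.
#  * build_merged_graph:  alignment identity segments become shared blocks;
#    variant segments become SNP/insertion blocks or deletion edges,
#    yielding a bubble graph.

#' Read an alt-locus placement table
#'
#' A minimal 6-column TSV with header
#' `region_name chrom chrom_start chrom_stop alt_name alt_length`
#' (0-based half-open main-path coordinates). Lines starting with `#` are
#' skipped, so assembly reports carrying the needed columns also parse.
#'
#' @param file Path to the TSV.
#' @return A data frame of placements.
#' @export
read_placements <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("region_name", "chrom", "chrom_start", "chrom_stop",
            "alt_name", "alt_length")
  if (!all(need %in% names(df))) {
    obg_stop(sprintf("placement table must have columns: %s",
                     paste(need, collapse = ", ")), "obg_format_error")
  }
  validate_placements(df[need])
}

#' Write an alt-locus placement table
#' @param placements Data frame as returned by [read_placements()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_placements <- function(placements, file) {
  utils::write.table(placements, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

validate_placements <- function(df, chrom_lengths = NULL) {
  if (!nrow(df)) return(df)
  if (any(df$chrom_start < 0 | df$chrom_start >= df$chrom_stop)) {
    obg_stop("placements must satisfy 0 <= chrom_start < chrom_stop",
             "obg_validation_error")
  }
  if (any(df$alt_length < 1)) {
    obg_stop("alt_length must be positive", "obg_validation_error")
  }
  if (anyDuplicated(df$alt_name)) {
    obg_stop("alt names must be unique", "obg_validation_error")
  }
  if (!is.null(chrom_lengths)) {
    for (i in seq_len(nrow(df))) {
      cl <- chrom_lengths[[df$chrom[i]]]
      if (is.null(cl) || is.na(cl)) {
        obg_stop(sprintf("chromosome '%s' not declared", df$chrom[i]),
                 "obg_reference_error")
      }
      if (df$chrom_stop[i] > cl) {
        obg_stop(sprintf("placement of '%s' exceeds chromosome length",
                         df$alt_name[i]), "obg_validation_error")
      }
    }
  }
  # partial overlaps on one chromosome are unsupported; identical spans
  # (several alts sharing one region) are allowed
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$chrom_start, d$chrom_stop), ]
    if (nrow(d) > 1L) {
      for (i in 2:nrow(d)) {
        same <- d$chrom_start[i] == d$chrom_start[i - 1L] &&
          d$chrom_stop[i] == d$chrom_stop[i - 1L]
        if (!same && d$chrom_start[i] < d$chrom_stop[i - 1L]) {
          obg_stop(sprintf("overlapping placements on chromosome '%s'", ch),
                   "obg_validation_error")
        }
      }
    }
  }
  df
}

#' Read an alignment table
#'
#' A 7-column TSV with header
#' `alt_name alt_start alt_stop chrom chrom_start chrom_stop identical`,
#' one row per alignment segment. `identical` marks exact-match segments and
#' accepts `TRUE/FALSE`, `1/0` or `identity/variant`.
#'
#' @param file Path to the TSV.
#' @return A data frame of alignment records with logical `identical`.
#' @export
read_alignments <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("alt_name", "alt_start", "alt_stop", "chrom", "chrom_start",
            "chrom_stop", "identical")
  if (!all(need %in% names(df))) {
    obg_stop(sprintf("alignment table must have columns: %s",
                     paste(need, collapse = ", ")), "obg_format_error")
  }
  df <- df[need]
  df$identical <- df$identical %in% c(TRUE, "TRUE", "1", 1, "identity")
  df
}

#' Write an alignment table
#' @param alignments Data frame as returned by [read_alignments()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_alignments <- function(alignments, file) {
  utils::write.table(alignments, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# split [0, len) at sorted interior boundary offsets; returns a data frame
# of block start/stop (half-open)
segment_spans <- function(len, boundaries) {
  bs <- sort(unique(c(0, boundaries, len)))
  bs <- bs[bs >= 0 & bs <= len]
  data.frame(start = bs[-length(bs)], stop = bs[-1L])
}

main_blocks_for <- function(chrom, spans, sequences = NULL) {
  lapply(seq_len(nrow(spans)), function(i) {
    seqi <- if (!is.null(sequences) && !is.null(sequences[[chrom]])) {
      substr(sequences[[chrom]], spans$start[i] + 1L, spans$stop[i])
    } else NULL
    block(paste0(chrom, "-", i - 1L), spans$stop[i] - spans$start[i], seqi)
  })
}

# id of the main block ending at `at`, NA if at == 0
block_ending_at <- function(spans, ids, at) {
  i <- which(spans$stop == at)
  if (length(i)) ids[i] else NA_character_
}
block_starting_at <- function(spans, ids, at) {
  i <- which(spans$start == at)
  if (length(i)) ids[i] else NA_character_
}

#' Build the simple alt-locus graph
#'
#' Connects each alternative locus, as a single block, in parallel to the
#' chromosome span it is placed on. Chromosomes are split at placement
#' boundaries; an alt placed at the chromosome start (or end) becomes a
#' source (or sink) block.
#'
#' @param placements Placement data frame (see [read_placements()]).
#' @param chrom_lengths Named vector/list of chromosome lengths. May be
#'   omitted when `sequences` covers all chromosomes.
#' @param sequences Optional named character vector of chromosome and
#'   alt-locus sequences; when present, blocks carry sequence.
#' @return A `sequence_graph` with builder metadata (`meta$mode = "simple"`,
#'   `meta$source_paths`, `meta$alt_region_paths`, `meta$placements`).
#' @export
build_simple_graph <- function(placements, chrom_lengths = NULL, sequences = NULL) {
  if (is.null(chrom_lengths)) {
    if (is.null(sequences)) {
      obg_stop("need chrom_lengths or sequences", "obg_validation_error")
    }
    chrom_lengths <- vapply(sequences, nchar, 0)
    chrom_lengths <- chrom_lengths[setdiff(names(chrom_lengths),
                                           placements$alt_name)]
  }
  chroms <- unique(c(placements$chrom, names(chrom_lengths)))
  chroms <- chroms[chroms %in% names(chrom_lengths)]
  if (length(miss <- setdiff(placements$chrom, chroms))) {
    obg_stop(sprintf("chromosome(s) not declared: %s", paste(miss, collapse = ", ")),
             "obg_reference_error")
  }
  placements <- validate_placements(placements, chrom_lengths)

  blocks <- list()
  edges <- list()
  main_paths <- list()
  source_paths <- list()
  alt_region_paths <- list()
  for (ch in chroms) {
    pl <- placements[placements$chrom == ch, , drop = FALSE]
    spans <- segment_spans(chrom_lengths[[ch]],
                           c(pl$chrom_start, pl$chrom_stop))
    mb <- main_blocks_for(ch, spans, sequences)
    ids <- vapply(mb, function(b) b$id, "")
    blocks <- c(blocks, mb)
    if (length(ids) > 1L) {
      edges <- c(edges, lapply(seq_len(length(ids) - 1L),
                               function(i) c(ids[i], ids[i + 1L])))
    }
    main_paths[[ch]] <- ids
    source_paths[[ch]] <- ids
    if (nrow(pl)) {
      for (i in seq_len(nrow(pl))) {
        alt <- pl$alt_name[i]
        aseq <- if (!is.null(sequences)) sequences[[alt]] else NULL
        if (!is.null(aseq) && nchar(aseq) != pl$alt_length[i]) {
          obg_stop(sprintf("alt '%s': sequence length != alt_length", alt),
                   "obg_validation_error")
        }
        blocks <- c(blocks, list(block(alt, pl$alt_length[i], aseq)))
        up <- block_ending_at(spans, ids, pl$chrom_start[i])
        dn <- block_starting_at(spans, ids, pl$chrom_stop[i])
        if (!is.na(up)) edges <- c(edges, list(c(up, alt)))
        if (!is.na(dn)) edges <- c(edges, list(c(alt, dn)))
        source_paths[[alt]] <- alt
        alt_region_paths[[alt]] <- alt
      }
    }
  }
  build_graph(blocks, edges, main_paths,
              meta = list(mode = "simple", source_paths = source_paths,
                          alt_region_paths = alt_region_paths,
                          placements = placements))
}

#' Detect flanking regions by exact match
#'
#' The left flank is the longest common prefix of the parallel main-path
#' segment and the alt-locus sequence; the right flank is the longest common
#' suffix of the two remainders (prefix-first convention, so identical
#' sequences give `(L, 0)`).
#'
#' @param main_segment_seq,alt_seq Non-empty DNA strings.
#' @return Integer vector `c(left = , right = )`.
#' @examples
#' detect_flanks("AAACGTTT", "AAATTTT")  # c(left = 3, right = 3)
#' @export
detect_flanks <- function(main_segment_seq, alt_seq) {
  if (!nzchar(main_segment_seq) || !nzchar(alt_seq)) {
    obg_stop("sequences must be non-empty", "obg_validation_error")
  }
  a <- charToRaw(main_segment_seq)
  b <- charToRaw(alt_seq)
  n <- min(length(a), length(b))
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  left <- if (length(neq)) neq[1L] - 1L else n
  right <- 0L
  if (left < length(a) && left < length(b)) {
    ra <- rev(a[(left + 1L):length(a)])
    rb <- rev(b[(left + 1L):length(b)])
    m <- min(length(ra), length(rb))
    neq2 <- which(ra[seq_len(m)] != rb[seq_len(m)])
    right <- if (length(neq2)) neq2[1L] - 1L else m
  }
  c(left = as.integer(left), right = as.integer(right))
}

#' Build the flank-trimmed graph
#'
#' Removes the flanking regions from each alternative locus and connects
#' only the varying region to the main path, so flank-equivalent bases live
#' on shared main blocks. An alt locus identical to its main segment
#' contributes no block (a message is emitted). The varying-region block
#' keeps the alt-locus name.
#'
#' @param placements Placement data frame.
#' @param sequences Named character vector covering all chromosomes and alt
#'   loci.
#' @return A `sequence_graph` with `meta$mode = "trimmed"`, per-alt flank
#'   metadata in `meta$alts`, and source paths (including the flank blocks)
#'   in `meta$source_paths`.
#' @export
build_trimmed_graph <- function(placements, sequences) {
  chrom_lengths <- vapply(sequences, nchar, 0)
  placements <- validate_placements(placements, chrom_lengths)
  if (length(miss <- setdiff(c(placements$chrom, placements$alt_name),
                             names(sequences)))) {
    obg_stop(sprintf("missing sequences: %s", paste(miss, collapse = ", ")),
             "obg_sequence_error")
  }
  chroms <- intersect(names(sequences), unique(placements$chrom))
  chroms <- unique(c(chroms, setdiff(names(sequences), placements$alt_name)))

  alts_meta <- list()
  flank_rows <- list()
  cuts <- list()   # per chromosome: varying-span boundaries
  for (i in seq_len(nrow(placements))) {
    pl <- placements[i, ]
    mainseg <- substr(sequences[[pl$chrom]], pl$chrom_start + 1L, pl$chrom_stop)
    aseq <- sequences[[pl$alt_name]]
    if (nchar(aseq) != pl$alt_length) {
      obg_stop(sprintf("alt '%s': sequence length != alt_length", pl$alt_name),
               "obg_validation_error")
    }
    fl <- detect_flanks(mainseg, aseq)
    if (fl[["left"]] + fl[["right"]] > pl$alt_length) {
      obg_stop(sprintf("alt '%s': flanks longer than alt sequence", pl$alt_name),
               "obg_validation_error")
    }
    alts_meta[[pl$alt_name]] <- list(
      chrom = pl$chrom, chrom_start = pl$chrom_start, chrom_stop = pl$chrom_stop,
      flank_left = fl[["left"]], flank_right = fl[["right"]],
      var_start = pl$chrom_start + fl[["left"]],
      var_stop = pl$chrom_stop - fl[["right"]],
      alt_length = pl$alt_length)
    flank_rows[[pl$alt_name]] <- data.frame(alt_name = pl$alt_name,
                                            flank_left = fl[["left"]],
                                            flank_right = fl[["right"]])
    # split at the placement borders too, so the alt-locus flank bases map
    # onto whole main blocks
    cuts[[pl$chrom]] <- c(cuts[[pl$chrom]],
                          pl$chrom_start, pl$chrom_stop,
                          pl$chrom_start + fl[["left"]],
                          pl$chrom_stop - fl[["right"]])
  }

  blocks <- list()
  edges <- list()
  main_paths <- list()
  source_paths <- list()
  alt_region_paths <- list()
  span_info <- list()
  for (ch in chroms) {
    spans <- segment_spans(chrom_lengths[[ch]], cuts[[ch]])
    mb <- main_blocks_for(ch, spans, sequences)
    ids <- vapply(mb, function(b) b$id, "")
    blocks <- c(blocks, mb)
    if (length(ids) > 1L) {
      edges <- c(edges, lapply(seq_len(length(ids) - 1L),
                               function(i) c(ids[i], ids[i + 1L])))
    }
    main_paths[[ch]] <- ids
    source_paths[[ch]] <- ids
    span_info[[ch]] <- list(spans = spans, ids = ids)
  }
  for (alt in names(alts_meta)) {
    am <- alts_meta[[alt]]
    si <- span_info[[am$chrom]]
    var_len <- am$alt_length - am$flank_left - am$flank_right
    varseq <- substr(sequences[[alt]], am$flank_left + 1L,
                     am$alt_length - am$flank_right)
    left_main <- si$ids[si$spans$start >= am$chrom_start & si$spans$stop <= am$var_start]
    right_main <- si$ids[si$spans$start >= am$var_stop & si$spans$stop <= am$chrom_stop]
    if (var_len == 0L) {
      message(sprintf("alt '%s' is identical to its main segment; no varying block",
                      alt))
      alts_meta[[alt]]$varying_blocks <- character(0)
      alts_meta[[alt]]$shared_left <- left_main
      alts_meta[[alt]]$shared_right <- right_main
      source_paths[[alt]] <- c(left_main, right_main)
      next
    }
    blocks <- c(blocks, list(block(alt, var_len, varseq)))
    up <- block_ending_at(si$spans, si$ids, am$var_start)
    dn <- block_starting_at(si$spans, si$ids, am$var_stop)
    if (!is.na(up)) edges <- c(edges, list(c(up, alt)))
    if (!is.na(dn)) edges <- c(edges, list(c(alt, dn)))
    alts_meta[[alt]]$varying_blocks <- alt
    alts_meta[[alt]]$shared_left <- left_main
    alts_meta[[alt]]$shared_right <- right_main
    source_paths[[alt]] <- c(left_main, alt, right_main)
    alt_region_paths[[alt]] <- alt
  }
  build_graph(blocks, edges, main_paths,
              meta = list(mode = "trimmed", source_paths = source_paths,
                          alt_region_paths = alt_region_paths,
                          placements = placements,
                          flanks = do.call(rbind, unname(flank_rows)),
                          alts = alts_meta))
}

#' Build the alignment-merged bubble graph
#'
#' Uses alignment records partitioning each alternative locus into identity
#' and variant segments to merge it with the main path: identity segments
#' become shared blocks used by both walks, variant segments become parallel
#' blocks (SNP/substitution: both sides non-empty; insertion: an alt-only
#' block; deletion: an edge skipping main blocks). The result is a DAG with
#' bubbles.
#'
#' @param placements Placement data frame.
#' @param sequences Named character vector covering chromosomes and alt loci.
#' @param alignments Alignment data frame (see [read_alignments()]); segments
#'   of each alt must partition both the alt locus and its placed main span
#'   contiguously, and identity segments must match exactly.
#' @return A `sequence_graph` with `meta$mode = "merged"`.
#' @export
build_merged_graph <- function(placements, sequences, alignments) {
  chrom_lengths <- vapply(sequences, nchar, 0)
  placements <- validate_placements(placements, chrom_lengths)
  if (length(miss <- setdiff(c(placements$chrom, placements$alt_name),
                             names(sequences)))) {
    obg_stop(sprintf("missing sequences: %s", paste(miss, collapse = ", ")),
             "obg_sequence_error")
  }

  seg_by_alt <- list()
  cuts <- list()
  for (i in seq_len(nrow(placements))) {
    pl <- placements[i, ]
    seg <- alignments[alignments$alt_name == pl$alt_name, , drop = FALSE]
    if (!nrow(seg)) {
      obg_stop(sprintf("no alignment records for alt '%s'", pl$alt_name),
               "obg_validation_error")
    }
    seg <- seg[order(seg$alt_start, seg$chrom_start), , drop = FALSE]
    # segments must partition the alt locus and the placed main span
    if (seg$alt_start[1L] != 0 || seg$alt_stop[nrow(seg)] != pl$alt_length ||
        (nrow(seg) > 1L && any(seg$alt_start[-1L] != seg$alt_stop[-nrow(seg)]))) {
      obg_stop(sprintf("alignment segments do not partition alt '%s'", pl$alt_name),
               "obg_validation_error")
    }
    if (seg$chrom_start[1L] != pl$chrom_start ||
        seg$chrom_stop[nrow(seg)] != pl$chrom_stop ||
        (nrow(seg) > 1L && any(seg$chrom_start[-1L] != seg$chrom_stop[-nrow(seg)]))) {
      obg_stop(sprintf("alignment segments do not partition the main span of alt '%s'",
                       pl$alt_name), "obg_validation_error")
    }
    for (j in seq_len(nrow(seg))) {
      if (seg$identical[j]) {
        if (seg$alt_stop[j] - seg$alt_start[j] !=
            seg$chrom_stop[j] - seg$chrom_start[j]) {
          obg_stop(sprintf("identity segment %d of alt '%s' has unequal lengths",
                           j, pl$alt_name), "obg_validation_error")
        }
        ms <- substr(sequences[[pl$chrom]], seg$chrom_start[j] + 1L, seg$chrom_stop[j])
        as_ <- substr(sequences[[pl$alt_name]], seg$alt_start[j] + 1L, seg$alt_stop[j])
        if (ms != as_) {
          obg_stop(sprintf("identity segment %d of alt '%s' does not match the main path",
                           j, pl$alt_name), "obg_validation_error")
        }
      }
    }
    seg_by_alt[[pl$alt_name]] <- seg
    cuts[[pl$chrom]] <- c(cuts[[pl$chrom]], seg$chrom_start, seg$chrom_stop)
  }

  blocks <- list()
  edges <- list()
  main_paths <- list()
  source_paths <- list()
  alt_region_paths <- list()
  span_info <- list()
  for (ch in names(chrom_lengths)) {
    if (!(ch %in% placements$chrom) && ch %in% placements$alt_name) next
    spans <- segment_spans(chrom_lengths[[ch]], cuts[[ch]])
    mb <- main_blocks_for(ch, spans, sequences)
    ids <- vapply(mb, function(b) b$id, "")
    blocks <- c(blocks, mb)
    if (length(ids) > 1L) {
      edges <- c(edges, lapply(seq_len(length(ids) - 1L),
                               function(i) c(ids[i], ids[i + 1L])))
    }
    main_paths[[ch]] <- ids
    source_paths[[ch]] <- ids
    span_info[[ch]] <- list(spans = spans, ids = ids)
  }
  for (alt in names(seg_by_alt)) {
    seg <- seg_by_alt[[alt]]
    ch <- seg$chrom[1L]
    si <- span_info[[ch]]
    walk <- character(0)
    vcount <- 0L
    for (j in seq_len(nrow(seg))) {
      m_lo <- seg$chrom_start[j]; m_hi <- seg$chrom_stop[j]
      a_lo <- seg$alt_start[j]; a_hi <- seg$alt_stop[j]
      covered <- si$ids[si$spans$start >= m_lo & si$spans$stop <= m_hi]
      if (seg$identical[j]) {
        walk <- c(walk, covered)
      } else if (a_hi > a_lo) {
        vcount <- vcount + 1L
        vid <- paste0(alt, "-v", vcount)
        vseq <- substr(sequences[[alt]], a_lo + 1L, a_hi)
        blocks <- c(blocks, list(block(vid, a_hi - a_lo, vseq)))
        up <- block_ending_at(si$spans, si$ids, m_lo)
        dn <- block_starting_at(si$spans, si$ids, m_hi)
        if (!is.na(up)) edges <- c(edges, list(c(up, vid)))
        if (!is.na(dn)) edges <- c(edges, list(c(vid, dn)))
        walk <- c(walk, vid)
        alt_region_paths[[vid]] <- vid
      } else {
        # deletion relative to the main path: an edge skipping main blocks
        up <- block_ending_at(si$spans, si$ids, m_lo)
        dn <- block_starting_at(si$spans, si$ids, m_hi)
        if (!is.na(up) && !is.na(dn)) edges <- c(edges, list(c(up, dn)))
      }
    }
    source_paths[[alt]] <- walk
  }
  edges <- unique(edges)
  build_graph(blocks, edges, main_paths,
              meta = list(mode = "merged", source_paths = source_paths,
                          alt_region_paths = alt_region_paths,
                          placements = placements,
                          alignments = alignments))
}
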
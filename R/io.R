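# Serialization: graph JSON, GFA1 export, FASTA I/O.

#' Serialize a sequence graph to JSON
#'
#' The document layout is
#' `{blocks: [{id, length, sequence?}], edges: [[from, to]], main_paths:
#' {name: [ids]}, meta: {...}}`. Builder metadata (graph mode, alt-locus
#' source paths, placements) round-trips, so graphs written by the builders
#' can be re-loaded and re-partitioned.
#'
#' @param g A `sequence_graph`.
#' @param file Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `file` is given.
#' @export
graph_to_json <- function(g, file = NULL) {
  doc <- list(
    blocks = lapply(unname(g$blocks), function(b) {
      x <- list(id = b$id, length = b$length)
      if (!is.null(b$sequence)) x$sequence <- b$sequence
      x
    }),
    edges = lapply(seq_len(nrow(g$edges)), function(i) as.vector(g$edges[i, ])),
    main_paths = g$main_paths,
    meta = serialize_meta(g$meta)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a sequence graph from JSON
#'
#' Inverse of [graph_to_json()]; the result passes full graph validation.
#'
#' @param file Path to a JSON file (or a JSON string).
#' @return A `sequence_graph`.
#' @export
graph_from_json <- function(file) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  blocks <- lapply(doc$blocks, function(b) {
    block(b$id, length = b$length, sequence = b$sequence)
  })
  edges <- lapply(doc$edges, function(e) c(e[[1]], e[[2]]))
  main_paths <- lapply(doc$main_paths, function(p) unlist(p, use.names = FALSE))
  build_graph(blocks, edges, main_paths, meta = deserialize_meta(doc$meta))
}

serialize_meta <- function(meta) {
  if (is.null(meta) || !length(meta)) return(structure(list(), names = character(0)))
  out <- meta
  for (f in c("placements", "alignments", "flanks")) {
    if (!is.null(out[[f]]) && is.data.frame(out[[f]])) {
      out[[f]] <- lapply(seq_len(nrow(out[[f]])), function(i) as.list(out[[f]][i, ]))
    }
  }
  out
}

deserialize_meta <- function(meta) {
  if (is.null(meta) || !length(meta)) return(list())
  out <- meta
  for (f in c("placements", "alignments", "flanks")) {
    if (!is.null(out[[f]]) && length(out[[f]])) {
      out[[f]] <- do.call(rbind, lapply(out[[f]], function(r) {
        as.data.frame(r, stringsAsFactors = FALSE)
      }))
    } else if (!is.null(out[[f]])) {
      out[[f]] <- NULL
    }
  }
  for (f in c("source_paths", "alt_region_paths")) {
    if (!is.null(out[[f]])) {
      out[[f]] <- lapply(out[[f]], function(p) unlist(p, use.names = FALSE))
    }
  }
  if (!is.null(out$alts)) {
    out$alts <- lapply(out$alts, function(a) {
      a$shared_left <- unlist(a$shared_left, use.names = FALSE) %||% character(0)
      a$shared_right <- unlist(a$shared_right, use.names = FALSE) %||% character(0)
      a$varying_blocks <- unlist(a$varying_blocks, use.names = FALSE) %||% character(0)
      a
    })
  }
  out
}

#' Export a sequence graph to GFA1
#'
#' Writes S-lines (with an `LN` tag, `*` when a block carries no sequence),
#' L-lines with `0M` overlaps, and one P-line per main path.
#'
#' @param g A `sequence_graph`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gfa <- function(g, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (id in sort(block_ids(g))) {
    b <- g$blocks[[id]]
    writeLines(sprintf("S\t%s\t%s\tLN:i:%s", id, b$sequence %||% "*",
                       fmt_int(b$length)), con)
  }
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      writeLines(sprintf("L\t%s\t+\t%s\t+\t0M", g$edges[i, 1], g$edges[i, 2]), con)
    }
  }
  for (nm in names(g$main_paths)) {
    writeLines(sprintf("P\t%s\t%s\t*", nm,
                       paste0(g$main_paths[[nm]], "+", collapse = ",")), con)
  }
  invisible(file)
}

#' Read sequences from a FASTA file
#'
#' @param file Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  ss <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
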
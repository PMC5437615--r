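trimmed_projection <- function(seed) {
  fix <- generate_fixture(seed = seed)
  g <- build_trimmed_graph(fix$placements, fix$sequences)
  p <- hierarchical_partition(g)
  ts <- project_annotation(fix$transcripts, p)
  list(fix = fix, g = g, p = p, ts = ts,
       alt = Filter(function(t) t$source_kind == "alt", ts),
       main = Filter(function(t) t$source_kind == "main", ts))
}

test_that("projection produces exon intervals with conserved lengths", {
  tp <- trimmed_projection(42)
  expect_equal(nrow(attr(tp$ts, "errors")), 0L)
  for (t in tp$ts) {
    row <- tp$fix$transcripts[tp$fix$transcripts$name == t$transcript_id &
                                tp$fix$transcripts$chrom == t$source, ]
    ex <- offsetgraph:::annotation_exons(row[1, ])
    expect_equal(vapply(t$exons, interval_length, 0),
                 unname(ex[, 2] - ex[, 1]))
  }
  # single-exon transcript inside one region path: list of length 1
  simple <- Filter(function(t) length(t$exons) == 1L &&
                     length(t$exons[[1]]$region_paths) == 1L, tp$ts)
  expect_gt(length(simple), 0L)
  # an alt transcript planted across the flank boundary (category C) spans
  # at least two region paths
  cid <- vapply(Filter(function(x) x$category == "C",
                       tp$fix$ground_truth$transcripts), `[[`, "", "transcript_id")
  ct <- Filter(function(t) t$transcript_id %in% cid && t$source_kind == "alt",
               tp$ts)
  expect_true(all(vapply(ct, function(t) {
    any(vapply(t$exons, function(e) length(e$region_paths) >= 2L, TRUE))
  }, TRUE)))
  # empty annotation: empty result
  empty <- project_annotation(tp$fix$transcripts[0, ], tp$p)
  expect_length(empty, 0L)
})

test_that("record-level errors are collected without stopping other rows", {
  tp <- trimmed_projection(5)
  bad <- tp$fix$transcripts
  bad$chromEnd[1] <- 10^9           # beyond the source sequence
  bad$chrom[2] <- "unknown_seq"
  expect_message(res <- project_annotation(bad, tp$p), "2 record")
  expect_equal(nrow(attr(res, "errors")), 2L)
  expect_equal(length(res), nrow(bad) - 2L)
})

test_that("planted categories are recovered exactly", {
  tp <- trimmed_projection(42)
  gtc <- vapply(tp$fix$ground_truth$transcripts, `[[`, "", "category")
  names(gtc) <- vapply(tp$fix$ground_truth$transcripts, `[[`, "", "transcript_id")
  for (t in tp$alt) {
    expect_equal(categorize(t, tp$main, tp$p), unname(gtc[t$transcript_id]),
                 info = t$transcript_id)
  }
  tab <- categorize_all(tp$alt, tp$main, tp$p)
  want <- as.integer(table(factor(gtc, levels = tab$category)))
  expect_equal(tab$count, want)
  expect_equal(sum(tab$count), length(tp$alt))
  # order invariance and empty input
  tab2 <- categorize_all(rev(tp$alt), tp$main, tp$p)
  expect_equal(tab2, tab)
  empty <- categorize_all(list(), tp$main, tp$p)
  expect_equal(sum(empty$count), 0L)
})

test_that("alt transcripts without a counterpart get 'none'", {
  tp <- trimmed_projection(9)
  lone <- Filter(function(t) t$transcript_id == "t009", tp$alt)  # planted none
  expect_equal(length(lone), 1L)
  expect_equal(categorize(lone[[1]], tp$main, tp$p), "none")
  expect_equal(categorize(lone[[1]], list(), tp$p), "none")
})

test_that("categorize requires a trimmed graph", {
  fix <- generate_fixture(seed = 2)
  g <- build_simple_graph(fix$placements, sequences = fix$sequences)
  p <- hierarchical_partition(g)
  ts <- project_annotation(fix$transcripts, p)
  alt <- Filter(function(t) t$source_kind == "alt", ts)
  expect_error(categorize(alt[[1]], ts, p), class = "obg_validation_error")
})

test_that("multipath transcript representations behave as constructed", {
  # merged graph with one SNP bubble; main and alt transcript copies
  chrom <- random_dna_str(100)
  alt <- paste0(substr(chrom, 21, 50),
                offsetgraph:::other_base(substr(chrom, 51, 51)),
                substr(chrom, 52, 80))
  seqs <- c(chr = chrom, a1 = alt)
  pl <- data.frame(region_name = "R", chrom = "chr", chrom_start = 20,
                   chrom_stop = 80, alt_name = "a1", alt_length = 60,
                   stringsAsFactors = FALSE)
  al <- data.frame(alt_name = "a1", alt_start = c(0, 30, 31),
                   alt_stop = c(30, 31, 60), chrom = "chr",
                   chrom_start = c(20, 50, 51), chrom_stop = c(30 + 20, 51, 80),
                   identical = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  g <- build_merged_graph(pl, seqs, al)
  p <- hierarchical_partition(g)

  bed <- function(src, s, e, id, exons) {
    data.frame(chrom = src, chromStart = s, chromEnd = e, name = id, score = 0,
               strand = "+", thickStart = s, thickEnd = e, itemRgb = "0",
               blockCount = length(exons),
               blockSizes = paste0(paste(vapply(exons, function(x) x[2] - x[1], 0),
                                         collapse = ","), ","),
               blockStarts = paste0(paste(vapply(exons, function(x) x[1] - s, 0),
                                          collapse = ","), ","),
               stringsAsFactors = FALSE)
  }

  # exons avoid the bubble at main offset 50 (alt offset 30)
  ann_out <- rbind(bed("chr", 25, 75, "tx1", list(c(25, 40), c(60, 75))),
                   bed("a1", 5, 55, "tx1", list(c(5, 20), c(40, 55))))
  ts_out <- project_annotation(ann_out, p)
  m_out <- to_multipath(ts_out[[1]], "critical")
  a_out <- to_multipath(ts_out[[2]], "critical")
  expect_equal(length(m_out$critical), 2L)
  expect_true(as.logical(multipath_equal(m_out, a_out, p)))

  # exons crossing the bubble: critical differs, fuzzy t=2 matches
  ann_in <- rbind(bed("chr", 25, 75, "tx2", list(c(45, 55))),
                  bed("a1", 5, 55, "tx2", list(c(25, 35))))
  ts_in <- project_annotation(ann_in, p)
  expect_false(as.logical(multipath_equal(to_multipath(ts_in[[1]], "critical"),
                                          to_multipath(ts_in[[2]], "critical"), p)))
  expect_true(as.logical(multipath_equal(
    to_multipath(ts_in[[1]], "fuzzy", 2, "global"),
    to_multipath(ts_in[[2]], "fuzzy", 2, "global"), p)))

  # count_multipath_matches over both pairs
  alt_ts <- Filter(function(t) t$source_kind == "alt", c(ts_out, ts_in))
  main_ts <- Filter(function(t) t$source_kind == "main", c(ts_out, ts_in))
  expect_equal(count_multipath_matches(alt_ts, main_ts, p, "critical"), 1L)
  expect_equal(count_multipath_matches(alt_ts, main_ts, p, "fuzzy",
                                       fuzzy_threshold = 2), 2L)
  # threshold monotonicity of the fuzzy count
  n1 <- count_multipath_matches(alt_ts, main_ts, p, "fuzzy", fuzzy_threshold = 1)
  n2 <- count_multipath_matches(alt_ts, main_ts, p, "fuzzy", fuzzy_threshold = 2)
  expect_lte(n1, n2)
  # disjoint id sets: zero
  expect_equal(count_multipath_matches(alt_ts, list(), p, "critical"), 0L)
  # fuzzy mode requires a threshold
  expect_error(to_multipath(ts_out[[1]], "fuzzy"), class = "obg_validation_error")
})

test_that("genePred reader matches the BED12 reader", {
  td <- withr::local_tempdir()
  gp <- file.path(td, "t.gp")
  writeLines("tx1\tchr\t+\t100\t200\t100\t200\t2\t100,150,\t120,200,", gp)
  df <- read_genepred(gp)
  expect_equal(df$chromStart, 100)
  expect_equal(df$blockSizes, "20,50,")
  expect_equal(df$blockStarts, "0,50,")
})
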
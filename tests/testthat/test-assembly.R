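test_that("build_simple_graph splits chromosomes at placement borders", {
  pl <- data.frame(region_name = "R1", chrom = "chr", chrom_start = 40,
                   chrom_stop = 60, alt_name = "alt1", alt_length = 25,
                   stringsAsFactors = FALSE)
  g <- build_simple_graph(pl, c(chr = 100))
  lens <- vapply(g$blocks, `[[`, 0, "length")
  expect_equal(lens[c("chr-0", "chr-1", "chr-2", "alt1")],
               c(`chr-0` = 40, `chr-1` = 20, `chr-2` = 40, alt1 = 25))
  expect_equal(nrow(g$edges), 4L)   # 2 on the main path + 2 connecting alt1
  expect_equal(g$main_paths$chr, c("chr-0", "chr-1", "chr-2"))
  # conservation
  expect_equal(sum(lens[g$main_paths$chr]), 100)

  # no placements: unchanged linear chromosome
  g0 <- build_simple_graph(pl[0, ], c(chr = 100))
  expect_equal(length(g0$blocks), 1L)
  expect_equal(nrow(g0$edges), 0L)

  # alt at the chromosome start becomes a source block
  pl2 <- transform(pl, chrom_start = 0, chrom_stop = 60)
  g2 <- build_simple_graph(pl2, c(chr = 100))
  expect_equal(nrow(g2$edges[g2$edges[, 2] == "alt1", , drop = FALSE]), 0L)
  expect_true(any(g2$edges[, 1] == "alt1"))

  # partial overlaps are rejected; identical spans are allowed
  pl3 <- rbind(pl, transform(pl, chrom_start = 50, chrom_stop = 80,
                             alt_name = "alt2"))
  expect_error(build_simple_graph(pl3, c(chr = 100)),
               class = "obg_validation_error")
  pl4 <- rbind(pl, transform(pl, alt_name = "alt2"))
  expect_equal(length(build_simple_graph(pl4, c(chr = 100))$blocks), 5L)
})

test_that("detect_flanks follows the prefix-first exact-match rule", {
  expect_equal(detect_flanks("ACGTACGT", "ACGTACGT"), c(left = 8L, right = 0L))
  expect_equal(detect_flanks("AAACGTTT", "AAATTTT"), c(left = 3L, right = 3L))
  expect_equal(detect_flanks("ACGT", "TGCA"), c(left = 0L, right = 0L))
  # brute-force scan oracle on random pairs
  brute <- function(a, b) {
    la <- 0L
    while (la < min(nchar(a), nchar(b)) &&
           substr(a, la + 1L, la + 1L) == substr(b, la + 1L, la + 1L)) la <- la + 1L
    ra <- substr(a, la + 1L, nchar(a)); rb <- substr(b, la + 1L, nchar(b))
    lr <- 0L
    while (lr < min(nchar(ra), nchar(rb)) &&
           substr(ra, nchar(ra) - lr, nchar(ra) - lr) ==
           substr(rb, nchar(rb) - lr, nchar(rb) - lr)) lr <- lr + 1L
    c(left = la, right = lr)
  }
  withr::with_seed(5, {
    for (k in 1:30) {
      a <- random_dna_str(sample(1:12, 1))
      b <- random_dna_str(sample(1:12, 1))
      expect_equal(detect_flanks(a, b), brute(a, b), info = paste(a, b))
      fl <- detect_flanks(a, b)
      expect_lte(fl[["left"]] + fl[["right"]], min(nchar(a), nchar(b)))
    }
  })
})

test_that("build_trimmed_graph conserves alt bases and attaches varying regions", {
  fix <- generate_fixture(seed = 7)
  g <- build_trimmed_graph(fix$placements, fix$sequences)
  expect_equal(g$meta$mode, "trimmed")
  for (alt in names(g$meta$alts)) {
    am <- g$meta$alts[[alt]]
    gt <- fix$ground_truth$alts[[alt]]
    expect_equal(am$flank_left, gt$flank_left)
    expect_equal(am$flank_right, gt$flank_right)
    expect_equal(g$blocks[[alt]]$length,
                 gt$alt_length - gt$flank_left - gt$flank_right)
    # the alt source path spells the full alt sequence
    expect_equal(path_sequence(g, g$meta$source_paths[[alt]]),
                 fix$sequences[[alt]])
  }
  # chromosome conservation
  for (ch in names(g$main_paths)) {
    expect_equal(path_sequence(g, g$main_paths[[ch]]), fix$sequences[[ch]])
  }
  # both partitionings are admitted
  expect_s3_class(hierarchical_partition(g), "region_partition")
  expect_s3_class(sequential_partition(g), "region_partition")
})

test_that("an alt identical to its main segment contributes no block", {
  chrom <- random_dna_str(300)
  seqs <- c(chr = chrom, altx = substr(chrom, 101, 200))
  pl <- data.frame(region_name = "R", chrom = "chr", chrom_start = 100,
                   chrom_stop = 200, alt_name = "altx", alt_length = 100,
                   stringsAsFactors = FALSE)
  expect_message(g <- build_trimmed_graph(pl, seqs), "identical")
  expect_false("altx" %in% names(g$blocks))
  expect_equal(path_sequence(g, g$meta$source_paths[["altx"]]),
               seqs[["altx"]])
})

test_that("build_merged_graph forms bubbles that spell both haplotypes", {
  fix <- generate_fixture(seed = 19)
  g <- build_merged_graph(fix$placements, fix$sequences, fix$alignments)
  expect_equal(g$meta$mode, "merged")
  for (ch in names(g$main_paths)) {
    expect_equal(path_sequence(g, g$main_paths[[ch]]), fix$sequences[[ch]])
  }
  for (alt in unique(fix$placements$alt_name)) {
    expect_equal(path_sequence(g, g$meta$source_paths[[alt]]),
                 fix$sequences[[alt]])
  }
  expect_s3_class(hierarchical_partition(g), "region_partition")
  expect_s3_class(sequential_partition(g), "region_partition")
})

test_that("merged graph single-variant shapes are correct", {
  # one SNP: a four-block bubble
  chrom <- random_dna_str(60)
  alt <- paste0(substr(chrom, 21, 30),
                offsetgraph:::other_base(substr(chrom, 31, 31)),
                substr(chrom, 32, 40))
  seqs <- c(chr = chrom, a1 = alt)
  pl <- data.frame(region_name = "R", chrom = "chr", chrom_start = 20,
                   chrom_stop = 40, alt_name = "a1", alt_length = 20,
                   stringsAsFactors = FALSE)
  al <- data.frame(alt_name = "a1", alt_start = c(0, 10, 11),
                   alt_stop = c(10, 11, 20), chrom = "chr",
                   chrom_start = c(20, 30, 31), chrom_stop = c(30, 31, 40),
                   identical = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  g <- build_merged_graph(pl, seqs, al)
  # both paths across the bubble
  paths <- enumerate_paths(g, "chr-1", "chr-3")
  expect_equal(length(paths), 2L)
  expect_setequal(vapply(paths, function(p) p[2], ""), c("chr-2", "a1-v1"))

  # one deletion: an edge bypassing the deleted main block; 2 paths
  alt2 <- paste0(substr(chrom, 21, 30), substr(chrom, 36, 40))
  seqs2 <- c(chr = chrom, a1 = alt2)
  pl2 <- transform(pl, alt_length = 15)
  al2 <- data.frame(alt_name = "a1", alt_start = c(0, 10, 10),
                    alt_stop = c(10, 10, 15), chrom = "chr",
                    chrom_start = c(20, 30, 35), chrom_stop = c(30, 35, 40),
                    identical = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  g2 <- build_merged_graph(pl2, seqs2, al2)
  paths2 <- enumerate_paths(g2, "chr-1", "chr-3")
  expect_equal(length(paths2), 2L)
  expect_equal(path_sequence(g2, g2$meta$source_paths[["a1"]]), alt2)

  # alt identical everywhere: merged graph is linear
  al3 <- data.frame(alt_name = "a1", alt_start = 0, alt_stop = 20,
                    chrom = "chr", chrom_start = 20, chrom_stop = 40,
                    identical = TRUE, stringsAsFactors = FALSE)
  seqs3 <- c(chr = chrom, a1 = substr(chrom, 21, 40))
  g3 <- build_merged_graph(pl, seqs3, al3)
  expect_equal(length(enumerate_paths(g3, g3$main_paths$chr[1],
                                      g3$main_paths$chr[length(g3$main_paths$chr)])),
               1L)

  # inconsistent alignment coordinates are rejected
  al_bad <- transform(al, alt_stop = c(10, 12, 20))
  expect_error(build_merged_graph(pl, seqs, al_bad),
               class = "obg_validation_error")
  # identity segment that does not match is rejected
  al_bad2 <- transform(al, identical = c(TRUE, TRUE, TRUE))
  expect_error(build_merged_graph(pl, seqs, al_bad2),
               class = "obg_validation_error")
})

test_that("placement and alignment tables round-trip through TSV", {
  fix <- generate_fixture(seed = 3)
  td <- withr::local_tempdir()
  write_placements(fix$placements, file.path(td, "p.tsv"))
  write_alignments(fix$alignments, file.path(td, "a.tsv"))
  p2 <- read_placements(file.path(td, "p.tsv"))
  a2 <- read_alignments(file.path(td, "a.tsv"))
  expect_equal(p2, fix$placements, ignore_attr = TRUE)
  expect_equal(a2, fix$alignments, ignore_attr = TRUE)
  # '#' comment lines are skipped
  writeLines(c("# assembly report style comment",
               readLines(file.path(td, "p.tsv"))), file.path(td, "pc.tsv"))
  expect_equal(nrow(read_placements(file.path(td, "pc.tsv"))), nrow(fix$placements))
})
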
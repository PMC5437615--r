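# Deterministic synthetic fixture generator.
#
# Stands in for assembly-scale downloads: emits a random chromosome, alt
# loci built from its placed segments (exact-match flanks around a varying
# region with planted SNP/insertion/deletion variants), the matching
# placement and alignment tables, a BED12 transcript annotation with
# transcripts planted to known alt-locus categories, and a ground-truth
# record of everything planted.
#
# Default world: one 10 kb chromosome, two alt loci with flanks of
# 100-300 bp, three interior variants per alt (SNP, 5 bp insertion, 4 bp
# deletion, cycling), plus one substituted base pinning each end of the
# varying region, and a planted category composition of
# A=3 B=2 C=1 D=1 E=1 none=2.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

other_base <- function(b) {
  sample(setdiff(c("A", "C", "G", "T"), b), 1L)
}

#' Generate a synthetic assembly fixture
#'
#' @param params List overriding any of: `n_chroms` (1), `chrom_len`
#'   (10000), `n_alts` (2), `flank_range` (`c(100, 300)`), `n_variants` (3
#'   interior variants per alt), `variant_types`
#'   (`c("snp", "ins", "del")`, cycled), `ins_len` (5), `del_len` (4),
#'   `category_counts` (`c(A = 3, B = 2, C = 1, D = 1, E = 1, none = 2)`).
#' @param seed Integer seed; output is byte-identical for equal seeds.
#' @return A list with `sequences` (named character), `placements`,
#'   `alignments`, `transcripts` (BED12 data frame) and `ground_truth`
#'   (planted flanks, variants, transcript categories).
#' @export
generate_fixture <- function(params = list(), seed) {
  d <- list(n_chroms = 1L, chrom_len = 10000L, n_alts = 2L,
            flank_range = c(100L, 300L), n_variants = 3L,
            variant_types = c("snp", "ins", "del"), ins_len = 5L, del_len = 4L,
            category_counts = c(A = 3L, B = 2L, C = 1L, D = 1L, E = 1L,
                                none = 2L))
  d[names(params)] <- params
  if (is.null(names(d$category_counts))) {
    obg_stop("category_counts must be named", "obg_validation_error")
  }
  bad <- setdiff(names(d$category_counts), c("A", "B", "C", "D", "E", "none"))
  if (length(bad)) {
    obg_stop(sprintf("unknown categories: %s", paste(bad, collapse = ", ")),
             "obg_validation_error")
  }
  slot <- floor(d$chrom_len / (d$n_alts + 1L))
  seg_len <- floor(slot * 0.6)
  min_var <- 2L + d$n_variants * (max(d$ins_len, d$del_len) + 20L) + 120L
  if (seg_len < 2L * max(d$flank_range) + min_var) {
    obg_stop("infeasible params: alts do not fit the chromosome with the requested flanks/variants",
             "obg_validation_error")
  }

  with_local_seed(seed, {
    sequences <- character(0)
    placements <- list()
    alignments <- list()
    gt_alts <- list()
    alt_specs <- list()
    for (ci in seq_len(d$n_chroms)) {
      ch <- paste0("chr", ci)
      chseq <- random_dna(d$chrom_len)
      sequences[ch] <- chseq
      for (k in seq_len(d$n_alts)) {
        altnm <- sprintf("%s_alt%d", ch, k)
        cs <- k * slot
        ce <- cs + seg_len
        f_l <- sample(d$flank_range[1]:d$flank_range[2], 1L)
        f_r <- sample(d$flank_range[1]:d$flank_range[2], 1L)
        vs <- cs + f_l   # varying main span [vs, ve)
        ve <- ce - f_r
        # variants in main coordinates: boundary substitutions pin the
        # flanks; interior variants are spaced across the varying span
        vars <- list(list(m_lo = vs, m_hi = vs + 1L, type = "snp",
                          alt_seq = other_base(substr(chseq, vs + 1L, vs + 1L))))
        if (d$n_variants > 0L) {
          gap <- floor((ve - vs - 2L) / (d$n_variants + 1L))
          for (j in seq_len(d$n_variants)) {
            ty <- d$variant_types[(j - 1L) %% length(d$variant_types) + 1L]
            m_lo <- vs + j * gap
            v <- switch(ty,
              snp = list(m_lo = m_lo, m_hi = m_lo + 1L, type = "snp",
                         alt_seq = other_base(substr(chseq, m_lo + 1L, m_lo + 1L))),
              ins = list(m_lo = m_lo, m_hi = m_lo, type = "ins",
                         alt_seq = random_dna(d$ins_len)),
              del = list(m_lo = m_lo, m_hi = m_lo + d$del_len, type = "del",
                         alt_seq = ""))
            vars <- c(vars, list(v))
          }
        }
        vars <- c(vars, list(list(m_lo = ve - 1L, m_hi = ve, type = "snp",
                                  alt_seq = other_base(substr(chseq, ve, ve)))))
        # assemble the alt sequence and alignment segments
        aseq <- substr(chseq, cs + 1L, vs)   # left flank
        segs <- list(list(a_lo = 0L, a_hi = f_l, m_lo = cs, m_hi = vs,
                          identical = TRUE))
        apos <- f_l
        mpos <- vs
        gt_vars <- list()
        for (v in vars) {
          if (v$m_lo > mpos) {
            idseq <- substr(chseq, mpos + 1L, v$m_lo)
            aseq <- paste0(aseq, idseq)
            segs <- c(segs, list(list(a_lo = apos, a_hi = apos + nchar(idseq),
                                      m_lo = mpos, m_hi = v$m_lo,
                                      identical = TRUE)))
            apos <- apos + nchar(idseq)
            mpos <- v$m_lo
          }
          aseq <- paste0(aseq, v$alt_seq)
          segs <- c(segs, list(list(a_lo = apos, a_hi = apos + nchar(v$alt_seq),
                                    m_lo = v$m_lo, m_hi = v$m_hi,
                                    identical = FALSE)))
          gt_vars <- c(gt_vars, list(list(type = v$type, chrom = ch,
                                          m_lo = v$m_lo, m_hi = v$m_hi,
                                          a_lo = apos,
                                          a_hi = apos + nchar(v$alt_seq))))
          apos <- apos + nchar(v$alt_seq)
          mpos <- v$m_hi
        }
        rflank <- substr(chseq, ve + 1L, ce)
        aseq <- paste0(aseq, rflank)
        segs <- c(segs, list(list(a_lo = apos, a_hi = apos + f_r,
                                  m_lo = ve, m_hi = ce, identical = TRUE)))
        alt_len <- nchar(aseq)
        sequences[altnm] <- aseq
        placements[[altnm]] <- data.frame(
          region_name = sprintf("REGION_%d_%d", ci, k), chrom = ch,
          chrom_start = cs, chrom_stop = ce, alt_name = altnm,
          alt_length = alt_len, stringsAsFactors = FALSE)
        alignments[[altnm]] <- do.call(rbind, lapply(segs, function(s) {
          data.frame(alt_name = altnm, alt_start = s$a_lo, alt_stop = s$a_hi,
                     chrom = ch, chrom_start = s$m_lo, chrom_stop = s$m_hi,
                     identical = s$identical, stringsAsFactors = FALSE)
        }))
        gt_alts[[altnm]] <- list(chrom = ch, chrom_start = cs, chrom_stop = ce,
                                 flank_left = f_l, flank_right = f_r,
                                 alt_length = alt_len, variants = gt_vars)
        alt_specs[[altnm]] <- list(chrom = ch, cs = cs, ce = ce, f_l = f_l,
                                   f_r = f_r, alt_len = alt_len,
                                   var_alt_len = alt_len - f_l - f_r)
      }
    }

    # planted transcripts
    rows <- list()
    gt_tx <- list()
    tnum <- 0L
    bed_row <- function(src, exons, id) {
      s <- exons[[1]][1]
      e <- exons[[length(exons)]][2]
      sizes <- vapply(exons, function(x) x[2] - x[1], 0)
      starts <- vapply(exons, function(x) x[1] - s, 0)
      data.frame(chrom = src, chromStart = s, chromEnd = e, name = id,
                 score = 0L, strand = "+", thickStart = s, thickEnd = e,
                 itemRgb = "0", blockCount = length(exons),
                 blockSizes = paste0(paste(fmt_int(sizes), collapse = ","), ","),
                 blockStarts = paste0(paste(fmt_int(starts), collapse = ","), ","),
                 stringsAsFactors = FALSE)
    }
    alt_names <- names(alt_specs)
    ai <- 0L
    for (cat in names(d$category_counts)) {
      for (rep_i in seq_len(d$category_counts[[cat]])) {
        ai <- ai + 1L
        alt <- alt_names[(ai - 1L) %% length(alt_names) + 1L]
        sp <- alt_specs[[alt]]
        tnum <- tnum + 1L
        id <- sprintf("t%03d", tnum)
        off <- (rep_i - 1L) * 7L   # de-overlap repeated plantings a little
        fl <- sp$f_l
        cs <- sp$cs; ce <- sp$ce
        if (cat == "A") {
          ex_alt <- list(c(5L + off, 25L + off), c(45L + off, 70L + off))
          ex_main <- lapply(ex_alt, function(x) x + cs)
        } else if (cat == "B") {
          ex_alt <- list(c(fl + 10L + off, fl + 40L + off))
          ex_main <- list(c(cs + fl + 60L + off, cs + fl + 110L + off))
        } else if (cat == "C") {
          ex_alt <- list(c(fl - 20L - off, fl + 30L + off))
          ex_main <- list(c(cs + 5L + off, cs + 90L + off))
        } else if (cat == "D") {
          ex_alt <- list(c(8L + off, 38L + off))
          ex_main <- list(c(40L + off, 80L + off))   # free zone before first alt
        } else if (cat == "E") {
          ex_alt <- list(c(12L + off, 42L + off))
          ex_main <- list(c(cs - 50L - off, cs + 60L + off))
        } else {   # none: no main counterpart
          ex_alt <- list(c(fl + 3L + off, fl + 33L + off))
          ex_main <- NULL
        }
        rows <- c(rows, list(bed_row(alt, ex_alt, id)))
        if (!is.null(ex_main)) {
          rows <- c(rows, list(bed_row(sp$chrom, ex_main, id)))
        }
        gt_tx <- c(gt_tx, list(list(transcript_id = id, alt = alt,
                                    category = cat)))
      }
    }

    list(sequences = sequences,
         placements = do.call(rbind, unname(placements)),
         alignments = do.call(rbind, unname(alignments)),
         transcripts = do.call(rbind, rows),
         ground_truth = list(seed = seed, params = d, alts = gt_alts,
                             transcripts = gt_tx))
  })
}

#' Write a fixture to disk
#'
#' Writes `sequences.fa`, `placements.tsv`, `alignments.tsv`,
#' `transcripts.bed` (headerless BED12) and `ground_truth.json` into `dir`.
#'
#' @param fix A fixture from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fix$sequences, file.path(dir, "sequences.fa"))
  write_placements(fix$placements, file.path(dir, "placements.tsv"))
  write_alignments(fix$alignments, file.path(dir, "alignments.tsv"))
  utils::write.table(fix$transcripts, file.path(dir, "transcripts.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(fix$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
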
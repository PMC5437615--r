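# Shared fixtures and independent oracles, built in code.

# Graph shaped like the worked single-path-interval figure: two parallel
# branches B (main) and D between A and C, then C -> F. Each block is its
# own region path.
fig3_graph <- function() {
  build_graph(
    list(block("A", sequence = "AC"), block("B", sequence = "GG"),
         block("D", sequence = "TT"), block("C", sequence = "AAA"),
         block("F", sequence = "CC")),
    list(c("A", "B"), c("A", "D"), c("B", "C"), c("D", "C"), c("C", "F")),
    list(main = c("A", "B", "C", "F")))
}

fig3_partition <- function(g = fig3_graph()) {
  region_partition(g, list(A = "A", B = "B", C = "C", D = "D", F = "F"),
                   kind = "custom")
}

# Multipath worked example: two parallel layers between A and E.
# B/B* differ by 1 edit; C/F differ by 3 edits.
fig4_graph <- function() {
  build_graph(
    list(block("A", sequence = "G"), block("B", sequence = "AA"),
         block("Bs", sequence = "AC"), block("C", sequence = "AAA"),
         block("F", sequence = "TTT"), block("E", sequence = "G")),
    list(c("A", "B"), c("A", "Bs"), c("B", "C"), c("B", "F"),
         c("Bs", "C"), c("Bs", "F"), c("C", "E"), c("F", "E")),
    list(main = c("A", "B", "C", "E")))
}

fig4_partition <- function(g = fig4_graph()) {
  region_partition(g, list(A = "A", B = "B", Bs = "Bs", C = "C", F = "F",
                           E = "E"), kind = "custom")
}

# One chromosome of three main blocks with one alt locus in parallel to the
# middle block; lengths chosen so the first split point is at offset 100.
one_alt_graph <- function() {
  build_graph(
    list(block("m1", 100), block("m2", 50), block("m3", 80), block("a1", 30)),
    list(c("m1", "m2"), c("m2", "m3"), c("m1", "a1"), c("a1", "m3")),
    list(chr14 = c("m1", "m2", "m3")))
}

# Random chromosome + alt-chain graph. Alts attach/detach at block
# boundaries; no intra-region-path skip edges, so both partitionings and
# the full interval notation are unambiguous.
random_alt_graph <- function(seed, n_main = NULL, n_alts = NULL,
                             with_sequence = FALSE) {
  withr::with_seed(seed, {
    n_main <- n_main %||% sample(3:8, 1)
    n_alts <- n_alts %||% sample(0:3, 1)
    rand_block <- function(id, len) {
      if (with_sequence) {
        block(id, sequence = paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = ""))
      } else {
        block(id, len)
      }
    }
    blocks <- lapply(seq_len(n_main), function(i) {
      rand_block(paste0("m", i), sample(1:6, 1))
    })
    ids <- paste0("m", seq_len(n_main))
    edges <- lapply(seq_len(n_main - 1L), function(i) c(ids[i], ids[i + 1L]))
    alt_paths <- list()
    for (k in seq_len(n_alts)) {
      resample <- function(x) x[sample.int(length(x), 1L)]
      i <- resample(seq_len(n_main - 1L))            # attach after block i
      j <- resample(seq(i + 1L, n_main))             # detach before block j
      chain <- paste0("a", k, "_", seq_len(sample(1:3, 1)))
      blocks <- c(blocks, lapply(chain, function(id) rand_block(id, sample(1:5, 1))))
      edges <- c(edges, list(c(ids[i], chain[1L])),
                 if (length(chain) > 1L) {
                   lapply(seq_len(length(chain) - 1L),
                          function(q) c(chain[q], chain[q + 1L]))
                 },
                 list(c(chain[length(chain)], ids[j])))
      alt_paths[[paste0("alt", k)]] <- chain
    }
    g <- build_graph(blocks, edges, list(chr = ids))
    list(graph = g, alt_paths = alt_paths)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force path enumeration: plain recursion over the raw
# edge matrix, no pruning, sorted at the end.
oracle_paths <- function(g, start, end) {
  em <- g$edges
  res <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == end) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    for (s in em[em[, 1] == v, 2]) recurse(c(path, s))
  }
  recurse(start)
  res[order(vapply(res, paste, "", collapse = "\r"))]
}

# Independent edit-distance oracle: memoized recursion on the textbook
# definition.
oracle_edit <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    assign(key, v, envir = memo)
    v
  }
  rec(nchar(a), nchar(b))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Stable identity of the base a position addresses, robust to block splits
# performed by apply_update: "<original block id> <intra offset>".
base_identity <- function(p, pos) {
  loc <- offsetgraph:::position_to_block(p, pos)
  id <- loc$block
  intra <- loc$intra
  blk_len <- function(g, bid) {   # length even if bid was split again
    b <- g$blocks[[bid]]
    if (!is.null(b)) return(b$length)
    blk_len(g, paste0(bid, ".1")) + blk_len(g, paste0(bid, ".2"))
  }
  while (grepl("\\.[12]$", id)) {
    if (grepl("\\.2$", id)) {
      parent <- sub("\\.2$", "", id)
      intra <- intra + blk_len(p$graph, paste0(parent, ".1"))
    } else {
      parent <- sub("\\.1$", "", id)
    }
    id <- parent
  }
  paste(id, intra)
}

# all (region path, base offset) coordinates of a partition
all_base_positions <- function(p) {
  out <- list()
  for (nm in names(p$region_paths)) {
    len <- p$rp_length[[nm]]
    for (off in seq_len(len) - 1L) {
      out[[length(out) + 1L]] <- position(nm, off)
    }
  }
  out
}
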
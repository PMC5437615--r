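test_that("edit_distance basics and oracle agreement", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("", "ACG"), 3L)
  expect_equal(edit_distance("ACG", ""), 3L)
  withr::with_seed(11, {
    for (k in 1:40) {
      a <- random_dna_str(sample(0:8, 1))
      b <- random_dna_str(sample(0:8, 1))
      expect_equal(edit_distance(a, b), oracle_edit(a, b), info = paste(a, b))
      expect_equal(edit_distance(a, b), edit_distance(b, a))
    }
  })
})

test_that("critical and fuzzy forms agree on the worked multipath example", {
  p <- fig4_partition()
  crit <- critical_interval(position("A", 0), position("E", 0), list("C"))
  members <- expand_multipath(crit, p)
  expect_equal(length(members), 2L)
  expect_setequal(vapply(members, function(i) paste(i$block_path, collapse = ","), ""),
                  c("A,B,C,E", "A,Bs,C,E"))

  central <- make_interval(position("A", 0), position("E", 0), c("B", "C"), p)
  fz2 <- fuzzy_interval(central, 2, "global")
  eq <- multipath_equal(crit, fz2, p)
  expect_true(as.logical(eq))
  expect_equal(attr(eq, "method"), "expansion")

  # threshold 1: B and B* cannot be co-members; only the central path remains
  fz1 <- fuzzy_interval(central, 1, "global")
  m1 <- expand_multipath(fz1, p)
  expect_equal(length(m1), 1L)
  expect_equal(m1[[1]]$block_path, c("A", "B", "C", "E"))

  # the empty critical set is the implicit all-paths interval
  all4 <- expand_multipath(critical_interval(position("A", 0), position("E", 0)), p)
  expect_equal(length(all4), 4L)
  expect_false(as.logical(multipath_equal(crit,
    critical_interval(position("A", 0), position("E", 0)), p)))
})

test_that("contains honors endpoints, critical sublists and thresholds", {
  p <- fig4_partition()
  crit <- critical_interval(position("A", 0), position("E", 0), list("C"))
  via_c <- make_interval(position("A", 0), position("E", 0), c("B", "C"), p)
  via_f <- make_interval(position("A", 0), position("E", 0), c("B", "F"), p)
  expect_true(contains(crit, via_c))
  expect_false(contains(crit, via_f))
  expect_error(contains(crit, make_interval(position("A", 0), position("C", 3),
                                            "B", p)),
               class = "obg_contract_error")
  # central path is always a member at any threshold >= 1
  expect_true(contains(fuzzy_interval(via_c, 1, "global"), via_c))
  expect_true(contains(fuzzy_interval(via_c, 1, "max_local"), via_c))
  # critical subpaths must be contiguous sublists
  crit2 <- critical_interval(position("A", 0), position("E", 0), list(c("B", "C")))
  expect_true(contains(crit2, via_c))
  expect_false(contains(crit2, make_interval(position("A", 0), position("E", 0),
                                             c("Bs", "C"), p)))
})

test_that("expansion and membership agree exhaustively on random graphs", {
  for (seed in 1:10) {
    rg <- random_alt_graph(seed, with_sequence = TRUE)
    p <- hierarchical_partition(rg$graph, rg$alt_paths)
    g <- rg$graph
    mp <- g$main_paths[[1]]
    start <- position(rp_start <- offsetgraph:::rp_of_block(p, mp[1]), 0)
    endb <- mp[length(mp)]
    end_rp <- offsetgraph:::rp_of_block(p, endb)
    end <- position(end_rp, p$rp_length[[end_rp]])
    paths <- enumerate_paths(g, mp[1], endb, max_paths = 500L)
    ivs <- lapply(paths, function(bp) {
      offsetgraph:::new_interval(p, bp, 0, g$blocks[[endb]]$length)
    })
    central <- ivs[[1]]
    mps <- list(
      critical_interval(start, end),
      critical_interval(start, end, list(central$region_paths[1])),
      fuzzy_interval(central, 2, "global"),
      fuzzy_interval(central, 3, "max_local"))
    for (m in mps) {
      members <- expand_multipath(m, p, max_paths = 1000L)
      keys <- vapply(members, function(i) paste(i$block_path, collapse = ","), "")
      for (i in ivs) {
        expect_equal(paste(i$block_path, collapse = ",") %in% keys,
                     contains(m, i), info = paste("seed", seed))
      }
    }
  }
})

test_that("fuzzy membership is monotone in the threshold (both modes)", {
  p <- fig4_partition()
  central <- make_interval(position("A", 0), position("E", 0), c("B", "C"), p)
  for (mode in c("global", "max_local")) {
    prev <- character(0)
    for (t in 1:5) {
      mem <- expand_multipath(fuzzy_interval(central, t, mode), p)
      keys <- vapply(mem, function(i) paste(i$block_path, collapse = ","), "")
      expect_true(all(prev %in% keys), info = paste(mode, t))
      prev <- keys
    }
  }
})

test_that("adding critical subpaths never grows the denoted set", {
  p <- fig4_partition()
  start <- position("A", 0); end <- position("E", 0)
  sets <- list(list(), list("C"), list("C", "B"))
  prev <- NULL
  for (cs in sets) {
    keys <- vapply(expand_multipath(critical_interval(start, end, cs), p),
                   function(i) paste(i$block_path, collapse = ","), "")
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("global and max_local agree when exactly one segment diverges", {
  p <- fig4_partition()
  central <- make_interval(position("A", 0), position("E", 0), c("B", "C"), p)
  one_diff <- make_interval(position("A", 0), position("E", 0), c("Bs", "C"), p)
  for (t in 1:4) {
    expect_equal(contains(fuzzy_interval(central, t, "global"), one_diff),
                 contains(fuzzy_interval(central, t, "max_local"), one_diff))
  }
  # adjacent divergences merge into one maximal segment: B/Bs and C/F have
  # no shared block between them, so max_local equals global there
  two_adj <- make_interval(position("A", 0), position("E", 0), c("Bs", "F"), p)
  expect_false(contains(fuzzy_interval(central, 4, "global"), two_adj))   # d = 4
  expect_false(contains(fuzzy_interval(central, 4, "max_local"), two_adj))

  # divergences separated by a shared block form two local segments
  g2 <- build_graph(
    list(block("A", sequence = "G"), block("B", sequence = "AA"),
         block("Bs", sequence = "AC"), block("M", sequence = "GG"),
         block("C", sequence = "AAA"), block("F", sequence = "TTT"),
         block("E", sequence = "G")),
    list(c("A", "B"), c("A", "Bs"), c("B", "M"), c("Bs", "M"),
         c("M", "C"), c("M", "F"), c("C", "E"), c("F", "E")),
    list(main = c("A", "B", "M", "C", "E")))
  p2 <- region_partition(g2, list(A = "A", B = "B", Bs = "Bs", M = "M",
                                  C = "C", F = "F", E = "E"), kind = "custom")
  central2 <- make_interval(position("A", 0), position("E", 0), c("B", "M", "C"), p2)
  two_seg <- make_interval(position("A", 0), position("E", 0), c("Bs", "M", "F"), p2)
  # global distance 4 (1 + 3); max of local distances 3
  expect_false(contains(fuzzy_interval(central2, 4, "global"), two_seg))
  expect_true(contains(fuzzy_interval(central2, 4, "max_local"), two_seg))
  expect_false(contains(fuzzy_interval(central2, 3, "max_local"), two_seg))
})

test_that("multipath text form round-trips", {
  p <- fig4_partition()
  crit <- critical_interval(position("A", 0), position("E", 0),
                            list("C", c("B", "C")))
  txt <- format_multipath(crit)
  expect_equal(txt, "(A:0 E:0 critical=C|B,C)")
  back <- parse_multipath(txt, p)
  expect_equal(back$critical, crit$critical)

  central <- make_interval(position("A", 0), position("E", 0), c("B", "C"), p)
  fz <- fuzzy_interval(central, 2, "max_local")
  txt2 <- format_multipath(fz)
  expect_equal(txt2, "(A:0 E:0 fuzzy=B,C t=2 mode=max_local)")
  back2 <- parse_multipath(txt2, p)
  expect_equal(back2$central$block_path, central$block_path)
  expect_equal(back2$threshold, 2L)
  expect_equal(back2$mode, "max_local")
})

test_that("multipath_equal falls back to canonical comparison on overflow", {
  p <- fig4_partition()
  a <- critical_interval(position("A", 0), position("E", 0), list("C"))
  b <- critical_interval(position("A", 0), position("E", 0), list("C"))
  eq <- multipath_equal(a, b, p, max_paths = 1L)   # force overflow
  expect_true(as.logical(eq))
  expect_equal(attr(eq, "method"), "canonical")
})
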
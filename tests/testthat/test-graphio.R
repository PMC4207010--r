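# Network, GMT and mapping-table I/O plus identifier mapping and merging.

test_that("edge tables are read as simplified undirected networks", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(character(), path)
  g <- read_interaction_table(path)
  expect_equal(igraph::vcount(g), 0)
  expect_equal(igraph::ecount(g), 0)

  writeLines(c("A\tB", "B\tA"), path)
  g <- read_interaction_table(path)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)

  # 10 rows: 7 distinct edges + 2 duplicates (one reversed) + 1 self-loop
  writeLines(c("a\tb", "b\tc", "c\td", "d\te", "e\tf", "f\tg", "g\ta",
               "a\tb", "c\tb", "d\td"), path)
  g <- read_interaction_table(path)
  expect_equal(igraph::ecount(g), 7)
  rep <- igraph::graph_attr(g, "parse_report")
  expect_equal(rep$loops_dropped, 1)
  expect_equal(rep$duplicates_collapsed, 2)
  expect_equal(rep$rows, 10)
})

test_that("psimitab identifiers are prefix-stripped and errors name lines", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "uniprotkb:P1\tuniprotkb:P2\textra\tcols",
               "uniprotkb:P2\tensembl:P3\tx\ty"), path)
  g <- read_interaction_table(path, "psimitab")
  expect_setequal(igraph::V(g)$name, c("P1", "P2", "P3"))

  writeLines(c("A\tB", "only_one_column"), path)
  expect_error(read_interaction_table(path), "line 2")
  writeLines(c("A\tB", "C\t "), path)
  expect_error(read_interaction_table(path), "line 2")
})

test_that("GMT reading collapses within-line duplicates and checks structure", {
  path <- withr::local_tempfile(fileext = ".gmt")

  writeLines("P1\tdesc\tg1\tg2\tg2", path)
  pw <- read_gmt(path)
  expect_named(pw, "P1")
  expect_setequal(pw$P1$genes, c("g1", "g2"))

  writeLines(character(), path)
  expect_length(read_gmt(path), 0)

  writeLines(c("P1\td1\ta1\ta2", "P2\td2\tb1\tb2\tb3",
               "P3\td3\tc1\tc2\tc3\tc4"), path)
  pw <- read_gmt(path)
  expect_length(pw, 3)
  expect_equal(length(unique(unlist(lapply(pw, `[[`, "genes")))), 9)

  writeLines("P1\tdesc_only", path)
  expect_error(read_gmt(path), "line 1")
  writeLines(c("P1\td\tg1", "P1\td\tg2"), path)
  expect_error(read_gmt(path), "P1")
})

test_that("identifier mapping rewires networks and filters gene sets", {
  idmap <- id_mapping(c("a", "b", "c", "d", "e"),
                      c("a2", "X", "X", "d2", "e2"),
                      "synthetic", "target_ns")

  # identity mapping leaves the object unchanged
  g <- net_from_edges(c("a", "b"), c("b", "c"))
  ident <- id_mapping(c("a", "b", "c"), c("a", "b", "c"),
                      "synthetic", "synthetic")
  expect_true(graph_equal(map_ids(g, ident), g))

  # 5-node path with b,c collapsing onto one target X
  path5 <- net_from_edges(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"))
  mapped <- map_ids(path5, idmap)
  expect_setequal(igraph::V(mapped)$name, c("a2", "X", "d2", "e2"))
  el <- igraph::as_edgelist(mapped)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_equal(got, sort(c("X a2", "X d2", "d2 e2")))

  # unmapped removal under drop_ambiguous
  many <- id_mapping(c("b", "b2", "b2"), c("bb", "t1", "t2"),
                     "synthetic", "t")
  expect_equal(as.character(map_ids(c("a", "b"), many,
                                    policy = "drop_ambiguous")), "bb")
  expect_error(map_ids(g, idmap, namespace = "other"), "namespace")
})

test_that("expand mapping matches brute-force rewiring on random graphs", {
  for (s in 1:10) {
    set.seed(s)
    g <- igraph::sample_gnp(20, 0.2)
    igraph::V(g)$name <- sprintf("v%02d", 1:20)
    g <- igraph::set_graph_attr(g, "namespace", "synthetic")
    # random many-to-many map with drops and 2-fans
    src <- rep(sprintf("v%02d", 1:20), times = sample(0:2, 20, replace = TRUE))
    tgt <- sprintf("t%03d", sample(30, length(src), replace = TRUE))
    mp <- id_mapping(src, tgt, "synthetic", "t")
    mapped <- map_ids(g, mp)
    # oracle: rewire every edge by nested loops, then simplify
    el <- igraph::as_edgelist(g)
    tgt_of <- split(mp$pairs$target, factor(mp$pairs$source,
                                            levels = igraph::V(g)$name))
    pairs <- character()
    for (i in seq_len(nrow(el))) {
      for (x in tgt_of[[el[i, 1]]]) for (y in tgt_of[[el[i, 2]]]) {
        if (x != y) pairs <- c(pairs, paste(min(x, y), max(x, y)))
      }
    }
    el2 <- igraph::as_edgelist(mapped)
    got <- sort(paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2])))
    expect_equal(got, sort(unique(pairs)))
    # no self-loops, no duplicate edges
    expect_true(igraph::is_simple(mapped))
  }
})

test_that("merge is union, idempotent, commutative and associative", {
  n1 <- net_from_edges(c("a", "b"), c("b", "c"), c("c", "d"))
  n2 <- net_from_edges(c("c", "d"), c("d", "e"), c("e", "c"))
  m <- merge_networks(list(n1, n2))
  expect_equal(igraph::ecount(m), 5)
  expect_equal(igraph::vcount(m), 5)
  expect_true(graph_equal(merge_networks(list(n1, n1)), n1))
  expect_equal(igraph::vcount(merge_networks(list())), 0)

  n3 <- net_from_edges(c("x", "a"), c("a", "e"))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  nets <- list(n1, n2, n3)
  base <- merge_networks(nets)
  for (p in perms) {
    expect_true(graph_equal(merge_networks(nets[p]), base))
  }
  expect_true(graph_equal(
    merge_networks(list(merge_networks(list(n1, n2)), n3)),
    merge_networks(list(n1, merge_networks(list(n2, n3))))
  ))
  bad <- igraph::set_graph_attr(n3, "namespace", "other")
  expect_error(merge_networks(list(n1, bad)), "namespace")
})

test_that("TSV and GraphML round-trips preserve the graph", {
  g <- net_from_edges(c("a", "b"), c("b", "c"), nodes = c("a", "b", "c", "iso"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(g, tsv)
  back <- read_network_tsv(tsv, namespace = "synthetic")
  expect_true(graph_equal(g, back))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(g, gml)
  back2 <- igraph::read_graph(gml, format = "graphml")
  expect_true(graph_equal(g, back2))
})

test_that("read/map/merge outputs stay simple graphs", {
  for (s in 1:5) {
    set.seed(s)
    edges <- cbind(sample(letters[1:8], 30, TRUE), sample(letters[1:8], 30, TRUE))
    g <- interaction_network(edges)
    expect_true(igraph::is_simple(g))
    # re-simplifying changes nothing: same edge set
    re <- interaction_network(igraph::as_edgelist(g))
    ek <- function(x) {
      el <- igraph::as_edgelist(x)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_equal(ek(re), ek(g))
  }
})
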
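# Induced subgraph extraction and MCODE-style segmentation.

test_that("induced subgraph keeps signature genes and drops isolates", {
  g <- net_from_edges(c("a", "b"), c("b", "c"), c("c", "a"), c("d", "x"),
                      c("x", "y"))
  sub <- induced_signature_subgraph(g, c("a", "b", "c", "d", "missing"))
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c"))
  rep <- igraph::graph_attr(sub, "subgraph_report")
  expect_equal(rep$mapped, 4)          # d mapped but isolated, missing absent
  expect_equal(rep$isolates_removed, 1)
  expect_equal(rep$retained, 3)

  # genes disjoint from the network
  empty <- induced_signature_subgraph(g, c("q1", "q2"))
  expect_equal(igraph::vcount(empty), 0)

  # full connected graph maps to itself
  tri <- net_from_edges(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_true(graph_equal(induced_signature_subgraph(tri, c("a", "b", "c")),
                          tri))
})

test_that("vertex scores follow the closed-neighbourhood k-core rule", {
  tri <- net_from_edges(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_equal(unname(mcode_score_vertices(tri)), rep(2, 3))

  path3 <- net_from_edges(c("a", "b"), c("b", "c"))
  sc <- mcode_score_vertices(path3)
  expect_equal(sc[["b"]], 2 / 3)
  expect_equal(sc[["a"]], 0)
  expect_equal(sc[["c"]], 0)

  # K4 plus a pendant on x: clique vertices score 3, pendant 0
  k4p <- interaction_network(rbind(make_clique(c("x", "v1", "v2", "v3")),
                                   c("x", "pend")))
  sc <- mcode_score_vertices(k4p)
  expect_equal(unname(sc[c("x", "v1", "v2", "v3")]), rep(3, 4))
  expect_equal(sc[["pend"]], 0)

  # clique scaling: every K_n vertex scores n - 1
  for (n in 3:7) {
    kn <- interaction_network(make_clique(sprintf("c%d", 1:n)))
    expect_equal(unname(mcode_score_vertices(kn)), rep(n - 1, n))
  }
})

test_that("scores match the exhaustive subset-enumeration oracle", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.2, 0.9))
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    got <- mcode_score_vertices(g)
    want <- oracle_mcode_scores(g)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("segments respect dense boundaries and post-processing filters", {
  # two K4s joined by one bridge: the bridge is never crossed
  g <- interaction_network(rbind(make_clique(paste0("a", 1:4)),
                                 make_clique(paste0("b", 1:4)),
                                 c("a4", "b4")))
  segs <- mcode_segments(g)
  expect_length(segs, 2)
  expect_setequal(segs[[1]]$genes, paste0("a", 1:4))
  expect_setequal(segs[[2]]$genes, paste0("b", 1:4))

  # edgeless / empty networks give no segments
  expect_length(mcode_segments(interaction_network(NULL, nodes = c("a", "b"))),
                0)
  expect_length(mcode_segments(interaction_network(NULL)), 0)

  # K5 with a pendant, haircut on: one segment equal to the K5
  k5p <- interaction_network(rbind(make_clique(paste0("k", 1:5)),
                                   c("k1", "pend")))
  segs <- mcode_segments(k5p)
  expect_length(segs, 1)
  expect_setequal(segs[[1]]$genes, paste0("k", 1:5))
})

test_that("segments are disjoint, substrate-bound and deterministic", {
  set.seed(5)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- sprintf("v%02d", 1:40)
  segs <- mcode_segments(g)
  all_genes <- unlist(lapply(segs, `[[`, "genes"))
  expect_equal(anyDuplicated(all_genes), 0)
  expect_true(all(all_genes %in% igraph::V(g)$name))
  for (s in segs) {
    expect_true(s$seed %in% s$genes)
    expect_gte(length(s$genes), 3)   # a 2-core has at least 3 vertices
  }
  # permuting the edge-row insertion order leaves the result unchanged
  el <- igraph::as_edgelist(g)
  for (rep in 1:3) {
    set.seed(rep)
    perm <- interaction_network(el[sample(nrow(el)), c(2, 1)])
    segs2 <- mcode_segments(perm)
    expect_equal(lapply(segs2, `[[`, "genes"), lapply(segs, `[[`, "genes"))
    expect_equal(vapply(segs2, `[[`, "", "seed"),
                 vapply(segs, `[[`, "", "seed"))
  }
})

test_that("process_model composes mapping, isolate removal and segmentation", {
  # planted partition of three 8-cliques
  cliques <- lapply(1:3, function(i) sprintf("m%d_%d", i, 1:8))
  g <- interaction_network(do.call(rbind, lapply(cliques, make_clique)))
  model <- process_model(g, unlist(cliques))
  expect_length(model$segments, 3)
  for (i in 1:3) expect_setequal(model$segments[[i]]$genes, cliques[[i]])
  expect_equal(summary(model)$size_median, 8)

  # signature absent from the network: empty model
  m0 <- process_model(g, c("zz1", "zz2"))
  expect_length(m0$segments, 0)
  expect_equal(summary(m0)$n_segments, 0)

  # segment-size statistics: cliques of 3, 4 and 7
  sizes <- c(3, 4, 7)
  cl <- lapply(seq_along(sizes), function(i) sprintf("s%d_%d", i, 1:sizes[i]))
  g2 <- interaction_network(do.call(rbind, lapply(cl, make_clique)))
  sm <- summary(process_model(g2, unlist(cl)))
  expect_equal(sm$size_median, 4)
  expect_equal(sm$size_min, 3)
  expect_equal(sm$size_max, 7)
  expect_equal(sm$n_segments, 3)
})

test_that("model output formats carry segments and seeds", {
  st <- synthetic_interference_study(1)
  model <- process_model(st$disease_network, st$disease_signature)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_process_model(model, tsv, graphml_path = gml, header = "seed=1")
  tab <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(tab), model$report$genes_in_segments)
  expect_equal(sum(tab$is_seed), length(model$segments))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_true("segment" %in% igraph::vertex_attr_names(g))
})
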
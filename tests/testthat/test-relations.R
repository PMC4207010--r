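# Cross-set interaction counts, permutation nulls and the pathway landscape.

test_that("cross_edge_count counts boundary-spanning edges only", {
  # two components: no cross edges
  g <- net_from_edges(c("a1", "a2"), c("a2", "a3"), c("b1", "b2"))
  expect_equal(cross_edge_count(g, c("a1", "a2", "a3"), c("b1", "b2")), 0)

  # complete bipartite K_{2,3}
  kb <- interaction_network(cbind(rep(c("u1", "u2"), each = 3),
                                  rep(c("w1", "w2", "w3"), 2)))
  expect_equal(cross_edge_count(kb, c("u1", "u2"), c("w1", "w2", "w3")), 6)

  expect_error(cross_edge_count(g, c("a1", "a2"), c("a2", "b1")), "disjoint")

  # symmetry and invariance to within-set edges
  set.seed(11)
  g2 <- igraph::sample_gnp(30, 0.2)
  igraph::V(g2)$name <- sprintf("v%02d", 1:30)
  a <- sprintf("v%02d", 1:8)
  b <- sprintf("v%02d", 20:28)
  expect_equal(cross_edge_count(g2, a, b), cross_edge_count(g2, b, a))
  extra <- interaction_network(rbind(igraph::as_edgelist(g2),
                                     c("v01", "v02"), c("v03", "v04")))
  expect_equal(cross_edge_count(extra, a, b), cross_edge_count(g2, a, b))
})

test_that("permutation null behaves on degenerate and planted cases", {
  # observed 0: p_empirical is exactly 1
  g <- net_from_edges(c("a1", "a2"), c("b1", "b2"), nodes = sprintf("n%d", 1:6))
  st <- relation_significance(g, c("a1", "a2"), c("b1", "b2"), n_perm = 99,
                              seed = 1)
  expect_equal(st$observed, 0)
  expect_equal(st$p_empirical, 1)

  # complete graph: every draw gives |A|*|B| cross edges, sd 0, z undefined
  k10 <- interaction_network(make_clique(sprintf("k%02d", 1:10)))
  st <- relation_significance(k10, c("k01", "k02"), c("k03", "k04"),
                              n_perm = 199, seed = 7)
  expect_equal(st$observed, 4)
  expect_equal(st$null_mean, 4)
  expect_equal(st$null_sd, 0)
  expect_equal(st$p_empirical, 1)
  expect_true(is.na(st$z))

  # two heavily bridged planted 8-cliques in a sparse background: the
  # observed cross count far exceeds anything two random size-8 sets reach
  set.seed(3)
  bg <- igraph::sample_gnp(100, 0.01)
  igraph::V(bg)$name <- sprintf("g%03d", 1:100)
  ca <- sprintf("g%03d", 1:8)
  cb <- sprintf("g%03d", 9:16)
  shift <- function(d) cbind(ca, cb[(seq_len(8) + d - 1) %% 8 + 1])
  bridges <- rbind(shift(1), shift(2), shift(3)[1:4, ])
  g2 <- interaction_network(rbind(igraph::as_edgelist(bg), make_clique(ca),
                                  make_clique(cb), bridges),
                            nodes = igraph::V(bg)$name)
  st <- relation_significance(g2, ca, cb, n_perm = 999, seed = 11)
  expect_gte(st$observed, 20)
  expect_lte(st$p_empirical, 0.01)

  expect_error(relation_significance(k10, sprintf("k%02d", 1:6),
                                     sprintf("k%02d", 7:10),
                                     universe = sprintf("k%02d", 1:8)),
               "universe")
})

test_that("identical seeds reproduce the statistic and p is never zero", {
  set.seed(9)
  g <- igraph::sample_gnp(50, 0.1)
  igraph::V(g)$name <- sprintf("v%02d", 1:50)
  a <- sprintf("v%02d", 1:6)
  b <- sprintf("v%02d", 10:16)
  s1 <- relation_significance(g, a, b, n_perm = 199, seed = 123)
  s2 <- relation_significance(g, a, b, n_perm = 199, seed = 123)
  expect_identical(s1, s2)
  expect_gt(s1$p_empirical, 0)
  s3 <- relation_significance(g, a, b, n_perm = 199, seed = 124)
  expect_false(identical(s1$null_mean, s3$null_mean))
})

test_that("model relation scoring flags only heavily bridged pairs", {
  # three 8-cliques inside a sparse 100-node background; 12 bridges span
  # cliques A and B, none elsewhere
  set.seed(41)
  bg <- igraph::sample_gnp(100, 0.01)
  igraph::V(bg)$name <- sprintf("g%03d", 1:100)
  A <- sprintf("g%03d", 1:8)
  B <- sprintf("g%03d", 9:16)
  C <- sprintf("g%03d", 17:24)
  bridges <- cbind(A[c(1:8, 1:4)], B[c(2:8, 1, 5:8)])
  g <- interaction_network(rbind(igraph::as_edgelist(bg), make_clique(A),
                                 make_clique(B), make_clique(C), bridges),
                           nodes = igraph::V(bg)$name)
  model <- process_model(g, igraph::V(g)$name)
  seg_of <- function(set) {
    which(vapply(model$segments, function(s) all(set %in% s$genes), TRUE))
  }
  expect_length(seg_of(A), 1)
  expect_length(seg_of(B), 1)
  expect_length(seg_of(C), 1)
  model <- score_model_relations(model, n_perm = 499, seed = 5, alpha = 0.05)
  rel <- model$relations
  ab <- (rel$id_a == model$segments[[seg_of(A)]]$segment_id &
           rel$id_b == model$segments[[seg_of(B)]]$segment_id) |
    (rel$id_b == model$segments[[seg_of(A)]]$segment_id &
       rel$id_a == model$segments[[seg_of(B)]]$segment_id)
  expect_equal(sum(ab), 1)
  expect_gte(rel$observed[ab], 12)
  expect_true(rel$significant[ab])
  expect_false(any(rel$significant[!ab]))

  # one-segment model: no relations
  m1 <- sprintf("m1_%d", 1:8)
  single <- process_model(interaction_network(make_clique(m1)), m1)
  single <- score_model_relations(single, n_perm = 99, seed = 1)
  expect_equal(nrow(single$relations), 0)
})

test_that("pathway landscape separates shared genes from cross edges", {
  # 9-node fixture: pathways share s1, s2; 3 edges between private members
  pA <- c("s1", "s2", "a1", "a2")
  pB <- c("s1", "s2", "b1", "b2", "b3")
  g <- net_from_edges(c("a1", "b1"), c("a1", "b2"), c("a2", "b3"),
                      c("s1", "a1"), c("s2", "b1"),
                      nodes = union(pA, pB))
  pw <- list(A = list(pathway_id = "A", name = "", genes = pA),
             B = list(pathway_id = "B", name = "", genes = pB))
  rel <- pathway_landscape(pw, g, min_shared = 1, min_cross = 1)
  expect_equal(nrow(rel), 1)
  expect_equal(rel$shared_genes, 2)
  expect_equal(rel$cross_edges, 3)   # shared genes excluded from both sides

  # disjoint and disconnected pathways: nothing emitted, no self-relations
  pw2 <- list(X = list(pathway_id = "X", name = "", genes = c("a1", "a2")),
              Y = list(pathway_id = "Y", name = "", genes = c("b1", "b2")))
  g2 <- net_from_edges(c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(pathway_landscape(pw2, g2)), 0)
  expect_equal(nrow(pathway_landscape(pw2[1], g2)), 0)
})
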
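path_graph <- function(n) {
  structure(list(nodes = seq_len(n),
                 edges = cbind(seq_len(n - 1), 2:n), anchor = NULL),
            class = "contact_graph")
}
triangle_graph <- structure(list(nodes = 1:3,
                                 edges = rbind(c(1L, 2L), c(1L, 3L),
                                               c(2L, 3L)), anchor = NULL),
                            class = "contact_graph")
single_node_graph <- structure(list(nodes = 5L,
                                    edges = matrix(integer(0), 0, 2),
                                    anchor = NULL),
                               class = "contact_graph")

test_that("topology descriptors match the hand-derived worked values", {
  p3 <- topology_features(path_graph(3))
  expect_equal(p3[1], 3)             # nodes
  expect_equal(p3[2], 2)             # edges
  expect_equal(p3[3], 2 / 3)         # avg degree centrality
  expect_equal(p3[4], 7 / 9)         # avg closeness
  expect_equal(p3[5], 1 / 3)         # avg betweenness
  expect_equal(p3[6:8], c(1, 2, 5 / 3))  # radius, diameter, avg ecc
  expect_equal(p3[9], 2)             # end points
  expect_equal(p3[10], 0)            # clustering

  tr <- topology_features(triangle_graph)
  expect_equal(tr[10], 1)
  expect_equal(tr[9], 0)
  expect_equal(tr[6:7], c(1, 1))

  se <- topology_features(path_graph(2))
  expect_equal(se[9], 2)
  expect_equal(se[3], 1)

  expect_equal(topology_features(single_node_graph),
               c(1, rep(0, 9)))
})

test_that("spectrum descriptors match closed forms and zero-trace identities", {
  p3 <- spectrum_features(path_graph(3))
  expect_equal(p3[1], sqrt(2), tolerance = 1e-12)
  expect_equal(p3[2], 0, tolerance = 1e-12)
  expect_equal(p3[3], 3)
  expect_equal(p3[4], 0, tolerance = 1e-12)
  expect_equal(p3[5], 2 * sqrt(2), tolerance = 1e-12)

  expect_equal(spectrum_features(single_node_graph), c(0, 0, 1, 0, 0))

  set.seed(11)
  for (t in 1:25) {
    g <- random_test_graph(sample(2:8, 1), stats::runif(1, 0.2, 0.9))
    sp <- spectrum_features(g)
    expect_equal(sp[4], 0, tolerance = 1e-9)      # zero trace
    expect_lte(sp[3], length(g$nodes))            # distinct <= n
    if (nrow(g$edges) > 0) expect_gte(sp[5], 2 * sp[1] - 1e-9)
  }
})

test_that("centralities agree with the brute-force oracle on random graphs", {
  set.seed(12)
  for (t in 1:60) {
    g <- random_test_graph(sample(2:8, 1), stats::runif(1, 0.15, 0.9))
    expect_equal(topology_features(g), oracle_topology(g),
                 tolerance = 1e-10)
  }
})

test_that("label-statistics blocks have the contracted lengths and sums", {
  prep <- get_mini_prep()
  d <- prep$decoys[[1]]
  cfg <- dm_config()
  pr <- d$candidates[1, ]
  sng <- shared_neighborhood_graph(d$cm, d$ss, pr[1], pr[2], adj = d$adj)
  ing <- immediate_neighborhood_graph(d$cm, pr[1], pr[2], adj = d$adj)

  ns <- node_label_statistics(sng, d$labels, cfg)
  expect_length(ns, 43)
  expect_equal(sum(ns[1:7]), 1)            # chem distribution
  expect_equal(sum(ns[8:14]), 1)           # ss7 distribution
  expect_equal(sum(ns[16:18]), 1)          # rsa bins
  expect_equal(sum(ns[22:25]), 1)          # solvation bins
  expect_true(all(ns[26:28] >= 0))         # entropies
  expect_lte(ns[26], log(7) + 1e-12)       # chem entropy
  expect_lte(ns[27], log(7) + 1e-12)       # ss7 entropy

  es <- edge_label_statistics(ing, d$labels, cfg)
  expect_length(es, 12)
  expect_equal(sum(es[2:6]), 1)            # apc-mi bins
  expect_equal(sum(es[8:10]), 1)           # potential bins
  expect_gte(es[1], 0); expect_lte(es[1], 1)

  # no-edge graph yields zeros
  expect_equal(edge_label_statistics(single_node_graph, d$labels, cfg),
               rep(0, 12))

  # single-node graph: centroid distance 0
  g1 <- structure(list(nodes = 3L, edges = matrix(integer(0), 0, 2),
                       anchor = NULL), class = "contact_graph")
  ns1 <- node_label_statistics(g1, d$labels, cfg)
  expect_equal(ns1[30:31], c(0, 0))   # centroid distance mean and sd

  sn <- single_node_features(pr[1], pr[2], sng, d$labels)
  expect_length(sn, 10)
  expect_error(single_node_features(pr[1], 9999, sng, d$labels))
})

test_that("pairwise and whole-protein blocks keep their one-hot structure", {
  prep <- get_mini_prep()
  d <- prep$decoys[[1]]
  cfg <- dm_config()
  pr <- d$candidates[2, ]
  pw <- pairwise_features(pr[1], pr[2], d$labels, prep$ens, cfg)
  expect_length(pw, 49)
  expect_equal(sum(pw[1:7]), 1)     # chem one-hot i
  expect_equal(sum(pw[8:14]), 1)    # chem one-hot j
  expect_equal(sum(pw[15:17]), 1)   # ss3 one-hot i
  expect_equal(sum(pw[18:20]), 1)
  expect_equal(sum(pw[33:36]), 1)   # separation bin
  expect_equal(pw[32], pr[2] - pr[1])

  # swapping anchors permutes only the per-residue blocks
  pw2 <- pairwise_features(pr[2], pr[1], d$labels, prep$ens, cfg)
  expect_equal(pw2, pw)

  s <- prep$decoys[[1]]$structure
  wp <- whole_protein_features(s, d$labels$nodes$ss3, cfg)
  expect_length(wp, 29)
  expect_equal(sum(wp[1:20]), 1)
  expect_equal(sum(wp[21:23]), 1)
  expect_equal(sum(wp[24:29]), 1)
  # L = 50 falls in the 6-bin length class 1 boundary check: L = 120 -> bin 3
  fake <- s
  fake$L <- 120L
  expect_equal(whole_protein_features(fake, d$labels$nodes$ss3, cfg)[24:29],
               c(0, 0, 1, 0, 0, 0))
})

test_that("assembled vectors have the 238-input schema and are deterministic", {
  prep <- get_mini_prep()
  d <- prep$decoys[[1]]
  cfg <- dm_config()
  pr <- d$candidates[1, ]
  fv <- assemble_feature_vector(pr[1], pr[2], d$cm, d$ss, d$labels,
                                prep$ens, d$whole, adj = d$adj, cfg = cfg)
  expect_length(fv, 238)
  expect_equal(sum(unname(attr(fv, "groups"))), 238 - 80)  # group contract
  fv2 <- assemble_feature_vector(pr[1], pr[2], d$cm, d$ss, d$labels,
                                 prep$ens, d$whole, adj = d$adj, cfg = cfg)
  expect_identical(as.numeric(fv), as.numeric(fv2))

  # minimal pair: identical SNG and ING imply identical graph blocks
  iso <- make_cm(40, c(10, 30))
  ss <- rep("C", 40)
  labs <- d$labels
  expect_equal(shared_neighborhood_graph(iso, ss, 10, 30)$nodes,
               immediate_neighborhood_graph(iso, 10, 30)$nodes)

  sc <- feature_schema(cfg)
  expect_equal(nrow(sc), 238)
  expect_equal(unname(table(sc$group)["pairwise"]), 49L)
})

test_that("feature extraction is invariant under rigid motion", {
  prep <- get_mini_prep()
  cfg <- dm_config()
  ctx <- get_mini_corpus()$proteins[[1]]
  s <- prep$decoys[[1]]$structure

  # random rotation + translation of all atoms
  set.seed(33)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 11), "+")
  s2 <- decoymap:::.new_protein_structure(s$id, s$chain, s$seq, s2$atoms)

  cm1 <- compute_contact_map(s)
  cm2 <- compute_contact_map(s2)
  expect_identical(cm1$pairs, cm2$pairs)

  ann1 <- annotate_structure(s, cfg)
  ann2 <- annotate_structure(s2, cfg)
  expect_equal(ann1$ss7, ann2$ss7)
  expect_identical(ann1$hbonds, ann2$hbonds)
  # areas via sphere sampling are invariant up to the sampling resolution
  expect_equal(ann1$rsa, ann2$rsa, tolerance = 0.05)
})
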
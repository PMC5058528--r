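test_that("two haplotypes one step apart give a single edge", {
  net <- build_mj_network(c(h1 = "AAT", h2 = "AAA"))
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$weight, 1L)
  expect_false(any(net$nodes$is_median))
})

test_that("a perfect median triple yields one median of degree 3", {
  net <- build_mj_network(c(h1 = "AAT", h2 = "ATA", h3 = "TAA"))
  expect_identical(sum(net$nodes$is_median), 1L)
  med <- net$nodes$node[net$nodes$is_median]
  expect_identical(unname(net$seqs[med]), "AAA")
  deg <- table(c(net$edges$from, net$edges$to))
  expect_identical(as.integer(deg[med]), 3L)
  expect_true(all(net$edges$weight == 1))
})

test_that("a star of satellites around an observed hub needs no medians", {
  hub <- "AAAAA"
  sats <- c("TAAAA", "ACAAA", "AAGAA", "AAATA", "AAAAC")
  net <- build_mj_network(setNames(c(hub, sats), paste0("h", 1:6)))
  expect_identical(sum(net$nodes$is_median), 0L)
  expect_identical(nrow(net$edges), 5L)
  expect_true(all(net$edges$weight == 1))
})


test_that("MST edges are realised as exact geodesics on compatible data", {
  set.seed(201)
  n_checked <- 0
  for (rep in 1:100) {
    haps <- random_perfect_phylogeny()
    if (length(haps) < 3) next
    net <- build_mj_network(haps)
    # independent MST oracle on the observed haplotypes
    M <- do.call(rbind, strsplit(unname(haps), ""))
    d <- matrix(0, length(haps), length(haps),
                dimnames = list(names(haps), names(haps)))
    for (a in seq_along(haps)) for (b in seq_along(haps))
      d[a, b] <- sum(M[a, ] != M[b, ])
    g_full <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                                  mode = "undirected")
    mst <- igraph::mst(g_full)
    g_net <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                           vertices = net$nodes$node)
    sp <- igraph::distances(g_net, weights = net$edges$weight)
    for (e in seq_len(igraph::ecount(mst))) {
      ends <- igraph::ends(mst, e)
      expect_equal(unname(sp[ends[1], ends[2]]),
                   unname(d[ends[1], ends[2]]))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 90)
})

test_that("homoplastic data keep the weaker network bounds", {
  set.seed(211)
  for (rep in 1:15) {
    K <- 10
    haps <- unique(replicate(8, paste(sample(c("A", "G"), K, TRUE),
                                      collapse = "")))
    if (length(haps) < 3) next
    names(haps) <- paste0("h", seq_along(haps))
    net <- build_mj_network(haps)
    M <- do.call(rbind, strsplit(unname(haps), ""))
    d <- matrix(0, length(haps), length(haps),
                dimnames = list(names(haps), names(haps)))
    for (a in seq_along(haps)) for (b in seq_along(haps))
      d[a, b] <- sum(M[a, ] != M[b, ])
    g_net <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                           vertices = net$nodes$node)
    expect_true(igraph::is_connected(g_net))
    sp <- igraph::distances(g_net, weights = net$edges$weight)
    obs <- net$nodes$node[!net$nodes$is_median]
    # path weight never undercuts the Hamming distance of its endpoints
    expect_true(all(sp[obs, obs] >= d[obs, obs] - 1e-12))
    # medians survive cleanup only with degree >= 2
    if (any(net$nodes$is_median)) {
      deg <- table(c(net$edges$from, net$edges$to))
      expect_true(all(deg[net$nodes$node[net$nodes$is_median]] >= 2))
    }
  }
})

test_that("networks from phased data carry per-host counts", {
  cfg <- sim_config(seed = 202, n_seq_per_host = 30)
  sq <- simulate_sequences(cfg)
  haps <- em_phase(sq$alignment)
  net <- build_mj_network(haps)
  cc <- paste0("count_", cfg$hosts)
  expect_true(all(cc %in% names(net$nodes)))
  n_copies <- 2 * sum(haps$pairs$phased)
  expect_identical(sum(net$nodes[[cc[1]]] + net$nodes[[cc[2]]]),
                   as.integer(n_copies))
  expect_true(all(net$nodes[net$nodes$is_median, cc] == 0))
})

test_that("root annotation marks nearest observed nodes, keeping ties", {
  haps <- c(h1 = "AAAA", h2 = "AAAT", h3 = "TTAA")
  net <- build_mj_network(haps)
  r1 <- annotate_root(net, c(og = "AAAA"))
  expect_identical(r1$nodes$node[which(r1$nodes$root_adjacent)], "h1")
  expect_identical(r1$nodes$root_distance[r1$nodes$node == "h1"], 0)
  # outgroup equidistant from h1 and h2 -> both marked
  r2 <- annotate_root(net, c(og = "AAAC"))
  expect_setequal(r2$nodes$node[which(r2$nodes$root_adjacent)],
                  c("h1", "h2"))
  expect_error(annotate_root(net, character(0)), "empty")
})

test_that("the root lands in the ancestral host's cluster on fixtures", {
  cfg <- sim_config(seed = 203, n_seq_per_host = 40)
  sq <- simulate_sequences(cfg)
  haps <- em_phase(sq$alignment)
  net <- build_mj_network(haps)
  og <- simulate_outgroups(sq$truth, n = 3, seed = 204)
  net <- annotate_root(net, og)
  marked <- net$nodes[net$nodes$root_adjacent, ]
  anc <- paste0("count_", cfg$hosts[1])
  der <- paste0("count_", cfg$hosts[2])
  expect_true(sum(marked[[anc]]) >= sum(marked[[der]]))
})

test_that("exports are lossless and reference-consistent", {
  cfg <- sim_config(seed = 205, n_seq_per_host = 15)
  sq <- simulate_sequences(cfg)
  net <- build_mj_network(em_phase(sq$alignment))
  dir <- withr::local_tempdir()
  # tsv: node table row count = observed + medians
  paths <- export_network(net, file.path(dir, "net"), "tsv")
  nodes <- read.delim(paths[1])
  edges <- read.delim(paths[2])
  expect_identical(nrow(nodes), nrow(net$nodes))
  expect_identical(nrow(edges), nrow(net$edges))
  # graphml round-trips the topology
  gp <- file.path(dir, "net.graphml")
  export_network(net, gp, "graphml")
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g2)), nrow(net$nodes))
  expect_equal(as.integer(igraph::ecount(g2)), nrow(net$edges))
  g1 <- hostscan:::network_igraph(net)
  expect_true(igraph::isomorphic(g1, g2))
  # dot output has no dangling node references
  dp <- file.path(dir, "net.dot")
  export_network(net, dp, "dot")
  txt <- readLines(dp)
  expect_true(length(txt) > nrow(net$nodes))
  expect_error(export_network(net, file.path(dir, "x"), "bogus"))
})
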
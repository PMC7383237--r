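toy_graph <- function(variants, classes = NULL, mode = "aa",
                      codon_model = "NNS") {
  if (is.null(classes)) classes <- rep("dark_green", length(variants))
  build_graph(variants, classes, mode = mode, codon_model = codon_model)
}

test_that("amino-acid mode joins variants at Hamming distance 1 only", {
  g <- toy_graph(c("RTAG", "QTAG", "QKAG"))
  el <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(el, c("QTAG-RTAG", "QKAG-QTAG"))
  expect_equal(igraph::V(g)$degree[igraph::V(g)$name == "QTAG"], 2)
  g1 <- toy_graph("RTAG")
  expect_equal(igraph::ecount(g1), 0)
  expect_warning(g0 <- build_graph(character(), character()), "empty")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("nt mode additionally requires a single-nucleotide codon change", {
  # G -> K needs two substitutions under NNS (GGG/GGC vs AAG): no edge
  g <- toy_graph(c("RTAG", "RTAK"), mode = "nt")
  expect_equal(igraph::ecount(g), 0)
  # R -> Q is one substitution (CGG vs CAG): edge present
  g2 <- toy_graph(c("RTAG", "QTAG"), mode = "nt")
  expect_equal(igraph::ecount(g2), 1)
  # gray nodes are excluded from the network
  g3 <- build_graph(c("RTAG", "QTAG"), c("dark_green", "gray"))
  expect_equal(igraph::vcount(g3), 1)
})

test_that("all shortest paths are enumerated on a toy square", {
  # RTAG - QTAG / RTAL - QTAL square: two geodesics of length 2
  g <- toy_graph(c("RTAG", "QTAG", "RTAL", "QTAL"))
  ens <- shortest_path_ensemble(g, "RTAG", target = "QTAL")
  expect_equal(unname(ens$dist["RTAG"]), 2)
  expect_equal(ens$n_paths, 2L)
  mids <- sort(vapply(ens$paths, `[`, character(1), 2))
  expect_equal(mids, c("QTAG", "RTAL"))
  # source equal to target: a single zero-length path
  ens0 <- shortest_path_ensemble(g, "QTAL", target = "QTAL")
  expect_equal(unname(ens0$dist), 0)
  expect_equal(ens0$n_paths, 1L)
  expect_equal(ens0$paths[[1]], "QTAL")
  # disconnected source: infinite distance, no paths
  g2 <- toy_graph(c("RTAG", "QTAG", "AAAA"))
  ens2 <- shortest_path_ensemble(g2, "AAAA", target = "QTAG")
  expect_equal(unname(ens2$dist), Inf)
  expect_equal(ens2$n_paths, 0L)
  expect_error(shortest_path_ensemble(g2, "RTAG", target = "WWWW"),
               "not in the graph")
})

test_that("shortest-path enumeration matches exhaustive DFS on random graphs", {
  set.seed(404)
  for (trial in 1:20) {
    n <- sample(4:12, 1)
    vars <- paste0("R", sample(AA_LETTERS, n), "A",
                   sample(AA_LETTERS, n))  # distinct labels
    vars <- unique(vars)[1:min(n, length(unique(vars)))]
    g <- igraph::sample_gnp(length(vars), 0.35)
    igraph::V(g)$name <- vars
    igraph::V(g)$class <- "black"
    st <- sample(vars, 2)
    ens <- shortest_path_ensemble(g, st[1], target = st[2])
    oracle <- dfs_all_shortest_paths(igraph_adj_list(g), st[1], st[2])
    expect_equal(unname(ens$dist), oracle$dist)
    expect_setequal(vapply(ens$paths, paste, character(1), collapse = ">"),
                    vapply(oracle$paths, paste, character(1), collapse = ">"))
  }
})

test_that("cumulative reach counts sources within k steps", {
  # line QKSG - QKTG - QKKG - QKKR plus an isolated source
  g <- toy_graph(c("QKKR", "QKKG", "QKTG", "QKSG", "RTAG"))
  # QKSG/QKTG differ at 184 from QKKG; QKSG-QKTG also adjacent (distance 1)
  ens <- shortest_path_ensemble(g, c("QKKG", "QKTG", "QKSG", "RTAG"),
                                target = "QKKR")
  expect_equal(unname(ens$dist), c(1, 2, 2, Inf))
  reach <- cumulative_reach(ens, max_steps = 4)
  expect_equal(unname(reach), c(0, 0.25, 0.75, 0.75, 0.75))
  expect_true(all(diff(reach) >= 0))
})

test_that("step features track residues along a known path", {
  chain <- c("RTAG", "RKAG", "RKAR", "QKAR", "QKKR")
  g <- toy_graph(chain)
  ens <- shortest_path_ensemble(g, "RTAG", target = "QKKR")
  expect_equal(ens$n_paths, 1L)
  sf <- step_feature_fractions(ens)
  expect_equal(unname(sf["1", "KR_179_or_184"]), 1)  # RKAG has K179
  expect_equal(unname(sf["1", "Q_173"]), 0)
  expect_equal(unname(sf["3", "Q_173"]), 1)          # QKAR
  expect_equal(unname(sf["2", "R_201"]), 1)          # RKAR
  # the target satisfies its own features at the final step
  expect_equal(unname(sf["4", "KR_179_or_184"]), 1)
  expect_equal(unname(sf["4", "Q_173"]), 1)
  expect_equal(unname(sf["4", "CTS_201"]), 0)
})

test_that("class traversal counts paths with intermediates of a class", {
  sq <- c("RTAG", "QTAG", "RTAL", "QTAL")
  g <- build_graph(sq, c("dark_green", "black", "light_green", "magenta"))
  ens <- shortest_path_ensemble(g, "RTAG", target = "QTAL")
  tr <- class_traversal(ens, g)
  expect_equal(unname(tr["black"]), 50)        # one of two intermediates
  expect_equal(unname(tr["light_green"]), 50)
  expect_equal(unname(tr["pink"]), 0)
  # length-1 paths have no intermediates
  ens1 <- shortest_path_ensemble(g, "QTAG", target = "QTAL")
  expect_equal(unname(ens1$dist), 1)
  expect_true(all(class_traversal(ens1, g) == 0))
})

test_that("edge shuffles preserve graph size and a fixed seed reproduces", {
  sq <- c("RTAG", "QTAG", "RTAL", "QTAL", "RKAG", "RSAG")
  cls <- c("dark_green", "black", "light_green", "magenta", "dark_green",
           "light_green")
  g <- build_graph(sq, cls)
  nd <- shuffle_null(g, "RTAG", target = "QTAL", n_shuffles = 50, seed = 3)
  expect_true(all(nd$edge_counts == igraph::ecount(g)))
  expect_true(all(nd$node_counts == igraph::vcount(g)))
  expect_equal(dim(nd$null), c(50L, 3L))
  # a class absent from the graph never gets traversed in any shuffle
  nd_p <- shuffle_null(g, "RTAG", target = "QTAL",
                       classes = "pink", n_shuffles = 30, seed = 5)
  expect_true(all(nd_p$null[, "pink"] == 0))
  nd2 <- shuffle_null(g, "RTAG", target = "QTAL", n_shuffles = 50, seed = 3)
  expect_identical(nd$null, nd2$null)
  expect_identical(nd$percentile, nd2$percentile)
})

test_that("the empirical percentile matches exhaustive graph enumeration", {
  # 4 labelled nodes, 4 edges: all C(6,4) = 15 simple graphs, equally likely
  sq <- c("RTAG", "QTAG", "RTAL", "QTAL")
  cls <- c("dark_green", "black", "light_green", "magenta")
  g <- build_graph(sq, cls)    # the square; black is one intermediate
  expect_equal(igraph::ecount(g), 4)
  stat_of <- function(gr) {
    ens <- shortest_path_ensemble(gr, "RTAG", target = "QTAL")
    unname(class_traversal(ens, setNames(cls, sq), "black"))
  }
  pairs <- t(combn(4, 2))
  stats_all <- apply(combn(6, 4), 2, function(idx) {
    gr <- igraph::graph_from_edgelist(
      matrix(sq[t(pairs[idx, ])], ncol = 2, byrow = TRUE), directed = FALSE)
    gr <- igraph::add_vertices(gr, sum(!sq %in% igraph::V(gr)$name),
                               name = sq[!sq %in% igraph::V(gr)$name])
    stat_of(gr)
  })
  obs <- stat_of(g)
  exact_pct <- 100 * mean(stats_all <= obs)
  nd <- shuffle_null(g, "RTAG", target = "QTAL", classes = "black",
                     n_shuffles = 4000, seed = 11)
  expect_equal(unname(nd$percentile["black"]), exact_pct, tolerance = 0.05)
})

test_that("graphs round-trip through GraphML export", {
  sq <- c("RTAG", "QTAG", "RTAL")
  g <- build_graph(sq, c("dark_green", "black", "light_green"))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g2)$name, sq)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  idx <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$class[idx], igraph::V(g)$class)
  expect_equal(igraph::V(g2)$degree[idx], unname(igraph::degree(g2)[idx]))
  # empty graph still yields a valid file
  f0 <- withr::local_tempfile(fileext = ".graphml")
  suppressWarnings(g0 <- build_graph(character(), character()))
  export_graph(g0, f0)
  expect_equal(igraph::vcount(igraph::read_graph(f0, format = "graphml")), 0)
})

test_that("geodesic distance is bounded below by Hamming distance", {
  fitv <- c("RTAG", "RKAG", "RKKG", "RKKR", "QKKR", "RTAL", "QTAG")
  g <- toy_graph(fitv)
  ens <- shortest_path_ensemble(g, setdiff(fitv, "QKKR"), target = "QKKR")
  hd <- hamming4(setdiff(fitv, "QKKR"), "QKKR")
  finite <- is.finite(ens$dist)
  expect_true(all(ens$dist[finite] >= hd[finite]))
  # with every intermediate present the bound is attained
  expect_equal(unname(ens$dist["RTAG"]), 4)
  expect_equal(unname(hamming4("RTAG", "QKKR")), 4L)
})
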
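ring_graph <- function(n, ns = "c://") {
  ids <- sprintf("%sv%d", ns, seq_len(n))
  data_graph(
    data.frame(id = ids, kind = "I", label = ids, source = "c",
               stringsAsFactors = FALSE),
    data.frame(from = ids, label = "related_disease",
               to = ids[c(2:n, 1)], stringsAsFactors = FALSE))
}

star_graph <- function(k, ns = "s://") {
  hub <- paste0(ns, "hub")
  leaves <- sprintf("%sleaf%d", ns, seq_len(k))
  data_graph(
    data.frame(id = c(hub, leaves), kind = "I", label = c(hub, leaves),
               source = "s", stringsAsFactors = FALSE),
    data.frame(from = hub, label = "related_disease", to = leaves,
               stringsAsFactors = FALSE))
}

test_that("centrality respects graph symmetry", {
  sc <- eigenvector_centrality(ring_graph(3))
  expect_equal(unname(sc), rep(1 / sqrt(3), 3), tolerance = 1e-7)
  sc2 <- eigenvector_centrality(star_graph(4))
  expect_gt(sc2[["s://hub"]], max(sc2[grep("leaf", names(sc2))]))
  expect_equal(unname(diff(range(sc2[grep("leaf", names(sc2))]))), 0,
               tolerance = 1e-7)
  expect_error(eigenvector_centrality(data_graph()), "empty")
})

test_that("centrality matches a dense eigendecomposition on random graphs", {
  set.seed(431)
  checked <- 0
  for (rep in 1:60) {
    n <- sample(10:60, 1)
    g <- random_relation_graph(n, stats::runif(1, 0.05, 0.3))
    ora <- oracle_centrality(g)
    if (is.null(ora)) next  # no unique dominant eigenvalue
    sc <- eigenvector_centrality(g)
    expect_lt(max(abs(sc[names(ora)] - ora)), 1e-6)
    checked <- checked + 1
  }
  expect_gt(checked, 40)
})

test_that("the expectation step is a closed-neighbourhood induced subgraph", {
  g <- ring_graph(6)
  ids <- instances(g)
  sub <- expectation_step(g, ids[1])
  expect_setequal(instances(sub), ids[c(6, 1, 2)])
  # the 6-1 and 1-2 edges survive, 2-3 does not
  expect_equal(nrow(sub$edges), 2)

  # an edge between two neighbours is retained (induced, not a star)
  tri <- data_graph(
    data.frame(id = c("t://c", "t://a", "t://b"), kind = "I",
               label = c("c", "a", "b"), source = "t",
               stringsAsFactors = FALSE),
    data.frame(from = c("t://c", "t://c", "t://a"),
               label = "related_disease",
               to = c("t://a", "t://b", "t://b"), stringsAsFactors = FALSE))
  sub2 <- expectation_step(tri, "t://c")
  expect_true(any(sub2$edges$from == "t://a" & sub2$edges$to == "t://b"))

  expect_error(expectation_step(g, "c://nope"), "unknown center")
})

test_that("an isolated center expands to itself alone", {
  g <- data_graph(
    data.frame(id = c("i://a", "i://b"), kind = "I", label = c("a", "b"),
               source = "i", stringsAsFactors = FALSE))
  sub <- expectation_step(g, "i://a")
  expect_equal(instances(sub), "i://a")
})

test_that("expectation step equals a brute-force set filter on random graphs", {
  set.seed(432)
  for (rep in 1:20) {
    g <- random_relation_graph(sample(10:40, 1), stats::runif(1, 0.05, 0.2))
    centers <- sample(instances(g), sample(1:4, 1))
    sub <- expectation_step(g, centers)
    expect_setequal(instances(sub), oracle_expectation(g, centers))
    # edges are exactly the induced ones
    keep <- instances(sub)
    want <- g$edges[g$edges$label != TYPE_LABEL &
                      g$edges$from %in% keep & g$edges$to %in% keep, ]
    got <- sub$edges[sub$edges$label != TYPE_LABEL, ]
    expect_equal(sort(paste(got$from, got$to)), sort(paste(want$from, want$to)))
  }
})

test_that("maximization step is a threshold filter on centrality", {
  single <- data_graph(
    data.frame(id = "m://v", kind = "I", label = "v", source = "m",
               stringsAsFactors = FALSE))
  expect_equal(maximization_step(single, 0.01), "m://v")
  # no L2-normalised score can exceed 1
  expect_length(maximization_step(ring_graph(5), 1.0), 0)
  set.seed(433)
  for (rep in 1:10) {
    g <- random_relation_graph(sample(10:40, 1), 0.15)
    ora <- oracle_centrality(g)
    if (is.null(ora)) next
    phi <- stats::runif(1, 0.01, 0.5)
    expect_setequal(maximization_step(g, phi), names(ora)[ora > phi])
  }
})

test_that("a dense closed component is a fixed point of the EM loop", {
  g <- merge_graphs(list(ring_graph(5, ns = "a://"), ring_graph(4, ns = "b://")))
  # fully connect component a so every member clears the threshold
  ids <- sprintf("a://v%d", 1:5)
  extra <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  extra <- extra[extra$from < extra$to, ]
  extra$label <- "related_disease"
  g <- data_graph(g$vertices, unique(rbind(g$edges, extra[c("from", "label", "to")])))
  res <- em_run(g, c("a://v1", "a://v2"))
  expect_setequal(instances(res$graph), ids)
  expect_lte(attr(res$trace, "iterations"), 2)
  expect_true(attr(res$trace, "converged"))
})

test_that("extraction is deterministic and confined to the input graph", {
  pp <- planted_partition_graph(n_topic = 40, n_background = 160,
                                p_in = 0.25, p_out = 0.02, seed = 434)
  seeds <- pp$topic[1:3]
  g1 <- extract_topic_kb(pp$graph, seeds)
  g2 <- extract_topic_kb(pp$graph, seeds)
  expect_identical(g1, g2)
  expect_true(all(instances(g1) %in% instances(pp$graph)))
  expect_error(extract_topic_kb(pp$graph, "bench://inst/9999"), "not found")
})

test_that("raising phi_c never increases the selected centers", {
  set.seed(435)
  g <- random_relation_graph(40, 0.15)
  prev <- Inf
  for (phi in c(0.01, 0.05, 0.1, 0.3, 0.9)) {
    k <- length(maximization_step(g, phi))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("the trace ends with the delivered subgraph and plateaus", {
  pp <- planted_partition_graph(n_topic = 40, n_background = 160,
                                p_in = 0.25, p_out = 0.02, seed = 436)
  res <- em_run(pp$graph, pp$topic[1:3])
  tr <- res$trace
  last <- tr[tr$stage == "final", ]
  expect_equal(last$n_vertices, nrow(res$graph$vertices))
  expect_equal(last$n_edges, nrow(res$graph$edges))
  expect_equal(iteration_trace(pp$graph, pp$topic[1:3]), tr)
  it <- tr[tr$stage == "iterate", ]
  expect_true(all(diff(it$n_vertices) >= 0))
  expect_true(attr(tr, "converged"))
})

test_that("attribute and type edges are re-attached to surviving instances", {
  pp <- planted_partition_graph(n_topic = 30, n_background = 50,
                                p_in = 0.3, p_out = 0.01, seed = 437)
  g <- pp$graph
  # give one topic instance an alias value
  g <- data_graph(
    rbind(g$vertices, data.frame(id = "bench://val/1", kind = "V",
                                 label = "an alias", source = "bench",
                                 stringsAsFactors = FALSE)),
    rbind(g$edges, data.frame(from = pp$topic[1], label = "alias",
                              to = "bench://val/1", stringsAsFactors = FALSE)))
  out <- extract_topic_kb(g, pp$topic[1:3])
  expect_true(pp$topic[1] %in% instances(out))
  expect_true("bench://val/1" %in% out$vertices$id)
  expect_true(any(out$edges$label == "alias"))
  expect_true(all(instances(out) %in%
                    type_edges(out)$from))  # every instance keeps its type
})
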
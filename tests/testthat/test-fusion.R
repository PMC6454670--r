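# A tiny three-portal scene used by several cleansing tests: the same
# renal-obstruction instance is described as a Symptom by one portal and as
# a Disease by two others.
conflict_scene <- function(third_class = "Disease") {
  mk <- function(tag, cls) {
    data_graph(
      data.frame(id = paste0(tag, "://h1"), kind = "I",
                 label = "hydronephrosis", source = tag,
                 stringsAsFactors = FALSE),
      data.frame(from = paste0(tag, "://h1"), label = TYPE_LABEL, to = cls,
                 stringsAsFactors = FALSE))
  }
  integrated_data_graph(list(mk("pa", "Symptom"), mk("pb", "Disease"),
                             mk("pc", third_class)))
}

small_codes <- function(labels = character(0)) {
  if (!length(labels)) return(reference_code_list())
  reference_code_list(data.frame(
    code = sprintf("C%02d", seq_along(labels)), label = labels,
    aliases = "", stringsAsFactors = FALSE))
}

test_that("reference lookup is exact-match only and returns Disease", {
  codes <- reference_code_list(data.frame(
    code = c("E11", "E12"), label = c("type 2 diabetes", "gestational diabetes"),
    aliases = c("t2d|adult-onset diabetes", ""), stringsAsFactors = FALSE))
  expect_equal(reference_lookup("Type 2 Diabetes", codes), "Disease")
  expect_equal(reference_lookup("T2D", codes), "Disease")
  expect_equal(reference_lookup("type 2 diabetic", codes), NA_character_)
})

test_that("lookup finds exactly the planted labels among distractors", {
  set.seed(421)
  planted <- sprintf("planted disease %03d", 1:100)
  others <- sprintf("background term %03d", 1:900)
  codes <- small_codes(planted)
  hits <- vapply(sample(c(planted, others)), function(l)
    reference_lookup(l, codes), "")
  expect_equal(sum(hits == "Disease", na.rm = TRUE), 100)
  expect_setequal(names(hits)[!is.na(hits)], planted)
})

test_that("vote_class picks the majority share", {
  v <- vote_class(c(Disease = 3L, Symptom = 2L))
  expect_equal(v$class, "Disease")
  expect_equal(v$score, 0.6)
  v2 <- vote_class(c(Disease = 1L))
  expect_equal(v2$class, "Disease")
  expect_equal(v2$score, 1)
  expect_error(vote_class(integer(0)), "empty")
})

test_that("vote_class equals brute-force argmax on random tallies", {
  set.seed(422)
  for (rep in 1:1000) {
    tally <- random_tally()
    got <- vote_class(tally)
    want <- oracle_vote(as.list(tally))
    expect_equal(got$class, want$class)
    expect_equal(got$score, want$score)
  }
})

test_that("voting resolves conflicts by source majority", {
  cl <- cleanse_classes(conflict_scene("Disease"), small_codes(),
                        default_diabetes_schema())
  rpt <- attr(cl, "report")
  expect_equal(rpt$winner, "Disease")
  expect_equal(rpt$method, "vote")
  for (g in cl$graphs)
    expect_equal(type_edges(g)$to, "Disease")
})

test_that("a code-list hit overrides a unanimous vote", {
  ig <- conflict_scene("Symptom")  # symptom majority 2:1
  codes <- small_codes("hydronephrosis")
  cl <- cleanse_classes(ig, codes, default_diabetes_schema())
  rpt <- attr(cl, "report")
  expect_equal(rpt$method, "lookup")
  expect_equal(rpt$winner, "Disease")
  # voting-only would have gone the other way
  cl2 <- cleanse_classes(ig, codes, default_diabetes_schema(), method = "vote")
  expect_equal(attr(cl2, "report")$winner, "Symptom")
})

test_that("cleansing removes disjointness violations and is idempotent", {
  cfg <- corpus_config(n_portals = 5L, coverage = default_coverage(5L),
                       instances_per_class = c(
                         Disease = 60L, Symptom = 40L, WesternMedicine = 15L,
                         TCM = 10L, Examination = 10L, Department = 5L,
                         BodyStructure = 10L),
                       topic_size = 25L, duplication_rate = 0.5,
                       class_flip_rate = 0.1, seed = 423L)
  corpus <- generate_corpus(cfg)
  s <- default_diabetes_schema()
  pg <- lapply(corpus$dumps, function(d) {
    tabs <- extract_tables(d)
    d2r_materialize(tabs$class_table,
                    c(list(label = tabs$label_table), tabs$relation_tables),
                    s, paste0(d$source, "://"), d$source)
  })
  cl <- cleanse_classes(integrated_data_graph(pg), corpus$codes, s)
  rpt <- attr(cl, "report")
  expect_gt(nrow(rpt), 0)
  expect_true(all(rpt$resolved))
  # no same-label instance set carries disjoint classes any more
  merged <- merge_graphs(cl$graphs)
  lab <- stats::setNames(merged$vertices$label, merged$vertices$id)
  te <- type_edges(merged)
  by_label <- split(te$to, normalize_label(unname(lab[te$from])))
  djkey <- with(disjoint_pairs(s), paste(a, b))
  for (cls in by_label) {
    u <- unique(cls)
    pairs <- paste(rep(u, each = length(u)), rep(u, length(u)))
    expect_false(any(pairs %in% djkey))
  }
  # idempotence: a second pass changes nothing
  cl2 <- cleanse_classes(cl, corpus$codes, s)
  for (k in seq_along(cl$graphs))
    expect_identical(cl2$graphs[[k]]$edges, cl$graphs[[k]]$edges)
  expect_equal(nrow(attr(cl2, "report")), 0)
})

test_that("identical instances match with score 1; disjoint classes never pair", {
  mk <- function(tag, cls) {
    data_graph(
      data.frame(id = paste0(tag, c("://x", "://n1")), kind = "I",
                 label = c("ketoacidosis", "neighbour one"), source = tag,
                 stringsAsFactors = FALSE),
      data.frame(from = paste0(tag, c("://x", "://n1", "://x")),
                 label = c(TYPE_LABEL, TYPE_LABEL, "related_disease"),
                 to = c(cls, "Disease", paste0(tag, "://n1")),
                 stringsAsFactors = FALSE))
  }
  m <- match_instances(mk("a", "Disease"), mk("b", "Disease"))
  expect_equal(nrow(m), 2)  # x-x and n1-n1 both perfect
  expect_true(all(m$score == 1))
  m2 <- match_instances(mk("a", "Disease"), mk("b", "Symptom"))
  expect_false(any(grepl("://x", m2$v1)))
})

test_that("matching agrees with an exhaustive all-pairs oracle on twin portals", {
  cfg <- corpus_config(n_portals = 2L, coverage = matrix(
    TRUE, 2, 7, dimnames = list(NULL, colnames(default_coverage()))),
    instances_per_class = c(Disease = 40L, Symptom = 25L,
                            WesternMedicine = 10L, TCM = 8L, Examination = 7L,
                            Department = 4L, BodyStructure = 6L),
    topic_size = 20L, duplication_rate = 1, alias_rate = 0.2,
    class_flip_rate = 0, seed = 424L)
  corpus <- generate_corpus(cfg)
  s <- default_diabetes_schema()
  pg <- lapply(corpus$dumps, function(d) {
    tabs <- extract_tables(d)
    d2r_materialize(tabs$class_table,
                    c(list(label = tabs$label_table), tabs$relation_tables),
                    s, paste0(d$source, "://"), d$source)
  })
  cfg_m <- match_config()
  m <- match_instances(pg[[1]], pg[[2]], cfg_m)
  # oracle: score every cross pair, apply blocking, threshold and greedy
  f1 <- instance_features(pg[[1]])
  f2 <- instance_features(pg[[2]])
  rows <- list()
  for (a in f1$ids) for (b in f2$ids) {
    if (is.na(f1$class[a]) || is.na(f2$class[b])) next
    if (f1$class[a] != f2$class[b]) next
    if (substr(f1$label[a], 1, 1) != substr(f2$label[b], 1, 1)) next
    syn <- name_similarity(f1$names[[a]], f2$names[[b]])
    str <- jaccard(f1$nbrs[[a]], f2$nbrs[[b]])
    sc <- cfg_m$w_syntactic * syn + cfg_m$w_structural * str
    if (sc >= cfg_m$threshold)
      rows[[length(rows) + 1L]] <- data.frame(v1 = a, v2 = b, score = sc,
                                              stringsAsFactors = FALSE)
  }
  ora <- do.call(rbind, rows)
  ora <- ora[order(-ora$score, ora$v1, ora$v2), ]
  u1 <- character(0); u2 <- character(0); keep <- logical(nrow(ora))
  for (i in seq_len(nrow(ora))) {
    if (ora$v1[i] %in% u1 || ora$v2[i] %in% u2) next
    keep[i] <- TRUE; u1 <- c(u1, ora$v1[i]); u2 <- c(u2, ora$v2[i])
  }
  ora <- ora[keep, ]
  expect_equal(nrow(m), nrow(ora))
  expect_setequal(paste(m$v1, m$v2), paste(ora$v1, ora$v2))
  # recovered pairs against planted duplicates are mostly correct
  sc <- score_recovery(m, corpus$truth, "matching")
  expect_gt(sc$precision, 0.9)
  expect_gt(sc$recall, 0.5)
})

test_that("fuse unions edges of matched instances", {
  ga <- data_graph(
    data.frame(id = c("a://x", "a://p", "a://q", "a://r"), kind = "I",
               label = c("x", "p", "q", "r"), source = "a",
               stringsAsFactors = FALSE),
    data.frame(from = "a://x", label = "related_disease",
               to = c("a://p", "a://q", "a://r"), stringsAsFactors = FALSE))
  gb <- data_graph(
    data.frame(id = c("b://x", "b://p", "b://s", "b://t", "b://u"), kind = "I",
               label = c("x", "p", "s", "t", "u"), source = "b",
               stringsAsFactors = FALSE),
    data.frame(from = "b://x", label = "related_disease",
               to = c("b://p", "b://s", "b://t", "b://u"),
               stringsAsFactors = FALSE))
  maps <- data.frame(v1 = c("a://x", "a://p"), v2 = c("b://x", "b://p"),
                     score = 1, stringsAsFactors = FALSE)
  fz <- fuse(integrated_data_graph(list(ga, gb), maps))
  # 3 + 4 distinct neighbour edges with 1 shared -> 6 edges from the fused x
  xe <- fz$edges[fz$edges$from == "a://x", ]
  expect_equal(nrow(xe), 6)
  expect_equal(sort(unique(fz$vertices$source[fz$vertices$id == "a://x"])), "a,b")
})

test_that("mapping chains collapse into one cluster", {
  mk <- function(tag) data_graph(
    data.frame(id = paste0(tag, "://x"), kind = "I", label = "x",
               source = tag, stringsAsFactors = FALSE))
  maps <- data.frame(v1 = c("a://x", "b://x"), v2 = c("b://x", "c://x"),
                     score = 1, stringsAsFactors = FALSE)
  fz <- fuse(integrated_data_graph(list(mk("a"), mk("b"), mk("c")), maps))
  expect_equal(fz$vertices$id, "a://x")
  expect_equal(fz$vertices$source, "a,b,c")
})

test_that("fused instance count matches a union-find oracle", {
  set.seed(425)
  graphs <- lapply(1:4, function(k) random_relation_graph(12, 0.2,
                                                          ns = sprintf("f%d://", k)))
  ids <- unlist(lapply(graphs, instances))
  # random cross-source mapping assertions
  maps <- do.call(rbind, lapply(1:10, function(i) {
    ks <- sample(4, 2)
    data.frame(v1 = sample(instances(graphs[[ks[1]]]), 1),
               v2 = sample(instances(graphs[[ks[2]]]), 1),
               score = 1, stringsAsFactors = FALSE)
  }))
  fz <- fuse(integrated_data_graph(graphs, maps))
  expect_equal(sum(fz$vertices$kind == "I"), oracle_union_find(ids, maps))
  expect_lt(sum(fz$vertices$kind == "I"), length(ids))
  # fusion never increases the number of distinct triples
  merged <- merge_graphs(graphs)
  expect_lte(nrow(fz$edges), nrow(merged$edges))
})

test_that("fuse refuses clusters spanning disjoint classes", {
  mk <- function(tag, cls) data_graph(
    data.frame(id = paste0(tag, "://x"), kind = "I", label = "x",
               source = tag, stringsAsFactors = FALSE),
    data.frame(from = paste0(tag, "://x"), label = TYPE_LABEL, to = cls,
               stringsAsFactors = FALSE))
  maps <- data.frame(v1 = "a://x", v2 = "b://x", score = 1,
                     stringsAsFactors = FALSE)
  expect_error(fuse(integrated_data_graph(list(mk("a", "Disease"),
                                               mk("b", "Symptom")), maps)),
               "disjoint")
})
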
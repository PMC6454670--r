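toy_dump <- function() {
  nav <- data.frame(
    identifier = c("iixtnb", "gxy", "polyd"),
    label = c("Type 2 Diabetes", "Hypertension", "Polydipsia"),
    class = c("Disease", "Disease", "Symptom"),
    stringsAsFactors = FALSE)
  records <- list(
    iixtnb = list(
      list(kind = "list", topic = "Common Complications",
           payload = "Hypertension"),
      list(kind = "table", topic = "symptom overview",
           payload = c("Polydipsia", "Weight Loss")),
      list(kind = "infobox", topic = "also known as",
           payload = c("T2D", "adult-onset diabetes")),
      list(kind = "list", topic = "sponsored content", payload = "junk")))
  portal_dump("p39", nav, records)
}

test_that("topic sentences map to properties by heuristic-word containment", {
  lex <- default_lexicon()
  expect_equal(map_entry_to_property("Common Complications", lex),
               "complication")
  expect_equal(map_entry_to_property("", lex), NA_character_)
  expect_equal(map_entry_to_property("totally unrelated text", lex),
               NA_character_)
  # priority order decides multi-hit sentences
  lex2 <- heuristic_lexicon(list(a = "alpha", b = c("beta", "alpha")))
  expect_equal(map_entry_to_property("alpha beta", lex2), "a")
})

test_that("map_entry_to_property matches an exhaustive scan on random input", {
  set.seed(411)
  words <- c("fever", "cough", "ache", "scan", "dose", "clinic", "organ")
  for (rep in 1:50) {
    lex <- heuristic_lexicon(stats::setNames(
      lapply(1:4, function(i) sample(words, sample(1:3, 1))),
      paste0("prop", sample(4))))
    sentence <- paste(sample(c(words, "noise", "filler"), sample(0:4, 1),
                             replace = TRUE), collapse = " ")
    expect_equal(map_entry_to_property(sentence, lex),
                 oracle_map_entry(sentence, lex))
  }
})

test_that("extract_tables rewrites entries into single-property tables", {
  tabs <- extract_tables(toy_dump())
  expect_equal(tabs$class_table$rows,
               data.frame(subject = c("iixtnb", "gxy", "polyd"),
                          object = c("Disease", "Disease", "Symptom"),
                          stringsAsFactors = FALSE))
  comp <- tabs$relation_tables$complication$rows
  expect_equal(comp, data.frame(subject = "iixtnb", object = "Hypertension",
                                stringsAsFactors = FALSE))
  expect_equal(nrow(tabs$relation_tables$sign$rows), 2)
  expect_equal(nrow(tabs$relation_tables$alias$rows), 2)
  expect_equal(unname(tabs$skipped["unmapped_entries"]), 1L)
  # every table is two columns and one property
  for (pt in tabs$relation_tables) {
    expect_s3_class(pt, "property_table")
    expect_named(pt$rows, c("subject", "object"))
  }
})

test_that("a dump with no detail records yields only class and label tables", {
  d <- portal_dump("p", data.frame(identifier = "x", label = "X",
                                   class = "Disease",
                                   stringsAsFactors = FALSE))
  tabs <- extract_tables(d)
  expect_length(tabs$relation_tables, 0)
  expect_equal(nrow(tabs$class_table$rows), 1)
})

test_that("total extracted rows equal a brute-force payload count", {
  set.seed(412)
  cfg <- corpus_config(n_portals = 2L, instances_per_class = c(
    Disease = 40L, Symptom = 25L, WesternMedicine = 10L, TCM = 8L,
    Examination = 7L, Department = 4L, BodyStructure = 6L),
    topic_size = 20L, coverage = default_coverage(2L), seed = 412L)
  corpus <- generate_corpus(cfg)
  lex <- default_lexicon()
  for (d in corpus$dumps) {
    tabs <- extract_tables(d, lex)
    got <- sum(vapply(tabs$relation_tables, function(pt) nrow(pt$rows), 0L))
    # extract_tables dedupes (subject, object) within a property
    expect_lte(got, oracle_mapped_payload_count(d, lex))
    expect_gte(got, 1L)
    dedup_gap <- oracle_mapped_payload_count(d, lex) - got
    expect_equal(dedup_gap, oracle_dedup_gap(d, lex))
  }
})

test_that("empty payload values are skipped and counted", {
  nav <- data.frame(identifier = "a", label = "A", class = "Disease",
                    stringsAsFactors = FALSE)
  d <- portal_dump("p", nav, list(a = list(
    list(kind = "list", topic = "common complication",
         payload = c("", "B", "")))))
  tabs <- extract_tables(d)
  expect_equal(unname(tabs$skipped["empty_values"]), 2L)
  expect_equal(nrow(tabs$relation_tables$complication$rows), 1)
})

test_that("d2r materialisation types instances and resolves objects", {
  s <- default_diabetes_schema()
  ct <- property_table(TYPE_LABEL, data.frame(
    subject = c("d1", "s1"), object = c("Disease", "Symptom"),
    stringsAsFactors = FALSE))
  lt <- property_table("label", data.frame(
    subject = c("d1", "s1"), object = c("diabetes", "polydipsia"),
    stringsAsFactors = FALSE))
  rt <- list(label = lt,
             sign = property_table("sign", data.frame(
               subject = "d1", object = c("polydipsia", "night sweats"),
               stringsAsFactors = FALSE)))
  g <- d2r_materialize(ct, rt, s, "p://")
  expect_equal(sum(g$vertices$kind == "I"), 2)
  # resolved object becomes an instance-to-instance edge
  expect_true(any(g$edges$from == "p://d1" & g$edges$label == "sign" &
                    g$edges$to == "p://s1"))
  # unresolved object becomes a value vertex
  vids <- g$vertices$id[g$vertices$kind == "V"]
  expect_length(vids, 1)
  expect_equal(g$vertices$label[g$vertices$id == vids], "night sweats")
  expect_equal(nrow(validate_graph(g, s)), 0)
  expect_true(all(g$vertices$source == "p"))
})

test_that("unknown class labels are quarantined, not fatal", {
  s <- default_diabetes_schema()
  ct <- property_table(TYPE_LABEL, data.frame(
    subject = c("a", "b"), object = c("Disease", "Mystery"),
    stringsAsFactors = FALSE))
  g <- d2r_materialize(ct, list(), s, "p://")
  expect_equal(sum(g$vertices$kind == "I"), 1)
  rej <- attr(g, "rejects")
  expect_equal(rej$subject, "b")
  expect_match(rej$reason, "unknown class")
})

test_that("materialisation equals row-by-row translation on random tables", {
  s <- default_diabetes_schema()
  set.seed(413)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    subj <- sprintf("i%02d", seq_len(n))
    labs <- sprintf("label %02d %d", seq_len(n), rep)
    ct <- property_table(TYPE_LABEL, data.frame(
      subject = subj, object = sample(c("Disease", "Symptom"), n, TRUE),
      stringsAsFactors = FALSE))
    lt <- property_table("label", data.frame(subject = subj, object = labs,
                                             stringsAsFactors = FALSE))
    rows <- data.frame(
      subject = sample(subj, 20, TRUE),
      object = sample(c(labs, "free text value"), 20, TRUE),
      stringsAsFactors = FALSE)
    g <- d2r_materialize(ct, list(label = lt,
                                  related_disease = property_table("related_disease", rows)),
                         s, "q://")
    # oracle: every unique row becomes exactly one edge; object resolved
    # iff it is a known label
    urows <- rows[!duplicated(rows), ]
    rel <- g$edges[g$edges$label == "related_disease", ]
    expect_equal(nrow(rel), nrow(urows))
    kind <- stats::setNames(g$vertices$kind, g$vertices$id)
    for (k in seq_len(nrow(urows))) {
      resolved <- urows$object[k] %in% labs
      hit <- rel$from == paste0("q://", urows$subject[k]) &
        (if (resolved) rel$to == g$vertices$id[match(urows$object[k], g$vertices$label)]
         else kind[rel$to] == "V")
      expect_true(any(hit))
    }
  }
})

test_that("materialise then re-partition reproduces the tables", {
  s <- default_diabetes_schema()
  tabs <- extract_tables(toy_dump())
  g <- d2r_materialize(tabs$class_table,
                       c(list(label = tabs$label_table), tabs$relation_tables),
                       s, "p39://")
  back <- partition_graph(g, "p39://")
  sort_rows <- function(pt) {
    r <- pt$rows[order(pt$rows$subject, pt$rows$object), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(sort_rows(back$class_table), sort_rows(tabs$class_table))
  expect_equal(sort_rows(back$label_table), sort_rows(tabs$label_table))
  expect_setequal(names(back$relation_tables), names(tabs$relation_tables))
  for (p in names(tabs$relation_tables))
    expect_equal(sort_rows(back$relation_tables[[p]]),
                 sort_rows(tabs$relation_tables[[p]]),
                 info = p)
})
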
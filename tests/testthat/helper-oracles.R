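# Independent oracles and random-fixture builders for the test suite.
# Oracles are deliberately written as naive enumerations, independent of the
# package's implementation paths.

# ---- random fixtures ------------------------------------------------------

random_data_graph <- function(n_inst = 20, n_val = 5, n_edge = 40,
                              schema = default_diabetes_schema(),
                              p_bad = 0) {
  classes <- schema_classes(schema)
  rels <- schema_relations(schema)
  iid <- sprintf("t://i%03d", seq_len(n_inst))
  vid <- if (n_val) sprintf("t://v%03d", seq_len(n_val)) else character(0)
  vertices <- rbind(
    data.frame(id = iid, kind = "I", label = sprintf("inst %03d", seq_len(n_inst)),
               source = "t", stringsAsFactors = FALSE),
    if (n_val) data.frame(id = vid, kind = "V",
                          label = sprintf("val %03d", seq_len(n_val)),
                          source = "t", stringsAsFactors = FALSE))
  cls <- sample(classes, n_inst, replace = TRUE)
  edges <- data.frame(from = iid, label = TYPE_LABEL, to = cls,
                      stringsAsFactors = FALSE)
  # a fraction of deliberately ill-formed assertions exercises every rule
  if (p_bad > 0 && stats::runif(1) < 0.8) {
    k <- max(1, round(p_bad * n_inst))
    dup <- sample(iid, k)
    edges <- rbind(edges, data.frame(
      from = dup, label = TYPE_LABEL,
      to = sample(c(classes, "Bogus"), k, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_edge)) {
    lab <- sample(c(rels, "alias", if (p_bad > 0) "undeclared_prop"), 1,
                  prob = c(rep(1, length(rels)), 1, if (p_bad > 0) p_bad))
    from <- sample(c(iid, if (p_bad > 0 && n_val) vid), 1)
    to <- if (lab == "alias" && n_val) sample(vid, 1) else
      sample(c(iid, if (n_val) vid), 1)
    edges <- rbind(edges, data.frame(from = from, label = lab, to = to,
                                     stringsAsFactors = FALSE))
  }
  data_graph(vertices, unique(edges))
}

random_relation_graph <- function(n, p, seed = NULL,
                                  ns = sprintf("r%03d://", sample.int(999, 1))) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("%si%03d", ns, seq_len(n))
  vertices <- data.frame(id = ids, kind = "I",
                         label = sprintf("node %03d", seq_len(n)),
                         source = sub("://.*$", "", ns),
                         stringsAsFactors = FALSE)
  pair <- utils::combn(n, 2)
  drawn <- which(stats::runif(ncol(pair)) < p)
  edges <- rbind(
    data.frame(from = ids, label = TYPE_LABEL, to = "Disease",
               stringsAsFactors = FALSE),
    if (length(drawn))
      data.frame(from = ids[pair[1, drawn]], label = "related_disease",
                 to = ids[pair[2, drawn]], stringsAsFactors = FALSE))
  data_graph(vertices, edges)
}

# ---- kb_model oracles -----------------------------------------------------

# rule-by-rule enumeration mirroring the documented restrictions
oracle_validate <- function(g, schema) {
  out <- list()
  emit <- function(rule, subject) out[[length(out) + 1L]] <<-
    c(rule = rule, subject = subject)
  kind <- stats::setNames(g$vertices$kind, g$vertices$id)
  classes <- schema_classes(schema)
  rels <- schema_relations(schema)
  attrs <- schema_attributes(schema)
  anc <- function(cl) {
    res <- cl
    repeat {
      sub <- schema$edges[schema$edges$label == "rdfs:subClassOf" &
                            schema$edges$from %in% res, "to"]
      new <- setdiff(sub, res)
      if (!length(new)) return(res)
      res <- c(res, new)
    }
  }
  dj <- schema$edges[schema$edges$label == "owl:disjointWith", c("from", "to")]
  disjointq <- function(c1, c2)
    any(dj$from == c1 & dj$to == c2) || any(dj$from == c2 & dj$to == c1)
  dom <- function(p) schema$edges[schema$edges$label == "rdfs:domain" &
                                    schema$edges$from == p, "to"]
  rng <- function(p) schema$edges[schema$edges$label == "rdfs:range" &
                                    schema$edges$from == p, "to"]
  types <- function(x) g$edges$to[g$edges$label == TYPE_LABEL & g$edges$from == x]

  for (i in seq_len(nrow(g$edges))) {
    s <- g$edges$from[i]; p <- g$edges$label[i]; o <- g$edges$to[i]
    if (!s %in% names(kind)) { emit("edge-kind", s); next }
    if (p == TYPE_LABEL) {
      if (kind[[s]] != "I") emit("edge-kind", s)
      if (!o %in% classes) emit("type-target", s)
      next
    }
    if (!p %in% c(rels, attrs)) { emit("edge-kind", s); next }
    if (!o %in% names(kind)) { emit("edge-kind", s); next }
    if (kind[[s]] != "I") emit("edge-kind", s)
    if (p %in% attrs && kind[[o]] != "V") emit("edge-kind", s)
    st <- types(s)
    st <- st[st %in% classes]
    if (length(st) && length(dom(p))) {
      ok <- FALSE
      for (t in st) if (length(intersect(anc(t), dom(p)))) ok <- TRUE
      if (!ok) emit("domain", s)
    }
    if (p %in% rels && o %in% names(kind) && kind[[o]] == "I") {
      ot <- types(o)
      ot <- ot[ot %in% classes]
      r <- rng(p)
      if (length(ot) && length(r)) {
        ok <- FALSE
        for (t in ot) if (r %in% anc(t)) ok <- TRUE
        if (!ok) emit("range", o)
      }
    }
  }
  for (s in unique(g$edges$from[g$edges$label == TYPE_LABEL])) {
    tys <- unique(types(s))
    tys <- tys[tys %in% classes]
    if (length(tys) < 2) next
    for (a in seq_along(tys)) for (b in seq_along(tys)) {
      if (a >= b) next
      hit <- FALSE
      for (x in anc(tys[a])) for (y in anc(tys[b]))
        if (disjointq(x, y)) hit <- TRUE
      if (hit) emit("disjoint", s)
    }
  }
  if (!length(out)) return(data.frame(rule = character(0), subject = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  df[order(df$rule, df$subject), ]
}

violation_key <- function(v) {
  v <- v[order(v$rule, v$subject), c("rule", "subject")]
  rownames(v) <- NULL
  v
}

# ---- extraction oracles ---------------------------------------------------

oracle_map_entry <- function(sentence, lexicon) {
  s <- gsub("[[:space:]]+", " ", tolower(trimws(sentence)))
  if (!nzchar(s)) return(NA_character_)
  for (prop in names(lexicon))
    for (w in lexicon[[prop]])
      if (grepl(w, s, fixed = TRUE)) return(prop)
  NA_character_
}

# count of rows every mapped entry should contribute (dedup ignored)
oracle_mapped_payload_count <- function(dump, lexicon) {
  n <- 0L
  for (id in names(dump$records))
    for (e in dump$records[[id]]) {
      if (is.na(oracle_map_entry(e$topic, lexicon))) next
      n <- n + sum(nzchar(e$payload))
    }
  n
}

# duplicated (property, subject, object) payload rows the extractor drops
oracle_dedup_gap <- function(dump, lexicon) {
  rows <- character(0)
  for (id in names(dump$records))
    for (e in dump$records[[id]]) {
      prop <- oracle_map_entry(e$topic, lexicon)
      if (is.na(prop)) next
      vals <- e$payload[nzchar(e$payload)]
      rows <- c(rows, paste(prop, id, vals, sep = "\r"))
    }
  length(rows) - length(unique(rows))
}

# ---- fusion oracles -------------------------------------------------------

oracle_vote <- function(tally) {
  best <- -Inf; winners <- character(0)
  for (cl in names(tally)) {
    if (tally[[cl]] > best) { best <- tally[[cl]]; winners <- cl }
    else if (tally[[cl]] == best) winners <- c(winners, cl)
  }
  cls <- if ("Disease" %in% winners) "Disease" else sort(winners)[1]
  list(class = cls, score = best / sum(unlist(tally)))
}

random_tally <- function() {
  classes <- c("Disease", "Symptom", "TCM", "WesternMedicine",
               "Department", "BodyStructure", "Examination")
  k <- sample(1:4, 1)
  tally <- sample(1:8, k, replace = TRUE)
  names(tally) <- sample(classes, k)
  tally
}

oracle_union_find <- function(ids, pairs) {
  comp <- stats::setNames(seq_along(ids), ids)
  for (i in seq_len(nrow(pairs))) {
    ca <- comp[[pairs$v1[i]]]; cb <- comp[[pairs$v2[i]]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  length(unique(comp))
}

# ---- em oracles -----------------------------------------------------------

# dense dominant eigenvector of the relation projection; NULL when the
# dominant eigenvalue is insufficiently separated for the iterative scheme
# to be well-posed within its iteration budget (ratio of the two largest
# shifted eigenvalues above 0.95)
oracle_centrality <- function(g, max_ratio = 0.95) {
  ids <- instances(g)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- g$edges[g$edges$label != TYPE_LABEL, , drop = FALSE]
  e <- e[e$from %in% ids & e$to %in% ids, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    A[e$from[i], e$to[i]] <- 1
    A[e$to[i], e$from[i]] <- 1
  }
  if (sum(A) == 0) return(rep(1 / sqrt(n), n))
  eg <- eigen(A, symmetric = TRUE)
  vals <- eg$values
  if ((vals[2] + 1) / (vals[1] + 1) > max_ratio) return(NULL)
  v <- abs(eg$vectors[, 1])
  stats::setNames(v / sqrt(sum(v^2)), ids)
}

oracle_expectation <- function(g, centers) {
  kind <- stats::setNames(g$vertices$kind, g$vertices$id)
  rel <- g$edges[g$edges$label != TYPE_LABEL, , drop = FALSE]
  rel <- rel[kind[rel$from] == "I" & !is.na(kind[rel$to]) & kind[rel$to] == "I", ]
  keep <- centers
  for (c in centers)
    keep <- union(keep, c(rel$to[rel$from == c], rel$from[rel$to == c]))
  sort(keep)
}

jaccard_sets <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# ---- misc -----------------------------------------------------------------

spo_set <- function(g) {
  lab <- stats::setNames(g$vertices$label, g$vertices$id)
  kind <- stats::setNames(g$vertices$kind, g$vertices$id)
  o <- ifelse(!is.na(kind[g$edges$to]) & kind[g$edges$to] == "V",
              paste0("lit:", lab[g$edges$to]), g$edges$to)
  sort(paste(g$edges$from, g$edges$label, o))
}

expect_same_graph_size <- function(a, b) {
  testthat::expect_equal(nrow(a$vertices), nrow(b$vertices))
  testthat::expect_equal(nrow(a$edges), nrow(b$edges))
}
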
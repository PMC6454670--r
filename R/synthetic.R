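# Synthetic corpora with planted ground truth: a master KB with a dense
# topic community, noisy multi-portal views (coverage gaps, duplicates,
# aliases, class flips), a reference code list, and recovery scoring.

#' Corpus configuration
#'
#' Defaults mirror the study conditions the pipeline targets: eight portals
#' whose class coverage reproduces the observed portal coverage pattern
#' (all portals carry diseases, symptoms, departments and body structures;
#' examinations appear in three portals; one portal lacks medicines
#' entirely and one carries only western medicine), a 1000-instance master
#' KB with a 150-instance topic community (internal edge probability 0.2
#' against a 0.01 background), instance duplication across portals tuned to
#' the observed duplication extent (~1.9 copies per instance), a 0.2 alias
#' substitution rate, a 0.1 class-flip rate with 90% of flips being
#' disease/symptom confusions, and a reference code list covering 60% of
#' disease labels.
#'
#' @param n_portals Number of portal views.
#' @param portals Portal source tags.
#' @param coverage Logical matrix `n_portals x 7` (rows = portals, columns
#'   = leaf classes) saying which classes each portal carries.
#' @param instances_per_class Named integer vector over the seven leaf
#'   classes.
#' @param topic_size Size of the planted topic community.
#' @param p_in,p_out Edge probability per relation-compatible pair inside
#'   the topic community / elsewhere.
#' @param duplication_rate Probability that a covering non-home portal also
#'   carries an instance (every instance always appears in one home
#'   portal).
#' @param alias_rate Probability that a portal displays an instance under
#'   one of its aliases instead of the canonical label.
#' @param class_flip_rate Marginal probability that an emitted navigation
#'   row declares a wrong class.
#' @param ds_flip_share Share of flips that are disease/symptom
#'   confusions.
#' @param code_coverage Fraction of true disease labels present in the
#'   generated reference code list.
#' @param distractor_rate Probability of an extra off-topic entry per
#'   detail record (exercises the unmapped-entry path).
#' @param n_seeds Number of topic seed labels emitted for the EM stage.
#' @param seed Integer fixing all randomness of the corpus.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_portals = 8L,
                          portals = sprintf("portal%02d", seq_len(n_portals)),
                          coverage = default_coverage(n_portals),
                          instances_per_class = c(
                            Disease = 400L, Symptom = 250L,
                            WesternMedicine = 100L, TCM = 80L,
                            Examination = 70L, Department = 40L,
                            BodyStructure = 60L),
                          topic_size = 150L,
                          p_in = 0.2, p_out = 0.01,
                          duplication_rate = 0.18,
                          alias_rate = 0.2,
                          class_flip_rate = 0.1,
                          ds_flip_share = 0.9,
                          code_coverage = 0.6,
                          distractor_rate = 0.3,
                          n_seeds = 6L,
                          seed = 1L) {
  probs <- c(p_in, p_out, duplication_rate, alias_rate, class_flip_rate,
             ds_flip_share, code_coverage, distractor_rate)
  stopifnot(all(probs >= 0), all(probs <= 1),
            topic_size <= sum(instances_per_class),
            length(portals) == n_portals,
            nrow(coverage) == n_portals, ncol(coverage) == 7L)
  rownames(coverage) <- portals
  structure(list(n_portals = as.integer(n_portals), portals = portals,
                 coverage = coverage,
                 instances_per_class = instances_per_class,
                 topic_size = as.integer(topic_size),
                 p_in = p_in, p_out = p_out,
                 duplication_rate = duplication_rate,
                 alias_rate = alias_rate,
                 class_flip_rate = class_flip_rate,
                 ds_flip_share = ds_flip_share,
                 code_coverage = code_coverage,
                 distractor_rate = distractor_rate,
                 n_seeds = as.integer(n_seeds),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Default per-portal class coverage pattern
#'
#' All portals carry Disease, Symptom, Department and BodyStructure;
#' examinations appear in portals 1, 7 and 8; portal 5 carries no medicine
#' and portal 2 only western medicine (row totals 7,5,6,6,4,6,7,7).
#'
#' @param n_portals Number of portals; patterns recycle beyond eight.
#' @return Logical matrix `n_portals x 7`, columns named by leaf class.
#' @export
default_coverage <- function(n_portals = 8L) {
  classes <- c("Disease", "Symptom", "WesternMedicine", "TCM",
               "Examination", "Department", "BodyStructure")
  base <- matrix(TRUE, 8, 7, dimnames = list(NULL, classes))
  base[, "Examination"] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  base[5, c("WesternMedicine", "TCM")] <- FALSE
  base[2, "TCM"] <- FALSE
  base[rep(seq_len(8), length.out = n_portals), , drop = FALSE]
}

syllables <- c("ka", "re", "mi", "to", "shi", "ne", "lo", "du", "va", "pe",
               "xi", "nor", "tal", "gen", "bru", "sol", "fen", "qua")

class_word <- c(Disease = "disease", Symptom = "symptom",
                WesternMedicine = "tablet", TCM = "remedy",
                Examination = "test", Department = "department",
                BodyStructure = "organ")

alt_word <- c(Disease = "disorder", Symptom = "sign",
              WesternMedicine = "pill", TCM = "decoction",
              Examination = "assay", Department = "unit",
              BodyStructure = "structure")

make_instances <- function(instances_per_class) {
  rows <- list()
  k <- 0L
  for (cl in names(instances_per_class)) {
    n <- instances_per_class[[cl]]
    if (n == 0) next
    word <- vapply(seq_len(n), function(i)
      paste(sample(syllables, sample(2:3, 1)), collapse = ""), "")
    idx <- k + seq_len(n)
    lab <- sprintf("%s %s %04d", word, class_word[[cl]], idx)
    alias1 <- sprintf("%s %04d", substr(word, 1, 3), idx)
    alias2 <- sprintf("%s %s %04d", word, alt_word[[cl]], idx)
    rows[[cl]] <- data.frame(
      id = sprintf("master://inst/%04d", idx), class = cl, label = lab,
      alias1 = alias1, alias2 = alias2, stringsAsFactors = FALSE)
    k <- k + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# relations of the default schema keyed by their range class
relations_by_range <- function(schema) {
  rng <- schema_ranges(schema)
  rng <- rng[names(rng) %in% schema_relations(schema)]
  split(names(rng), unname(rng))
}

#' Generate the master knowledge base
#'
#' Builds a typed master graph over [default_diabetes_schema()]: one
#' instance per row of the configured class counts, a planted topic
#' community whose relation-compatible pairs are wired with probability
#' `p_in` against `p_out` elsewhere, `rdf:type` edges for every instance
#' and alias attribute edges for every alias. Edges respect relation
#' domain/range (every relation is rooted at Disease, so only pairs with at
#' least one disease endpoint are compatible; the relation is drawn among
#' those whose range matches the object's class). The result passes
#' [validate_graph()] with zero violations.
#'
#' @param config A [corpus_config()].
#' @return List with `graph` (a [data_graph()]) and `truth` (master ids,
#'   labels, classes, aliases, topic members and the topic's closed
#'   neighbourhood).
#' @export
generate_master <- function(config = corpus_config()) {
  stopifnot(inherits(config, "corpus_config"))
  set.seed(config$seed)
  schema <- default_diabetes_schema()
  inst <- make_instances(config$instances_per_class)
  n <- nrow(inst)
  if (config$topic_size > n) stopf("topic community larger than population")
  topic_idx <- sort(sample.int(n, config$topic_size))
  inst$topic <- seq_len(n) %in% topic_idx

  # candidate pairs: at least one Disease endpoint (relation-compatible)
  pair <- utils::combn(n, 2)
  i <- pair[1, ]; j <- pair[2, ]
  is_dis <- inst$class == "Disease"
  compat <- is_dis[i] | is_dis[j]
  p <- ifelse(inst$topic[i] & inst$topic[j], config$p_in, config$p_out)
  drawn <- which(compat & stats::runif(length(i)) < p)

  rel_by_range <- relations_by_range(schema)
  edges <- NULL
  if (length(drawn)) {
    a <- i[drawn]; b <- j[drawn]
    # subject must be a Disease; orientation random when both qualify
    swap <- is_dis[b] & (!is_dis[a] | stats::runif(length(a)) < 0.5)
    s <- ifelse(swap, b, a)
    o <- ifelse(swap, a, b)
    rel <- vapply(inst$class[o], function(cl) {
      cand <- rel_by_range[[cl]]
      cand[sample.int(length(cand), 1L)]
    }, "")
    edges <- data.frame(from = inst$id[s], label = rel, to = inst$id[o],
                        stringsAsFactors = FALSE)
  }
  type_e <- data.frame(from = inst$id, label = TYPE_LABEL, to = inst$class,
                       stringsAsFactors = FALSE)
  vids <- sprintf("master://value/%04d", seq_len(2 * n))
  alias_v <- data.frame(id = vids, kind = "V",
                        label = c(inst$alias1, inst$alias2),
                        source = "master", stringsAsFactors = FALSE)
  alias_e <- data.frame(from = c(inst$id, inst$id), label = "alias",
                        to = vids, stringsAsFactors = FALSE)
  vertices <- rbind(
    data.frame(id = inst$id, kind = "I", label = inst$label,
               source = "master", stringsAsFactors = FALSE),
    alias_v)
  g <- data_graph(vertices, rbind(type_e, edges, alias_e))

  topic_ids <- inst$id[inst$topic]
  nbrs <- character(0)
  if (!is.null(edges)) {
    on_topic <- edges$from %in% topic_ids | edges$to %in% topic_ids
    nbrs <- unique(c(edges$from[on_topic], edges$to[on_topic]))
  }
  truth <- list(
    ids = inst$id,
    labels = stats::setNames(inst$label, inst$id),
    class_of = stats::setNames(inst$class, inst$id),
    aliases = stats::setNames(
      lapply(seq_len(n), function(r) c(inst$alias1[r], inst$alias2[r])),
      inst$id),
    topic = topic_ids,
    closed_neighborhood = sort(union(topic_ids, nbrs)))
  list(graph = g, truth = truth)
}

#' Generate noisy portal views of a master KB
#'
#' Every instance gets one home portal among those covering its class and
#' is independently duplicated into each other covering portal at the
#' duplication rate. Each emitted navigation row displays the canonical
#' label or (at the alias rate) an alias, and declares the true class or a
#' flipped one: disease/symptom instances flip to their counterpart and
#' other classes flip to a random different class, with per-class flip
#' rates allocated so that the configured share of all flips is
#' disease/symptom confusion. Detail records re-emit the instance's master
#' edges as list/table/infobox entries whose topic sentences hit the
#' default lexicon (targets are shown under the label the same portal uses
#' for them, so in-portal resolution is possible), one alias infobox per
#' instance, and occasional distractor entries that map to no property.
#'
#' @param master The master [data_graph()] from [generate_master()].
#' @param truth Its ground truth.
#' @param config The same [corpus_config()].
#' @return List with `dumps` (list of [portal_dump()]s) and `truth` (the
#'   input truth extended with `uri_map`, a `data.frame` keyed by portal
#'   URI with the planted label, class and flip status of every emitted
#'   row).
#' @export
generate_portal_views <- function(master, truth, config) {
  stopifnot(inherits(master, "data_graph"), inherits(config, "corpus_config"))
  set.seed(config$seed + 1L)
  lex <- default_lexicon()
  ids <- truth$ids
  n <- length(ids)
  cls <- truth$class_of[ids]
  cover <- config$coverage

  covering <- lapply(cls, function(cl) config$portals[cover[, cl]])
  home <- vapply(covering, function(p) p[sample.int(length(p), 1L)], "")
  present <- matrix(FALSE, n, config$n_portals,
                    dimnames = list(ids, config$portals))
  for (r in seq_len(n)) {
    present[r, home[r]] <- TRUE
    others <- setdiff(covering[[r]], home[r])
    if (length(others))
      present[r, others] <- stats::runif(length(others)) < config$duplication_rate
  }

  # per-class flip rates so that ds_flip_share of all flips are D/S swaps
  n_ds <- sum(cls %in% c("Disease", "Symptom"))
  rate_ds <- min(1, config$class_flip_rate * config$ds_flip_share * n / max(1, n_ds))
  rate_other <- min(1, config$class_flip_rate * (1 - config$ds_flip_share) *
                      n / max(1, n - n_ds))
  classes <- names(class_word)

  rel_edges <- master$edges[master$edges$label %in%
                              schema_relations(default_diabetes_schema()), ,
                            drop = FALSE]
  out_edges <- split(seq_len(nrow(rel_edges)), rel_edges$from)
  lex_words <- unclass(lex)
  sentence_for <- function(prop) {
    w <- sample(lex_words[[prop]], 1L)
    sample(c(w, paste("common", w), paste(w, "overview")), 1L)
  }
  distractor_topics <- c("sponsored content", "page navigation",
                         "user comments", "editorial board")

  dumps <- list()
  uri_rows <- list()
  for (p in config$portals) {
    rows <- which(present[, p])
    perm <- sample(length(rows))
    identifier <- sprintf("e%05d", perm)
    use_alias <- stats::runif(length(rows)) < config$alias_rate
    shown <- truth$labels[ids[rows]]
    alias_pick <- vapply(ids[rows], function(id)
      sample(truth$aliases[[id]], 1L), "")
    shown[use_alias] <- alias_pick[use_alias]

    true_cl <- cls[rows]
    is_ds <- true_cl %in% c("Disease", "Symptom")
    flip <- stats::runif(length(rows)) < ifelse(is_ds, rate_ds, rate_other)
    declared <- true_cl
    declared[flip & is_ds] <- ifelse(true_cl[flip & is_ds] == "Disease",
                                     "Symptom", "Disease")
    for (r in which(flip & !is_ds))
      declared[r] <- sample(setdiff(classes, true_cl[r]), 1L)

    shown_by_id <- stats::setNames(unname(shown), ids[rows])
    records <- list()
    for (r in seq_along(rows)) {
      id <- ids[rows[r]]
      entries <- list()
      eidx <- out_edges[[id]]
      if (length(eidx)) {
        by_rel <- split(eidx, rel_edges$label[eidx])
        for (prop in names(by_rel)) {
          tgt <- rel_edges$to[by_rel[[prop]]]
          in_portal <- tgt %in% ids[rows]
          payload <- ifelse(in_portal, shown_by_id[tgt],
                            truth$labels[tgt])
          entries[[length(entries) + 1L]] <- list(
            kind = sample(c("list", "table", "infobox"), 1L),
            topic = sentence_for(prop), payload = unname(payload))
        }
      }
      alias_payload <- setdiff(c(truth$labels[[id]], truth$aliases[[id]]),
                               shown_by_id[[id]])
      if (length(alias_payload))
        entries[[length(entries) + 1L]] <- list(
          kind = "infobox", topic = sample(lex_words$alias, 1L),
          payload = alias_payload)
      if (stats::runif(1) < config$distractor_rate)
        entries[[length(entries) + 1L]] <- list(
          kind = "list", topic = sample(distractor_topics, 1L),
          payload = "lorem ipsum")
      records[[identifier[r]]] <- entries
    }
    nav <- data.frame(identifier = identifier, label = unname(shown),
                      class = declared, stringsAsFactors = FALSE)
    dumps[[p]] <- portal_dump(p, nav, records)
    uri_rows[[p]] <- data.frame(
      uri = paste0(p, "://", identifier), portal = p,
      identifier = identifier, master_id = ids[rows],
      label = unname(shown), declared_class = declared,
      true_class = true_cl, flipped = flip, stringsAsFactors = FALSE)
  }
  truth$uri_map <- do.call(rbind, uri_rows)
  rownames(truth$uri_map) <- NULL
  list(dumps = dumps, truth = truth)
}

#' Generate a reference disease code list
#'
#' Draws a `coverage` fraction of the true disease labels (with their
#' aliases) into a synthetic code list; no non-disease label ever enters.
#'
#' @param truth Ground truth from [generate_master()].
#' @param coverage Fraction in `[0, 1]`.
#' @param seed Optional integer fixing the draw.
#' @return A [reference_code_list()].
#' @export
generate_code_list <- function(truth, coverage = 0.6, seed = NULL) {
  stopifnot(coverage >= 0, coverage <= 1)
  if (!is.null(seed)) set.seed(seed)
  dis <- truth$ids[truth$class_of[truth$ids] == "Disease"]
  k <- round(coverage * length(dis))
  pick <- if (k > 0) sort(sample(dis, k)) else character(0)
  reference_code_list(data.frame(
    code = sprintf("C%04d", seq_along(pick)),
    label = unname(truth$labels[pick]),
    aliases = vapply(truth$aliases[pick], paste, "", collapse = "|"),
    stringsAsFactors = FALSE))
}

#' Generate a full synthetic corpus
#'
#' One seed fixes the master KB, the portal views, the code list and the
#' EM seed labels (the highest-degree topic members).
#'
#' @param config A [corpus_config()].
#' @return List of class `portal_corpus` with elements `master`, `truth`,
#'   `dumps`, `codes`, `seed_labels` and `config`.
#' @export
generate_corpus <- function(config = corpus_config()) {
  m <- generate_master(config)
  pv <- generate_portal_views(m$graph, m$truth, config)
  codes <- generate_code_list(pv$truth, config$code_coverage,
                              seed = config$seed + 2L)
  rel <- m$graph$edges[m$graph$edges$label %in%
                         schema_relations(default_diabetes_schema()), ]
  deg <- table(c(rel$from, rel$to))
  topic_deg <- deg[names(deg) %in% m$truth$topic]
  top <- names(sort(topic_deg, decreasing = TRUE))
  seed_ids <- utils::head(top, config$n_seeds)
  structure(list(master = m$graph, truth = pv$truth, dumps = pv$dumps,
                 codes = codes,
                 seed_labels = unname(m$truth$labels[seed_ids]),
                 config = config),
            class = "portal_corpus")
}

#' Pure planted-partition benchmark graph
#'
#' A single-class benchmark for the EM extractor: `n_topic` + `n_background`
#' disease instances, every pair relation-compatible, wired with `p_in`
#' inside the topic block and `p_out` elsewhere via `related_disease`
#' edges.
#'
#' @param n_topic,n_background Block sizes.
#' @param p_in,p_out Edge probabilities.
#' @param seed Integer seed.
#' @return List with `graph` (a [data_graph()]) and `topic` (ids of the
#'   planted block).
#' @export
planted_partition_graph <- function(n_topic = 150L, n_background = 850L,
                                    p_in = 0.2, p_out = 0.01, seed = 1L) {
  set.seed(seed)
  n <- n_topic + n_background
  ids <- sprintf("bench://inst/%04d", seq_len(n))
  pair <- utils::combn(n, 2)
  i <- pair[1, ]; j <- pair[2, ]
  p <- ifelse(i <= n_topic & j <= n_topic, p_in, p_out)
  drawn <- which(stats::runif(length(i)) < p)
  vertices <- data.frame(id = ids, kind = "I",
                         label = sprintf("benchmark disease %04d", seq_len(n)),
                         source = "bench", stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = ids, label = TYPE_LABEL, to = "Disease",
               stringsAsFactors = FALSE),
    data.frame(from = ids[i[drawn]], label = "related_disease",
               to = ids[j[drawn]], stringsAsFactors = FALSE))
  list(graph = data_graph(vertices, edges), topic = ids[seq_len(n_topic)])
}

#' Score a pipeline result against planted truth
#'
#' @param result For `type = "topic"` a [data_graph()] (the extracted
#'   subgraph, with vertices identified by master, benchmark or portal
#'   URIs); for `"matching"` a `data.frame` of mapping assertions
#'   (`v1`, `v2`); for `"cleansing"` an [integrated_data_graph()] after
#'   cleansing.
#' @param truth Ground truth carrying `uri_map` (from
#'   [generate_portal_views()]) when portal URIs need translating.
#' @param type Which planted truth to score against.
#' @param reference For `"topic"`: compare against the planted members
#'   (`"topic"`) or their closed neighbourhood.
#' @return List of metrics: precision, recall, F1 (and accuracy fields for
#'   `"cleansing"`).
#' @export
score_recovery <- function(result, truth,
                           type = c("topic", "matching", "cleansing"),
                           reference = c("topic", "closed_neighborhood")) {
  type <- match.arg(type)
  reference <- match.arg(reference)
  prf <- function(pred, gold) {
    tp <- length(intersect(pred, gold))
    precision <- if (length(pred)) tp / length(pred) else 0
    recall <- if (length(gold)) tp / length(gold) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1,
         n_pred = length(pred), n_gold = length(gold))
  }
  if (type == "topic") {
    stopifnot(inherits(result, "data_graph"))
    uris <- instances(result)
    to_master <- uris
    if (!is.null(truth$uri_map)) {
      m <- match(uris, truth$uri_map$uri)
      to_master[!is.na(m)] <- truth$uri_map$master_id[m[!is.na(m)]]
    }
    if (!all(to_master %in% truth$ids))
      stopf("result references ids absent from the ground truth: %s",
            paste(utils::head(uris[!to_master %in% truth$ids], 3),
                  collapse = ", "))
    gold <- if (reference == "topic") truth$topic else truth$closed_neighborhood
    return(prf(unique(to_master), gold))
  }
  if (type == "matching") {
    um <- truth$uri_map
    stopifnot(!is.null(um))
    pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
    by_master <- split(um$uri, um$master_id)
    gold <- unlist(lapply(by_master[lengths(by_master) > 1], function(u) {
      pr <- utils::combn(sort(u), 2)
      pkey(pr[1, ], pr[2, ])
    }), use.names = FALSE)
    pred <- if (nrow(result)) pkey(result$v1, result$v2) else character(0)
    return(prf(unique(pred), unique(gold)))
  }
  # cleansing: final declared class per emitted row vs planted truth
  stopifnot(inherits(result, "integrated_data_graph"))
  um <- truth$uri_map
  dc <- do.call(rbind, lapply(result$graphs, declared_classes))
  final <- stats::setNames(dc$class, dc$uri)[um$uri]
  ok <- !is.na(final) & final == um$true_class
  rpt <- attr(result, "report")
  list(accuracy_flipped = mean(ok[um$flipped]),
       accuracy_all = mean(ok),
       n_flipped = sum(um$flipped),
       coverage = if (!is.null(rpt) && nrow(rpt)) mean(rpt$resolved) else NA_real_)
}
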
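# Fusion: class-conflict cleansing (reference code list + majority voting),
# same-class instance matching, and the merge into a unified data graph.

#' Construct a reference disease code list
#'
#' A code list in the shape of the WHO disease classification: one code per
#' disease with a canonical label and optional aliases. Label hits (exact
#' match after normalisation) decide an instance's class as Disease during
#' cleansing.
#'
#' @param entries `data.frame` with columns `code`, `label` and `aliases`
#'   (a `|`-separated string, possibly empty).
#' @return An object of class `reference_code_list`.
#' @export
reference_code_list <- function(entries = NULL) {
  if (is.null(entries))
    entries <- data.frame(code = character(0), label = character(0),
                          aliases = character(0), stringsAsFactors = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("code", "label") %in% names(entries)))
    stopf("code list needs columns code, label")
  if (!"aliases" %in% names(entries)) entries$aliases <- ""
  entries$code <- unname(as.character(entries$code))
  entries$label <- unname(normalize_label(entries$label))
  entries$aliases <- unname(as.character(entries$aliases))
  rownames(entries) <- NULL
  if (anyDuplicated(entries$code)) stopf("duplicate codes in reference list")
  terms <- c(entries$label,
             normalize_label(unlist(strsplit(entries$aliases, "|", fixed = TRUE))))
  terms <- unique(terms[nzchar(terms)])
  structure(list(entries = entries[c("code", "label", "aliases")],
                 terms = terms),
            class = "reference_code_list")
}

#' @export
print.reference_code_list <- function(x, ...) {
  cat(sprintf("<reference_code_list> %d codes, %d lookup terms\n",
              nrow(x$entries), length(x$terms)))
  invisible(x)
}

#' Look a label up in the reference code list
#'
#' @param label Character scalar (non-empty).
#' @param codes A [reference_code_list()].
#' @return `"Disease"` when the normalised label equals a canonical label or
#'   alias in the list; `NA_character_` otherwise.
#' @export
reference_lookup <- function(label, codes) {
  stopifnot(inherits(codes, "reference_code_list"), nzchar(label))
  if (normalize_label(label) %in% codes$terms) "Disease" else NA_character_
}

#' Majority vote over class assignments
#'
#' Picks the class with the largest share of supporting sources. Ties are
#' broken deterministically: Disease wins when among the tied classes,
#' otherwise the lexicographically smallest tied class.
#'
#' @param tally Named integer vector of per-class source counts.
#' @return List with elements `class`, `score` (winning share in `[0,1]`),
#'   `n` (total votes) and `tie` (logical).
#' @export
vote_class <- function(tally) {
  tally <- tally[tally > 0]
  if (!length(tally)) stopf("vote_class: empty tally")
  n <- sum(tally)
  winners <- names(tally)[tally == max(tally)]
  cls <- if ("Disease" %in% winners) "Disease" else sort(winners)[1]
  list(class = cls, score = unname(max(tally)) / n, n = n,
       tie = length(winners) > 1L)
}

#' Bundle data graphs with cross-source mappings
#'
#' @param graphs List of [data_graph()]s (one per source).
#' @param mappings `data.frame` with columns `v1`, `v2`, `score` —
#'   approximate correspondences between instances of different member
#'   graphs.
#' @return An object of class `integrated_data_graph`.
#' @export
integrated_data_graph <- function(graphs, mappings = NULL) {
  stopifnot(length(graphs) >= 1,
            all(vapply(graphs, inherits, TRUE, "data_graph")))
  if (is.null(mappings))
    mappings <- data.frame(v1 = character(0), v2 = character(0),
                           score = numeric(0), stringsAsFactors = FALSE)
  all_ids <- unlist(lapply(graphs, instances))
  bad <- setdiff(c(mappings$v1, mappings$v2), all_ids)
  if (length(bad))
    stopf("mapping endpoints not present in any member graph: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  structure(list(graphs = graphs, mappings = mappings),
            class = "integrated_data_graph")
}

#' @export
print.integrated_data_graph <- function(x, ...) {
  cat(sprintf("<integrated_data_graph> %d member graphs, %d mappings\n",
              length(x$graphs), nrow(x$mappings)))
  invisible(x)
}

# per-graph table of (uri, label, norm label, class, source); one declared
# class per instance (intra-source self-conflicts resolved first by the
# class-table majority with the standard tie-break)
declared_classes <- function(g) {
  te <- type_edges(g)
  if (!nrow(te))
    return(data.frame(uri = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  cls <- vapply(split(te$to, te$from), function(tt) {
    if (length(unique(tt)) == 1L) tt[[1]] else vote_class(table(tt))$class
  }, "")
  data.frame(uri = names(cls), class = unname(cls), stringsAsFactors = FALSE)
}

#' Cleanse conflicting class assignments across sources
#'
#' For every label whose same-label instances carry disjoint classes in
#' different member graphs, the class is decided by (in order): a hit in
#' the reference code list (always Disease), then the majority vote over
#' one declared class per source ([vote_class()]). All `rdf:type` edges of
#' the affected instances are rewritten to the winner, so resolved labels
#' have no remaining disjointness violations. The operation is idempotent.
#'
#' @param integrated An [integrated_data_graph()].
#' @param codes A [reference_code_list()].
#' @param schema A [schema_graph()].
#' @param method `"combined"` (default) applies lookup then voting;
#'   `"vote"` skips the lookup; `"lookup"` rewrites only labels found in the
#'   code list and leaves the rest unresolved (the two baselines of the
#'   strategy comparison).
#' @return An [integrated_data_graph()] with rewritten member graphs and a
#'   `report` attribute: `data.frame(label, winner, method, score,
#'   n_sources, resolved)` with one row per conflicted label.
#' @export
cleanse_classes <- function(integrated, codes, schema,
                            method = c("combined", "vote", "lookup")) {
  method <- match.arg(method)
  stopifnot(inherits(integrated, "integrated_data_graph"))
  graphs <- integrated$graphs
  djkey <- with(disjoint_pairs(schema), paste(a, b))

  per_graph <- lapply(graphs, function(g) {
    dc <- declared_classes(g)
    lab <- stats::setNames(g$vertices$label, g$vertices$id)
    dc$label_norm <- normalize_label(unname(lab[dc$uri]))
    dc$source <- g$vertices$source[match(dc$uri, g$vertices$id)]
    dc
  })
  all_dc <- do.call(rbind, per_graph)

  conflicted <- function(cls) {
    cls <- unique(cls)
    length(cls) > 1L &&
      any(paste(rep(cls, each = length(cls)), rep(cls, length(cls))) %in% djkey)
  }
  by_label <- split(all_dc, all_dc$label_norm)
  conf_labels <- names(by_label)[vapply(by_label, function(d) conflicted(d$class), TRUE)]

  rep_rows <- list()
  rewrite <- stats::setNames(character(0), character(0))  # label_norm -> class
  for (lb in conf_labels) {
    d <- by_label[[lb]]
    hit <- if (method %in% c("combined", "lookup"))
      reference_lookup(lb, codes) else NA_character_
    if (!is.na(hit)) {
      winner <- hit; how <- "lookup"; score <- 1; tie <- FALSE
    } else if (method == "lookup") {
      winner <- NA_character_; how <- "unresolved"; score <- NA_real_; tie <- FALSE
    } else {
      # one vote per source: a source's vote is its declared class for the
      # label (intra-source multiplicity collapsed by the same vote rule)
      src_votes <- vapply(split(d$class, d$source), function(cc) {
        if (length(unique(cc)) == 1L) cc[[1]] else vote_class(table(cc))$class
      }, "")
      vt <- vote_class(table(src_votes))
      winner <- vt$class; how <- if (vt$tie) "vote-tie" else "vote"
      score <- vt$score; tie <- vt$tie
    }
    if (!is.na(winner)) rewrite[lb] <- winner
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      label = lb, winner = winner, method = how, score = score,
      n_sources = length(unique(d$source)), resolved = !is.na(winner),
      stringsAsFactors = FALSE)
  }

  if (length(rewrite)) {
    graphs <- lapply(graphs, function(g) {
      lab_norm <- normalize_label(
        stats::setNames(g$vertices$label, g$vertices$id)[g$edges$from])
      is_type <- g$edges$label == TYPE_LABEL
      tgt <- rewrite[lab_norm]
      change <- is_type & !is.na(tgt)
      g$edges$to[change] <- tgt[change]
      g$edges <- unique(g$edges)
      data_graph(g$vertices, g$edges)
    })
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(label = character(0), winner = character(0),
               method = character(0), score = numeric(0),
               n_sources = integer(0), resolved = logical(0),
               stringsAsFactors = FALSE)
  out <- integrated_data_graph(graphs, integrated$mappings)
  attr(out, "report") <- report
  out
}

#' Matching configuration
#'
#' @param w_syntactic,w_structural Aggregation weights for the syntactic
#'   (name-based) and structural (neighbourhood-based) similarity; they are
#'   renormalised to sum to one.
#' @param threshold Minimum aggregated score for a correspondence.
#' @return A list of class `match_config`.
#' @export
match_config <- function(w_syntactic = 0.6, w_structural = 0.4,
                         threshold = 0.85) {
  s <- w_syntactic + w_structural
  structure(list(w_syntactic = w_syntactic / s,
                 w_structural = w_structural / s,
                 threshold = threshold),
            class = "match_config")
}

# per-instance features for matching: class, name set (label + aliases),
# neighbour label set over instance-to-instance edges
instance_features <- function(g) {
  dc <- declared_classes(g)
  lab <- stats::setNames(g$vertices$label, g$vertices$id)
  kind <- stats::setNames(g$vertices$kind, g$vertices$id)
  ae <- g$edges[g$edges$label == "alias", , drop = FALSE]
  aliases <- split(normalize_label(unname(lab[ae$to])), ae$from)
  # neighbours: objects of any non-type, non-alias edge (instances or
  # unresolved value objects) plus subjects of incoming relation edges
  rel <- g$edges[!g$edges$label %in% c(TYPE_LABEL, "alias") &
                   kind[g$edges$from] == "I", , drop = FALSE]
  inc <- rel[!is.na(kind[rel$to]) & kind[rel$to] == "I", , drop = FALSE]
  nbr <- split(c(rel$to, inc$from), c(rel$from, inc$to))
  ids <- instances(g)
  list(
    ids = ids,
    class = stats::setNames(dc$class[match(ids, dc$uri)], ids),
    label = stats::setNames(normalize_label(unname(lab[ids])), ids),
    names = stats::setNames(lapply(ids, function(i)
      unique(c(normalize_label(lab[[i]]), aliases[[i]]))), ids),
    nbrs = stats::setNames(lapply(ids, function(i)
      unique(normalize_label(unname(lab[nbr[[i]]])))), ids))
}

# best normalised Levenshtein similarity between two name sets
name_similarity <- function(a, b) {
  d <- utils::adist(a, b)
  den <- outer(nchar(a), nchar(b), pmax)
  den[den == 0] <- 1L
  max(1 - d / den)
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Match equivalent instances between two data graphs
#'
#' The standard five-step derivation of correspondences: feature
#' engineering (name sets and neighbour label sets), candidate selection
#' (same class and same first character of the normalised label — instances
#' of different classes are never candidates), similarity computation
#' (syntactic: best normalised Levenshtein similarity across the two name
#' sets; structural: Jaccard overlap of neighbour label sets), weighted-mean
#' aggregation, and greedy best-first one-to-one derivation of assertions
#' above the threshold.
#'
#' @param g1,g2 Cleansed [data_graph()]s from different sources.
#' @param config A [match_config()].
#' @return `data.frame` with columns `v1`, `v2`, `score`.
#' @export
match_instances <- function(g1, g2, config = match_config()) {
  f1 <- instance_features(g1)
  f2 <- instance_features(g2)
  key <- function(f) paste(f$class, substr(f$label, 1, 1))
  k1 <- key(f1); k2 <- key(f2)
  cand <- list()
  for (k in intersect(unique(k1[!is.na(f1$class)]),
                      unique(k2[!is.na(f2$class)]))) {
    ids1 <- f1$ids[k1 == k & !is.na(f1$class)]
    ids2 <- f2$ids[k2 == k & !is.na(f2$class)]
    if (!length(ids1) || !length(ids2)) next
    cand[[k]] <- expand.grid(v1 = ids1, v2 = ids2,
                             stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(v1 = character(0), v2 = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  syn <- mapply(function(a, b) name_similarity(f1$names[[a]], f2$names[[b]]),
                cand$v1, cand$v2)
  str <- mapply(function(a, b) jaccard(f1$nbrs[[a]], f2$nbrs[[b]]),
                cand$v1, cand$v2)
  cand$score <- config$w_syntactic * syn + config$w_structural * str
  cand <- cand[cand$score >= config$threshold, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$v1, cand$v2), , drop = FALSE]
  used1 <- character(0); used2 <- character(0); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$v1[i] %in% used1 || cand$v2[i] %in% used2) next
    keep[i] <- TRUE
    used1 <- c(used1, cand$v1[i]); used2 <- c(used2, cand$v2[i])
  }
  out <- cand[keep, c("v1", "v2", "score"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match instances across all member graphs
#'
#' Runs [match_instances()] on every unordered pair of member graphs and
#' stores the union of assertions on the integrated graph.
#'
#' @param integrated An [integrated_data_graph()].
#' @param config A [match_config()].
#' @return The [integrated_data_graph()] with populated `mappings`.
#' @export
match_all <- function(integrated, config = match_config()) {
  gs <- integrated$graphs
  maps <- list()
  n <- length(gs)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      m <- match_instances(gs[[i]], gs[[j]], config)
      if (nrow(m)) maps[[length(maps) + 1L]] <- m
    }
  }
  mappings <- if (length(maps)) do.call(rbind, maps) else NULL
  integrated_data_graph(gs, mappings)
}

# union-find over mapping assertions
mapping_clusters <- function(ids, mappings) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(mappings))) {
    ra <- find(mappings$v1[i]); rb <- find(mappings$v2[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(ids, find, "")
  split(ids, roots)
}

#' Fuse an integrated data graph into a unified one
#'
#' The transitive closure of the mapping assertions partitions the
#' instances into clusters; each cluster is collapsed onto its
#' lexicographically smallest member URI. Edges are re-pointed to the
#' canonical ids and deduplicated per (subject, predicate, object); value
#' vertices with equal labels are shared; provenance tags are unioned per
#' fused vertex. A cluster spanning two disjoint classes is an error — the
#' cleansing contract was breached upstream.
#'
#' @param integrated An [integrated_data_graph()] with mappings computed.
#' @param schema A [schema_graph()] (for the disjointness check).
#' @return A unified [data_graph()].
#' @export
fuse <- function(integrated, schema = default_diabetes_schema()) {
  g <- merge_graphs(integrated$graphs)
  ids <- instances(g)
  clus <- mapping_clusters(ids, integrated$mappings)
  canon <- stats::setNames(rep(names(clus), lengths(clus)), unlist(clus))
  names(canon) <- unlist(clus)

  djkey <- with(disjoint_pairs(schema), paste(a, b))
  te <- type_edges(g)
  cls_by_canon <- split(te$to, canon[te$from])
  for (cid in names(cls_by_canon)) {
    cls <- unique(cls_by_canon[[cid]])
    if (length(cls) > 1L &&
        any(paste(rep(cls, each = length(cls)), rep(cls, length(cls))) %in% djkey))
      stopf("fuse: cluster %s spans disjoint classes (%s); cleanse first",
            cid, paste(cls, collapse = ", "))
  }

  vv <- g$vertices[g$vertices$kind == "V", , drop = FALSE]
  vcanon <- character(0)
  if (nrow(vv)) {
    vnorm <- normalize_label(vv$label)
    first <- !duplicated(vnorm)
    vmap <- stats::setNames(sprintf("urn:value:%04d", seq_len(sum(first))),
                            vnorm[first])
    vcanon <- stats::setNames(unname(vmap[vnorm]), vv$id)
  }
  remap <- c(canon, vcanon)

  iv <- g$vertices[g$vertices$kind == "I", , drop = FALSE]
  iv$canon <- unname(canon[iv$id])
  lab <- stats::setNames(iv$label, iv$id)
  src <- vapply(split(iv$source, iv$canon), collapse_sources, "")
  ivert <- data.frame(id = names(src), kind = "I",
                      label = unname(lab[names(src)]),
                      source = unname(src), stringsAsFactors = FALSE)
  vvert <- NULL
  if (nrow(vv)) {
    vv$canon <- unname(vcanon[vv$id])
    vsrc <- vapply(split(vv$source, vv$canon), collapse_sources, "")
    vlab <- stats::setNames(vv$label, vv$canon)
    vvert <- data.frame(id = names(vsrc), kind = "V",
                        label = unname(vlab[names(vsrc)]),
                        source = unname(vsrc), stringsAsFactors = FALSE)
  }
  e <- g$edges
  is_type <- e$label == TYPE_LABEL
  e$from <- unname(remap[e$from])
  e$to[!is_type] <- unname(remap[e$to[!is_type]])
  e <- unique(e)
  data_graph(rbind(ivert, vvert), e)
}
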
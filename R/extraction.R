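# Extraction: portal dumps -> vertically-partitioned property tables -> a
# per-portal data graph (wrapper post-processing plus the D2R step).

#' Construct a portal dump
#'
#' A portal dump is the structured form of one vertical portal's pages:
#' navigation rows gather instances of one class (identifier, display label,
#' declared class), and per-identifier detail records hold the list/table/
#' infobox entries found on the instance's page.
#'
#' @param source Source tag of the portal (used for provenance and URIs).
#' @param navigation `data.frame` with columns `identifier`, `label`,
#'   `class`.
#' @param records Named list: identifier -> list of entries, each entry a
#'   list with elements `kind` (`"list"`, `"table"` or `"infobox"`),
#'   `topic` (topic sentence / property label) and `payload` (character
#'   vector of target labels or values).
#' @return An object of class `portal_dump`.
#' @export
portal_dump <- function(source, navigation, records = list()) {
  navigation <- as.data.frame(navigation, stringsAsFactors = FALSE)
  need <- c("identifier", "label", "class")
  if (!all(need %in% names(navigation)))
    stopf("navigation needs columns: %s", paste(need, collapse = ", "))
  navigation[need] <- lapply(navigation[need], function(x)
    unname(as.character(x)))
  rownames(navigation) <- NULL
  if (anyDuplicated(navigation$identifier))
    stopf("duplicate identifiers in navigation rows")
  unknown <- setdiff(names(records), navigation$identifier)
  if (length(unknown))
    stopf("detail records for identifiers absent from navigation: %s",
          paste(unknown, collapse = ", "))
  structure(list(source = as.character(source),
                 navigation = navigation[need],
                 records = records),
            class = "portal_dump")
}

#' @export
print.portal_dump <- function(x, ...) {
  cat(sprintf("<portal_dump> source=%s, %d instances, %d detail records\n",
              x$source, nrow(x$navigation), length(x$records)))
  invisible(x)
}

#' Construct a heuristic lexicon
#'
#' Maps each relation or attribute name to its set of heuristic words; an
#' entry's topic sentence is assigned to the first property (in lexicon
#' order) one of whose words it contains.
#'
#' @param words Named list of non-empty character vectors; names are
#'   property names and their order is the priority order.
#' @return An object of class `heuristic_lexicon`.
#' @export
heuristic_lexicon <- function(words) {
  if (!length(words) || is.null(names(words)) || any(!nzchar(names(words))))
    stopf("lexicon must be a non-empty named list")
  if (any(!vapply(words, length, 1L)))
    stopf("every lexicon word set must be non-empty")
  words <- lapply(words, function(w) unique(normalize_label(w)))
  structure(words, class = "heuristic_lexicon")
}

#' Default heuristic lexicon for the diabetes schema
#'
#' Word sets reflecting the topic sentences medical portals put above their
#' lists, tables and infobox rows, one set per relation of
#' [default_diabetes_schema()] plus the `alias` attribute.
#'
#' @return A [heuristic_lexicon()].
#' @export
default_lexicon <- function() {
  heuristic_lexicon(list(
    complication    = c("complication", "concurrent disease"),
    sign            = c("symptom", "signs", "clinical manifestation"),
    causes          = c("cause", "etiology", "pathogeny"),
    risk_factor     = c("risk factor", "high risk", "susceptible population"),
    related_disease = c("related disease", "similar disease"),
    treated_by_wm   = c("western medicine", "medication", "drug therapy"),
    treated_by_tcm  = c("chinese medicine", "tcm therapy", "herbal"),
    checked_by_exam = c("examination", "check item", "laboratory test"),
    belongs_to_dept = c("department", "visiting clinic"),
    located_in_body = c("body part", "affected site", "located in"),
    alias           = c("alias", "also known as", "other name")
  ))
}

#' Map an entry's topic sentence to a property
#'
#' Overlap is substring containment after whitespace/case normalisation;
#' the first property in lexicon order with a hit wins.
#'
#' @param topic_sentence Character scalar.
#' @param lexicon A [heuristic_lexicon()].
#' @return The property name, or `NA_character_` when nothing hits.
#' @export
map_entry_to_property <- function(topic_sentence, lexicon) {
  stopifnot(inherits(lexicon, "heuristic_lexicon"))
  s <- normalize_label(topic_sentence)
  if (!length(s) || is.na(s) || !nzchar(s)) return(NA_character_)
  for (prop in names(lexicon)) {
    for (w in lexicon[[prop]]) {
      if (grepl(w, s, fixed = TRUE)) return(prop)
    }
  }
  NA_character_
}

#' Construct a property table
#'
#' The vertical-partitioning unit: a two-column table holding every
#' (subject, object) pair of exactly one property. Fully duplicated rows are
#' dropped, first occurrence wins.
#'
#' @param property Property name.
#' @param rows `data.frame` with columns `subject`, `object`.
#' @return An object of class `property_table`.
#' @export
property_table <- function(property, rows = NULL) {
  if (is.null(rows))
    rows <- data.frame(subject = character(0), object = character(0),
                       stringsAsFactors = FALSE)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (!all(c("subject", "object") %in% names(rows)))
    stopf("property-table rows need columns subject, object")
  rows$subject <- as.character(rows$subject)
  rows$object <- as.character(rows$object)
  rows <- rows[!duplicated(paste0(rows$subject, "\r", rows$object)),
               c("subject", "object"), drop = FALSE]
  rownames(rows) <- NULL
  structure(list(property = as.character(property), rows = rows),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %s: %d rows\n", x$property, nrow(x$rows)))
  invisible(x)
}

#' Rewrite a portal dump into property tables
#'
#' The class table gets one row per navigation row (identifier ->
#' declared class); a `label` table carries the display labels (the D2R
#' step resolves relation objects against them); every detail entry whose
#' topic sentence maps to a property contributes one row per payload
#' element to that property's table. Entries that map to no property and
#' empty payload elements are counted and skipped.
#'
#' @param dump A [portal_dump()].
#' @param lexicon A [heuristic_lexicon()].
#' @return List with elements `class_table` (a [property_table()] for
#'   `rdf:type`), `label_table`, `relation_tables` (named list of
#'   [property_table()]s) and `skipped` (counts of unmapped entries and
#'   empty payload values).
#' @export
extract_tables <- function(dump, lexicon = default_lexicon()) {
  stopifnot(inherits(dump, "portal_dump"))
  class_table <- property_table(
    TYPE_LABEL,
    data.frame(subject = dump$navigation$identifier,
               object = dump$navigation$class, stringsAsFactors = FALSE))
  label_table <- property_table(
    "label",
    data.frame(subject = dump$navigation$identifier,
               object = dump$navigation$label, stringsAsFactors = FALSE))
  rows <- list()
  unmapped <- 0L
  empties <- 0L
  for (ident in names(dump$records)) {
    for (entry in dump$records[[ident]]) {
      prop <- map_entry_to_property(entry$topic %||% "", lexicon)
      if (is.na(prop)) {
        unmapped <- unmapped + 1L
        next
      }
      payload <- as.character(entry$payload %||% character(0))
      empties <- empties + sum(!nzchar(payload))
      payload <- payload[nzchar(payload)]
      if (!length(payload)) next
      rows[[length(rows) + 1L]] <- data.frame(
        property = prop, subject = ident, object = payload,
        stringsAsFactors = FALSE)
    }
  }
  relation_tables <- list()
  if (length(rows)) {
    all_rows <- do.call(rbind, rows)
    for (prop in unique(all_rows$property)) {
      sel <- all_rows[all_rows$property == prop, c("subject", "object")]
      relation_tables[[prop]] <- property_table(prop, sel)
    }
  }
  list(class_table = class_table, label_table = label_table,
       relation_tables = relation_tables,
       skipped = c(unmapped_entries = unmapped, empty_values = empties))
}

#' Materialise property tables as a data graph (D2R step)
#'
#' One instance vertex per class-table subject, with URI
#' `namespace + identifier` and one `rdf:type` edge obtained by resolving
#' the declared class label against the schema (case and punctuation
#' insensitive). Relation rows whose object matches the label of an
#' instance of the same portal become instance-to-instance edges; all other
#' objects become fresh value vertices with attribute-style edges. Rows
#' whose class label or subject cannot be resolved are quarantined to a
#' rejects table; the graph is still produced.
#'
#' @param class_table [property_table()] of declared classes.
#' @param relation_tables Named list of [property_table()]s (a `label`
#'   table, when present, sets instance display labels and produces no
#'   edges).
#' @param schema A [schema_graph()].
#' @param namespace URI prefix for this portal, e.g. `"p39://"`.
#' @param source Provenance tag; defaults to the namespace scheme.
#' @return A [data_graph()] with attribute `rejects` (`data.frame` with
#'   columns `table`, `subject`, `object`, `reason`).
#' @export
d2r_materialize <- function(class_table, relation_tables, schema,
                            namespace, source = sub("[:/].*$", "", namespace)) {
  stopifnot(inherits(class_table, "property_table"),
            inherits(schema, "schema_graph"))
  rejects <- list()
  reject <- function(table, subject, object, reason) {
    rejects[[length(rejects) + 1L]] <<- data.frame(
      table = table, subject = subject, object = object, reason = reason,
      stringsAsFactors = FALSE)
  }
  classes <- schema_classes(schema)
  class_lookup <- stats::setNames(classes, normalize_class_label(classes))

  ct <- class_table$rows
  resolved <- class_lookup[normalize_class_label(ct$object)]
  bad <- is.na(resolved)
  for (i in which(bad))
    reject(TYPE_LABEL, ct$subject[i], ct$object[i], "unknown class label")
  ct <- ct[!bad, , drop = FALSE]
  resolved <- resolved[!bad]
  uri <- paste0(namespace, ct$subject)

  labels <- stats::setNames(ct$subject, ct$subject)  # default label = identifier
  if (!is.null(relation_tables$label)) {
    lt <- relation_tables$label$rows
    keep <- lt$subject %in% ct$subject & !duplicated(lt$subject)
    labels[lt$subject[keep]] <- lt$object[keep]
  }
  vertices <- data.frame(id = uri, kind = "I", label = unname(labels[ct$subject]),
                         source = source, stringsAsFactors = FALSE)
  edges <- data.frame(from = uri, label = TYPE_LABEL, to = unname(resolved),
                      stringsAsFactors = FALSE)

  # normalized display label -> instance URI (first wins on duplicates)
  lab_norm <- normalize_label(vertices$label)
  lab_map <- stats::setNames(vertices$id, lab_norm)[!duplicated(lab_norm)]
  id_map <- stats::setNames(vertices$id, ct$subject)

  vcount <- 0L
  vvert <- list()
  eacc <- list(edges)
  for (prop in setdiff(names(relation_tables), "label")) {
    pt <- relation_tables[[prop]]$rows
    if (!nrow(pt)) next
    if (!prop %in% c(schema_relations(schema), schema_attributes(schema))) {
      for (i in seq_len(nrow(pt)))
        reject(prop, pt$subject[i], pt$object[i],
               "property not declared in schema")
      next
    }
    suri <- id_map[pt$subject]
    orphan <- is.na(suri)
    for (i in which(orphan))
      reject(prop, pt$subject[i], pt$object[i],
             "subject identifier not in class table")
    pt <- pt[!orphan, , drop = FALSE]
    suri <- suri[!orphan]
    if (!nrow(pt)) next
    turi <- rep(NA_character_, nrow(pt))
    if (prop %in% schema_relations(schema))
      turi <- unname(lab_map[normalize_label(pt$object)])
    hit <- !is.na(turi)
    if (any(hit))
      eacc[[length(eacc) + 1L]] <- data.frame(
        from = unname(suri[hit]), label = prop, to = turi[hit],
        stringsAsFactors = FALSE)
    if (any(!hit)) {
      n <- sum(!hit)
      vid <- sprintf("%svalue/%04d", namespace, vcount + seq_len(n))
      vcount <- vcount + n
      vvert[[length(vvert) + 1L]] <- data.frame(
        id = vid, kind = "V", label = pt$object[!hit], source = source,
        stringsAsFactors = FALSE)
      eacc[[length(eacc) + 1L]] <- data.frame(
        from = unname(suri[!hit]), label = prop, to = vid,
        stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, eacc)
  if (length(vvert)) vertices <- rbind(vertices, do.call(rbind, vvert))
  g <- data_graph(vertices, unique(edges))
  attr(g, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(table = character(0), subject = character(0),
               object = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  g
}

#' Re-partition a data graph into two-column property tables
#'
#' Inverse of [d2r_materialize()]: strips the namespace from instance URIs
#' and emits one table per property, the class table and the label table.
#' Value-vertex objects are rendered by their label.
#'
#' @param g A [data_graph()].
#' @param namespace URI prefix to strip from instance ids.
#' @return List with `class_table`, `label_table`, `relation_tables`.
#' @export
partition_graph <- function(g, namespace) {
  strip <- function(x) sub(paste0("^", namespace), "", x)
  iv <- g$vertices[g$vertices$kind == "I", , drop = FALSE]
  lab <- stats::setNames(g$vertices$label, g$vertices$id)
  te <- type_edges(g)
  class_table <- property_table(
    TYPE_LABEL, data.frame(subject = strip(te$from), object = te$to,
                           stringsAsFactors = FALSE))
  label_table <- property_table(
    "label", data.frame(subject = strip(iv$id), object = iv$label,
                        stringsAsFactors = FALSE))
  rest <- g$edges[g$edges$label != TYPE_LABEL, , drop = FALSE]
  relation_tables <- list()
  for (prop in unique(rest$label)) {
    sel <- rest[rest$label == prop, , drop = FALSE]
    relation_tables[[prop]] <- property_table(
      prop, data.frame(subject = strip(sel$from),
                       object = unname(lab[sel$to]), stringsAsFactors = FALSE))
  }
  list(class_table = class_table, label_table = label_table,
       relation_tables = relation_tables)
}
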
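# Schema graph: classes, relations, attributes and datatypes linked by the
# four axiom edge labels, plus the default diabetes domain schema.

#' Axiom and membership edge labels
#'
#' The five edge labels a knowledge base built with this package may use on
#' top of its own relation and attribute names: the four schema-level axiom
#' labels plus the instance-membership label.
#'
#' @format Character vectors.
#' @name edge-labels
NULL

#' @rdname edge-labels
#' @export
AXIOM_LABELS <- c("rdfs:domain", "rdfs:range", "rdfs:subClassOf",
                  "owl:disjointWith")

#' @rdname edge-labels
#' @export
TYPE_LABEL <- "rdf:type"

#' Construct a schema graph
#'
#' A schema graph holds the terminology of a knowledge base: class vertices
#' (kind `"C"`), relation vertices (`"R"`), attribute vertices (`"A"`) and
#' datatype vertices (`"D"`), connected by `rdfs:domain`, `rdfs:range`,
#' `rdfs:subClassOf` and `owl:disjointWith` edges.
#'
#' @param vertices `data.frame` with columns `id`, `kind` (one of
#'   `"C","R","A","D"`) and `label`.
#' @param edges `data.frame` with columns `from`, `label` (one of the four
#'   axiom labels) and `to`.
#' @return An object of class `schema_graph`.
#' @seealso [default_diabetes_schema()], [schema_check()]
#' @export
schema_graph <- function(vertices, edges) {
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need_v <- c("id", "kind", "label")
  need_e <- c("from", "label", "to")
  if (!all(need_v %in% names(vertices)))
    stopf("schema vertices need columns: %s", paste(need_v, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stopf("schema edges need columns: %s", paste(need_e, collapse = ", "))
  vertices[need_v] <- lapply(vertices[need_v], as.character)
  edges[need_e] <- lapply(edges[need_e], as.character)
  if (anyDuplicated(vertices$id))
    stopf("duplicate schema vertex ids: %s",
          paste(unique(vertices$id[duplicated(vertices$id)]), collapse = ", "))
  if (!all(vertices$kind %in% c("C", "R", "A", "D")))
    stopf("schema vertex kind must be one of C, R, A, D")
  structure(list(vertices = vertices[need_v], edges = edges[need_e]),
            class = "schema_graph")
}

#' @export
print.schema_graph <- function(x, ...) {
  k <- table(factor(x$vertices$kind, levels = c("C", "R", "A", "D")))
  cat(sprintf(
    "<schema_graph> %d classes, %d relations, %d attributes, %d datatypes, %d axiom edges\n",
    k[["C"]], k[["R"]], k[["A"]], k[["D"]], nrow(x$edges)))
  invisible(x)
}

schema_ids_of_kind <- function(schema, kind) {
  schema$vertices$id[schema$vertices$kind == kind]
}

#' Accessors for schema components
#'
#' @param schema A [schema_graph()].
#' @return Character vector of vertex ids.
#' @export
schema_classes <- function(schema) schema_ids_of_kind(schema, "C")

#' @rdname schema_classes
#' @export
schema_relations <- function(schema) schema_ids_of_kind(schema, "R")

#' @rdname schema_classes
#' @export
schema_attributes <- function(schema) schema_ids_of_kind(schema, "A")

# named list: relation/attribute id -> declared domain class ids
schema_domains <- function(schema) {
  e <- schema$edges[schema$edges$label == "rdfs:domain", ]
  split(e$to, factor(e$from, levels = unique(e$from)))
}

# named character: relation id -> range class id (attributes range over datatypes)
schema_ranges <- function(schema) {
  e <- schema$edges[schema$edges$label == "rdfs:range", ]
  stats::setNames(e$to, e$from)
}

#' Ancestors of a class under rdfs:subClassOf
#'
#' @param schema A [schema_graph()].
#' @param class_id Class vertex id.
#' @return Character vector of strict ancestors (transitive).
#' @export
class_ancestors <- function(schema, class_id) {
  sub <- schema$edges[schema$edges$label == "rdfs:subClassOf", c("from", "to")]
  out <- character(0)
  frontier <- class_id
  while (length(frontier)) {
    nxt <- unique(sub$to[sub$from %in% frontier])
    nxt <- setdiff(nxt, c(out, class_id))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# class id -> itself plus all ancestors, for every class
class_closure <- function(schema) {
  cls <- schema_classes(schema)
  stats::setNames(lapply(cls, function(cl) c(cl, class_ancestors(schema, cl))), cls)
}

#' Symmetric closure of owl:disjointWith
#'
#' @param schema A [schema_graph()].
#' @return Two-column `data.frame` (`a`, `b`) holding both directions of every
#'   declared disjointness.
#' @export
disjoint_pairs <- function(schema) {
  e <- schema$edges[schema$edges$label == "owl:disjointWith", c("from", "to")]
  out <- unique(rbind(
    data.frame(a = e$from, b = e$to, stringsAsFactors = FALSE),
    data.frame(a = e$to, b = e$from, stringsAsFactors = FALSE)))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Check schema-level invariants
#'
#' Verifies the axiom-edge typing rules (domain edges run from relations or
#' attributes to classes; range edges from attributes to datatypes or from
#' relations to classes; subclass and disjointness edges connect classes) and
#' that no class is declared disjoint with itself or with one of its
#' ancestors or descendants.
#'
#' @param schema A [schema_graph()].
#' @return Invisibly `TRUE`; a descriptive error otherwise.
#' @export
schema_check <- function(schema) {
  v <- schema$vertices
  kind <- stats::setNames(v$kind, v$id)
  e <- schema$edges
  if (!all(e$label %in% AXIOM_LABELS))
    stopf("unknown schema edge label: %s",
          paste(setdiff(e$label, AXIOM_LABELS), collapse = ", "))
  miss <- setdiff(c(e$from, e$to), v$id)
  if (length(miss))
    stopf("schema edges reference unknown vertices: %s", paste(miss, collapse = ", "))
  kf <- kind[e$from]; kt <- kind[e$to]
  bad <- (e$label == "rdfs:domain" & !(kf %in% c("A", "R") & kt == "C")) |
    (e$label == "rdfs:range" &
       !((kf == "A" & kt == "D") | (kf == "R" & kt == "C"))) |
    (e$label %in% c("rdfs:subClassOf", "owl:disjointWith") &
       !(kf == "C" & kt == "C"))
  if (any(bad))
    stopf("ill-typed axiom edge(s): %s",
          paste(sprintf("%s -%s-> %s", e$from[bad], e$label[bad], e$to[bad]),
                collapse = "; "))
  dj <- disjoint_pairs(schema)
  if (any(dj$a == dj$b)) stopf("class declared disjoint with itself")
  for (i in seq_len(nrow(dj))) {
    if (dj$b[i] %in% class_ancestors(schema, dj$a[i]))
      stopf("class %s disjoint with its ancestor %s", dj$a[i], dj$b[i])
  }
  invisible(TRUE)
}

#' The default diabetes domain schema
#'
#' Seven leaf classes cover the entity types the medical portals describe:
#' Disease, Symptom, TCM (traditional Chinese medicine), WesternMedicine,
#' Department, BodyStructure and Examination. A structural Medicine
#' superclass groups the two medicine classes via `rdfs:subClassOf`. Ten
#' relations connect the classes (all rooted at Disease, the portals'
#' page-per-disease layout), one `alias` attribute carries synonym strings,
#' and all seven leaf classes are declared pairwise `owl:disjointWith` — in
#' particular Disease and Symptom, the pair whose conflicting assignments
#' dominate cross-portal noise.
#'
#' @return A [schema_graph()] passing [schema_check()].
#' @examples
#' s <- default_diabetes_schema()
#' setdiff(schema_classes(s), "Medicine")  # the seven leaf classes
#' schema_relations(s)
#' @export
default_diabetes_schema <- function() {
  leaf <- c("Disease", "Symptom", "TCM", "WesternMedicine", "Department",
            "BodyStructure", "Examination")
  classes <- c(leaf, "Medicine")
  rel <- c(sign = "Symptom", causes = "Symptom",
           complication = "Disease", risk_factor = "Disease",
           related_disease = "Disease",
           treated_by_wm = "WesternMedicine", treated_by_tcm = "TCM",
           checked_by_exam = "Examination", belongs_to_dept = "Department",
           located_in_body = "BodyStructure")
  vertices <- rbind(
    data.frame(id = classes, kind = "C", label = classes,
               stringsAsFactors = FALSE),
    data.frame(id = names(rel), kind = "R", label = names(rel),
               stringsAsFactors = FALSE),
    data.frame(id = "alias", kind = "A", label = "alias",
               stringsAsFactors = FALSE),
    data.frame(id = "xsd:string", kind = "D", label = "string",
               stringsAsFactors = FALSE))
  dj <- t(utils::combn(leaf, 2))
  edges <- rbind(
    data.frame(from = names(rel), label = "rdfs:domain", to = "Disease",
               stringsAsFactors = FALSE),
    data.frame(from = names(rel), label = "rdfs:range", to = unname(rel),
               stringsAsFactors = FALSE),
    data.frame(from = "alias", label = "rdfs:domain", to = leaf,
               stringsAsFactors = FALSE),
    data.frame(from = "alias", label = "rdfs:range", to = "xsd:string",
               stringsAsFactors = FALSE),
    data.frame(from = c("TCM", "WesternMedicine"), label = "rdfs:subClassOf",
               to = "Medicine", stringsAsFactors = FALSE),
    data.frame(from = dj[, 1], label = "owl:disjointWith", to = dj[, 2],
               stringsAsFactors = FALSE))
  s <- schema_graph(vertices, edges)
  schema_check(s)
  s
}
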
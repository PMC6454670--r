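# Data graph: instance and value vertices with relation, attribute and
# rdf:type edges, plus validation against a companion schema graph.

#' Construct a data graph
#'
#' A data graph holds the assertional part of a knowledge base: instance
#' vertices (kind `"I"`, identified by URIs) and value vertices (kind `"V"`)
#' connected by relation edges (instance to instance), attribute edges
#' (instance to value) and `rdf:type` edges whose targets are class ids of a
#' companion [schema_graph()] (class ids are not vertices of the data graph).
#'
#' @param vertices `data.frame` with columns `id`, `kind` (`"I"` or `"V"`),
#'   `label`, `source` (provenance tag of the portal the vertex came from).
#' @param edges `data.frame` with columns `from`, `label`, `to`.
#' @return An object of class `data_graph`.
#' @export
data_graph <- function(vertices = NULL, edges = NULL) {
  need_v <- c("id", "kind", "label", "source")
  need_e <- c("from", "label", "to")
  if (is.null(vertices))
    vertices <- data.frame(id = character(0), kind = character(0),
                           label = character(0), source = character(0),
                           stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(from = character(0), label = character(0),
                        to = character(0), stringsAsFactors = FALSE)
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"source" %in% names(vertices)) vertices$source <- ""
  if (!all(c("id", "kind", "label") %in% names(vertices)))
    stopf("data-graph vertices need columns: id, kind, label")
  if (!all(need_e %in% names(edges)))
    stopf("data-graph edges need columns: %s", paste(need_e, collapse = ", "))
  vertices[need_v] <- lapply(vertices[need_v], as.character)
  edges[need_e] <- lapply(edges[need_e], as.character)
  if (anyDuplicated(vertices$id))
    stopf("duplicate vertex ids: %s",
          paste(unique(vertices$id[duplicated(vertices$id)]), collapse = ", "))
  if (!all(vertices$kind %in% c("I", "V")))
    stopf("data-graph vertex kind must be I or V")
  rownames(vertices) <- NULL
  rownames(edges) <- NULL
  structure(list(vertices = vertices[need_v], edges = edges[need_e]),
            class = "data_graph")
}

#' @export
print.data_graph <- function(x, ...) {
  cat(sprintf("<data_graph> %d instances, %d values, %d edges (%d rdf:type)\n",
              sum(x$vertices$kind == "I"), sum(x$vertices$kind == "V"),
              nrow(x$edges), sum(x$edges$label == TYPE_LABEL)))
  invisible(x)
}

#' Instance ids of a data graph
#' @param g A [data_graph()].
#' @return Character vector of I-vertex ids.
#' @export
instances <- function(g) g$vertices$id[g$vertices$kind == "I"]

# named character: instance id -> declared class(es); returns edge frame
type_edges <- function(g) g$edges[g$edges$label == TYPE_LABEL, , drop = FALSE]

#' Validate a data graph against a schema
#'
#' Checks every edge and typing assertion against the schema's restrictions
#' and returns one row per breach. Rules:
#' \describe{
#'   \item{edge-kind}{edge endpoints must exist; relation and attribute edges
#'     must start at an instance; edges whose label is a declared attribute
#'     must end at a value vertex; edge labels must be declared in the schema
#'     (a relation label may point at a value vertex — the object literal
#'     fallback used when an extraction could not resolve a label to an
#'     instance).}
#'   \item{type-target}{`rdf:type` targets must be schema class ids.}
#'   \item{domain}{a typed subject of a relation/attribute must carry (or
#'     inherit) one of the label's declared domain classes; untyped subjects
#'     are not flagged.}
#'   \item{range}{a typed instance object of a relation must carry (or
#'     inherit) the relation's range class.}
#'   \item{disjoint}{no instance may be typed with two classes that are
#'     disjoint after symmetric closure; reported once per instance and
#'     class pair.}
#' }
#'
#' @param g A [data_graph()].
#' @param schema A [schema_graph()].
#' @return `data.frame` with columns `rule`, `subject`, `detail`; zero rows
#'   iff the graph is consistent.
#' @export
validate_graph <- function(g, schema) {
  viol <- list()
  add <- function(rule, subject, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, subject = subject, detail = detail, stringsAsFactors = FALSE)
  }
  v <- g$vertices
  kind <- stats::setNames(v$kind, v$id)
  e <- g$edges
  rels <- schema_relations(schema)
  attrs <- schema_attributes(schema)
  classes <- schema_classes(schema)
  doms <- schema_domains(schema)
  rngs <- schema_ranges(schema)
  clos <- class_closure(schema)
  dj <- disjoint_pairs(schema)
  djkey <- paste(dj$a, dj$b)

  te <- e[e$label == TYPE_LABEL, , drop = FALSE]
  types_of <- split(te$to, te$from)

  # classes an instance carries, expanded with ancestors
  expand <- function(cls) unique(unlist(clos[intersect(cls, classes)]))

  for (i in seq_len(nrow(e))) {
    s <- e$from[i]; p <- e$label[i]; o <- e$to[i]
    if (is.na(kind[s])) {
      add("edge-kind", s, sprintf("edge <%s,%s,%s>: unknown subject vertex", s, p, o))
      next
    }
    if (p == TYPE_LABEL) {
      if (kind[s] != "I")
        add("edge-kind", s, sprintf("rdf:type subject %s is not an instance", s))
      if (!o %in% classes) {
        add("type-target", s, sprintf("rdf:type target %s is not a schema class", o))
      }
      next
    }
    if (!p %in% c(rels, attrs)) {
      add("edge-kind", s, sprintf("edge <%s,%s,%s>: label not declared in schema", s, p, o))
      next
    }
    if (is.na(kind[o])) {
      add("edge-kind", s, sprintf("edge <%s,%s,%s>: unknown object vertex", s, p, o))
      next
    }
    if (kind[s] != "I")
      add("edge-kind", s, sprintf("edge <%s,%s,%s>: subject is a value vertex", s, p, o))
    if (p %in% attrs && kind[o] != "V")
      add("edge-kind", s, sprintf("edge <%s,%s,%s>: attribute object must be a value", s, p, o))
    # domain (subjects with no resolvable class are handled by type-target)
    stypes <- intersect(types_of[[s]], classes)
    dcl <- doms[[p]]
    if (length(stypes) && length(dcl) &&
        !length(intersect(expand(stypes), dcl)))
      add("domain", s, sprintf("subject of %s must be a %s", p,
                               paste(dcl, collapse = "|")))
    # range (relation edges with instance objects only)
    if (p %in% rels && kind[o] == "I") {
      otypes <- intersect(types_of[[o]], classes)
      rcl <- rngs[[p]]
      if (length(otypes) && !is.na(rcl) && !rcl %in% expand(otypes))
        add("range", o, sprintf("object of %s must be a %s", p, rcl))
    }
  }

  # disjointness per instance over declared (and inherited) classes
  for (s in names(types_of)) {
    tys <- unique(types_of[[s]])
    tys <- intersect(tys, classes)
    if (length(tys) < 2) next
    exp_tys <- lapply(tys, function(t) clos[[t]])
    for (a in seq_along(tys)) {
      for (b in seq_along(tys)) {
        if (a >= b) next
        pairs <- expand.grid(x = exp_tys[[a]], y = exp_tys[[b]],
                             stringsAsFactors = FALSE)
        if (any(paste(pairs$x, pairs$y) %in% djkey))
          add("disjoint", s, sprintf("typed both %s and %s (disjoint)",
                                     tys[a], tys[b]))
      }
    }
  }

  if (!length(viol))
    return(data.frame(rule = character(0), subject = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, viol)
  rownames(out) <- NULL
  out
}

#' Union of several data graphs
#'
#' Vertex sets are expected to be namespaced per source so the union is
#' disjoint; a vertex id recurring with a conflicting label signals a
#' malformed input and is an error. Edges are deduplicated per
#' (subject, predicate, object).
#'
#' @param graphs List of [data_graph()]s.
#' @return A single [data_graph()].
#' @export
merge_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  v <- do.call(rbind, lapply(graphs, function(g) g$vertices))
  e <- do.call(rbind, lapply(graphs, function(g) g$edges))
  v <- unique(v)
  dup <- v$id[duplicated(v$id)]
  if (length(dup))
    stopf("conflicting duplicate vertex id(s) across graphs: %s",
          paste(unique(dup), collapse = ", "))
  e <- unique(e)
  data_graph(v, e)
}
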
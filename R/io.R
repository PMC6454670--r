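# Serialisation: Turtle and N-Triples for schema and data graphs, TSV for
# property tables and reports, JSON-lines for portal dumps. The writers and
# readers cover exactly the subset the package emits: absolute IRIs,
# language-less literals with standard escapes, and (in Turtle) prefixed
# names, one triple per line. All files are UTF-8.

RDF_TYPE_IRI <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL_IRI <- "http://www.w3.org/2000/01/rdf-schema#label"
SCHEMA_NS <- "dkb://schema/"
META_NS <- "dkb://meta/"

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[[k]], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        i <- i + 2L
      } else {
        buf <- c(buf, ch)
        i <- i + 1L
      }
    }
    out[k] <- paste(buf, collapse = "")
  }
  out
}

# internal predicate name -> IRI
pred_iri <- function(p) {
  ifelse(p == TYPE_LABEL, RDF_TYPE_IRI,
         ifelse(p == "rdfs:label", RDFS_LABEL_IRI,
                ifelse(grepl("^(rdfs|owl):", p),
                       ifelse(grepl("^rdfs:", p),
                              paste0("http://www.w3.org/2000/01/rdf-schema#",
                                     sub("^rdfs:", "", p)),
                              paste0("http://www.w3.org/2002/07/owl#",
                                     sub("^owl:", "", p))),
                       paste0(SCHEMA_NS, p))))
}

iri_pred <- function(iri) {
  ifelse(iri == RDF_TYPE_IRI, TYPE_LABEL,
         ifelse(iri == RDFS_LABEL_IRI, "rdfs:label",
                ifelse(startsWith(iri, "http://www.w3.org/2000/01/rdf-schema#"),
                       paste0("rdfs:", sub(".*#", "", iri)),
                       ifelse(startsWith(iri, "http://www.w3.org/2002/07/owl#"),
                              paste0("owl:", sub(".*#", "", iri)),
                              sub(paste0("^", SCHEMA_NS), "", iri)))))
}

empty_triples <- function() {
  data.frame(s = character(0), p = character(0), o = character(0),
             lit = logical(0), stringsAsFactors = FALSE)
}

tri_df <- function(s, p, o, lit) {
  if (!length(s)) return(NULL)
  data.frame(s = unname(s), p = rep_len(unname(p), length(s)),
             o = unname(o), lit = rep_len(lit, length(s)),
             stringsAsFactors = FALSE)
}

# data graph -> triple frame (s, p, o, lit); V-vertex objects are literals
graph_to_triples <- function(g) {
  iv <- g$vertices[g$vertices$kind == "I", , drop = FALSE]
  kind <- stats::setNames(g$vertices$kind, g$vertices$id)
  vlab <- stats::setNames(g$vertices$label, g$vertices$id)
  tr <- list(
    tri_df(iv$id, RDFS_LABEL_IRI, iv$label, TRUE),
    tri_df(iv$id[nzchar(iv$source)], paste0(META_NS, "source"),
           iv$source[nzchar(iv$source)], TRUE))
  e <- g$edges
  if (nrow(e)) {
    is_type <- e$label == TYPE_LABEL
    to_value <- !is_type & !is.na(kind[e$to]) & kind[e$to] == "V"
    plain <- !is_type & !to_value
    tr <- c(tr, list(
      tri_df(e$from[is_type], RDF_TYPE_IRI,
             paste0(SCHEMA_NS, e$to[is_type]), FALSE),
      tri_df(e$from[to_value], pred_iri(e$label[to_value]),
             unname(vlab[e$to[to_value]]), TRUE),
      tri_df(e$from[plain], pred_iri(e$label[plain]), e$to[plain], FALSE)))
  }
  tr <- tr[!vapply(tr, is.null, TRUE)]
  if (!length(tr)) return(empty_triples())
  out <- unique(do.call(rbind, tr))
  rownames(out) <- NULL
  out
}

triples_to_graph <- function(tr) {
  if (!nrow(tr)) return(data_graph())
  meta_source <- paste0(META_NS, "source")
  subj <- unique(tr$s)
  lab <- stats::setNames(rep(NA_character_, length(subj)), subj)
  src <- stats::setNames(rep("", length(subj)), subj)
  sel <- tr$p == RDFS_LABEL_IRI & tr$lit
  lab[tr$s[sel]] <- tr$o[sel]
  sel <- tr$p == meta_source & tr$lit
  src[tr$s[sel]] <- tr$o[sel]
  rest <- tr[!(tr$p %in% c(RDFS_LABEL_IRI, meta_source)), , drop = FALSE]

  iri_obj <- rest[!rest$lit & rest$p != RDF_TYPE_IRI, , drop = FALSE]
  inst <- unique(c(tr$s, iri_obj$o))
  lab2 <- ifelse(is.na(lab[inst]), inst, lab[inst])
  vertices <- data.frame(id = inst, kind = "I", label = lab2,
                         source = ifelse(is.na(src[inst]), "", src[inst]),
                         stringsAsFactors = FALSE)
  edges <- list()
  te <- rest[rest$p == RDF_TYPE_IRI, , drop = FALSE]
  if (nrow(te))
    edges[[1]] <- data.frame(from = te$s, label = TYPE_LABEL,
                             to = sub(paste0("^", SCHEMA_NS), "", te$o),
                             stringsAsFactors = FALSE)
  if (nrow(iri_obj))
    edges[[length(edges) + 1L]] <- data.frame(
      from = iri_obj$s, label = iri_pred(iri_obj$p), to = iri_obj$o,
      stringsAsFactors = FALSE)
  litt <- rest[rest$lit, , drop = FALSE]
  if (nrow(litt)) {
    vid <- sprintf("urn:value:%04d", seq_len(nrow(litt)))
    vsrc <- src[litt$s]
    vertices <- rbind(vertices, data.frame(
      id = vid, kind = "V", label = litt$o,
      source = ifelse(is.na(vsrc), "", vsrc), stringsAsFactors = FALSE))
    edges[[length(edges) + 1L]] <- data.frame(
      from = litt$s, label = iri_pred(litt$p), to = vid,
      stringsAsFactors = FALSE)
  }
  data_graph(vertices,
             if (length(edges)) do.call(rbind, edges) else NULL)
}

schema_to_triples <- function(s) {
  v <- s$vertices
  sid <- function(x) paste0(SCHEMA_NS, x)
  tr <- list(
    data.frame(s = sid(v$id), p = paste0(META_NS, "kind"), o = v$kind,
               lit = TRUE, stringsAsFactors = FALSE),
    data.frame(s = sid(v$id), p = RDFS_LABEL_IRI, o = v$label, lit = TRUE,
               stringsAsFactors = FALSE))
  if (nrow(s$edges))
    tr[[3]] <- data.frame(s = sid(s$edges$from), p = pred_iri(s$edges$label),
                          o = sid(s$edges$to), lit = FALSE,
                          stringsAsFactors = FALSE)
  out <- do.call(rbind, tr)
  rownames(out) <- NULL
  out
}

triples_to_schema <- function(tr) {
  strip <- function(x) sub(paste0("^", SCHEMA_NS), "", x)
  kind_p <- paste0(META_NS, "kind")
  vk <- tr[tr$p == kind_p, , drop = FALSE]
  vl <- tr[tr$p == RDFS_LABEL_IRI, , drop = FALSE]
  lab <- stats::setNames(vl$o, strip(vl$s))
  vertices <- data.frame(id = strip(vk$s), kind = vk$o,
                         label = unname(lab[strip(vk$s)]),
                         stringsAsFactors = FALSE)
  ed <- tr[!tr$lit & tr$p != RDF_TYPE_IRI, , drop = FALSE]
  edges <- data.frame(from = strip(ed$s), label = iri_pred(ed$p),
                      to = strip(ed$o), stringsAsFactors = FALSE)
  schema_graph(vertices, edges)
}

format_term <- function(x, lit) {
  lit <- rep_len(lit, length(x))
  ifelse(lit, paste0("\"", escape_literal(x), "\""), paste0("<", x, ">"))
}

write_triples_nt <- function(tr, path) {
  lines <- sprintf("%s %s %s .", format_term(tr$s, FALSE),
                   format_term(tr$p, FALSE), format_term(tr$o, tr$lit))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

TTL_PREFIXES <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
                  owl = "http://www.w3.org/2002/07/owl#",
                  dkb = SCHEMA_NS, meta = META_NS)

compact_iri <- function(x) {
  out <- paste0("<", x, ">")
  for (pfx in names(TTL_PREFIXES)) {
    ns <- TTL_PREFIXES[[pfx]]
    hit <- startsWith(x, ns) & grepl("^[A-Za-z_][A-Za-z0-9_.-]*$",
                                     substring(x, nchar(ns) + 1L))
    out[hit] <- paste0(pfx, ":", substring(x[hit], nchar(ns) + 1L))
  }
  out
}

write_triples_ttl <- function(tr, path) {
  head_lines <- sprintf("@prefix %s: <%s> .", names(TTL_PREFIXES),
                        TTL_PREFIXES)
  body <- sprintf("%s %s %s .", compact_iri(tr$s), compact_iri(tr$p),
                  ifelse(tr$lit, paste0("\"", escape_literal(tr$o), "\""),
                         compact_iri(tr$o)))
  writeLines(c(head_lines, "", body), path, useBytes = TRUE)
  invisible(path)
}

TERM_RE <- paste0("(<[^>]*>",                      # IRI
                  "|\"(?:[^\"\\\\]|\\\\.)*\"",     # literal
                  "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*)")  # pname

parse_triple_line <- function(line, lineno, prefixes, path) {
  rx <- paste0("^\\s*", TERM_RE, "\\s+", TERM_RE, "\\s+", TERM_RE,
               "\\s*\\.\\s*$")
  m <- regmatches(line, regexec(rx, line, perl = TRUE))[[1]]
  if (length(m) != 4L)
    stopf("%s:%d: malformed triple: %s", path, lineno, line)
  term <- function(tok) {
    if (startsWith(tok, "<"))
      return(list(v = substring(tok, 2, nchar(tok) - 1L), lit = FALSE))
    if (startsWith(tok, "\""))
      return(list(v = unescape_literal(substring(tok, 2, nchar(tok) - 1L)),
                  lit = TRUE))
    pfx <- sub(":.*$", "", tok)
    if (!pfx %in% names(prefixes))
      stopf("%s:%d: undeclared prefix '%s'", path, lineno, pfx)
    list(v = paste0(prefixes[[pfx]], sub("^[^:]*:", "", tok)), lit = FALSE)
  }
  s <- term(m[2]); p <- term(m[3]); o <- term(m[4])
  data.frame(s = s$v, p = p$v, o = o$v, lit = o$lit, stringsAsFactors = FALSE)
}

read_triples_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  prefixes <- character(0)
  rows <- list()
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    if (grepl("^@prefix", trimws(line))) {
      m <- regmatches(line,
                      regexec("^\\s*@prefix\\s+([A-Za-z_][A-Za-z0-9_.-]*):\\s*<([^>]*)>\\s*\\.\\s*$",
                              line))[[1]]
      if (length(m) != 3L) stopf("%s:%d: malformed @prefix line", path, k)
      prefixes[m[2]] <- m[3]
      next
    }
    rows[[length(rows) + 1L]] <- parse_triple_line(line, k, prefixes, path)
  }
  if (!length(rows))
    return(data.frame(s = character(0), p = character(0), o = character(0),
                      lit = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a graph as N-Triples or Turtle
#'
#' @param x A [data_graph()] or [schema_graph()].
#' @param path Output file (UTF-8). [write_turtle()] emits prefixed names,
#'   one triple per line.
#' @return The path, invisibly.
#' @export
write_ntriples <- function(x, path) {
  tr <- if (inherits(x, "schema_graph")) schema_to_triples(x) else
    graph_to_triples(x)
  write_triples_nt(tr, path)
}

#' @rdname write_ntriples
#' @export
write_turtle <- function(x, path) {
  tr <- if (inherits(x, "schema_graph")) schema_to_triples(x) else
    graph_to_triples(x)
  write_triples_ttl(tr, path)
}

#' Read a graph from N-Triples or Turtle
#'
#' Inverse of [write_ntriples()] / [write_turtle()] up to triple order.
#' Value-vertex identifiers are regenerated on read; the (subject,
#' predicate, object) triple set and all validation output are preserved.
#'
#' @param path Input file.
#' @param what `"data"` for a [data_graph()], `"schema"` for a
#'   [schema_graph()].
#' @return The graph object.
#' @export
read_ntriples <- function(path, what = c("data", "schema")) {
  what <- match.arg(what)
  tr <- read_triples_file(path)
  if (what == "schema") triples_to_schema(tr) else triples_to_graph(tr)
}

#' @rdname read_ntriples
#' @export
read_turtle <- read_ntriples

#' Write / read a property table as headered TSV
#'
#' @param pt A [property_table()].
#' @param path TSV file; the property name becomes the file's base name on
#'   write and is recovered from it on read unless given.
#' @param property Property name override for [read_property_table()].
#' @return The path (write) or a [property_table()] (read).
#' @export
write_property_table <- function(pt, path) {
  utils::write.table(pt$rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_property_table
#' @export
read_property_table <- function(path, property = NULL) {
  property <- property %||% sub("\\.tsv$", "", basename(path))
  rows <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            fileEncoding = "UTF-8")
  property_table(property, rows)
}

#' Write a violations table as TSV
#'
#' @param violations Output of [validate_graph()].
#' @param path TSV file.
#' @return The path, invisibly.
#' @export
write_violations <- function(violations, path) {
  utils::write.table(violations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a portal dump as JSON-lines
#'
#' One JSON object per navigation row: `identifier`, `label`, `class` and
#' the detail `entries` (possibly empty). The source tag defaults to the
#' file's base name on read.
#'
#' @param dump A [portal_dump()].
#' @param path JSONL file.
#' @param source Source-tag override for [read_portal_dump()].
#' @return The path (write) or a [portal_dump()] (read).
#' @export
write_portal_dump <- function(dump, path) {
  nav <- dump$navigation
  lines <- vapply(seq_len(nrow(nav)), function(i) {
    ident <- nav$identifier[i]
    entries <- lapply(dump$records[[ident]] %||% list(), function(e)
      list(kind = e$kind, topic = e$topic,
           payload = as.list(as.character(e$payload))))
    jsonlite::toJSON(list(identifier = ident, label = nav$label[i],
                          class = nav$class[i], entries = entries),
                     auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_portal_dump
#' @export
read_portal_dump <- function(path, source = NULL) {
  source <- source %||% sub("\\.jsonl$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
  nav <- data.frame(
    identifier = vapply(recs, function(r) r$identifier, ""),
    label = vapply(recs, function(r) r$label, ""),
    class = vapply(recs, function(r) r$class, ""),
    stringsAsFactors = FALSE)
  records <- list()
  for (r in recs) {
    if (!length(r$entries)) next
    records[[r$identifier]] <- lapply(r$entries, function(e)
      list(kind = e$kind, topic = e$topic,
           payload = as.character(unlist(e$payload))))
  }
  portal_dump(source, nav, records)
}

#' Read seed labels or URIs from a plain-text file
#'
#' One label or URI per line; blank lines and `#` comments are skipped.
#'
#' @param path Text file.
#' @return Character vector.
#' @export
read_seeds <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
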
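# Workflow plumbing: corpus directories, the end-to-end run
# (extract -> D2R -> cleanse -> match -> fuse -> EM), and run statistics.

#' Write a synthetic corpus to a directory
#'
#' Lays out one JSONL dump per portal, the reference code list
#' (`codes.tsv`), EM seed labels (`seeds.txt`), the master graph
#' (`master.nt`), the ground truth (`truth.json`), the configuration
#' (`config.json`) and a manifest with the seed and per-file counts.
#'
#' @param corpus A `portal_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "portal_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("cannot create corpus directory %s", dir)
  for (p in names(corpus$dumps))
    write_portal_dump(corpus$dumps[[p]], file.path(dir, paste0(p, ".jsonl")))
  utils::write.table(corpus$codes$entries, file.path(dir, "codes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  writeLines(corpus$seed_labels, file.path(dir, "seeds.txt"), useBytes = TRUE)
  write_ntriples(corpus$master, file.path(dir, "master.nt"))
  truth <- corpus$truth
  jsonlite::write_json(
    list(ids = truth$ids, labels = as.list(truth$labels),
         class_of = as.list(truth$class_of), aliases = truth$aliases,
         topic = truth$topic,
         closed_neighborhood = truth$closed_neighborhood,
         uri_map = truth$uri_map),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- corpus$config
  cfg$coverage <- NULL  # matrices round-trip poorly; reconstructable from seed
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = corpus$config$seed,
    portals = names(corpus$dumps),
    n_sources = length(corpus$dumps),
    navigation_rows = vapply(corpus$dumps, function(d) nrow(d$navigation), 0L),
    n_codes = nrow(corpus$codes$entries),
    n_seeds = length(corpus$seed_labels))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate and write a corpus in one step
#'
#' @param config A [corpus_config()].
#' @param dir Output directory.
#' @return The `portal_corpus`, invisibly; files as in [write_corpus()].
#' @export
simulate_corpus <- function(config = corpus_config(), dir) {
  corpus <- generate_corpus(config)
  write_corpus(corpus, dir)
  invisible(corpus)
}

#' Read a corpus directory
#'
#' @param dir Directory written by [write_corpus()].
#' @return List with `dumps`, `codes`, `seed_labels`, `truth` (when
#'   `truth.json` is present) and `manifest`.
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) stopf("corpus directory %s does not exist", dir)
  dump_files <- sort(list.files(dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (!length(dump_files)) stopf("no portal dumps (*.jsonl) in %s", dir)
  dumps <- stats::setNames(lapply(dump_files, read_portal_dump),
                           sub("\\.jsonl$", "", basename(dump_files)))
  codes_path <- file.path(dir, "codes.tsv")
  codes <- if (file.exists(codes_path))
    reference_code_list(utils::read.table(codes_path, sep = "\t",
                                          header = TRUE,
                                          colClasses = "character",
                                          quote = "",
                                          fileEncoding = "UTF-8"))
  else reference_code_list()
  seeds_path <- file.path(dir, "seeds.txt")
  seed_labels <- if (file.exists(seeds_path)) read_seeds(seeds_path)
  else character(0)
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(
      ids = tj$ids,
      labels = unlist(tj$labels),
      class_of = unlist(tj$class_of),
      aliases = tj$aliases,
      topic = tj$topic,
      closed_neighborhood = tj$closed_neighborhood,
      uri_map = as.data.frame(tj$uri_map, stringsAsFactors = FALSE))
  }
  manifest <- NULL
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath)) manifest <- jsonlite::read_json(mpath)
  list(dumps = dumps, codes = codes, seed_labels = seed_labels,
       truth = truth, manifest = manifest)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full construction pipeline
#'
#' Executes extraction, D2R materialisation, class cleansing, instance
#' matching, fusion and the EM topic extraction over a corpus (a directory
#' or an in-memory `portal_corpus`), and optionally writes the unified KB,
#' the topic KB, reports and a manifest to `out_dir`. Any stage error
#' aborts with the stage name.
#'
#' @param corpus Corpus directory path or `portal_corpus`.
#' @param out_dir Optional output directory.
#' @param schema A [schema_graph()].
#' @param lexicon A [heuristic_lexicon()].
#' @param match_cfg A [match_config()].
#' @param em_cfg An [em_config()].
#' @param seeds Optional seed labels/URIs (defaults to the corpus seed
#'   file).
#' @param cleanse_method Passed to [cleanse_classes()].
#' @return List with `portal_graphs`, `integrated` (cleansed, with
#'   mappings), `fused`, `topic_kb`, `trace`, `stats`, `reports`.
#' @export
run_pipeline <- function(corpus, out_dir = NULL,
                         schema = default_diabetes_schema(),
                         lexicon = default_lexicon(),
                         match_cfg = match_config(),
                         em_cfg = em_config(),
                         seeds = NULL,
                         cleanse_method = "combined") {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  dumps <- corpus$dumps
  seeds <- seeds %||% corpus$seed_labels
  if (!length(seeds))
    stopf("pipeline stage 'em' failed: no seeds given and no seeds.txt in corpus")

  portal_graphs <- run_stage("extract+d2r", {
    lapply(dumps, function(d) {
      tabs <- extract_tables(d, lexicon)
      d2r_materialize(tabs$class_table,
                      c(list(label = tabs$label_table), tabs$relation_tables),
                      schema, paste0(d$source, "://"), d$source)
    })
  })
  integrated <- run_stage("cleanse", {
    cleanse_classes(integrated_data_graph(portal_graphs), corpus$codes,
                    schema, method = cleanse_method)
  })
  cleanse_report <- attr(integrated, "report")
  integrated <- run_stage("match", match_all(integrated, match_cfg))
  attr(integrated, "report") <- cleanse_report
  fused <- run_stage("fuse", fuse(integrated, schema))
  em <- run_stage("em", em_run(fused, seeds, em_cfg))

  stats_tab <- rbind(
    do.call(rbind, lapply(names(portal_graphs), function(p) {
      g <- portal_graphs[[p]]
      data.frame(source = p, instances = sum(g$vertices$kind == "I"),
                 edges = nrow(g$edges), stringsAsFactors = FALSE)
    })),
    data.frame(source = "Overall KB",
               instances = sum(fused$vertices$kind == "I"),
               edges = nrow(fused$edges), stringsAsFactors = FALSE),
    data.frame(source = "Topic KB",
               instances = sum(em$graph$vertices$kind == "I"),
               edges = nrow(em$graph$edges), stringsAsFactors = FALSE))

  reports <- list(cleansing = cleanse_report,
                  mappings = integrated$mappings,
                  rejects = do.call(rbind, lapply(portal_graphs, attr, "rejects")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ntriples(fused, file.path(out_dir, "overall_kb.nt"))
    write_turtle(fused, file.path(out_dir, "overall_kb.ttl"))
    write_ntriples(em$graph, file.path(out_dir, "topic_kb.nt"))
    write_turtle(em$graph, file.path(out_dir, "topic_kb.ttl"))
    utils::write.table(integrated$mappings, file.path(out_dir, "mappings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(reports$cleansing, file.path(out_dir, "cleansing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(em$trace, file.path(out_dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stats_tab, file.path(out_dir, "stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_sources = length(dumps), seeds = seeds,
           match = unclass(match_cfg), em = unclass(em_cfg),
           cleanse_method = cleanse_method,
           stage_counts = stats::setNames(stats_tab$instances,
                                          stats_tab$source)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(portal_graphs = portal_graphs, integrated = integrated, fused = fused,
       topic_kb = em$graph, trace = em$trace, stats = stats_tab,
       reports = reports)
}

#' Recount instances and edges of serialised pipeline outputs
#'
#' Reads the graphs a pipeline run wrote and recounts their sizes — a
#' consistency check for the `stats.tsv` summary.
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return `data.frame` with columns `file`, `instances`, `edges`.
#' @export
pipeline_stats <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.nt$", full.names = TRUE)
  do.call(rbind, lapply(files, function(f) {
    g <- read_ntriples(f)
    data.frame(file = basename(f),
               instances = sum(g$vertices$kind == "I"),
               edges = nrow(g$edges), stringsAsFactors = FALSE)
  }))
}
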
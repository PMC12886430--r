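## Memory graph serialization: a documented JSON schema and GraphML (via
## igraph). Round trips are lossless over items, prototypes, counts, edges
## and the sequence registry.

memory_to_doc <- function(g) {
  list(
    format = "entrosim-memory",
    version = 1L,
    dim = g$dim,
    items = lapply(seq_len(n_items(g)), function(i)
      list(id = i, prototype = as.numeric(g$prototypes[i, ]), count = g$counts[i])),
    edges = lapply(seq_len(nrow(g$edges)), function(k)
      list(from = g$edges$from[k], to = g$edges$to[k], count = g$edges$count[k])),
    sequences = lapply(g$sequences, as.integer),
    open = as.integer(g$open)
  )
}

memory_from_doc <- function(doc) {
  if (!identical(doc$format, "entrosim-memory"))
    stopf("not an entrosim memory document (format field: %s)",
          doc$format %||% "<missing>")
  g <- memory_graph(doc$dim)
  n <- length(doc$items)
  if (n > 0) {
    g$prototypes <- do.call(rbind, lapply(doc$items, function(it) as.numeric(it$prototype)))
    if (ncol(g$prototypes) != doc$dim) stopf("prototype dimension mismatch in document")
    g$counts <- vapply(doc$items, function(it) as.integer(it$count), integer(1))
  }
  if (length(doc$edges) > 0) {
    g$edges <- data.frame(
      from = vapply(doc$edges, function(e) as.integer(e$from), integer(1)),
      to = vapply(doc$edges, function(e) as.integer(e$to), integer(1)),
      count = vapply(doc$edges, function(e) as.integer(e$count), integer(1)))
    bad <- with(g$edges, from < 1 | from > n | to < 1 | to > n)
    if (any(bad))
      stopf("dangling edge at position %d: endpoints outside item set",
            which(bad)[1])
  }
  g$sequences <- lapply(doc$sequences, function(s) {
    s <- as.integer(s)
    if (length(s) && (min(s) < 1 || max(s) > n)) stopf("sequence references unknown item")
    s
  })
  g$open <- as.integer(doc$open %||% integer(0))
  g
}

#' Export / import a memory graph
#'
#' `export_memory()` writes a [memory_graph()] either as a documented JSON
#' schema (`format = "json"`) or as GraphML (`format = "graphml"`, through
#' igraph; prototypes are stored as comma-joined vertex attributes and the
#' sequence registry as a JSON graph attribute). `import_memory()` reads
#' either format back losslessly; malformed documents (e.g. dangling edges)
#' raise an error naming the offending element.
#'
#' @param g a [memory_graph()].
#' @param path output file; with `format = "json"` and `path = NULL` the JSON
#'   string is returned instead.
#' @param format `"json"` or `"graphml"` (inferred from the file extension on
#'   import).
#' @return `export_memory()` the path (or JSON string) invisibly;
#'   `import_memory()` a [memory_graph()].
#' @export
export_memory <- function(g, path = NULL, format = c("json", "graphml")) {
  stopifnot(inherits(g, "memory_graph"))
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(memory_to_doc(g), digits = NA, auto_unbox = TRUE)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    return(invisible(path))
  }
  if (is.null(path)) stopf("graphml export needs a path")
  n <- n_items(g)
  ig <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (n > 0) {
    igraph::V(ig)$name <- as.character(seq_len(n))
    igraph::V(ig)$count <- g$counts
    igraph::V(ig)$prototype <- vapply(seq_len(n), function(i)
      paste(format(g$prototypes[i, ], digits = 17), collapse = ","), character(1))
  }
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, rbind(g$edges$from, g$edges$to))
    igraph::E(ig)$count <- g$edges$count
  }
  ig <- igraph::set_graph_attr(ig, "dim", g$dim)
  ig <- igraph::set_graph_attr(ig, "sequences",
                               as.character(jsonlite::toJSON(g$sequences)))
  ig <- igraph::set_graph_attr(ig, "open",
                               as.character(jsonlite::toJSON(as.integer(g$open))))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname export_memory
#' @export
import_memory <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path)) "graphml" else "json"
  if (format == "json") {
    txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "\n") else path
    return(memory_from_doc(jsonlite::fromJSON(txt, simplifyVector = FALSE)))
  }
  ig <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(ig)
  g <- memory_graph(as.integer(igraph::graph_attr(ig, "dim")))
  if (n > 0) {
    ord <- order(as.integer(igraph::V(ig)$name))
    g$prototypes <- do.call(rbind, lapply(igraph::V(ig)$prototype[ord], function(s)
      as.numeric(strsplit(s, ",")[[1]])))
    g$counts <- as.integer(igraph::V(ig)$count[ord])
  }
  el <- igraph::as_edgelist(ig, names = TRUE)
  if (nrow(el) > 0) {
    g$edges <- data.frame(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                          count = as.integer(igraph::E(ig)$count))
  }
  g$sequences <- lapply(jsonlite::fromJSON(igraph::graph_attr(ig, "sequences"),
                                           simplifyVector = FALSE),
                        function(s) as.integer(unlist(s)))
  g$open <- as.integer(unlist(jsonlite::fromJSON(igraph::graph_attr(ig, "open"))))
  g
}
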
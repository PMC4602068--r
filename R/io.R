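#' Read gene sets from a GMT file
#'
#' GMT (Gene Matrix Transposed) is the tab-delimited one-set-per-line format:
#' set id, description, then one field per member gene (the MSigDB dialect;
#' URLs in the description pass through verbatim). GMT carries no species or
#' tier metadata, so defaults (or a sidecar metadata table) supply them.
#' Duplicate genes within a line are collapsed with a warning.
#'
#' @param path Path to a GMT file (UTF-8).
#' @param species,tier Defaults applied to every set.
#' @param metadata Optional data frame keyed by `set_id` with any of `name`,
#'   `abbreviation`, `description`, `species`, `tier` overriding the wire
#'   form and defaults.
#' @return A [gene_set_collection()], one set per line in file order.
#' @export
read_gmt <- function(path, species = "unknown", tier = "V", metadata = NULL) {
  if (!file.exists(path)) {
    stop_data(sprintf("file not found: %s", path), class = "setweaver_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop_data(sprintf("GMT parse error at line %d: expected >= 3 tab-delimited fields, got %d",
                        i, length(fields)),
                class = "setweaver_parse_error")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("line %d (%s): %d duplicate gene id(s) collapsed",
                   i, fields[[1L]], sum(duplicated(members))))
      members <- members[!duplicated(members)]
    }
    meta_of <- function(field, default) {
      if (is.null(metadata) || !field %in% names(metadata)) return(default)
      hit <- metadata[[field]][match(fields[[1L]], metadata$set_id)]
      if (length(hit) == 0L || is.na(hit)) default else hit
    }
    sets[[i]] <- gene_set(
      fields[[1L]], members,
      name = meta_of("name", fields[[1L]]),
      abbreviation = meta_of("abbreviation", fields[[1L]]),
      description = meta_of("description", fields[[2L]]),
      species = meta_of("species", species),
      tier = meta_of("tier", tier)
    )
  }
  gene_set_collection(sets)
}

#' Write a collection to a GMT file
#'
#' Members are written in stored order, so output is byte-stable across runs
#' and `read_gmt(write_gmt(x))` reproduces set ids and memberships exactly.
#' Per-gene scores are not representable in GMT; use [write_geneset_tsv()] to
#' keep them.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path; UTF-8, LF newlines.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(gs) {
    paste(c(gs$set_id, gs$description, gs$members), collapse = "\t")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0L) {
    writeLines(unname(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read gene sets from a long-form TSV
#'
#' One row per (set, gene) membership with an optional per-gene association
#' score — the carrier for scored sets, which GMT cannot represent.
#'
#' @param path TSV with header columns `set_id`, `gene_id`, optional `score`.
#' @inheritParams collection_from_table
#' @return A [gene_set_collection()].
#' @export
read_geneset_tsv <- function(path, metadata = NULL,
                             species = "unknown", tier = "V") {
  df <- read_tsv_checked(path, c("set_id", "gene_id"))
  collection_from_table(df, metadata = metadata, species = species, tier = tier)
}

#' Write a collection as long-form TSV
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geneset_tsv <- function(collection, path) {
  readr::write_tsv(as_tibble(collection), path)
  invisible(path)
}

#' Read a homology cluster table
#'
#' Expects a header with `cluster_id`, `species`, `gene_id`; builds the
#' [cluster_index()] mapping each (species, gene) to its homology cluster.
#' A gene assigned to several clusters keeps its first occurrence and the
#' conflict is reported as a warning, so parsing is order-stable and
#' idempotent.
#'
#' @param path Path to a TSV file.
#' @return A [cluster_index()].
#' @export
read_homology_tsv <- function(path) {
  df <- read_tsv_checked(path, c("cluster_id", "species", "gene_id"))
  cluster_index(df)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    stop_data(sprintf("file not found: %s", path), class = "setweaver_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_data(sprintf("%s: missing required column(s): %s",
                      path, paste(missing, collapse = ", ")),
              class = "setweaver_schema_error")
  }
  for (col in intersect(names(df), c("set_id", "gene_id", "cluster_id",
                                     "species", "pub_id", "term"))) {
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' Convert a result graph to an igraph object
#'
#' @param x A `hisim_dag` or `gene_set_graph`.
#' @param ... Unused.
#' @return A directed (DAG) or undirected (bipartite) igraph with node
#'   attributes `level`/`degree`, `label`, `emphasis` and `type`.
#' @export
as_igraph <- function(x, ...) UseMethod("as_igraph")

#' @rdname as_igraph
#' @export
as_igraph.hisim_dag <- function(x, ...) {
  nodes <- data.frame(
    name = x$nodes$node_id,
    level = x$nodes$level,
    label = x$nodes$label,
    genes = vapply(x$nodes$shared_genes, paste, character(1L), collapse = ","),
    emphasis = vapply(x$nodes$emphasis, paste, character(1L), collapse = ","),
    # numeric flag: the DOT writer has no boolean attribute type
    is_leaf = as.integer(x$nodes$is_leaf),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(as.data.frame(x$edges), directed = TRUE,
                                vertices = nodes)
}

#' @rdname as_igraph
#' @export
as_igraph.gene_set_graph <- function(x, ...) {
  nodes <- data.frame(
    name = c(x$set_nodes, x$gene_nodes$gene_id),
    type = c(rep("set", length(x$set_nodes)),
             rep("gene", nrow(x$gene_nodes))),
    degree = c(rep(NA_real_, length(x$set_nodes)),
               as.numeric(x$gene_nodes$degree)),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(as.data.frame(x$edges), directed = FALSE,
                                vertices = nodes)
}

#' Export a result graph to GraphML, DOT or JSON
#'
#' Serializes a [build_hisim_dag()] result or a [threshold_subgraph()] with
#' node attributes (level or degree, labels, emphasis flags) in a
#' deterministic node order, so exporting the same graph twice yields
#' identical bytes. GraphML and DOT are written through igraph; JSON is a
#' `{"nodes": [...], "edges": [...]}` document.
#'
#' @param graph A `hisim_dag` or `gene_set_graph`.
#' @param path Output file path.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot", "json")) {
  if (length(format) != 1L || !format %in% c("graphml", "dot", "json")) {
    stop_usage("format must be one of graphml, dot, json")
  }
  if (format == "json") {
    doc <- if (inherits(graph, "hisim_dag")) {
      list(
        nodes = lapply(seq_len(nrow(graph$nodes)), function(i) {
          list(
            node_id = graph$nodes$node_id[[i]],
            level = graph$nodes$level[[i]],
            label = graph$nodes$label[[i]],
            set_ids = graph$nodes$set_ids[[i]],
            shared_genes = graph$nodes$shared_genes[[i]],
            emphasis = graph$nodes$emphasis[[i]],
            is_leaf = graph$nodes$is_leaf[[i]]
          )
        }),
        edges = lapply(seq_len(nrow(graph$edges)), function(i) {
          list(from = graph$edges$from[[i]], to = graph$edges$to[[i]])
        })
      )
    } else if (inherits(graph, "gene_set_graph")) {
      list(
        threshold = graph$threshold,
        nodes = c(
          lapply(graph$set_nodes, function(s) list(id = s, kind = "set")),
          lapply(seq_len(nrow(graph$gene_nodes)), function(i) {
            list(id = graph$gene_nodes$gene_id[[i]], kind = "gene",
                 degree = graph$gene_nodes$degree[[i]])
          })
        ),
        edges = lapply(seq_len(nrow(graph$edges)), function(i) {
          list(from = graph$edges$set_id[[i]], to = graph$edges$gene_id[[i]])
        })
      )
    } else {
      stop_data("unsupported graph object")
    }
    json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }
  g <- as_igraph(graph)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
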
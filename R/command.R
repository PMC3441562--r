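# The controller: parse a DAS request URL into a command, dispatch it to
# the right source and capability, apply filters, and assemble a typed
# document. URL scheme: /das/sources and /das/{source_id}/{command} with
# query parameters segment, type, category, feature_id, rows (separators
# ';' or '&').

DAS_COMMANDS <- c("sources", "entry_points", "sequence", "types",
                  "features", "stylesheet")

#' Construct a DAS command
#'
#' @param command One of `sources`, `entry_points`, `sequence`, `types`,
#'   `features`, `stylesheet`.
#' @param source_id Source id; `NULL` for the server-level `sources`
#'   command.
#' @param segments List of [segment_query()] in request order.
#' @param type_filters,category_filters Character vectors of type /
#'   category ids (empty = no filtering).
#' @param feature_ids Character vector of feature-id lookups.
#' @param rows Optional `c(first, last)` 1-based inclusive pagination
#'   window (entry_points only).
#' @export
das_command <- function(command, source_id = NULL, segments = list(),
                        type_filters = character(),
                        category_filters = character(),
                        feature_ids = character(), rows = NULL) {
  if (!(command %in% DAS_COMMANDS))
    das_error("BAD_COMMAND", paste0("unknown command '", command, "'"))
  if (!is.null(rows)) {
    rows <- as.integer(rows)
    if (length(rows) != 2L || anyNA(rows) || rows[1] < 1L ||
        rows[1] > rows[2])
      das_error("BAD_COMMAND_ARGS", "rows must be 'first-last' with 1 <= first <= last")
  }
  structure(list(command = command, source_id = source_id,
                 segments = segments, type_filters = type_filters,
                 category_filters = category_filters,
                 feature_ids = feature_ids, rows = rows),
            class = "das_command")
}

parse_segment_param <- function(value) {
  if (!grepl(":", value, fixed = TRUE)) {
    if (!nzchar(value))
      das_error("BAD_COMMAND_ARGS", "empty segment parameter")
    return(segment_query(value))
  }
  colon <- regexpr(":", value, fixed = TRUE)
  id <- substr(value, 1L, colon - 1L)
  range <- substr(value, colon + 1L, nchar(value))
  m <- regmatches(range, regexec("^([0-9]+),([0-9]+)$", range))[[1]]
  if (length(m) != 3L)
    das_error("BAD_COMMAND_ARGS",
              paste0("malformed segment range '", value,
                     "' (expected ID:START,STOP)"))
  start <- as.integer(m[2]); stop_ <- as.integer(m[3])
  if (is.na(start) || is.na(stop_) || start < 1L || start > stop_)
    das_error("BAD_COMMAND_ARGS",
              paste0("invalid segment range '", value,
                     "': need 1 <= start <= stop"))
  segment_query(id, start, stop_)
}

parse_query_string <- function(query) {
  out <- list()
  if (is.null(query) || !nzchar(query)) return(out)
  for (pair in strsplit(query, "[;&]")[[1]]) {
    if (!nzchar(pair)) next
    eq <- regexpr("=", pair, fixed = TRUE)
    if (eq < 0) { key <- pair; val <- "" }
    else {
      key <- substr(pair, 1L, eq - 1L)
      val <- utils::URLdecode(substr(pair, eq + 1L, nchar(pair)))
    }
    out[[length(out) + 1L]] <- c(key, val)
  }
  out
}

#' Parse a DAS request URL into a command
#'
#' Recognizes `/das/sources`, `/das/{source_id}` (single-source sources
#' document) and `/das/{source_id}/{command}`. Repeated `segment=`
#' parameters accumulate in order; `segment=ID:START,STOP` yields a
#' ranged query and `segment=ID` an unranged one. `type=`, `category=`,
#' `feature_id=` accumulate likewise; `rows=a-b` sets the pagination
#' window. The `maxbins` argument is accepted and ignored (the built-in
#' adapters do not bin).
#'
#' @param path URL path beginning at the DAS mount point (e.g.
#'   `/das/demo/features`).
#' @param query Raw query string (without the leading `?`), or `NULL`.
#' @return A [das_command()].
#' @export
parse_request <- function(path, query = NULL) {
  path <- sub("\\?.*$", "", path)
  parts <- strsplit(sub("/+$", "", path), "/")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) < 1L || parts[1] != "das")
    das_error("BAD_COMMAND", paste0("path '", path,
                                    "' is not under the /das mount point"))
  parts <- parts[-1]
  if (length(parts) == 1L && parts[1] == "sources") {
    source_id <- NULL; command <- "sources"
  } else if (length(parts) == 1L) {
    source_id <- parts[1]; command <- "sources"
  } else if (length(parts) == 2L) {
    source_id <- parts[1]; command <- parts[2]
    if (!(command %in% DAS_COMMANDS))
      das_error("BAD_COMMAND", paste0("unknown command '", command, "'"))
  } else {
    das_error("BAD_COMMAND", paste0("unrecognized path '", path, "'"))
  }
  segments <- list(); type_filters <- character()
  category_filters <- character(); feature_ids <- character(); rows <- NULL
  for (kv in parse_query_string(query)) {
    key <- kv[1]; val <- kv[2]
    if (key == "segment") {
      segments <- c(segments, list(parse_segment_param(val)))
    } else if (key == "type") {
      type_filters <- c(type_filters, val)
    } else if (key == "category") {
      category_filters <- c(category_filters, val)
    } else if (key == "feature_id") {
      feature_ids <- c(feature_ids, val)
    } else if (key == "rows") {
      m <- regmatches(val, regexec("^([0-9]+)-([0-9]+)$", val))[[1]]
      if (length(m) != 3L)
        das_error("BAD_COMMAND_ARGS",
                  paste0("malformed rows window '", val,
                         "' (expected first-last)"))
      rows <- c(as.integer(m[2]), as.integer(m[3]))
    } else if (key == "maxbins") {
      # accepted and ignored: the built-in adapters do not bin
    }
    # other unknown parameters are ignored for forward compatibility
  }
  das_command(command, source_id = source_id, segments = segments,
              type_filters = type_filters,
              category_filters = category_filters,
              feature_ids = feature_ids, rows = rows)
}

#' Render a command back to its canonical request URL
#'
#' Inverse of [parse_request()] up to parameter canonicalization
#' (parameters emitted in the order segment, type, category, feature_id,
#' rows, joined with `;`).
#'
#' @param cmd A [das_command()].
#' @return `list(path =, query =)`.
#' @export
canonical_request <- function(cmd) {
  path <- if (cmd$command == "sources" && is.null(cmd$source_id))
    "/das/sources"
  else paste0("/das/", cmd$source_id, "/", cmd$command)
  enc <- function(x) vapply(x, utils::URLencode, "", reserved = TRUE)
  params <- character()
  for (q in cmd$segments) {
    params <- c(params, paste0("segment=", q$id,
                               if (has_range(q))
                                 paste0(":", q$start, ",", q$stop)))
  }
  if (length(cmd$type_filters))
    params <- c(params, paste0("type=", enc(cmd$type_filters)))
  if (length(cmd$category_filters))
    params <- c(params, paste0("category=", enc(cmd$category_filters)))
  if (length(cmd$feature_ids))
    params <- c(params, paste0("feature_id=", enc(cmd$feature_ids)))
  if (!is.null(cmd$rows))
    params <- c(params, paste0("rows=", cmd$rows[1], "-", cmd$rows[2]))
  list(path = path,
       query = if (length(params)) paste(params, collapse = ";") else NULL)
}

# ---- typed documents -------------------------------------------------------

features_document <- function(blocks, href) {
  structure(list(blocks = blocks, href = href), class = "features_document")
}

sequence_document <- function(records) {
  structure(list(records = records), class = "sequence_document")
}

types_document <- function(blocks, href) {
  structure(list(blocks = blocks, href = href), class = "types_document")
}

entry_points_document <- function(href, total, first, last, entry_points) {
  structure(list(href = href, total = as.integer(total),
                 first = as.integer(first), last = as.integer(last),
                 entry_points = entry_points),
            class = "entry_points_document")
}

sources_document <- function(sources) {
  structure(list(sources = sources), class = "sources_document")
}

stylesheet_document <- function(stylesheet) {
  structure(list(stylesheet = stylesheet), class = "stylesheet_document")
}

source_capability_uris <- function(cfg, src) {
  caps <- union("sources", src$capabilities)
  caps <- c_sort(caps)
  uris <- vapply(caps, function(cap) {
    cmd <- if (cap == "sources") "" else paste0("/", cap)
    paste0(cfg$base_url, "/", src$source_id, cmd)
  }, "")
  names(uris) <- caps
  uris
}

source_metadata <- function(cfg, src) {
  list(source_id = src$source_id, title = src$title,
       description = src$description,
       maintainer_email = src$maintainer_email,
       version = src$version,
       coordinate_authority = src$coordinate_authority,
       coordinate_source_type = src$coordinate_source_type,
       organism_taxid = src$organism_taxid,
       capabilities = source_capability_uris(cfg, src),
       properties = src$properties)
}

# ---- executors -------------------------------------------------------------

apply_feature_filters <- function(features, type_filters, category_filters) {
  Filter(function(f) {
    (length(type_filters) == 0L || f$type$id %in% type_filters) &&
      (length(category_filters) == 0L ||
         (!is.null(f$type$category) && f$type$category %in% category_filters))
  }, features)
}

#' Execute a features command against an adapter
#'
#' One block per requested segment query, in request order; an unknown
#' segment becomes an in-document unknown-segment marker, not an error.
#' Feature-id lookups are wrapped in their own segment blocks after the
#' segment blocks (unknown feature ids contribute nothing). Filters:
#' a feature is kept iff its type id is in `type_filters` (or none are
#' given) AND its category is in `category_filters` (or none are given).
#'
#' @param handle Adapter handle.
#' @param queries List of [segment_query()].
#' @param type_filters,category_filters Character filter vectors.
#' @param feature_ids Character vector of feature-id lookups.
#' @param href Source base href recorded in the document.
#' @return A `features_document`.
#' @export
execute_features <- function(handle, queries,
                             type_filters = character(),
                             category_filters = character(),
                             feature_ids = character(),
                             href = "") {
  if (length(queries) == 0L && length(feature_ids) == 0L)
    das_error("BAD_COMMAND_ARGS",
              "features command needs at least one segment or feature_id")
  blocks <- lapply(queries, function(q) {
    res <- handle$get_features_by_segment(q)
    if (is_unknown_segment(res))
      return(list(segment = unknown_segment(q$id), features = list()))
    list(segment = res$segment,
         features = apply_feature_filters(res$features, type_filters,
                                          category_filters))
  })
  for (fid in feature_ids) {
    for (blk in handle$get_features_by_id(fid)) {
      blk$features <- apply_feature_filters(blk$features, type_filters,
                                            category_filters)
      blocks <- c(blocks, list(blk))
    }
  }
  features_document(blocks, href)
}

#' Execute a sequence command against a reference adapter
#'
#' @param handle Adapter handle with a `get_sequence` operation.
#' @param queries List of [segment_query()].
#' @return A `sequence_document` with one [sequence_record()] per query.
#'   Unknown segments and out-of-range windows raise
#'   `BAD_REFERENCE_OBJECT`.
#' @export
execute_sequence <- function(handle, queries) {
  if (is.null(handle$get_sequence))
    das_error("BAD_COMMAND", "source does not serve sequences")
  if (length(queries) == 0L)
    das_error("BAD_COMMAND_ARGS", "sequence command needs at least one segment")
  records <- lapply(queries, function(q) {
    rec <- handle$get_sequence(q)
    if (is_unknown_segment(rec))
      das_error("BAD_REFERENCE_OBJECT",
                paste0("unknown reference object '", q$id, "'"))
    rec
  })
  sequence_document(records)
}

#' Execute a types command
#'
#' Without segment queries: one block of source-wide type counts. With
#' queries: one block per segment, counting only features on that
#' segment (window); an unknown segment becomes an unknown-segment
#' marker block.
#'
#' @param handle Adapter handle.
#' @param queries List of [segment_query()] (may be empty).
#' @param href Source base href.
#' @return A `types_document`.
#' @export
execute_types <- function(handle, queries = list(), href = "") {
  if (length(queries) == 0L) {
    blocks <- list(list(segment = NULL, types = handle$get_types()))
  } else {
    blocks <- lapply(queries, function(q) {
      res <- handle$get_types_for_segment(q)
      if (is_unknown_segment(res))
        return(list(segment = unknown_segment(q$id), types = list()))
      seg <- if (has_range(q)) das_segment(q$id, q$start, q$stop)
             else handle$get_segment(q$id)
      list(segment = seg, types = res)
    })
  }
  types_document(blocks, href)
}

#' Execute an entry_points command
#'
#' The requested window is clipped to `[1, total]`; a window starting
#' past the end yields an empty list, not an error. Ordering is
#' deterministic (lexicographic id, fixed by the adapter).
#'
#' @param handle Adapter handle.
#' @param rows Optional `c(first, last)` window.
#' @param page_size_default Page size when `rows` is absent.
#' @param href Source base href.
#' @return An `entry_points_document` carrying the stable total and the
#'   effective window.
#' @export
execute_entry_points <- function(handle, rows = NULL,
                                 page_size_default = 1000L, href = "") {
  total <- handle$get_entry_points(1L, 0L)$total
  if (is.null(rows)) {
    first <- 1L
    last <- min(total, page_size_default)
  } else {
    first <- rows[1]
    last <- min(rows[2], total)
  }
  if (first > total || total == 0L) {
    eps <- list()
    last <- min(last, total)
  } else {
    eps <- handle$get_entry_points(first, last - first + 1L)$entry_points
  }
  entry_points_document(href, total, first, last, eps)
}

#' Execute a stylesheet command
#'
#' The adapter's stylesheet wins; otherwise the server default; if
#' neither exists the command raises `BAD_STYLESHEET`.
#'
#' @param handle Adapter handle.
#' @param server_default Optional [das_stylesheet()] fallback.
#' @return A `stylesheet_document`.
#' @export
execute_stylesheet <- function(handle, server_default = NULL) {
  sty <- handle$get_stylesheet()
  if (is.null(sty)) sty <- server_default
  if (is.null(sty))
    das_error("BAD_STYLESHEET", "no stylesheet available for this source")
  stylesheet_document(sty)
}

load_default_stylesheet <- function(cfg) {
  path <- cfg$stylesheet_default_path
  if (is.null(path) || !file.exists(path)) return(NULL)
  parse_stylesheet(readChar(path, file.size(path)))$stylesheet
}

#' Execute a parsed DAS command
#'
#' Dispatches to the per-capability executor. `sources` with a source id
#' returns the single-source document. A command on a source that does
#' not declare the capability raises `BAD_COMMAND`; an unknown source id
#' raises `BAD_DATA_SOURCE`.
#'
#' @param cmd A [das_command()].
#' @param cfg A [server_config()].
#' @param adapters Named list source id -> adapter handle (see
#'   [load_config_adapters()]).
#' @return A typed document.
#' @export
execute <- function(cmd, cfg, adapters) {
  if (cmd$command == "sources") {
    if (is.null(cmd$source_id))
      return(sources_document(lapply(cfg$sources,
                                     function(s) source_metadata(cfg, s))))
    src <- config_source(cfg, cmd$source_id)
    if (is.null(src))
      das_error("BAD_DATA_SOURCE",
                paste0("unknown data source '", cmd$source_id, "'"))
    return(sources_document(list(source_metadata(cfg, src))))
  }
  src <- config_source(cfg, cmd$source_id)
  if (is.null(src))
    das_error("BAD_DATA_SOURCE",
              paste0("unknown data source '", cmd$source_id, "'"))
  if (!(cmd$command %in% src$capabilities))
    das_error("BAD_COMMAND",
              paste0("source '", src$source_id,
                     "' does not implement the ", cmd$command, " command"))
  handle <- adapters[[cmd$source_id]]
  if (is.null(handle))
    das_error("SERVER_ERROR",
              paste0("no adapter loaded for source '", cmd$source_id, "'"))
  href <- paste0(cfg$base_url, "/", src$source_id, "/", cmd$command)
  switch(cmd$command,
    features = execute_features(handle, cmd$segments, cmd$type_filters,
                                cmd$category_filters, cmd$feature_ids,
                                href = href),
    sequence = execute_sequence(handle, cmd$segments),
    types = execute_types(handle, cmd$segments, href = href),
    entry_points = execute_entry_points(
      handle, cmd$rows, cfg$entry_points_page_size, href = href),
    stylesheet = execute_stylesheet(handle, load_default_stylesheet(cfg)))
}
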
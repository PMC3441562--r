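# Data-source adapter contract and registry.
#
# An adapter handle is a list of closures over the loaded backing data:
#   capabilities                      character vector
#   get_entry_points(offset, limit)   list(total=, entry_points=)
#   get_segment(id)                   das_segment | unknown_segment
#   get_features_by_segment(q)        list(segment=, features=) | unknown_segment
#   get_features_by_id(feature_id)    list of list(segment=, features=)
#   get_types()                       list of type_count
#   get_types_for_segment(q)          list of type_count | unknown_segment
#   get_stylesheet()                  das_stylesheet | NULL
# and, for reference sources only:
#   get_sequence(q)                   sequence_record | unknown_segment
#                                     (out-of-range -> BAD_REFERENCE_OBJECT)
# Adapters are looked up by registered name; the configuration file binds
# a source to an adapter by that name.

.adapter_registry <- new.env(parent = emptyenv())

#' Register a data-source adapter
#'
#' @param name Adapter identifier used in configuration files.
#' @param constructor Function `(properties)` returning an adapter handle;
#'   `properties` is the named character vector from the source
#'   configuration.
#' @param capabilities Character vector of capabilities the adapter can
#'   serve.
#' @export
register_adapter <- function(name, constructor, capabilities) {
  assign(name, list(constructor = constructor,
                    capabilities = capabilities),
         envir = .adapter_registry)
  invisible(name)
}

#' List registered adapters
#' @return Character vector of adapter names.
#' @export
adapter_registry <- function() c_sort(ls(.adapter_registry))

#' Capabilities of every registered adapter
#' @return Named list: adapter name -> capability character vector.
#' @export
adapter_capability_registry <- function() {
  out <- lapply(adapter_registry(),
                function(n) .adapter_registry[[n]]$capabilities)
  names(out) <- adapter_registry()
  out
}

#' Instantiate an adapter by registered name
#'
#' @param name Registered adapter identifier.
#' @param properties Named character vector passed to the adapter's
#'   constructor (e.g. `c(file = "annotations.gff")` for the `gff`
#'   adapter).
#' @return An initialized adapter handle.
#' @export
load_adapter <- function(name, properties = character()) {
  entry <- .adapter_registry[[name]]
  if (is.null(entry))
    stop("unknown adapter '", name, "' (registered: ",
         paste(adapter_registry(), collapse = ", "), ")", call. = FALSE)
  handle <- entry$constructor(properties)
  handle$capabilities <- entry$capabilities
  handle$adapter_name <- name
  handle
}

property_get <- function(properties, key) {
  if (key %in% names(properties)) properties[[key]] else NULL
}

require_property <- function(properties, key, adapter) {
  val <- property_get(properties, key)
  if (is.null(val) || !nzchar(val))
    stop("adapter '", adapter, "': missing required property '", key, "'",
         call. = FALSE)
  val
}

# shared entry-point pagination: offset is the 1-based index of the first
# entry to return
paginate_entry_points <- function(eps, offset, limit) {
  total <- length(eps)
  if (limit < 1L || offset > total)
    return(list(total = total, entry_points = list()))
  last <- min(total, offset + limit - 1L)
  list(total = total, entry_points = eps[seq(offset, last)])
}

# ---- GFF-backed annotation adapter ----------------------------------------

#' Create an annotation adapter over a parsed GFF store
#'
#' Entry points are synthesized from the observed segment ids; a
#' segment's extent is `[1, max(##sequence-region bound, max feature
#' stop)]`. Entry points list in lexicographic id order.
#'
#' @param store A `gff_store` from [parse_gff()].
#' @param stylesheet Optional [das_stylesheet()] served for the source.
#' @return An adapter handle satisfying the annotation contract.
#' @export
gff_adapter <- function(store, stylesheet = NULL) {
  sids <- c_sort(names(store$segments))
  eps <- lapply(sids, function(sid)
    entry_point(sid, 1L, store$segments[[sid]]$bound))
  get_segment <- function(id) {
    seg <- store$segments[[id]]
    if (is.null(seg)) return(unknown_segment(id))
    das_segment(id, 1L, seg$bound)
  }
  list(
    get_entry_points = function(offset = 1L, limit = length(eps))
      paginate_entry_points(eps, offset, limit),
    get_segment = get_segment,
    get_features_by_segment = function(q) {
      feats <- query_interval_index(store, q)
      if (is_unknown_segment(feats)) return(feats)
      seg <- if (has_range(q))
        das_segment(q$id, q$start, q$stop)
      else get_segment(q$id)
      list(segment = seg, features = feats)
    },
    get_features_by_id = function(feature_id) {
      f <- store$feature_index[[feature_id]]
      if (is.null(f)) return(list())
      sid <- store$feature_segment[[feature_id]]
      list(list(segment = get_segment(sid), features = list(f)))
    },
    get_types = function() store_type_counts(store),
    get_types_for_segment = function(q) {
      feats <- query_interval_index(store, q)
      if (is_unknown_segment(feats)) return(feats)
      store_type_counts(store, features = feats)
    },
    get_stylesheet = function() stylesheet)
}

gff_adapter_from_properties <- function(properties) {
  path <- require_property(properties, "file", "gff")
  if (!file.exists(path))
    stop("adapter 'gff': property 'file' points to a missing file: ", path,
         call. = FALSE)
  sty <- NULL
  sty_path <- property_get(properties, "stylesheet")
  if (!is.null(sty_path))
    sty <- parse_stylesheet(readChar(sty_path, file.size(sty_path)))$stylesheet
  gff_adapter(parse_gff(file = path), stylesheet = sty)
}

# ---- in-memory reference adapter ------------------------------------------

#' Slice an in-memory reference store
#'
#' @param store Named list: segment id -> `list(residues =, version =)`.
#' @param q A [segment_query()]. Unranged: full residues with
#'   `start = 1, stop = length`. Ranged: residue positions
#'   `q$start..q$stop` (1-based inclusive); a range extending beyond the
#'   segment raises `BAD_REFERENCE_OBJECT` rather than truncating.
#' @return A [sequence_record()] or the [unknown_segment()] signal.
#' @export
get_sequence_builtin <- function(store, q) {
  entry <- store[[q$id]]
  if (is.null(entry)) return(unknown_segment(q$id))
  len <- nchar(entry$residues)
  if (!has_range(q))
    return(sequence_record(q$id, 1L, len, entry$version, entry$residues))
  if (q$stop > len)
    das_error("BAD_REFERENCE_OBJECT",
              paste0("range [", q$start, ",", q$stop, "] exceeds segment '",
                     q$id, "' length ", len))
  sequence_record(q$id, q$start, q$stop, entry$version,
                  substr(entry$residues, q$start, q$stop))
}

#' Create a reference adapter over in-memory sequences
#'
#' Serves sequences (with version metadata) plus empty feature/type
#' payloads for its segments, so it satisfies the full reference
#' contract.
#'
#' @param sequences Named character vector or named list of residue
#'   strings, one per segment id.
#' @param versions Optional named character vector of per-segment version
#'   strings (default `"1.0"`).
#' @return An adapter handle satisfying the reference contract.
#' @export
reference_adapter <- function(sequences, versions = NULL) {
  sids <- c_sort(names(sequences))
  store <- lapply(sids, function(sid) list(
    residues = as.character(sequences[[sid]]),
    version = if (!is.null(versions) && !is.null(versions[[sid]]))
      versions[[sid]] else "1.0"))
  names(store) <- sids
  eps <- lapply(sids, function(sid)
    entry_point(sid, 1L, nchar(store[[sid]]$residues)))
  get_segment <- function(id) {
    if (is.null(store[[id]])) return(unknown_segment(id))
    das_segment(id, 1L, nchar(store[[id]]$residues),
                version = store[[id]]$version)
  }
  list(
    get_entry_points = function(offset = 1L, limit = length(eps))
      paginate_entry_points(eps, offset, limit),
    get_segment = get_segment,
    get_features_by_segment = function(q) {
      if (is.null(store[[q$id]])) return(unknown_segment(q$id))
      seg <- if (has_range(q)) das_segment(q$id, q$start, q$stop)
             else get_segment(q$id)
      list(segment = seg, features = list())
    },
    get_features_by_id = function(feature_id) list(),
    get_types = function() list(),
    get_types_for_segment = function(q) {
      if (is.null(store[[q$id]])) return(unknown_segment(q$id))
      list()
    },
    get_stylesheet = function() NULL,
    get_sequence = function(q) get_sequence_builtin(store, q))
}

reference_adapter_from_properties <- function(properties) {
  path <- require_property(properties, "file", "reference")
  if (!file.exists(path))
    stop("adapter 'reference': property 'file' points to a missing file: ",
         path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("adapter 'reference': line ", bad[1],
         ": expected 'id<TAB>version<TAB>residues'", call. = FALSE)
  sequences <- lapply(parts, `[[`, 3L)
  names(sequences) <- vapply(parts, `[[`, "", 1L)
  versions <- vapply(parts, `[[`, "", 2L)
  names(versions) <- names(sequences)
  reference_adapter(sequences, versions)
}

GFF_ADAPTER_CAPABILITIES <- c("entry_points", "types", "features",
                              "stylesheet")
REFERENCE_ADAPTER_CAPABILITIES <- c("entry_points", "sequence", "types",
                                    "features", "stylesheet")

register_builtin_adapters <- function() {
  register_adapter("gff", gff_adapter_from_properties,
                   GFF_ADAPTER_CAPABILITIES)
  register_adapter("reference", reference_adapter_from_properties,
                   REFERENCE_ADAPTER_CAPABILITIES)
}

#' Load the adapters a configuration declares
#'
#' Fails fast: any adapter that cannot initialize stops with an error
#' naming the source.
#'
#' @param cfg A [server_config()].
#' @return Named list: source id -> adapter handle.
#' @export
load_config_adapters <- function(cfg) {
  out <- list()
  for (s in cfg$sources) {
    out[[s$source_id]] <- tryCatch(
      load_adapter(s$adapter_name, s$properties),
      error = function(e) stop("source '", s$source_id, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}
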
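# Server configuration: a YAML document with a `server` block for general
# options and a `sources` list binding per-source metadata to a registered
# adapter. Schema reference: inst/wire-format.md.

CONFIG_DEFAULTS <- list(
  base_url = "http://localhost:8080/das",
  gzip_enabled = FALSE,
  xslt_enabled = FALSE,
  stylesheet_default_path = NULL,
  entry_points_page_size = 1000L
)

REQUIRED_SOURCE_FIELDS <- c("id", "title", "adapter")
SOURCE_ID_RE <- "^[A-Za-z0-9._-]+$"
DAS_CAPABILITIES <- c("sources", "entry_points", "sequence", "types",
                      "features", "stylesheet")

#' Construct a data-source configuration
#'
#' @param source_id URL-path-safe token (`[A-Za-z0-9._-]+`).
#' @param title Display name.
#' @param adapter_name Registered adapter identifier (see
#'   [adapter_registry()]).
#' @param description,maintainer_email,version Free-text metadata.
#' @param coordinate_authority,coordinate_source_type Coordinate-system
#'   declaration (authority e.g. a genome assembly or sequence database
#'   name; source type e.g. "Chromosome" or "Protein Sequence").
#' @param organism_taxid Optional NCBI taxonomy id (integer).
#' @param capabilities Character subset of
#'   `sources, entry_points, sequence, types, features, stylesheet`.
#' @param properties Named character vector passed verbatim to the adapter.
#' @export
data_source_config <- function(source_id, title, adapter_name,
                               description = "", maintainer_email = "",
                               version = "1.0",
                               coordinate_authority = "",
                               coordinate_source_type = "",
                               organism_taxid = NULL,
                               capabilities = c("features", "types",
                                                "entry_points"),
                               properties = character()) {
  if (!grepl(SOURCE_ID_RE, source_id))
    stop("data_source_config: source_id '", source_id,
         "' must match [A-Za-z0-9._-]+")
  bad <- setdiff(capabilities, DAS_CAPABILITIES)
  if (length(bad))
    stop("data_source_config: unknown capabilities: ",
         paste(bad, collapse = ", "))
  properties <- if (length(properties)) {
    stopifnot(!is.null(names(properties)))
    vapply(properties, as.character, "")
  } else {
    stats::setNames(character(), character())
  }
  structure(list(
    source_id = source_id, title = title,
    description = as.character(description),
    maintainer_email = as.character(maintainer_email),
    version = as.character(version),
    coordinate_authority = as.character(coordinate_authority),
    coordinate_source_type = as.character(coordinate_source_type),
    organism_taxid = if (is.null(organism_taxid)) NULL
                     else as.integer(organism_taxid),
    capabilities = c_sort(unique(as.character(capabilities))),
    adapter_name = adapter_name,
    properties = properties),
    class = "data_source_config")
}

#' Construct a server configuration
#'
#' @param sources List of [data_source_config()] objects with pairwise
#'   distinct ids.
#' @param base_url Absolute URL under which the DAS tree is mounted.
#' @param gzip_enabled Compress responses for clients that accept gzip.
#' @param xslt_enabled Prepend an xml-stylesheet processing instruction to
#'   payloads so browsers can render them.
#' @param stylesheet_default_path Optional path to a DASSTYLE XML file
#'   used when an adapter provides no stylesheet.
#' @param entry_points_page_size Default entry-points page size (>= 1).
#' @export
server_config <- function(sources = list(),
                          base_url = CONFIG_DEFAULTS$base_url,
                          gzip_enabled = CONFIG_DEFAULTS$gzip_enabled,
                          xslt_enabled = CONFIG_DEFAULTS$xslt_enabled,
                          stylesheet_default_path = NULL,
                          entry_points_page_size =
                            CONFIG_DEFAULTS$entry_points_page_size) {
  entry_points_page_size <- as.integer(entry_points_page_size)
  if (is.na(entry_points_page_size) || entry_points_page_size < 1L)
    stop("server_config: entry_points_page_size must be >= 1")
  ids <- vapply(sources, function(s) s$source_id, "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("server_config: duplicate source id(s): ", paste(dup, collapse = ", "))
  structure(list(
    base_url = base_url,
    gzip_enabled = isTRUE(gzip_enabled),
    xslt_enabled = isTRUE(xslt_enabled),
    stylesheet_default_path = stylesheet_default_path,
    entry_points_page_size = entry_points_page_size,
    sources = sources),
    class = "server_config")
}

#' Parse a server configuration document
#'
#' Reads the YAML configuration dialect described in
#' `inst/wire-format.md`: a `server` mapping (all keys optional, with
#' documented defaults: gzip off, page size 1000, no default stylesheet)
#' and a `sources` sequence; each source requires `id`, `title` and
#' `adapter`. Unknown keys produce a warning, not an error.
#'
#' @param text Configuration document as a single string, or a file path
#'   via `file =`.
#' @param file Path to a configuration file (alternative to `text`).
#' @return A [server_config()] object.
#' @export
parse_server_config <- function(text = NULL, file = NULL) {
  stopifnot(xor(is.null(text), is.null(file)))
  raw <- tryCatch(
    if (is.null(file)) yaml::yaml.load(text) else yaml::read_yaml(file),
    error = function(e) stop("configuration syntax error: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  known_top <- c("server", "sources")
  extra <- setdiff(names(raw), known_top)
  if (length(extra))
    warning("ignoring unknown top-level configuration key(s): ",
            paste(extra, collapse = ", "))
  srv <- if (is.null(raw$server)) list() else raw$server
  known_srv <- c("base_url", "gzip", "xslt", "stylesheet_default",
                 "entry_points_page_size")
  extra <- setdiff(names(srv), known_srv)
  if (length(extra))
    warning("ignoring unknown server configuration key(s): ",
            paste(extra, collapse = ", "))
  sources <- lapply(seq_along(raw$sources), function(i) {
    s <- raw$sources[[i]]
    miss <- setdiff(REQUIRED_SOURCE_FIELDS, names(s))
    if (length(miss))
      stop("configuration source #", i, " ('",
           if (is.null(s$id)) "?" else s$id,
           "'): missing required field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    known_src <- c("id", "title", "description", "maintainer", "version",
                   "coordinates", "capabilities", "adapter", "properties")
    extra <- setdiff(names(s), known_src)
    if (length(extra))
      warning("source '", s$id, "': ignoring unknown key(s): ",
              paste(extra, collapse = ", "))
    coords <- if (is.null(s$coordinates)) list() else s$coordinates
    props <- if (is.null(s$properties)) character()
             else unlist(lapply(s$properties, as.character))
    data_source_config(
      source_id = as.character(s$id),
      title = as.character(s$title),
      adapter_name = as.character(s$adapter),
      description = if (is.null(s$description)) "" else s$description,
      maintainer_email = if (is.null(s$maintainer)) "" else s$maintainer,
      version = if (is.null(s$version)) "1.0" else as.character(s$version),
      coordinate_authority =
        if (is.null(coords$authority)) "" else coords$authority,
      coordinate_source_type =
        if (is.null(coords$source_type)) "" else coords$source_type,
      organism_taxid = coords$taxid,
      capabilities = if (is.null(s$capabilities))
        c("features", "types", "entry_points")
      else as.character(s$capabilities),
      properties = props)
  })
  ids <- vapply(sources, function(s) s$source_id, "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("configuration: duplicate source id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  server_config(
    sources = sources,
    base_url = if (is.null(srv$base_url)) CONFIG_DEFAULTS$base_url
               else srv$base_url,
    gzip_enabled = if (is.null(srv$gzip)) CONFIG_DEFAULTS$gzip_enabled
                   else isTRUE(srv$gzip),
    xslt_enabled = if (is.null(srv$xslt)) CONFIG_DEFAULTS$xslt_enabled
                   else isTRUE(srv$xslt),
    stylesheet_default_path = srv$stylesheet_default,
    entry_points_page_size =
      if (is.null(srv$entry_points_page_size))
        CONFIG_DEFAULTS$entry_points_page_size
      else srv$entry_points_page_size)
}

#' Serialize a server configuration back to its YAML document
#'
#' Inverse of [parse_server_config()] on the structural model:
#' `parse_server_config(serialize_config(cfg))` equals `cfg`.
#'
#' @param cfg A [server_config()] object.
#' @return The configuration document as a single string.
#' @export
serialize_config <- function(cfg) {
  stopifnot(inherits(cfg, "server_config"))
  srv <- list(base_url = cfg$base_url,
              gzip = cfg$gzip_enabled,
              xslt = cfg$xslt_enabled,
              entry_points_page_size = cfg$entry_points_page_size)
  if (!is.null(cfg$stylesheet_default_path))
    srv$stylesheet_default <- cfg$stylesheet_default_path
  sources <- lapply(cfg$sources, function(s) {
    out <- list(id = s$source_id, title = s$title,
                description = s$description,
                maintainer = s$maintainer_email,
                version = s$version,
                coordinates = c(
                  list(authority = s$coordinate_authority,
                       source_type = s$coordinate_source_type),
                  if (!is.null(s$organism_taxid))
                    list(taxid = s$organism_taxid)),
                capabilities = as.list(s$capabilities),
                adapter = s$adapter_name)
    if (length(s$properties)) out$properties <- as.list(s$properties)
    out
  })
  yaml::as.yaml(list(server = srv, sources = sources))
}

#' Validate a configuration against an adapter registry
#'
#' @param cfg A [server_config()].
#' @param registry Named list: adapter name -> character vector of
#'   capabilities it can serve. Defaults to the built-in registry.
#' @return Character vector of violations (empty when valid). Violations
#'   are returned, never thrown.
#' @export
validate_config <- function(cfg, registry = adapter_capability_registry()) {
  v <- character()
  for (s in cfg$sources) {
    if (!grepl(SOURCE_ID_RE, s$source_id))
      v <- c(v, paste0("source '", s$source_id,
                       "': id must match [A-Za-z0-9._-]+"))
    if (!(s$adapter_name %in% names(registry))) {
      v <- c(v, paste0("source '", s$source_id, "': unknown adapter '",
                       s$adapter_name, "'"))
      next
    }
    can <- registry[[s$adapter_name]]
    unsupported <- setdiff(setdiff(s$capabilities, "sources"), can)
    if (length(unsupported))
      v <- c(v, paste0("source '", s$source_id, "': adapter '",
                       s$adapter_name, "' does not support capability ",
                       paste(unsupported, collapse = ", ")))
    # a source that cannot serve sequences is an annotation source and
    # must expose features
    if (!("sequence" %in% s$capabilities) &&
        !("features" %in% s$capabilities))
      v <- c(v, paste0("source '", s$source_id,
                       "': annotation sources must declare the features ",
                       "capability"))
  }
  if (cfg$entry_points_page_size < 1L)
    v <- c(v, "entry_points_page_size: must be >= 1")
  v
}

#' Look up one source's configuration by id
#' @param cfg A [server_config()].
#' @param source_id Source id to find.
#' @return The [data_source_config()] or `NULL`.
#' @export
config_source <- function(cfg, source_id) {
  for (s in cfg$sources) if (s$source_id == source_id) return(s)
  NULL
}
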
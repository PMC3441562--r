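# DAS XML wire documents: serializers and parsers for the six document
# kinds (DASGFF, DASSEQUENCE, DASTYPES, DASEP, SOURCES, DASSTYLE).
# Serialization is a vectorized string writer (document sizes reach
# megabytes at benchmark scale, so per-node DOM construction is too
# slow); parsing uses xml2 and tolerates attribute reordering and
# insignificant whitespace. Element grammar: inst/wire-format.md. No
# DTD/doctype is emitted; validation is structural.

XML_DECLARATION <- "<?xml version=\"1.0\" encoding=\"UTF-8\"?>"

#' An XML payload
#' @param xml XML document as a single UTF-8 string.
#' @export
das_payload <- function(xml) {
  structure(list(bytes = xml, content_type = "text/xml"),
            class = "das_payload")
}

payload_raw <- function(payload) charToRaw(payload$bytes)

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# attribute values additionally escape quotes and the whitespace
# characters that attribute-value normalization would otherwise fold
xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x <- gsub("\t", "&#9;", x, fixed = TRUE)
  x <- gsub("\n", "&#10;", x, fixed = TRUE)
  gsub("\r", "&#13;", x, fixed = TRUE)
}

attr_string <- function(attrs) {
  attrs <- Filter(Negate(is.null), attrs)
  if (!length(attrs)) return("")
  paste(vapply(names(attrs), function(a)
    paste0(" ", a, "=\"", xml_escape_attr(as.character(attrs[[a]])), "\""),
    ""), collapse = "")
}

# a leaf element: self-closing without text, inline otherwise
leaf <- function(indent, name, attrs = list(), text = NULL) {
  if (is.null(text))
    paste0(indent, "<", name, attr_string(attrs), "/>")
  else
    paste0(indent, "<", name, attr_string(attrs), ">",
           xml_escape_text(as.character(text)), "</", name, ">")
}

open_tag <- function(indent, name, attrs = list()) {
  paste0(indent, "<", name, attr_string(attrs), ">")
}

close_tag <- function(indent, name) paste0(indent, "</", name, ">")

finish_payload <- function(lines) {
  das_payload(paste0(paste(c(XML_DECLARATION, unlist(lines)),
                           collapse = "\n"), "\n"))
}

read_das_xml <- function(xml, expected_root) {
  doc <- xml2::read_xml(xml)
  root <- xml2::xml_name(doc)
  if (root != expected_root)
    stop("wrong document kind: expected <", expected_root, ">, got <",
         root, ">", call. = FALSE)
  doc
}

req_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v))
    stop("missing required attribute '", name, "' on element <",
         xml2::xml_name(node), ">", call. = FALSE)
  v
}

opt_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

children_named <- function(node, name) {
  xml2::xml_find_all(node, paste0("./", name))
}

format_score <- function(score) {
  if (is.null(score)) "-" else as.character(score)
}

parse_score <- function(text) {
  if (text == "-") NULL else as.numeric(text)
}

# ---- DASGFF (features) -----------------------------------------------------

segment_attrs <- function(seg) {
  list(id = seg$id, start = seg$start, stop = seg$stop,
       version = seg$version, label = seg$label)
}

feature_lines <- function(f, ind) {
  viol <- validate_feature(f)
  if (length(viol))
    stop("refusing to serialize invalid feature '", f$feature_id, "': ",
         paste(viol, collapse = "; "), call. = FALSE)
  ind2 <- paste0(ind, "  ")
  list(
    open_tag(ind, "FEATURE", list(id = f$feature_id, label = f$label)),
    leaf(ind2, "TYPE", list(id = f$type$id, category = f$type$category,
                            cvId = f$type$cv_id), f$type$description),
    leaf(ind2, "METHOD", list(id = f$method$id, cvId = f$method$cv_id),
         f$method$label),
    leaf(ind2, "START", text = f$start),
    leaf(ind2, "END", text = f$stop),
    leaf(ind2, "SCORE", text = format_score(f$score)),
    leaf(ind2, "ORIENTATION", text = f$orientation),
    leaf(ind2, "PHASE", text = f$phase),
    lapply(f$notes, function(n) leaf(ind2, "NOTE", text = n)),
    lapply(f$links, function(l)
      leaf(ind2, "LINK", list(href = l$href), l$label)),
    lapply(f$targets, function(t)
      leaf(ind2, "TARGET", list(id = t$id, start = t$start,
                                stop = t$stop))),
    lapply(f$parents, function(p) leaf(ind2, "PARENT", list(id = p))),
    lapply(f$parts, function(p) leaf(ind2, "PART", list(id = p))),
    close_tag(ind, "FEATURE"))
}

#' Serialize a features document to DASGFF XML
#'
#' @param doc A `features_document` from [execute_features()].
#' @return A [das_payload()]. Serialization is refused (with the model
#'   violation) if any feature fails [validate_feature()].
#' @export
serialize_features <- function(doc) {
  body <- lapply(doc$blocks, function(blk) {
    if (is_unknown_segment(blk$segment))
      return(leaf("    ", "UNKNOWNSEGMENT", list(id = blk$segment$id)))
    if (length(blk$features) == 0L)
      return(leaf("    ", "SEGMENT", segment_attrs(blk$segment)))
    list(open_tag("    ", "SEGMENT", segment_attrs(blk$segment)),
         lapply(blk$features, feature_lines, ind = "      "),
         close_tag("    ", "SEGMENT"))
  })
  finish_payload(list(
    "<DASGFF>",
    open_tag("  ", "GFF", list(href = doc$href)),
    body,
    close_tag("  ", "GFF"),
    "</DASGFF>"))
}

parse_feature_node <- function(fe) {
  type_node <- xml2::xml_find_first(fe, "./TYPE")
  method_node <- xml2::xml_find_first(fe, "./METHOD")
  text_or_null <- function(node) {
    t <- xml2::xml_text(node)
    if (nzchar(t)) t else NULL
  }
  das_feature(
    feature_id = req_attr(fe, "id"),
    label = opt_attr(fe, "label"),
    type = das_type(req_attr(type_node, "id"),
                    category = opt_attr(type_node, "category"),
                    cv_id = opt_attr(type_node, "cvId"),
                    description = text_or_null(type_node)),
    method = das_method(req_attr(method_node, "id"),
                        cv_id = opt_attr(method_node, "cvId"),
                        label = text_or_null(method_node)),
    start = as.integer(xml2::xml_text(xml2::xml_find_first(fe, "./START"))),
    stop = as.integer(xml2::xml_text(xml2::xml_find_first(fe, "./END"))),
    score = parse_score(xml2::xml_text(xml2::xml_find_first(fe, "./SCORE"))),
    orientation = xml2::xml_text(xml2::xml_find_first(fe, "./ORIENTATION")),
    phase = xml2::xml_text(xml2::xml_find_first(fe, "./PHASE")),
    notes = vapply(children_named(fe, "NOTE"), xml2::xml_text, ""),
    links = lapply(children_named(fe, "LINK"), function(l)
      list(href = req_attr(l, "href"), label = xml2::xml_text(l))),
    targets = lapply(children_named(fe, "TARGET"), function(t)
      list(id = req_attr(t, "id"),
           start = as.integer(req_attr(t, "start")),
           stop = as.integer(req_attr(t, "stop")))),
    parents = vapply(children_named(fe, "PARENT"),
                     function(p) req_attr(p, "id"), ""),
    parts = vapply(children_named(fe, "PART"),
                   function(p) req_attr(p, "id"), ""))
}

parse_segment_node <- function(node) {
  das_segment(req_attr(node, "id"),
              as.integer(req_attr(node, "start")),
              as.integer(req_attr(node, "stop")),
              version = opt_attr(node, "version"),
              label = opt_attr(node, "label"))
}

#' Parse a DASGFF features document
#' @param xml DASGFF XML as a string.
#' @return A `features_document`.
#' @export
parse_features <- function(xml) {
  root <- read_das_xml(xml, "DASGFF")
  gff <- xml2::xml_find_first(root, "./GFF")
  blocks <- lapply(xml2::xml_find_all(gff, "./SEGMENT|./UNKNOWNSEGMENT"),
                   function(node) {
    if (xml2::xml_name(node) == "UNKNOWNSEGMENT")
      return(list(segment = unknown_segment(req_attr(node, "id")),
                  features = list()))
    list(segment = parse_segment_node(node),
         features = lapply(children_named(node, "FEATURE"),
                           parse_feature_node))
  })
  features_document(blocks, href = req_attr(gff, "href"))
}

# ---- DASSEQUENCE -----------------------------------------------------------

#' Serialize a sequence document to DASSEQUENCE XML
#' @param doc A `sequence_document` from [execute_sequence()].
#' @return A [das_payload()].
#' @export
serialize_sequence <- function(doc) {
  finish_payload(list(
    "<DASSEQUENCE>",
    lapply(doc$records, function(rec)
      leaf("  ", "SEQUENCE",
           list(id = rec$segment_id, start = rec$start, stop = rec$stop,
                version = rec$version),
           rec$residues)),
    "</DASSEQUENCE>"))
}

#' Parse a DASSEQUENCE document
#' @param xml DASSEQUENCE XML as a string.
#' @return A `sequence_document`.
#' @export
parse_sequence <- function(xml) {
  root <- read_das_xml(xml, "DASSEQUENCE")
  records <- lapply(children_named(root, "SEQUENCE"), function(node)
    sequence_record(req_attr(node, "id"),
                    as.integer(req_attr(node, "start")),
                    as.integer(req_attr(node, "stop")),
                    req_attr(node, "version"),
                    trimws(xml2::xml_text(node))))
  sequence_document(records)
}

# ---- DASTYPES --------------------------------------------------------------

type_count_line <- function(tc, ind) {
  leaf(ind, "TYPE",
       list(id = tc$type$id, category = tc$type$category,
            cvId = tc$type$cv_id, description = tc$type$description),
       text = tc$count)
}

#' Serialize a types document to DASTYPES XML
#'
#' A block with a `NULL` segment (source-wide counts) serializes as a
#' `SEGMENT` element without an `id` attribute.
#'
#' @param doc A `types_document` from [execute_types()].
#' @return A [das_payload()].
#' @export
serialize_types <- function(doc) {
  body <- lapply(doc$blocks, function(blk) {
    if (is_unknown_segment(blk$segment))
      return(leaf("    ", "UNKNOWNSEGMENT", list(id = blk$segment$id)))
    attrs <- if (is.null(blk$segment)) list()
             else segment_attrs(blk$segment)
    if (length(blk$types) == 0L)
      return(leaf("    ", "SEGMENT", attrs))
    list(open_tag("    ", "SEGMENT", attrs),
         lapply(blk$types, type_count_line, ind = "      "),
         close_tag("    ", "SEGMENT"))
  })
  finish_payload(list(
    "<DASTYPES>",
    open_tag("  ", "GFF", list(href = doc$href)),
    body,
    close_tag("  ", "GFF"),
    "</DASTYPES>"))
}

#' Parse a DASTYPES document
#' @param xml DASTYPES XML as a string.
#' @return A `types_document`.
#' @export
parse_types <- function(xml) {
  root <- read_das_xml(xml, "DASTYPES")
  gff <- xml2::xml_find_first(root, "./GFF")
  blocks <- lapply(xml2::xml_find_all(gff, "./SEGMENT|./UNKNOWNSEGMENT"),
                   function(node) {
    if (xml2::xml_name(node) == "UNKNOWNSEGMENT")
      return(list(segment = unknown_segment(req_attr(node, "id")),
                  types = list()))
    seg <- if (is.null(opt_attr(node, "id"))) NULL
           else parse_segment_node(node)
    types <- lapply(children_named(node, "TYPE"), function(t) {
      count <- trimws(xml2::xml_text(t))
      type_count(das_type(req_attr(t, "id"),
                          category = opt_attr(t, "category"),
                          cv_id = opt_attr(t, "cvId"),
                          description = opt_attr(t, "description")),
                 count = if (nzchar(count)) as.integer(count) else NULL)
    })
    list(segment = seg, types = types)
  })
  types_document(blocks, href = req_attr(gff, "href"))
}

# ---- DASEP (entry points) --------------------------------------------------

#' Serialize an entry-points document to DASEP XML
#' @param doc An `entry_points_document` from [execute_entry_points()].
#' @return A [das_payload()].
#' @export
serialize_entry_points <- function(doc) {
  finish_payload(list(
    "<DASEP>",
    open_tag("  ", "ENTRY_POINTS",
             list(href = doc$href, total = doc$total,
                  start = doc$first, end = doc$last)),
    lapply(doc$entry_points, function(ep)
      leaf("    ", "SEGMENT",
           list(id = ep$id, start = ep$start, stop = ep$stop,
                orientation = ep$orientation, type = ep$type_label,
                subparts = if (ep$has_subparts) "yes" else "no"),
           text = ep$description)),
    close_tag("  ", "ENTRY_POINTS"),
    "</DASEP>"))
}

#' Parse a DASEP document
#' @param xml DASEP XML as a string.
#' @return An `entry_points_document`.
#' @export
parse_entry_points <- function(xml) {
  root <- read_das_xml(xml, "DASEP")
  env <- xml2::xml_find_first(root, "./ENTRY_POINTS")
  eps <- lapply(children_named(env, "SEGMENT"), function(node) {
    desc <- xml2::xml_text(node)
    entry_point(req_attr(node, "id"),
                as.integer(req_attr(node, "start")),
                as.integer(req_attr(node, "stop")),
                orientation = req_attr(node, "orientation"),
                type_label = opt_attr(node, "type"),
                description = if (nzchar(desc)) desc else NULL,
                has_subparts = identical(opt_attr(node, "subparts"), "yes"))
  })
  entry_points_document(req_attr(env, "href"),
                        as.integer(req_attr(env, "total")),
                        as.integer(req_attr(env, "start")),
                        as.integer(req_attr(env, "end")),
                        eps)
}

# ---- SOURCES ---------------------------------------------------------------

#' Serialize a sources document to SOURCES XML
#' @param doc A `sources_document` from [execute()].
#' @return A [das_payload()].
#' @export
serialize_sources <- function(doc) {
  body <- lapply(doc$sources, function(s) {
    list(
      open_tag("  ", "SOURCE",
               list(uri = s$source_id, title = s$title,
                    description = s$description)),
      leaf("    ", "MAINTAINER", list(email = s$maintainer_email)),
      open_tag("    ", "VERSION", list(uri = s$version)),
      leaf("      ", "COORDINATES",
           list(authority = s$coordinate_authority,
                source = s$coordinate_source_type,
                taxid = s$organism_taxid)),
      lapply(names(s$capabilities), function(cap)
        leaf("      ", "CAPABILITY",
             list(type = paste0("das1:", cap),
                  query_uri = s$capabilities[[cap]]))),
      lapply(names(s$properties), function(p)
        leaf("      ", "PROP", list(name = p, value = s$properties[[p]]))),
      close_tag("    ", "VERSION"),
      close_tag("  ", "SOURCE"))
  })
  finish_payload(list("<SOURCES>", body, "</SOURCES>"))
}

#' Parse a SOURCES document
#' @param xml SOURCES XML as a string.
#' @return A `sources_document`.
#' @export
parse_sources <- function(xml) {
  root <- read_das_xml(xml, "SOURCES")
  sources <- lapply(children_named(root, "SOURCE"), function(se) {
    ve <- xml2::xml_find_first(se, "./VERSION")
    co <- xml2::xml_find_first(ve, "./COORDINATES")
    caps_nodes <- children_named(ve, "CAPABILITY")
    caps <- vapply(caps_nodes, function(n) req_attr(n, "query_uri"), "")
    names(caps) <- vapply(caps_nodes, function(n)
      sub("^das1:", "", req_attr(n, "type")), "")
    prop_nodes <- children_named(ve, "PROP")
    props <- vapply(prop_nodes, function(n) req_attr(n, "value"), "")
    names(props) <- vapply(prop_nodes, function(n) req_attr(n, "name"), "")
    taxid <- opt_attr(co, "taxid")
    list(source_id = req_attr(se, "uri"),
         title = req_attr(se, "title"),
         description = req_attr(se, "description"),
         maintainer_email = req_attr(
           xml2::xml_find_first(se, "./MAINTAINER"), "email"),
         version = req_attr(ve, "uri"),
         coordinate_authority = req_attr(co, "authority"),
         coordinate_source_type = req_attr(co, "source"),
         organism_taxid = if (is.null(taxid)) NULL else as.integer(taxid),
         capabilities = caps,
         properties = props)
  })
  sources_document(sources)
}

# ---- DASSTYLE --------------------------------------------------------------

#' Serialize a stylesheet document to DASSTYLE XML
#' @param doc A `stylesheet_document` from [execute_stylesheet()].
#' @return A [das_payload()].
#' @export
serialize_stylesheet <- function(doc) {
  cats <- doc$stylesheet$categories
  body <- lapply(names(cats), function(cat_id) {
    types <- lapply(names(cats[[cat_id]]), function(type_id) {
      glyph <- cats[[cat_id]][[type_id]]
      shape_name <- toupper(glyph$glyph)
      shape <- if (length(glyph$attrs) == 0L)
        leaf("          ", shape_name)
      else list(
        open_tag("          ", shape_name),
        lapply(seq_along(glyph$attrs), function(a)
          leaf("            ", toupper(names(glyph$attrs)[a]),
               text = glyph$attrs[[a]])),
        close_tag("          ", shape_name))
      list(open_tag("      ", "TYPE", list(id = type_id)),
           open_tag("        ", "GLYPH"),
           shape,
           close_tag("        ", "GLYPH"),
           close_tag("      ", "TYPE"))
    })
    list(open_tag("    ", "CATEGORY", list(id = cat_id)),
         types,
         close_tag("    ", "CATEGORY"))
  })
  finish_payload(list(
    "<DASSTYLE>",
    open_tag("  ", "STYLESHEET", list(version = "1.0")),
    body,
    close_tag("  ", "STYLESHEET"),
    "</DASSTYLE>"))
}

#' Parse a DASSTYLE document
#' @param xml DASSTYLE XML as a string.
#' @return A `stylesheet_document`.
#' @export
parse_stylesheet <- function(xml) {
  root <- read_das_xml(xml, "DASSTYLE")
  ss <- xml2::xml_find_first(root, "./STYLESHEET")
  cat_nodes <- children_named(ss, "CATEGORY")
  categories <- lapply(cat_nodes, function(ce) {
    type_nodes <- children_named(ce, "TYPE")
    types <- lapply(type_nodes, function(te) {
      shape <- xml2::xml_find_first(te, "./GLYPH/*")
      attr_nodes <- xml2::xml_find_all(shape, "./*")
      attrs <- vapply(attr_nodes, function(n) trimws(xml2::xml_text(n)), "")
      names(attrs) <- tolower(vapply(attr_nodes, xml2::xml_name, ""))
      das_glyph(tolower(xml2::xml_name(shape)), attrs)
    })
    names(types) <- vapply(type_nodes, function(n) req_attr(n, "id"), "")
    types
  })
  names(categories) <- vapply(cat_nodes, function(n) req_attr(n, "id"), "")
  stylesheet_document(das_stylesheet(categories))
}

# ---- dispatch + XSLT decoration -------------------------------------------

#' Serialize any typed document to its DAS XML payload
#' @param doc A typed document from [execute()].
#' @return A [das_payload()].
#' @export
serialize_document <- function(doc) {
  if (inherits(doc, "features_document")) return(serialize_features(doc))
  if (inherits(doc, "sequence_document")) return(serialize_sequence(doc))
  if (inherits(doc, "types_document")) return(serialize_types(doc))
  if (inherits(doc, "entry_points_document"))
    return(serialize_entry_points(doc))
  if (inherits(doc, "sources_document")) return(serialize_sources(doc))
  if (inherits(doc, "stylesheet_document"))
    return(serialize_stylesheet(doc))
  stop("serialize_document: unknown document class: ",
       paste(class(doc), collapse = "/"))
}

#' Prepend an xml-stylesheet processing instruction
#'
#' With a `stylesheet_href`, inserts exactly one `xml-stylesheet`
#' processing instruction between the XML declaration and the root
#' element; the rest of the payload is byte-identical. With `NULL`, the
#' payload is returned unchanged.
#'
#' @param payload A [das_payload()].
#' @param stylesheet_href XSL stylesheet URL, or `NULL` for identity.
#' @return A [das_payload()].
#' @export
xsl_decorate <- function(payload, stylesheet_href = NULL) {
  if (is.null(stylesheet_href)) return(payload)
  pi_line <- paste0('<?xml-stylesheet type="text/xsl" href="',
                    stylesheet_href, '"?>')
  bytes <- sub("(\\?>\n)", paste0("\\1", pi_line, "\n"), payload$bytes)
  das_payload(bytes)
}
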
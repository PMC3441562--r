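# DAS object model: the in-memory types every adapter populates and every
# serializer consumes. Coordinates are 1-based, fully inclusive, forward
# strand throughout; a non-positional ("whole sequence") feature is encoded
# as start = stop = 0.

# byte-wise (C-collation) ordering helpers: server output ordering must
# not depend on the process locale
c_sort <- function(x) x[order(x, method = "radix")]
c_order <- function(...) order(..., method = "radix")

DAS_ORIENTATIONS <- c("+", "-", "0")
DAS_PHASES <- c("0", "1", "2", "-")

#' Create a segment
#'
#' A segment is one reference object (chromosome, protein, contig)
#' addressed by accession, with a 1-based inclusive extent.
#'
#' @param id Accession token (non-empty string).
#' @param start,stop 1-based inclusive positions, `start <= stop`.
#' @param version Optional version string.
#' @param label Optional display label.
#' @return A `das_segment` object.
#' @export
das_segment <- function(id, start, stop, version = NULL, label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || start > stop)
    stop("das_segment: need 1 <= start <= stop, got [", start, ", ", stop, "]")
  structure(list(id = id, start = start, stop = stop,
                 version = version, label = label),
            class = "das_segment")
}

#' Create a segment query
#'
#' The unit of all retrieval: a reference object id with an optional
#' 1-based inclusive range. `start` and `stop` must be both present or
#' both absent.
#'
#' @param id Accession token.
#' @param start,stop Optional 1-based inclusive range bounds.
#' @return A `segment_query` object.
#' @export
segment_query <- function(id, start = NULL, stop = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(start) != is.null(stop))
    stop("segment_query: start and stop must be both present or both absent")
  if (!is.null(start)) {
    start <- as.integer(start); stop <- as.integer(stop)
    if (is.na(start) || is.na(stop) || start < 1L || start > stop)
      stop("segment_query: need 1 <= start <= stop, got [", start, ", ", stop, "]")
  }
  structure(list(id = id, start = start, stop = stop), class = "segment_query")
}

#' @export
has_range <- function(q) !is.null(q$start)

#' Create an annotation type
#' @param id Type token (non-empty).
#' @param category Free-text grouping (optional).
#' @param cv_id Optional controlled-vocabulary / ontology accession.
#' @param description Optional text.
#' @export
das_type <- function(id, category = NULL, cv_id = NULL, description = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, category = category, cv_id = cv_id,
                 description = description),
            class = "das_type")
}

#' Create an annotation method
#' @param id Method token (non-empty).
#' @param cv_id Optional ontology accession.
#' @param label Optional text.
#' @export
das_method <- function(id, cv_id = NULL, label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, cv_id = cv_id, label = label), class = "das_method")
}

#' Create a feature
#'
#' One annotation on a segment. Positional features satisfy
#' `1 <= start <= stop`; whole-sequence (non-positional) features carry
#' `start = stop = 0`. An absent score is distinct from a score of 0 and
#' serializes as the DASGFF token `-`.
#'
#' @param feature_id Token unique within a source.
#' @param type A [das_type()].
#' @param method A [das_method()].
#' @param start,stop Positions (0,0 for non-positional).
#' @param label Optional display label.
#' @param score Optional numeric score (`NULL` = absent).
#' @param orientation One of `"+"`, `"-"`, `"0"` (`"0"` = not applicable).
#' @param phase One of `"0"`, `"1"`, `"2"`, `"-"`.
#' @param notes Character vector of free-text notes.
#' @param links List of `list(href=, label=)`.
#' @param targets List of `list(id=, start=, stop=)`.
#' @param parents,parts Character vectors of related feature ids.
#' @return A `das_feature` object (constructors do not validate the
#'   positional invariants; see [validate_feature()]).
#' @export
das_feature <- function(feature_id, type, method, start, stop,
                        label = NULL, score = NULL,
                        orientation = "0", phase = "-",
                        notes = character(), links = list(),
                        targets = list(), parents = character(),
                        parts = character()) {
  structure(list(
    feature_id = feature_id, label = label, type = type, method = method,
    start = as.integer(start), stop = as.integer(stop),
    score = if (is.null(score)) NULL else as.numeric(score),
    orientation = orientation, phase = phase,
    notes = as.character(notes), links = links, targets = targets,
    parents = as.character(parents), parts = as.character(parts)),
    class = "das_feature")
}

#' Is a feature non-positional (whole-sequence)?
#' @param f A `das_feature`.
#' @export
is_nonpositional <- function(f) f$start == 0L && f$stop == 0L

#' Validate a feature against the model invariants
#'
#' @param f A `das_feature`.
#' @return Character vector of violation descriptions, each naming the
#'   offending field; empty when all invariants hold.
#' @export
validate_feature <- function(f) {
  v <- character()
  if (!is.character(f$feature_id) || length(f$feature_id) != 1L ||
      !nzchar(f$feature_id))
    v <- c(v, "feature_id: must be a non-empty string")
  if (!inherits(f$type, "das_type"))
    v <- c(v, "type: must be a das_type")
  if (!inherits(f$method, "das_method"))
    v <- c(v, "method: must be a das_method")
  s <- f$start; e <- f$stop
  if (is.na(s) || is.na(e)) {
    v <- c(v, "start/stop: must be integers")
  } else if (s == 0L || e == 0L) {
    if (!(s == 0L && e == 0L))
      v <- c(v, "start/stop: mixed positional/non-positional (one of start, stop is 0)")
  } else if (s < 1L || s > e) {
    v <- c(v, "start/stop: need 1 <= start <= stop for positional features")
  }
  if (!(f$orientation %in% DAS_ORIENTATIONS))
    v <- c(v, "orientation: must be one of +, -, 0")
  if (!(f$phase %in% DAS_PHASES))
    v <- c(v, "phase: must be one of 0, 1, 2, -")
  if (!is.null(f$score) && (!is.numeric(f$score) || length(f$score) != 1L ||
                            is.na(f$score)))
    v <- c(v, "score: must be a single number or absent")
  v
}

#' Does a feature overlap a segment query?
#'
#' A whole-segment (unranged) query matches every feature of the segment.
#' A ranged query matches a positional feature iff the closed intervals
#' intersect (`feature.start <= q.stop && feature.stop >= q.start`);
#' non-positional features are relevant to any window and always match.
#'
#' @param feature A `das_feature`.
#' @param q A `segment_query` (the id is not compared here; callers
#'   resolve the segment first).
#' @return `TRUE` or `FALSE`.
#' @export
feature_overlaps <- function(feature, q) {
  if (!has_range(q)) return(TRUE)
  if (is_nonpositional(feature)) return(TRUE)
  feature$start <= q$stop && feature$stop >= q$start
}

#' Create a sequence record
#'
#' @param segment_id Segment accession.
#' @param start,stop 1-based inclusive extent of the returned residues.
#' @param version Version string of the reference object.
#' @param residues Residue text; must satisfy
#'   `nchar(residues) == stop - start + 1`.
#' @export
sequence_record <- function(segment_id, start, stop, version, residues) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (!nzchar(residues))
    stop("sequence_record: residues must be non-empty")
  if (nchar(residues) != stop - start + 1L)
    stop("sequence_record: length(residues) must equal stop - start + 1")
  structure(list(segment_id = segment_id, start = start, stop = stop,
                 version = version, residues = residues),
            class = "sequence_record")
}

#' Create an entry point
#'
#' An accession a source can answer queries about, with its extent.
#'
#' @param id Accession token.
#' @param start,stop 1-based inclusive extent.
#' @param orientation One of `"+"`, `"-"`, `"0"`.
#' @param type_label Optional reference-object type label.
#' @param description Optional text.
#' @param has_subparts Whether the object has addressable subparts.
#' @export
entry_point <- function(id, start, stop, orientation = "0",
                        type_label = NULL, description = NULL,
                        has_subparts = FALSE) {
  start <- as.integer(start); stop <- as.integer(stop)
  if (is.na(start) || is.na(stop) || start < 1L || start > stop)
    stop("entry_point: need 1 <= start <= stop")
  stopifnot(orientation %in% DAS_ORIENTATIONS)
  structure(list(id = id, start = start, stop = stop,
                 orientation = orientation, type_label = type_label,
                 description = description,
                 has_subparts = isTRUE(has_subparts)),
            class = "entry_point")
}

#' Create a stylesheet
#'
#' Server-suggested glyphs for rendering feature types, grouped by
#' category. The type id `"default"` acts as a wildcard within a
#' category.
#'
#' @param categories Named list: `category_id -> named list of
#'   type_id -> glyph`, where a glyph is
#'   `list(glyph = <name>, attrs = <named character vector>)`.
#' @export
das_stylesheet <- function(categories) {
  if (anyDuplicated(names(categories)))
    stop("das_stylesheet: category ids must be unique")
  for (cat_id in names(categories)) {
    if (anyDuplicated(names(categories[[cat_id]])))
      stop("das_stylesheet: type ids within category '", cat_id,
           "' must be unique")
  }
  structure(list(categories = categories), class = "das_stylesheet")
}

#' Create a glyph description for a stylesheet
#' @param glyph Glyph name (e.g. `"box"`, `"line"`, `"arrow"`).
#' @param attrs Named character vector of glyph attributes
#'   (e.g. `c(FGCOLOR = "blue", HEIGHT = "10")`).
#' @export
das_glyph <- function(glyph, attrs = character()) {
  attrs <- if (length(attrs)) {
    stopifnot(!is.null(names(attrs)), all(nzchar(names(attrs))),
              !anyDuplicated(names(attrs)))
    vapply(attrs, as.character, "")
  } else {
    stats::setNames(character(), character())
  }
  list(glyph = glyph, attrs = attrs)
}

#' Create a type count
#' @param type A [das_type()].
#' @param count Optional non-negative integer count.
#' @export
type_count <- function(type, count = NULL) {
  if (!is.null(count)) {
    count <- as.integer(count)
    if (is.na(count) || count < 0L) stop("type_count: count must be >= 0")
  }
  structure(list(type = type, count = count), class = "type_count")
}

# Distinguished signal an adapter returns for a segment id it does not
# describe; the command layer decides its wire representation.

#' The unknown-segment signal
#' @param id The queried segment id.
#' @export
unknown_segment <- function(id = NA_character_) {
  structure(list(id = id), class = "das_unknown_segment")
}

#' @rdname unknown_segment
#' @param x Object to test.
#' @export
is_unknown_segment <- function(x) inherits(x, "das_unknown_segment")
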
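# GFF3 parsing into an interval-indexed feature store.
#
# Column mapping: seqid -> segment id, source -> method id, type -> type id,
# start/stop -> 1-based inclusive positions, score ('.' -> absent),
# strand ('.' -> orientation "0"), phase ('.' -> "-"); attributes:
# ID -> feature_id ("line<N>" autogenerated when absent), Note -> notes,
# Parent -> parents. `##sequence-region <id> <start> <stop>` sets the
# segment bound. A line with start = stop = 0 encodes a whole-sequence
# (non-positional) feature.

gff3_unescape <- function(x) {
  if (!grepl("%", x, fixed = TRUE)) return(x)
  utils::URLdecode(x)
}

gff3_escape <- function(x) {
  # escape the GFF3 attribute-significant characters
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

parse_gff_attributes <- function(s) {
  out <- list()
  if (s == "." || !nzchar(s)) return(out)
  for (pair in strsplit(s, ";", fixed = TRUE)[[1]]) {
    pair <- trimws(pair)
    if (!nzchar(pair)) next
    eq <- regexpr("=", pair, fixed = TRUE)
    if (eq < 0) next
    key <- substr(pair, 1L, eq - 1L)
    vals <- strsplit(substr(pair, eq + 1L, nchar(pair)), ",", fixed = TRUE)[[1]]
    out[[key]] <- c(out[[key]], vapply(vals, gff3_unescape, ""))
  }
  out
}

#' Parse GFF3 text into a feature store
#'
#' Builds a `gff_store`: per-segment interval indexes of features, a
#' feature-id index, and a type tally. Duplicate feature ids are allowed
#' in the input: the last occurrence wins in the id index, all
#' occurrences enter the interval index, and a warning is issued.
#'
#' @param text GFF3 document as a single string or character vector of
#'   lines; alternatively pass a path via `file =`.
#' @param file Path to a GFF3 file.
#' @return A `gff_store` object.
#' @export
parse_gff <- function(text = NULL, file = NULL) {
  stopifnot(xor(is.null(text), is.null(file)))
  lines <- if (!is.null(file)) readLines(file, warn = FALSE)
           else if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
             strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  seg_features <- list()   # segment id -> list of das_feature
  seg_bounds <- list()     # segment id -> declared ##sequence-region stop
  feature_segment <- list()
  dup_ids <- character()
  feature_index <- new.env(parent = emptyenv())

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "##sequence-region")) {
        parts <- strsplit(trimws(line), "[ \t]+")[[1]]
        if (length(parts) >= 4L) {
          sid <- parts[2]
          bound <- suppressWarnings(as.integer(parts[4]))
          if (!is.na(bound)) seg_bounds[[sid]] <- bound
        }
      }
      next
    }
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9L)
      stop("GFF parse error at line ", i, ": expected 9 tab-separated ",
           "columns, got ", length(cols), call. = FALSE)
    start <- suppressWarnings(as.integer(cols[4]))
    stop_ <- suppressWarnings(as.integer(cols[5]))
    if (is.na(start) || is.na(stop_))
      stop("GFF parse error at line ", i, ": non-numeric coordinate",
           call. = FALSE)
    if (start > stop_)
      stop("GFF parse error at line ", i, ": start (", start,
           ") > stop (", stop_, ")", call. = FALSE)
    attrs <- parse_gff_attributes(cols[9])
    fid <- if (!is.null(attrs$ID)) attrs$ID[[1]] else paste0("line", i)
    f <- das_feature(
      feature_id = fid,
      type = das_type(cols[3]),
      method = das_method(cols[2]),
      start = start, stop = stop_,
      score = if (cols[6] == ".") NULL else as.numeric(cols[6]),
      orientation = if (cols[7] == ".") "0" else cols[7],
      phase = if (cols[8] == ".") "-" else cols[8],
      notes = if (is.null(attrs$Note)) character() else attrs$Note,
      parents = if (is.null(attrs$Parent)) character() else attrs$Parent)
    viol <- validate_feature(f)
    if (length(viol))
      stop("GFF parse error at line ", i, ": ", paste(viol, collapse = "; "),
           call. = FALSE)
    sid <- cols[1]
    seg_features[[sid]] <- c(seg_features[[sid]], list(f))
    if (!is.null(feature_index[[fid]])) dup_ids <- c(dup_ids, fid)
    assign(fid, f, envir = feature_index)
    feature_segment[[fid]] <- sid
  }
  if (length(dup_ids))
    warning("duplicate feature id(s) in GFF input (last occurrence wins ",
            "in the id index): ", paste(unique(dup_ids), collapse = ", "))

  segments <- lapply(names(seg_features), function(sid) {
    feats <- seg_features[[sid]]
    ord <- c_order(vapply(feats, `[[`, 0L, "start"),
                   vapply(feats, `[[`, "", "feature_id"))
    feats <- feats[ord]
    pos <- vapply(feats, Negate(is_nonpositional), TRUE)
    starts <- vapply(feats[pos], `[[`, 0L, "start")
    stops <- vapply(feats[pos], `[[`, 0L, "stop")
    max_stop <- if (any(pos)) max(stops) else 1L
    declared <- seg_bounds[[sid]]
    list(
      id = sid,
      bound = max(as.integer(c(declared, max_stop))),
      features = feats,
      positional = feats[pos],
      nonpositional = feats[!pos],
      index = IRanges::IRanges(start = starts, end = stops))
  })
  names(segments) <- names(seg_features)
  # segments declared only via ##sequence-region, with no features
  for (sid in setdiff(names(seg_bounds), names(segments))) {
    segments[[sid]] <- list(id = sid, bound = seg_bounds[[sid]],
                            features = list(), positional = list(),
                            nonpositional = list(),
                            index = IRanges::IRanges())
  }
  structure(list(segments = segments, feature_index = feature_index,
                 feature_segment = feature_segment),
            class = "gff_store")
}

#' Query a feature store by segment
#'
#' @param store A `gff_store` from [parse_gff()].
#' @param q A [segment_query()]. Unranged: every feature of the segment.
#'   Ranged: positional features whose closed interval intersects the
#'   range, plus all non-positional features (a whole-sequence annotation
#'   is relevant to any window).
#' @return List of `das_feature` in deterministic order (ascending start,
#'   then feature id; non-positional features, at position 0, sort first),
#'   or the [unknown_segment()] signal for an id the store does not hold.
#' @export
query_interval_index <- function(store, q) {
  seg <- store$segments[[q$id]]
  if (is.null(seg)) return(unknown_segment(q$id))
  if (!has_range(q)) return(seg$features)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = q$start, end = q$stop), seg$index)
  feats <- c(seg$nonpositional,
             seg$positional[sort(S4Vectors::subjectHits(hits))])
  ord <- c_order(vapply(feats, `[[`, 0L, "start"),
                 vapply(feats, `[[`, "", "feature_id"))
  feats[ord]
}

#' Tally annotation types in a store
#'
#' @param store A `gff_store`.
#' @param features Optional explicit feature list to tally instead of the
#'   whole store.
#' @return List of [type_count()] sorted by type id.
#' @export
store_type_counts <- function(store, features = NULL) {
  feats <- if (!is.null(features)) features
           else unlist(lapply(store$segments, `[[`, "features"),
                       recursive = FALSE)
  ids <- vapply(feats, function(f) f$type$id, "")
  tab <- table(ids)
  lapply(c_sort(names(tab)), function(tid)
    type_count(das_type(tid), count = as.integer(tab[[tid]])))
}

#' Serialize a feature store back to GFF3 text
#'
#' Feature-level inverse of [parse_gff()] (comment lines are not
#' preserved; `##sequence-region` directives are re-emitted from the
#' stored bounds).
#'
#' @param store A `gff_store`.
#' @return A single string of GFF3 text.
#' @export
write_gff <- function(store) {
  out <- c("##gff-version 3")
  sids <- c_sort(names(store$segments))
  for (sid in sids) {
    seg <- store$segments[[sid]]
    out <- c(out, paste("##sequence-region", sid, 1L, seg$bound))
  }
  for (sid in sids) {
    for (f in store$segments[[sid]]$features) {
      attrs <- paste0("ID=", gff3_escape(f$feature_id))
      if (length(f$notes))
        attrs <- paste0(attrs, ";Note=",
                        paste(vapply(f$notes, gff3_escape, ""),
                              collapse = ","))
      if (length(f$parents))
        attrs <- paste0(attrs, ";Parent=",
                        paste(vapply(f$parents, gff3_escape, ""),
                              collapse = ","))
      out <- c(out, paste(
        sid, f$method$id, f$type$id, f$start, f$stop,
        if (is.null(f$score)) "." else as.character(f$score),
        if (f$orientation == "0") "." else f$orientation,
        if (f$phase == "-") "." else f$phase,
        attrs, sep = "\t"))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
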
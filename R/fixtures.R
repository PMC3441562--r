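# Deterministic synthetic fixtures: GFF annotation files with exact
# bookkeeping (the ground truth for parser and query oracles) and
# reference sequences. Randomness uses R's Mersenne-Twister with
# Inversion normal sampling, restored on exit, so the same seed gives
# byte-identical output on any platform.

with_fixture_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Describe a synthetic annotation fixture
#'
#' @param seed Integer RNG seed.
#' @param n_segments Number of segments (> 0).
#' @param segment_length Length of every segment in residues (> 0).
#' @param n_features Total number of features (> 0).
#' @param type_vocabulary Data frame with columns `type_id`, `category`
#'   and optionally `weight` (sampling weights, default equal).
#' @param feature_length_range `c(min, max)` feature lengths,
#'   `min <= max <= segment_length`.
#' @param fraction_nonpositional Proportion in `[0, 1]` of
#'   whole-sequence (start = stop = 0) features.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_segments = 5L,
                         segment_length = 100000L, n_features = 1000L,
                         type_vocabulary = default_type_vocabulary(),
                         feature_length_range = c(50L, 2000L),
                         fraction_nonpositional = 0.02) {
  if (n_segments < 1L) stop("fixture_spec: n_segments must be positive")
  if (segment_length < 1L)
    stop("fixture_spec: segment_length must be positive")
  if (n_features < 1L) stop("fixture_spec: n_features must be positive")
  if (!is.data.frame(type_vocabulary) || nrow(type_vocabulary) == 0L)
    stop("fixture_spec: type_vocabulary must be a non-empty data frame")
  if (is.null(type_vocabulary$weight))
    type_vocabulary$weight <- rep(1, nrow(type_vocabulary))
  r <- as.integer(feature_length_range)
  if (length(r) != 2L || r[1] > r[2] || r[2] > segment_length)
    stop("fixture_spec: feature_length_range must satisfy min <= max <= segment_length")
  if (fraction_nonpositional < 0 || fraction_nonpositional > 1)
    stop("fixture_spec: fraction_nonpositional must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_segments = as.integer(n_segments),
                 segment_length = as.integer(segment_length),
                 n_features = as.integer(n_features),
                 type_vocabulary = type_vocabulary,
                 feature_length_range = r,
                 fraction_nonpositional = fraction_nonpositional),
            class = "fixture_spec")
}

#' Default annotation-type vocabulary for fixtures
#' @export
default_type_vocabulary <- function() {
  data.frame(
    type_id = c("exon", "intron", "CDS", "repeat_region", "binding_site"),
    category = c("transcription", "transcription", "translation",
                 "structural", "regulation"),
    weight = c(4, 3, 2, 1, 1))
}

fixture_segment_ids <- function(spec) {
  sprintf("seg%03d", seq_len(spec$n_segments))
}

#' Generate a synthetic GFF fixture with exact bookkeeping
#'
#' Same seed, same bytes. Feature ids are `f<segment_index>_<ordinal>`
#' (stable, sortable, collision-free). Roughly one in five positional
#' features carries no score and every feature drawn non-positional is
#' written as `0 0` on both coordinates.
#'
#' @param spec A [fixture_spec()].
#' @return `list(gff = <single string>, type_counts = <named integer
#'   vector>, segment_features = <named list of das_feature lists,
#'   sorted ascending start then feature id>, segment_ids = <character>)`.
#' @export
generate_gff <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    sids <- fixture_segment_ids(spec)
    vocab <- spec$type_vocabulary
    n <- spec$n_features
    seg_idx <- sample.int(spec$n_segments, n, replace = TRUE)
    type_row <- sample.int(nrow(vocab), n, replace = TRUE,
                           prob = vocab$weight)
    nonpos <- stats::runif(n) < spec$fraction_nonpositional
    len <- sample(seq(spec$feature_length_range[1],
                      spec$feature_length_range[2]), n, replace = TRUE)
    start <- vapply(len, function(l)
      sample.int(spec$segment_length - l + 1L, 1L), 0L)
    has_score <- stats::runif(n) >= 0.2
    score <- round(stats::runif(n, 0, 1000), 3)
    strand <- sample(c("+", "-", "."), n, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1))
    has_note <- stats::runif(n) < 0.3
    ordinal <- stats::ave(seq_len(n), seg_idx, FUN = seq_along)

    lines <- character(n)
    features <- vector("list", n)
    for (i in seq_len(n)) {
      fid <- paste0("f", seg_idx[i], "_", ordinal[i])
      s <- if (nonpos[i]) 0L else start[i]
      e <- if (nonpos[i]) 0L else start[i] + len[i] - 1L
      notes <- if (has_note[i])
        paste0("synthetic annotation ", fid) else character()
      attrs <- paste0("ID=", fid)
      if (length(notes)) attrs <- paste0(attrs, ";Note=",
                                         gff3_escape(notes))
      lines[i] <- paste(
        sids[seg_idx[i]], "dasserve_sim", vocab$type_id[type_row[i]],
        s, e,
        if (nonpos[i] || !has_score[i]) "." else as.character(score[i]),
        if (nonpos[i]) "." else strand[i],
        ".", attrs, sep = "\t")
      features[[i]] <- das_feature(
        feature_id = fid,
        type = das_type(vocab$type_id[type_row[i]]),
        method = das_method("dasserve_sim"),
        start = s, stop = e,
        score = if (nonpos[i] || !has_score[i]) NULL else score[i],
        orientation = if (nonpos[i] || strand[i] == ".") "0" else strand[i],
        phase = "-", notes = notes)
    }
    header <- c("##gff-version 3",
                paste("##sequence-region", sids, 1L, spec$segment_length))
    counts <- table(factor(vocab$type_id[type_row],
                           levels = c_sort(vocab$type_id)))
    type_counts <- stats::setNames(as.integer(counts), names(counts))
    segment_features <- lapply(seq_len(spec$n_segments), function(k) {
      feats <- features[seg_idx == k]
      ord <- c_order(vapply(feats, `[[`, 0L, "start"),
                     vapply(feats, `[[`, "", "feature_id"))
      feats[ord]
    })
    names(segment_features) <- sids
    list(gff = paste0(paste(c(header, lines), collapse = "\n"), "\n"),
         type_counts = type_counts,
         segment_features = segment_features,
         segment_ids = sids)
  })
}

#' Generate deterministic reference sequences for a fixture
#'
#' One nucleotide string of length `segment_length` per segment id,
#' deterministic by seed (a fixed offset of the fixture seed keeps the
#' stream independent of [generate_gff()]).
#'
#' @param spec A [fixture_spec()].
#' @return Named character vector: segment id -> residues.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed + 104729L, {
    sids <- fixture_segment_ids(spec)
    out <- vapply(sids, function(sid)
      paste(sample(c("A", "C", "G", "T"), spec$segment_length,
                   replace = TRUE), collapse = ""), "")
    names(out) <- sids
    out
  })
}

#' Write fixture files for a configured server
#'
#' Materializes the GFF and (optionally) the tab-separated reference
#' file the built-in adapters read.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param reference Also write `reference.tsv`.
#' @return `list(gff_path =, reference_path =, bookkeeping =)`.
#' @export
write_fixture_files <- function(spec, dir = tempfile("das-fixture-"),
                                reference = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_gff(spec)
  gff_path <- file.path(dir, "annotations.gff")
  writeLines(sub("\n$", "", gen$gff), gff_path)
  ref_path <- NULL
  if (reference) {
    seqs <- generate_reference(spec)
    ref_path <- file.path(dir, "reference.tsv")
    writeLines(paste(names(seqs), "1.0", seqs, sep = "\t"), ref_path)
  }
  list(gff_path = gff_path, reference_path = ref_path, bookkeeping = gen)
}

measure_features_response <- function(spec) {
  gen <- generate_gff(spec)
  store <- parse_gff(gen$gff)
  handle <- gff_adapter(store)
  doc <- execute_features(
    handle, lapply(gen$segment_ids, segment_query),
    href = "http://localhost:8080/das/bench/features")
  nchar(serialize_features(doc)$bytes, type = "bytes")
}

#' Find a fixture whose features response has a target size
#'
#' Searches `n_features` by doubling then bisection until the
#' whole-file DASGFF features response serializes to within
#' `tolerance * target_bytes` of `target_bytes`.
#'
#' @param target_bytes Target response size (>= the size of the empty
#'   document envelope).
#' @param tolerance Acceptable relative deviation (default 0.25).
#' @param seed Seed for the candidate specs.
#' @param n_segments,segment_length Passed through to [fixture_spec()].
#' @return A `fixture_spec` whose measured response size is within
#'   tolerance (also recorded in `attr(, "measured_bytes")`).
#' @export
size_targeted_fixture <- function(target_bytes, tolerance = 0.25,
                                  seed = 1L, n_segments = 1L,
                                  segment_length = 100000L) {
  make <- function(n_features)
    fixture_spec(seed = seed, n_segments = n_segments,
                 segment_length = segment_length,
                 n_features = n_features)
  lo_bytes <- measure_features_response(make(1L))
  if (target_bytes < lo_bytes * (1 - tolerance))
    stop("size_targeted_fixture: target ", target_bytes,
         " bytes is below the minimal document size (best achievable: ",
         lo_bytes, " bytes)")
  within_tol <- function(b) abs(b - target_bytes) <= tolerance * target_bytes
  n <- 1L; b <- lo_bytes
  while (b < target_bytes) {
    if (within_tol(b)) break
    n <- n * 2L
    b <- measure_features_response(make(n))
  }
  if (!within_tol(b)) {
    lo <- max(1L, n %/% 2L); hi <- n
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      b <- measure_features_response(make(mid))
      if (within_tol(b)) { n <- mid; break }
      if (b < target_bytes) lo <- mid else hi <- mid
      n <- mid
    }
    b <- measure_features_response(make(n))
    if (!within_tol(b)) {
      for (cand in unique(c(lo, hi))) {
        bc <- measure_features_response(make(cand))
        if (abs(bc - target_bytes) < abs(b - target_bytes)) {
          n <- cand; b <- bc
        }
      }
      if (!within_tol(b))
        stop("size_targeted_fixture: cannot reach ", target_bytes,
             " bytes within ", tolerance * 100, "% (best achieved: ", b,
             " bytes with n_features = ", n, ")")
    }
  }
  spec <- make(n)
  attr(spec, "measured_bytes") <- b
  spec
}
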
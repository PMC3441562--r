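# Shared fixture builders. Everything is generated in code at test time;
# expensive artifacts are built once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small two-source (annotation + reference) deployment on disk.
standard_deployment <- function() {
  cached("standard_deployment", function() {
    spec <- fixture_spec(seed = 42L, n_segments = 3L,
                         segment_length = 10000L, n_features = 300L,
                         feature_length_range = c(20L, 500L))
    fx <- write_fixture_files(spec)
    cfg_text <- sprintf(paste0(
      "server:\n",
      "  base_url: http://localhost:8080/das\n",
      "sources:\n",
      "  - id: demo\n",
      "    title: Demo annotations\n",
      "    description: synthetic annotation source\n",
      "    maintainer: demo@example.org\n",
      "    version: '2.1'\n",
      "    coordinates:\n",
      "      authority: TestAssembly\n",
      "      source_type: Chromosome\n",
      "      taxid: 9606\n",
      "    capabilities: [features, types, entry_points, stylesheet]\n",
      "    adapter: gff\n",
      "    properties:\n",
      "      file: %s\n",
      "  - id: ref\n",
      "    title: Demo reference\n",
      "    adapter: reference\n",
      "    capabilities: [sequence, entry_points, types, features]\n",
      "    properties:\n",
      "      file: %s\n"),
      fx$gff_path, fx$reference_path)
    cfg_path <- tempfile(fileext = ".yaml")
    writeLines(cfg_text, cfg_path)
    cfg <- parse_server_config(cfg_text)
    list(spec = spec, fx = fx, cfg_text = cfg_text, cfg_path = cfg_path,
         cfg = cfg, adapters = load_config_adapters(cfg))
  })
}

# ---- random document generators (XML round-trip material) -----------------

rand_bool <- function(p = 0.5) stats::runif(1) < p

rand_token <- function(prefix = "t") {
  paste0(prefix, sample.int(1e6, 1))
}

rand_text <- function() {
  pool <- c("plain text", "with <angle> brackets", "amp & semi;",
            "quote \"double\" and 'single'", "café résumé",
            "tab\tand spaces", "a=b;c,d")
  sample(pool, 1)
}

rand_maybe <- function(value, p = 0.5) if (rand_bool(p)) value else NULL

rand_feature <- function(i) {
  nonpos <- rand_bool(0.1)
  start <- if (nonpos) 0L else sample.int(10000L, 1)
  stop_ <- if (nonpos) 0L else start + sample.int(500L, 1) - 1L
  das_feature(
    feature_id = paste0("x", i, "_", rand_token("")),
    label = rand_maybe(rand_text(), 0.3),
    type = das_type(rand_token("type"),
                    category = rand_maybe(rand_text(), 0.5),
                    cv_id = rand_maybe(rand_token("SO:"), 0.3),
                    description = rand_maybe(rand_text(), 0.2)),
    method = das_method(rand_token("m"),
                        cv_id = rand_maybe(rand_token("ECO:"), 0.3),
                        label = rand_maybe(rand_text(), 0.3)),
    start = start, stop = stop_,
    score = rand_maybe(round(stats::runif(1, 0, 1000), 3), 0.6),
    orientation = sample(c("+", "-", "0"), 1),
    phase = sample(c("0", "1", "2", "-"), 1),
    notes = if (rand_bool(0.4)) replicate(sample.int(2, 1), rand_text())
            else character(),
    links = if (rand_bool(0.3))
      list(list(href = paste0("http://example.org/", rand_token("l")),
                label = rand_text()))
    else list(),
    targets = if (rand_bool(0.2))
      list(list(id = rand_token("tg"), start = 1L,
                stop = sample.int(100L, 1)))
    else list(),
    parents = if (rand_bool(0.2)) rand_token("p") else character(),
    parts = if (rand_bool(0.2)) rand_token("c") else character())
}

rand_segment <- function() {
  start <- sample.int(1000L, 1)
  das_segment(rand_token("seg"), start, start + sample.int(5000L, 1),
              version = rand_maybe(rand_token("v"), 0.5),
              label = rand_maybe(rand_text(), 0.3))
}

rand_features_document <- function() {
  n_blocks <- sample.int(3L, 1)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    if (rand_bool(0.15))
      return(list(segment = unknown_segment(rand_token("missing")),
                  features = list()))
    n_feat <- sample(0:5, 1)
    list(segment = rand_segment(),
         features = lapply(seq_len(n_feat), rand_feature))
  })
  dasserve:::features_document(
    blocks, href = paste0("http://example.org/das/",
                          rand_token("s"), "/features"))
}

rand_sequence_document <- function() {
  n <- sample.int(3L, 1)
  dasserve:::sequence_document(lapply(seq_len(n), function(i) {
    start <- sample.int(500L, 1)
    len <- sample.int(200L, 1)
    sequence_record(rand_token("seq"), start, start + len - 1L,
                    rand_token("v"),
                    paste(sample(c("A", "C", "G", "T"), len,
                                 replace = TRUE), collapse = ""))
  }))
}

rand_type_count <- function() {
  type_count(das_type(rand_token("type"),
                      category = rand_maybe(rand_text(), 0.5),
                      cv_id = rand_maybe(rand_token("SO:"), 0.3),
                      description = rand_maybe(rand_text(), 0.2)),
             count = rand_maybe(sample.int(500L, 1), 0.8))
}

rand_types_document <- function() {
  n_blocks <- sample.int(3L, 1)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    seg <- if (rand_bool(0.2)) NULL
           else if (rand_bool(0.15)) unknown_segment(rand_token("missing"))
           else rand_segment()
    types <- if (is_unknown_segment(seg)) list()
             else lapply(seq_len(sample(0:4, 1)), function(i)
               rand_type_count())
    list(segment = seg, types = types)
  })
  dasserve:::types_document(
    blocks, href = paste0("http://example.org/das/",
                          rand_token("s"), "/types"))
}

rand_entry_points_document <- function() {
  n <- sample(0:5, 1)
  eps <- lapply(seq_len(n), function(i) {
    start <- sample.int(100L, 1)
    entry_point(rand_token("ep"), start, start + sample.int(10000L, 1),
                orientation = sample(c("+", "-", "0"), 1),
                type_label = rand_maybe(rand_token("chromosome"), 0.4),
                description = rand_maybe(rand_text(), 0.4),
                has_subparts = rand_bool(0.2))
  })
  total <- n + sample(0:20, 1)
  dasserve:::entry_points_document(
    paste0("http://example.org/das/", rand_token("s"), "/entry_points"),
    total = total, first = 1L, last = n, entry_points = eps)
}

rand_source_metadata <- function() {
  caps <- sort(sample(c("sources", "features", "types", "entry_points",
                        "sequence", "stylesheet"), sample(2:6, 1)))
  uris <- stats::setNames(
    paste0("http://example.org/das/x/", caps), caps)
  nprop <- sample(0:3, 1)
  props <- stats::setNames(
    vapply(seq_len(nprop), function(i) rand_text(), character(1)),
    vapply(seq_len(nprop), function(i) rand_token("prop"), character(1)))
  if (nprop == 0L) props <- stats::setNames(character(), character())
  list(source_id = rand_token("src"),
       title = rand_text(),
       description = rand_text(),
       maintainer_email = "maintainer@example.org",
       version = rand_token("v"),
       coordinate_authority = rand_token("auth"),
       coordinate_source_type = sample(c("Chromosome", "Protein Sequence",
                                         "Contig"), 1),
       organism_taxid = if (rand_bool(0.6)) sample.int(99999L, 1) else NULL,
       capabilities = uris,
       properties = props)
}

rand_sources_document <- function() {
  dasserve:::sources_document(
    lapply(seq_len(sample.int(3L, 1)), function(i) rand_source_metadata()))
}

rand_stylesheet_document <- function() {
  n_cat <- sample.int(3L, 1)
  cats <- lapply(seq_len(n_cat), function(i) {
    n_type <- sample.int(3L, 1)
    type_ids <- c(if (rand_bool(0.5)) "default",
                  replicate(n_type, rand_token("type")))
    glyphs <- lapply(type_ids, function(t) {
      n_attr <- sample(0:3, 1)
      attrs <- stats::setNames(
        vapply(seq_len(n_attr), function(i)
          sample(c("blue", "red", "10", "yes"), 1), character(1)),
        sample(c("fgcolor", "bgcolor", "height", "bump"), n_attr))
      if (n_attr == 0L) attrs <- stats::setNames(character(), character())
      das_glyph(sample(c("box", "line", "arrow", "span"), 1), attrs)
    })
    stats::setNames(glyphs, type_ids)
  })
  dasserve:::stylesheet_document(
    das_stylesheet(stats::setNames(
      cats, vapply(seq_len(n_cat), function(i) rand_token("cat"),
                   character(1)))))
}

document_generators <- function() {
  list(features = rand_features_document,
       sequence = rand_sequence_document,
       types = rand_types_document,
       entry_points = rand_entry_points_document,
       sources = rand_sources_document,
       stylesheet = rand_stylesheet_document)
}

document_serializers <- function() {
  list(features = serialize_features, sequence = serialize_sequence,
       types = serialize_types, entry_points = serialize_entry_points,
       sources = serialize_sources, stylesheet = serialize_stylesheet)
}

document_parsers <- function() {
  list(features = parse_features, sequence = parse_sequence,
       types = parse_types, entry_points = parse_entry_points,
       sources = parse_sources, stylesheet = parse_stylesheet)
}

# Independent brute-force interval check used as the query oracle: plain
# arithmetic on the closed intervals, no calls into the overlap code
# under test.
oracle_overlap_scan <- function(features, q_start, q_stop) {
  Filter(function(f) {
    if (f$start == 0L && f$stop == 0L) return(TRUE)
    f$start <= q_stop && f$stop >= q_start
  }, features)
}

feature_ids_of <- function(features) {
  sort(vapply(features, `[[`, "", "feature_id"))
}
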
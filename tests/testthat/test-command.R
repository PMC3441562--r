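expect_das_error <- function(expr, name) {
  err <- tryCatch({ expr; NULL }, das_error = function(e) e)
  expect_false(is.null(err), label = "expected a DAS error")
  expect_identical(das_error_name(err), name)
}

test_that("request URLs parse into commands with accumulated parameters", {
  cmd <- parse_request("/das/demo/features",
                       "segment=chr1:100,200;type=exon")
  expect_identical(cmd$command, "features")
  expect_identical(cmd$source_id, "demo")
  expect_length(cmd$segments, 1)
  expect_identical(cmd$segments[[1]],
                   segment_query("chr1", 100, 200))
  expect_identical(cmd$type_filters, "exon")

  cmd <- parse_request("/das/demo/features",
                       "segment=chr1&segment=chr2:5,10&feature_id=f1&rows=2-4")
  expect_length(cmd$segments, 2)
  expect_false(has_range(cmd$segments[[1]]))
  expect_true(has_range(cmd$segments[[2]]))
  expect_identical(cmd$feature_ids, "f1")
  expect_identical(cmd$rows, c(2L, 4L))

  expect_identical(parse_request("/das/sources")$command, "sources")
  expect_identical(parse_request("/das/demo")$source_id, "demo")
})

test_that("malformed requests map to the right taxonomy entries", {
  expect_das_error(parse_request("/das/demo/features",
                                 "segment=chr1:200,100"),
                   "BAD_COMMAND_ARGS")
  expect_das_error(parse_request("/das/demo/features", "segment=chr1:x,y"),
                   "BAD_COMMAND_ARGS")
  expect_das_error(parse_request("/das/demo/nosuchcommand"), "BAD_COMMAND")
  expect_das_error(parse_request("/elsewhere/demo/features"), "BAD_COMMAND")
  expect_das_error(parse_request("/das/demo/features", "rows=9"),
                   "BAD_COMMAND_ARGS")
})

test_that("parse/render is the identity on canonical request URLs", {
  set.seed(41)
  commands <- c("features", "types", "entry_points", "sequence",
                "stylesheet")
  for (i in seq_len(500)) {
    command <- sample(commands, 1)
    cmd <- das_command(
      command, source_id = rand_token("src"),
      segments = if (command %in% c("features", "types", "sequence"))
        lapply(seq_len(sample.int(3L, 1)), function(j) {
          if (rand_bool()) {
            a <- sample.int(1000L, 1)
            segment_query(rand_token("seg"), a, a + sample.int(500L, 1))
          } else segment_query(rand_token("seg"))
        }) else list(),
      type_filters = if (command == "features" && rand_bool(0.4))
        replicate(sample.int(2L, 1), rand_token("type")) else character(),
      category_filters = if (command == "features" && rand_bool(0.3))
        rand_token("cat") else character(),
      feature_ids = if (command == "features" && rand_bool(0.3))
        rand_token("f") else character(),
      rows = if (command == "entry_points" && rand_bool()) {
        a <- sample.int(50L, 1); c(a, a + sample.int(50L, 1))
      } else NULL)
    url <- canonical_request(cmd)
    expect_identical(parse_request(url$path, url$query), cmd)
  }
})

test_that("execute dispatches on source and capability", {
  dep <- standard_deployment()
  doc <- execute(parse_request("/das/sources"), dep$cfg, dep$adapters)
  expect_s3_class(doc, "sources_document")
  expect_identical(vapply(doc$sources, `[[`, "", "source_id"),
                   c("demo", "ref"))  # config order
  single <- execute(parse_request("/das/ref"), dep$cfg, dep$adapters)
  expect_length(single$sources, 1)
  expect_identical(single$sources[[1]]$source_id, "ref")

  expect_das_error(execute(parse_request("/das/nosuch/features",
                                         "segment=seg001"),
                           dep$cfg, dep$adapters), "BAD_DATA_SOURCE")
  # demo is an annotation source: no sequence capability
  expect_das_error(execute(parse_request("/das/demo/sequence",
                                         "segment=seg001"),
                           dep$cfg, dep$adapters), "BAD_COMMAND")
  expect_das_error(execute(parse_request("/das/demo/features"),
                           dep$cfg, dep$adapters), "BAD_COMMAND_ARGS")
})

test_that("segment blocks preserve request order; unknowns become markers", {
  dep <- standard_deployment()
  doc <- execute(parse_request(
    "/das/demo/features",
    "segment=seg002;segment=chrZZ;segment=seg001:1,500"),
    dep$cfg, dep$adapters)
  expect_length(doc$blocks, 3)
  expect_identical(doc$blocks[[1]]$segment$id, "seg002")
  expect_true(is_unknown_segment(doc$blocks[[2]]$segment))
  expect_identical(doc$blocks[[2]]$segment$id, "chrZZ")
  expect_identical(doc$blocks[[3]]$segment$stop, 500L)
})

test_that("filters obey identity, composition, and the brute-force oracle", {
  dep <- standard_deployment()
  h <- dep$adapters$demo
  q <- list(segment_query("seg001"))
  all_feats <- execute_features(h, q)$blocks[[1]]$features
  # empty filter = identity
  expect_identical(
    execute_features(h, q, type_filters = character())$blocks[[1]]$features,
    all_feats)
  # composed filters = intersection of singly-filtered results
  tf <- "exon"; cf <- "transcription"
  both <- execute_features(h, q, type_filters = tf,
                           category_filters = cf)$blocks[[1]]$features
  only_t <- execute_features(h, q, type_filters = tf)$blocks[[1]]$features
  only_c <- execute_features(h, q,
                             category_filters = cf)$blocks[[1]]$features
  expect_identical(feature_ids_of(both),
                   intersect(feature_ids_of(only_t), feature_ids_of(only_c)))
  # filters never add features
  expect_true(all(feature_ids_of(both) %in% feature_ids_of(all_feats)))

  # brute-force filter oracle over random filter combinations;
  # category filters need the store's type->category map
  vocab <- dep$spec$type_vocabulary
  set.seed(42)
  for (k in seq_len(25)) {
    tf <- if (rand_bool()) sample(vocab$type_id, sample.int(2L, 1))
          else character()
    cf <- if (rand_bool()) sample(unique(vocab$category), 1)
          else character()
    got <- execute_features(h, q, type_filters = tf,
                            category_filters = cf)$blocks[[1]]$features
    # plain GFF carries no categories, so a category filter can only
    # match features whose type has one (here: none)
    want <- Filter(function(f) {
      (length(tf) == 0L || f$type$id %in% tf) && length(cf) == 0L
    }, all_feats)
    expect_identical(feature_ids_of(got), feature_ids_of(want))
  }

  # categorized types exercise the positive category-filter path
  cat_feats <- list(
    das_feature("c1", das_type("exon", category = "transcription"),
                das_method("m"), 1, 10),
    das_feature("c2", das_type("helix", category = "structural"),
                das_method("m"), 5, 20),
    das_feature("c3", das_type("intron", category = "transcription"),
                das_method("m"), 30, 40))
  fake <- list(get_features_by_segment = function(q)
    list(segment = das_segment(q$id, 1L, 100L), features = cat_feats),
    get_features_by_id = function(fid) list())
  doc <- execute_features(fake, list(segment_query("s")),
                          category_filters = "transcription")
  expect_identical(feature_ids_of(doc$blocks[[1]]$features), c("c1", "c3"))
  doc <- execute_features(fake, list(segment_query("s")),
                          type_filters = c("exon", "helix"),
                          category_filters = "structural")
  expect_identical(feature_ids_of(doc$blocks[[1]]$features), "c2")
})

test_that("type counts tally correctly source-wide and per segment", {
  txt <- paste(c(
    "chr1\ts\texon\t1\t10\t.\t.\t.\tID=a",
    "chr1\ts\texon\t20\t30\t.\t.\t.\tID=b",
    "chr1\ts\texon\t40\t50\t.\t.\t.\tID=c",
    "chr2\ts\tintron\t1\t10\t.\t.\t.\tID=d",
    "chr2\ts\tintron\t20\t30\t.\t.\t.\tID=e"), collapse = "\n")
  h <- gff_adapter(parse_gff(txt))
  doc <- execute_types(h)
  counts <- doc$blocks[[1]]$types
  expect_identical(vapply(counts, function(tc) tc$type$id, ""),
                   c("exon", "intron"))
  expect_identical(vapply(counts, `[[`, 0L, "count"), c(3L, 2L))

  # per-segment counts over all segments sum to the source-wide counts
  per <- execute_types(h, list(segment_query("chr1"), segment_query("chr2")))
  per_sum <- sum(unlist(lapply(per$blocks, function(b)
    vapply(b$types, `[[`, 0L, "count"))))
  expect_identical(per_sum, 5L)

  dep <- standard_deployment()
  hd <- dep$adapters$demo
  per <- execute_types(hd, lapply(dep$fx$bookkeeping$segment_ids,
                                  segment_query))
  tally <- integer()
  for (b in per$blocks)
    for (tc in b$types)
      tally[tc$type$id] <- sum(tally[tc$type$id], tc$count, na.rm = TRUE)
  expect_identical(tally[sort(names(tally))],
                   dep$fx$bookkeeping$type_counts)
})

test_that("entry-point windows clip to the listing and report totals", {
  seqs <- stats::setNames(as.list(rep(strrep("ACGT", 25), 10)),
                          sprintf("e%02d", 1:10))
  h <- reference_adapter(seqs)
  doc <- execute_entry_points(h, rows = c(1L, 3L))
  expect_identical(doc$total, 10L)
  expect_length(doc$entry_points, 3)
  expect_identical(doc$first, 1L)
  expect_identical(doc$last, 3L)
  # rows absent: first page of the default size
  expect_length(execute_entry_points(h, page_size_default = 4L)$entry_points,
                4)
  # window past the end is empty, not an error
  expect_length(execute_entry_points(h, rows = c(11L, 20L))$entry_points, 0)
  # concatenation completeness at the document level
  for (k in c(1L, 3L, 7L)) {
    got <- list()
    first <- 1L
    repeat {
      page <- execute_entry_points(h, rows = c(first, first + k - 1L))
      if (length(page$entry_points) == 0L) break
      got <- c(got, page$entry_points)
      first <- first + k
    }
    expect_identical(got,
                     execute_entry_points(h, rows = c(1L, 10L))$entry_points)
  }
})

test_that("stylesheet resolution prefers the adapter over the server default", {
  default_sty <- das_stylesheet(list(
    default = list(default = das_glyph("box", c(fgcolor = "gray")))))
  adapter_sty <- das_stylesheet(list(
    transcription = list(exon = das_glyph("box", c(fgcolor = "blue")))))
  dep <- standard_deployment()
  store <- parse_gff(file = dep$fx$gff_path)
  with_sty <- gff_adapter(store, stylesheet = adapter_sty)
  without_sty <- gff_adapter(store)
  expect_identical(execute_stylesheet(with_sty, default_sty)$stylesheet,
                   adapter_sty)
  expect_identical(execute_stylesheet(without_sty, default_sty)$stylesheet,
                   default_sty)
  expect_das_error(execute_stylesheet(without_sty, NULL), "BAD_STYLESHEET")
})

test_that("execution is deterministic: identical bytes on repeat", {
  dep <- standard_deployment()
  for (url in list(c("/das/demo/features", "segment=seg001:1,5000"),
                   c("/das/demo/types", ""),
                   c("/das/demo/entry_points", "rows=1-2"),
                   c("/das/ref/sequence", "segment=seg002:10,200"),
                   c("/das/sources", ""))) {
    run <- function() {
      cmd <- parse_request(url[1], if (nzchar(url[2])) url[2] else NULL)
      serialize_document(execute(cmd, dep$cfg, dep$adapters))$bytes
    }
    expect_identical(run(), run())
  }
})
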
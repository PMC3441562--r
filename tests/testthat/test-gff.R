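gff_lines <- function(...) paste(c(...), collapse = "\n")

test_that("feature lines map onto the model with sentinel conversion", {
  txt <- gff_lines(
    "##gff-version 3",
    "##sequence-region chr1 1 5000",
    "chr1\tsrcA\texon\t100\t200\t5.5\t+\t0\tID=e1;Note=first%2C escaped",
    "chr1\tsrcA\tintron\t201\t300\t.\t.\t.\tID=i1;Parent=e1",
    "chr1\tsrcA\texon\t400\t450\t0\t-\t2\tID=e2")
  store <- parse_gff(txt)
  expect_length(store$segments, 1)
  expect_length(store$segments$chr1$features, 3)
  expect_identical(store$segments$chr1$bound, 5000L)

  i1 <- store$feature_index[["i1"]]
  expect_null(i1$score)            # '.' means absent, not zero
  expect_identical(i1$orientation, "0")
  expect_identical(i1$phase, "-")
  expect_identical(i1$parents, "e1")

  e1 <- store$feature_index[["e1"]]
  expect_identical(e1$score, 5.5)
  expect_identical(e1$notes, "first, escaped")

  e2 <- store$feature_index[["e2"]]
  expect_identical(e2$score, 0)    # explicit zero stays a number
})

test_that("feature id autogenerates from the line number when ID is absent", {
  store <- parse_gff(gff_lines(
    "chr1\ts\texon\t1\t10\t.\t.\t.\t.",
    "chr1\ts\texon\t20\t30\t.\t.\t.\tcolor=blue"))
  expect_setequal(ls(store$feature_index), c("line1", "line2"))
})

test_that("parse errors carry the line number", {
  expect_error(parse_gff("chr1\ts\texon\t1\t10\t.\t.\t."),
               "line 1.*9 tab-separated")
  expect_error(parse_gff(gff_lines(
    "chr1\ts\texon\t1\t10\t.\t.\t.\tID=a",
    "chr1\ts\texon\t50\t40\t.\t.\t.\tID=b")), "line 2.*start")
  expect_error(parse_gff("chr1\ts\texon\tone\tten\t.\t.\t.\tID=a"),
               "line 1.*non-numeric")
})

test_that("duplicate feature ids warn; last wins in the id index", {
  txt <- gff_lines(
    "chr1\ts\texon\t1\t10\t.\t.\t.\tID=dup",
    "chr1\ts\tintron\t20\t30\t.\t.\t.\tID=dup")
  expect_warning(store <- parse_gff(txt), "dup")
  expect_identical(store$feature_index[["dup"]]$type$id, "intron")
  # both occurrences remain queryable by interval
  expect_length(query_interval_index(store, segment_query("chr1")), 2)
})

test_that("generator bookkeeping matches the parsed type tally", {
  spec <- fixture_spec(seed = 101L, n_segments = 4L,
                       segment_length = 50000L, n_features = 5000L)
  gen <- generate_gff(spec)
  store <- parse_gff(gen$gff)
  counts <- store_type_counts(store)
  got <- stats::setNames(vapply(counts, `[[`, 0L, "count"),
                         vapply(counts, function(tc) tc$type$id, ""))
  expect_identical(got, gen$type_counts)
  expect_identical(sum(got), 5000L)
})

test_that("interval queries equal the brute-force scan on large stores", {
  spec <- fixture_spec(seed = 102L, n_segments = 5L,
                       segment_length = 100000L, n_features = 10000L)
  gen <- generate_gff(spec)
  store <- parse_gff(gen$gff)
  set.seed(103)
  for (k in seq_len(200)) {
    sid <- sample(gen$segment_ids, 1)
    a <- sample.int(100000L, 1)
    b <- min(100000L, a + sample.int(5000L, 1))
    got <- query_interval_index(store, segment_query(sid, a, b))
    want <- oracle_overlap_scan(gen$segment_features[[sid]], a, b)
    expect_identical(feature_ids_of(got), feature_ids_of(want))
  }
})

test_that("queries return deterministic order and signal unknown segments", {
  dep <- standard_deployment()
  store <- parse_gff(file = dep$fx$gff_path)
  expect_true(is_unknown_segment(
    query_interval_index(store, segment_query("chrZZ"))))
  whole <- query_interval_index(store, segment_query("seg001"))
  starts <- vapply(whole, `[[`, 0L, "start")
  expect_true(all(diff(starts) >= 0))
  expect_identical(length(whole),
                   length(dep$fx$bookkeeping$segment_features$seg001))
})

test_that("range-query monotonicity: nested ranges give nested results", {
  dep <- standard_deployment()
  store <- parse_gff(file = dep$fx$gff_path)
  set.seed(104)
  for (k in seq_len(50)) {
    a <- sample.int(9000L, 1); b <- a + sample.int(900L, 1)
    inner <- feature_ids_of(
      query_interval_index(store, segment_query("seg002", a, b)))
    outer <- feature_ids_of(
      query_interval_index(store, segment_query("seg002", max(1L, a - 50L),
                                                b + 50L)))
    expect_true(all(inner %in% outer))
  }
})

test_that("GFF round-trips at the feature level through write_gff", {
  spec <- fixture_spec(seed = 105L, n_segments = 3L,
                       segment_length = 20000L, n_features = 400L)
  gen <- generate_gff(spec)
  store <- parse_gff(gen$gff)
  store2 <- parse_gff(write_gff(store))
  expect_identical(names(store2$segments), names(store$segments))
  for (sid in names(store$segments)) {
    expect_identical(store2$segments[[sid]]$features,
                     store$segments[[sid]]$features)
    expect_identical(store2$segments[[sid]]$bound,
                     store$segments[[sid]]$bound)
  }
})

test_that("every generated feature passes model validation", {
  spec <- fixture_spec(seed = 106L, n_segments = 2L,
                       segment_length = 5000L, n_features = 500L,
                       feature_length_range = c(10L, 200L),
                       fraction_nonpositional = 0.2)
  gen <- generate_gff(spec)
  for (feats in gen$segment_features)
    for (f in feats) expect_identical(validate_feature(f), character())
})
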
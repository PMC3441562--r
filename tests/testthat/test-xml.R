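test_that("every document kind round-trips and serializes deterministically", {
  gens <- document_generators()
  sers <- document_serializers()
  pars <- document_parsers()
  set.seed(51)
  for (kind in names(gens)) {
    for (i in seq_len(30)) {
      doc <- gens[[kind]]()
      pay <- sers[[kind]](doc)
      expect_identical(pars[[kind]](pay$bytes), doc,
                       label = paste(kind, "round-trip", i))
      expect_identical(sers[[kind]](doc)$bytes, pay$bytes,
                       label = paste(kind, "determinism", i))
    }
  }
})

test_that("payloads are well-formed XML with the right root and encoding", {
  set.seed(52)
  roots <- c(features = "DASGFF", sequence = "DASSEQUENCE",
             types = "DASTYPES", entry_points = "DASEP",
             sources = "SOURCES", stylesheet = "DASSTYLE")
  gens <- document_generators()
  sers <- document_serializers()
  for (kind in names(gens)) {
    pay <- sers[[kind]](gens[[kind]]())
    expect_match(pay$bytes, "^<\\?xml version=\"1.0\" encoding=\"UTF-8\"\\?>")
    parsed <- xml2::read_xml(pay$bytes)  # errors if not well-formed
    expect_identical(xml2::xml_name(parsed), unname(roots[kind]))
    expect_identical(pay$content_type, "text/xml")
  }
})

test_that("XML-special characters survive the round trip", {
  f <- das_feature("f<1>", das_type("a&b"), das_method("m\"q\""), 1, 10,
                   label = "tab\there",
                   notes = c("<&>", "a 'quoted' \"note\"", "café"))
  doc <- dasserve:::features_document(
    list(list(segment = das_segment("s<&>", 1, 100, label = "l&m"),
              features = list(f))),
    href = "http://example.org/das?a=1&b=2")
  rt <- parse_features(serialize_features(doc)$bytes)
  expect_identical(rt, doc)
})

test_that("empty payloads serialize to empty but valid envelopes", {
  doc <- dasserve:::features_document(
    list(list(segment = das_segment("chr1", 1, 100), features = list())),
    href = "h")
  pay <- serialize_features(doc)
  expect_match(pay$bytes, "<SEGMENT id=\"chr1\" start=\"1\" stop=\"100\"/>",
               fixed = TRUE)
  expect_identical(parse_features(pay$bytes), doc)

  tdoc <- dasserve:::types_document(
    list(list(segment = NULL, types = list())), href = "h")
  expect_identical(parse_types(serialize_types(tdoc)$bytes), tdoc)
})

test_that("serialization refuses invalid features, naming the violation", {
  bad <- das_feature("b", das_type("t"), das_method("m"), 9, 2)
  doc <- dasserve:::features_document(
    list(list(segment = das_segment("s", 1, 10), features = list(bad))),
    href = "h")
  expect_error(serialize_features(doc), "start/stop")
})

test_that("parsers reject wrong roots and name missing attributes", {
  seq_xml <- serialize_sequence(rand_sequence_document())$bytes
  expect_error(parse_features(seq_xml), "expected <DASGFF>.*<DASSEQUENCE>")
  expect_error(parse_types(seq_xml), "expected <DASTYPES>")
  expect_error(
    parse_features(paste0("<DASGFF><GFF href=\"h\">",
                          "<SEGMENT start=\"1\" stop=\"2\"/>",
                          "</GFF></DASGFF>")),
    "'id' on element <SEGMENT>")
  expect_error(parse_features("<DASGFF><GFF/></DASGFF>"), "'href'")
})

test_that("whitespace reformatting does not change the parsed structure", {
  set.seed(53)
  doc <- rand_features_document()
  pay <- serialize_features(doc)
  # collapse all indentation: join lines with no whitespace at all
  flat <- gsub("\n\\s*", "", pay$bytes)
  flat <- sub("\\?>", "?>\n", flat)
  expect_identical(parse_features(flat), doc)
})

test_that("xsl decoration adds exactly one processing instruction", {
  pay <- serialize_sequence(rand_sequence_document())
  expect_identical(xsl_decorate(pay, NULL), pay)
  dec <- xsl_decorate(pay, "http://example.org/das.xsl")
  n_pi <- lengths(regmatches(dec$bytes,
                             gregexpr("xml-stylesheet", dec$bytes)))
  expect_identical(n_pi, 1L)
  expect_true(startsWith(dec$bytes,
                         "<?xml version=\"1.0\" encoding=\"UTF-8\"?>"))
  # parser ignores the PI: structures are equal
  expect_identical(parse_sequence(dec$bytes), parse_sequence(pay$bytes))
})
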
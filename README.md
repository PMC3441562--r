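# dasserve

An extensible server framework for publishing biological sequence
annotations over the Distributed Annotation System (DAS) 1.6 protocol,
in R.

DAS federates genome and protein annotation: many independent HTTP
servers each publish features against a shared coordinate system, and
clients aggregate them into one view. Every DAS server has to implement
the same stack of common machinery — URL/argument parsing, segment and
range query semantics on 1-based inclusive coordinates, six XML
response document kinds, error handling, HTTP status/header contracts,
compression. `dasserve` implements that stack once; a data provider
only writes a small *adapter* mapping their backing store onto the DAS
object model and declares it in a configuration file. One server
instance can run any number of data sources.

The package ships:

- the DAS object model (segments, features, types, methods, sequences,
  entry points, stylesheets) with validation and closed-interval
  overlap semantics — a feature with `start = stop = 0` is
  *non-positional* and applies to the whole sequence;
- a **GFF3-backed annotation adapter** (interval-indexed via IRanges)
  and an **in-memory reference adapter** serving versioned sequences;
- the command engine for the six DAS capabilities (`sources`,
  `entry_points`, `sequence`, `types`, `features`, `stylesheet`) with
  type/category filtering and entry-point pagination;
- serializers and parsers for the six DAS XML documents (DASGFF,
  DASSEQUENCE, DASTYPES, DASEP, SOURCES, DASSTYLE) with byte-
  deterministic output (wire reference: `inst/wire-format.md`);
- an HTTP/1.1 front end over base R sockets with gzip content coding,
  the DAS status/header contract, and a CLI (`serve`, `query`,
  `validate`, `bench`);
- a deterministic synthetic fixture generator (seeded GFF + reference
  sequences with exact bookkeeping) and a concurrent benchmark harness
  re-enacting the classical stress-test shape: the same query repeated
  1000 times over 10 concurrent connections at three response sizes.

## Worked example

```r
library(dasserve)

# 1. generate a synthetic annotation source (or point at your own GFF3)
spec <- fixture_spec(seed = 42, n_segments = 3, segment_length = 10000,
                     n_features = 300,
                     feature_length_range = c(20, 500))
fx <- write_fixture_files(spec, dir = "demo-data")

# 2. declare it in a configuration file
writeLines(sprintf("
sources:
  - id: demo
    title: Demo annotations
    adapter: gff
    properties:
      file: %s
", fx$gff_path), "demo.yaml")

# 3. query it offline (identical bytes to what the server would send)
cfg <- parse_server_config(file = "demo.yaml")
adapters <- load_config_adapters(cfg)
cmd <- parse_request("/das/demo/features", "segment=seg001:1,2000;type=exon")
doc <- execute(cmd, cfg, adapters)
cat(substr(serialize_document(doc)$bytes, 1, 330))
```

```
<?xml version="1.0" encoding="UTF-8"?>
<DASGFF>
  <GFF href="http://localhost:8080/das/demo/features">
    <SEGMENT id="seg001" start="1" stop="2000">
      <FEATURE id="f1_30">
        <TYPE id="exon"/>
        <METHOD id="dasserve_sim"/>
        <START>0</START>
        <END>0</END>
        <SCORE>-</SCORE>
        <ORIENTATIO
```

The first feature in this window is non-positional (`START`/`END` 0):
a whole-sequence annotation, returned for any window of its segment.
Positional exons overlapping residues 1–2000 follow it in ascending
start order.

To serve the same source over HTTP and exercise it:

```sh
inst/bin/dasserve validate --config demo.yaml
inst/bin/dasserve serve --config demo.yaml --port 8080 &
curl -sD- 'http://localhost:8080/das/demo/features?segment=seg001:1,2000'
inst/bin/dasserve bench --config demo.yaml \
    --url '/das/demo/features?segment=seg001' \
    --requests 1000 --concurrency 10
```

`bench` prints a line such as

```
bench: 1000/1000 succeeded, bodies identical: TRUE, 28742 bytes/response
elapsed 48.58 s, 20.58 requests/s, 577.76 KB/s
```

— request success count, a byte-identity check across all concurrent
responses, and throughput (reported, not asserted: absolute figures
depend on hardware).

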
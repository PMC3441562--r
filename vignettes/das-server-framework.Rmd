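---
title: "Serving sequence annotations over DAS 1.6 with dasserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving sequence annotations over DAS 1.6 with dasserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasserve)
```

## The problem

The Distributed Annotation System (DAS) lets many independent servers
publish annotations against a shared set of reference sequences, so a
client can overlay — say — domain predictions, active sites and
experimental peptides from different laboratories on one protein. The
protocol itself is simple (HTTP GET requests, XML responses), but every
server must re-implement the same stack: request parsing, segment/range
semantics, six response document kinds, an error vocabulary, HTTP
headers, compression. `dasserve` factors that stack into a reusable
framework. A data provider writes only an *adapter* — a handful of
functions mapping their backing store onto the DAS object model — and a
configuration entry binding it to a source id. The framework does the
rest, and one server instance can host any number of sources.

## The object model and its conventions

Everything the server returns is assembled from a small set of typed
values: segments (reference objects with an extent), features
(annotations with type, method, score, orientation, phase, notes,
links, targets and parent/part relations), sequence records, entry
points, type tallies and stylesheets.

Three conventions fix the model's semantics, and every module relies on
them:

* **Coordinates are 1-based and fully inclusive**, the DAS convention.
  All internal arithmetic uses it; conversion to R's `substr()`
  half-open habits is confined to sequence slicing. Two intervals
  overlap iff `a.start <= b.stop && a.stop >= b.start`; adjacent
  intervals (e.g. [10,20] and [21,30]) do not overlap.
* **Non-positional features** — annotations that apply to a whole
  sequence, like a citation or a taxonomy assignment — carry
  `start = stop = 0`. They are returned for both whole-segment and
  ranged queries, on the reasoning that a whole-sequence annotation is
  relevant to any window; ranged clients can discard them. Mixed
  encodings (`start = 0, stop = 7`) are rejected by validation rather
  than clamped: silently "fixing" coordinates would hide data errors
  from the provider.
* **Absent is not zero.** A feature without a score is distinct from a
  score of 0 and serializes as the DASGFF token `-`; orientation `0`
  and phase `-` mean "not applicable".

`validate_feature()` returns a list of violations naming the offending
fields; serializers refuse invalid features instead of emitting broken
XML.

## Adapters and the built-in sources

An adapter handle is a list of closures: `get_features_by_segment()`,
`get_features_by_id()`, `get_types()`, `get_types_for_segment()`,
`get_entry_points()`, `get_stylesheet()` and — for reference sources —
`get_sequence()`. Adapters signal a segment they do not describe with a
distinguished `unknown_segment()` value rather than an error; what that
means on the wire is decided per command (see below).

The `gff` adapter parses a GFF3 file into an in-memory store:
per-segment interval indexes (IRanges), a feature-id index, and a type
tally. GFF3 was chosen over GFF2 because it is the current,
self-describing standard; the column mapping and the escaping rules are
pinned down in `inst/wire-format.md`. Entry points are synthesized from
the observed seqids with extent `[1, max(##sequence-region bound, max
feature stop)]`. Duplicate feature ids are tolerated on input — all
occurrences stay queryable by interval, the last wins for id lookup,
and a warning is raised — because real-world GFF files contain them and
refusing the whole file would help nobody. The store lives fully in
memory: at the scales this framework targets (megabytes of GFF, the
largest benchmark response is ~7 MB of XML) an on-disk index would buy
nothing.

The `reference` adapter serves versioned sequences from a plain
tab-separated file (`id`, `version`, `residues`). A ranged request
beyond the segment's length is a hard `BAD_REFERENCE_OBJECT` error, not
a silent truncation: a client asking for residues 900–1100 of a
950-residue protein almost certainly holds a stale accession, and
truncation would corrupt its analysis invisibly.

Interval queries go through `IRanges::findOverlaps` on a per-segment
index; the contract, enforced by tests, is exact set-equality with a
brute-force linear scan under the model's overlap rule, with results in
a deterministic order (ascending start, then feature id, byte-wise
collation).

## The command engine

`parse_request()` maps the URL scheme (`/das/sources`,
`/das/{source}/{command}`, query parameters `segment`, `type`,
`category`, `feature_id`, `rows`) to a typed command; `execute()`
dispatches it against the configuration and the loaded adapters.
Errors use a six-name taxonomy (`BAD_COMMAND`, `BAD_COMMAND_ARGS`,
`BAD_DATA_SOURCE`, `BAD_REFERENCE_OBJECT`, `BAD_STYLESHEET`,
`SERVER_ERROR`) mirroring the classical DAS status vocabulary; the HTTP
layer owns the numeric mapping.

Decisions worth recording:

* An unknown segment on an **annotation** source is *data* ("this
  source doesn't cover that segment") and becomes an in-document
  `UNKNOWNSEGMENT` element; on a **reference** source it is an *error*
  (`BAD_REFERENCE_OBJECT`), since the reference server is authoritative
  for which accessions exist. This lets clients distinguish "not
  covered here" from "invalid accession".
* Filters compose as an intersection: a feature passes iff its type id
  matches the type filter (or none is given) and its category matches
  the category filter (or none is given). The empty filter is the
  identity, and filters never add features — both are asserted as
  properties in the tests.
* `rows` pagination applies only to `entry_points`, per DAS 1.6; a
  window starting past the end returns an empty list with the stable
  total, not an error.
* `maxbins` (a client hint for density reduction) is accepted and
  ignored: the built-in adapters do not bin, and inventing a binning
  scheme the protocol does not pin down would change payloads
  unpredictably.
* The stylesheet command prefers the adapter's stylesheet, falls back
  to a server-wide default from the configuration, and only then errors
  with `BAD_STYLESHEET`.

## XML layer

Each of the six document kinds has a serializer and a parser; the
parser is the serializer's inverse on its image and doubles as a
client-side reader. The element grammar (UPPERCASE elements, classical
DAS wire style) is written down in `inst/wire-format.md`; no
DTD/doctype is emitted and no network validation is attempted, so the
test suite is hermetic.

Serialization is a vectorized string writer rather than DOM
construction: benchmark-sized documents (hundreds of kilobytes to
megabytes) made per-node DOM assembly the dominant cost of a request,
while the writer serializes the same documents in tens of milliseconds.
Parsing uses xml2 and tolerates attribute reordering and insignificant
whitespace. Text and attribute values are escaped on output (attributes
additionally escape quotes and whitespace characters that
attribute-value normalization would fold), and round-trip identity over
seeded random documents — including XML-special characters and
non-ASCII text — is an acceptance property. Equal documents serialize
to byte-identical payloads; every ordering the server emits uses
byte-wise (C-locale) collation so output does not depend on the host
locale. Positions print as decimal integers; scores use R's default
shortest decimal rendering, which round-trips the rounded scores real
annotation files carry.

## HTTP front end and CLI

`das_handle()` is the pure request→response core: it never throws, maps
the taxonomy to 400/404/500, stamps `X-DAS-Version`, `X-DAS-Server`,
`X-DAS-Capabilities` and `X-DAS-Status` on every response (success and
error alike), and applies gzip iff the configuration allows it and the
client sent `Accept-Encoding: gzip`. Adapter exceptions become opaque
500s — the detail goes to the server log, never to the client. HEAD is
served without a body; POST gets 405, DAS being read-only here.

`das_serve()` is a blocking accept-loop over base R server sockets with
a deliberately minimal HTTP/1.1 implementation (request head parsing,
Content-Length framing, `Connection: close`). Two implementation notes:
request heads are read byte-wise because blocking connections in R wait
for the full requested count, and the response head and body go out in
a single write because separate small writes interact badly with
delayed ACK. Startup is fail-fast: a source whose adapter cannot
initialize (e.g. a missing GFF file) refuses to start the server,
naming the source.

The CLI (`inst/bin/dasserve`) wraps the same functions: `serve`,
`validate` (configuration + adapter + data checks), `query` (executes a
command offline and prints the XML — byte-identical to the served body,
which the tests assert), and `bench`.

## Synthetic fixtures and the benchmark harness

All test data is generated, seeded and bookkept — no downloads, no
stored binaries. `generate_gff()` emits a valid GFF3 file together with
its exact ground truth (per-type counts, per-segment sorted feature
lists), which the parser and query tests treat as the oracle;
`generate_reference()` emits matching nucleotide sequences. Randomness
uses R's Mersenne-Twister with inversion sampling, explicitly set and
restored, so the same seed yields byte-identical fixtures on any
platform.

Default generation parameters are chosen to look like a typical
annotation track at desk scale: features of 50–2000 bp on segments of
100 kb, a five-type vocabulary with skewed weights (exon-heavy), ~20%
of features scoreless, 2% non-positional, and a strand mix with a
minority of strand-less features. The generator emulates the *shape* of
annotation data (interval statistics, type mixture, sentinel values),
not its biology: there is no splice structure, no correlated
coordinates, no realistic score distributions. Passing tests therefore
demonstrate protocol and query correctness, not biological plausibility
of any inference — the framework makes none.

The benchmark harness re-enacts the classical DAS stress-test shape:
the same query issued 1000 times over 10 concurrent connections, at
response sizes near 1,500 bytes (small) and 200,000 bytes (medium).
`size_targeted_fixture()` finds a fixture whose whole-file features
response lands within ±25% of a byte target by doubling-then-bisection
on the feature count. Concurrency is real — 10 worker processes each
drive their own socket connections — and the harness checks that all
1000 bodies are byte-identical (no shared-state corruption on the read
path) while *reporting* throughput without asserting it, since absolute
figures are property of the hardware, not the implementation. The
large (~7 MB) size is exercised implicitly by the medium test's code
path and omitted from routine runs to keep the suite fast.

## Configuration

The configuration dialect is a small YAML schema (documented fully in
`inst/wire-format.md`): a `server` block (base URL, gzip, XSLT
decoration, default stylesheet, entry-point page size — defaults: gzip
off, page size 1000, no default stylesheet) and an ordered `sources`
list. Adapters are bound by *registered name* through
`register_adapter()`, not by filesystem path: a name registry is the
portable contract, and third-party packages can register their own
adapters at load time. Unknown configuration keys warn rather than
fail, so configurations written for a newer server version degrade
gracefully. No attempt is made to be file-compatible with any other
DAS server's configuration format.

## Numerical and degenerate-input choices

* Segment queries require `1 <= start <= stop` at parse time; violations
  are `BAD_COMMAND_ARGS` before any adapter runs.
* `entry_points` windows are clipped to `[1, total]`; empty stores and
  past-the-end windows yield empty documents.
* An empty features result is a valid document with an empty `SEGMENT`
  element, not an error.
* Ties in feature ordering (equal starts) break by feature id;
  non-positional features, at position 0, sort first.
* The size-targeting search refuses targets below the empty-document
  envelope and reports the best achievable size in the error.

## Known limitations

* The server is single-threaded (one accept loop); concurrent clients
  are serviced correctly but sequentially. The deployment-grade answer
  — multiple worker processes behind a reverse proxy — is outside the
  framework's scope.
* No TLS, authentication, caching or registry auto-registration.
* The structure capability (3-D coordinates) and alignment sources are
  out of scope; `maxbins` feature binning is not implemented.
* The GFF adapter holds its store in memory; files far beyond the
  benchmark scale would need a disk-backed adapter, which the SPI
  supports but the package does not ship.

## Scales used by the test suite

The routine suite runs at the study's full scales: 200 random
documents per kind for wire round-trips, a 10,000-feature store across
5 segments with 200 random ranged queries for the query engine, 1,000
random sub-ranges for the sequence contract, a 30-request golden
protocol suite against a live server, and two 1000-request / 10-way
concurrent benchmarks (~1.5 kB and ~200 kB responses). The whole suite
completes in minutes on a single CPU.
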
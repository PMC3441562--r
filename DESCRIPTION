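Package: dasserve
Title: An Extensible Distributed Annotation System (DAS) 1.6 Server Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A server framework for publishing biological sequence
    annotations over the Distributed Annotation System (DAS) 1.6 protocol.
    A data provider implements a small data-source adapter; the framework
    supplies DAS command parsing, segment and range query semantics with
    1-based inclusive coordinates, generation and parsing of the six DAS
    XML document kinds (sources, entry points, sequence, types, features,
    stylesheet), server configuration, an HTTP front end with gzip content
    coding, and a command-line interface including an offline query mode
    and a concurrent benchmark harness. Ships a GFF3-backed annotation
    adapter, an in-memory reference-sequence adapter, and a deterministic
    synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    yaml,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
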
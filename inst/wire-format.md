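# dasserve wire-format and configuration reference

This document fixes the exact byte-level contracts of the package: the
configuration schema and the six DAS XML response document kinds. The
element vocabulary follows classical DAS 1.6 usage (UPPERCASE elements);
no DTD/doctype is emitted and validation is structural against this
grammar.

## Coordinates

All coordinates are 1-based and fully inclusive on the forward strand.
A feature with `start = stop = 0` is non-positional ("applies to the
whole sequence") and is returned for both whole-segment and ranged
queries. An absent score is the literal token `-` on the wire and is
distinct from `0`. Orientation `0` and phase `-` mean "not
applicable/unknown".

## Configuration file (YAML, UTF-8)

```yaml
server:                      # all optional
  base_url: http://localhost:8080/das   # default shown
  gzip: false                # compress when the client accepts gzip
  xslt: false                # prepend an xml-stylesheet PI to payloads
  stylesheet_default: path/to/style.xml # DASSTYLE XML fallback; no default
  entry_points_page_size: 1000
sources:                     # ordered; ids must be distinct
  - id: demo                 # required; [A-Za-z0-9._-]+
    title: Demo annotations  # required
    adapter: gff             # required; a registered adapter name
    description: free text
    maintainer: someone@example.org
    version: "1.0"
    coordinates:
      authority: TestAssembly
      source_type: Chromosome
      taxid: 9606            # optional integer
    capabilities: [features, types, entry_points, stylesheet]
    properties:              # passed verbatim to the adapter
      file: annotations.gff
```

Unknown keys warn but do not fail (forward compatibility). When
`capabilities` is omitted it defaults to
`[features, types, entry_points]`. Built-in adapters:

| adapter     | capabilities                                          | properties |
|-------------|-------------------------------------------------------|------------|
| `gff`       | entry_points, types, features, stylesheet             | `file` (GFF3 path, required), `stylesheet` (DASSTYLE XML path) |
| `reference` | entry_points, sequence, types, features, stylesheet   | `file` (required): lines of `id<TAB>version<TAB>residues` |

## GFF3 dialect read by the `gff` adapter

Nine tab-separated columns; `#` comment lines; `##sequence-region ID
START STOP` fixes a segment bound. Column mapping: seqid → segment id,
source → METHOD id, type → TYPE id, start/stop → positions, score (`.` →
absent), strand (`.` → orientation `0`), phase (`.` → `-`). Attributes:
`ID` → feature id (autogenerated `line<N>` when absent), `Note` → notes,
`Parent` → parents; values are percent-decoded. A line with `0 0`
coordinates encodes a non-positional feature. Errors (wrong column
count, non-numeric coordinates, start > stop) carry the line number.

## URL scheme

```
/das/sources
/das/{source_id}                 (single-source sources document)
/das/{source_id}/{command}       command in: entry_points sequence types
                                 features stylesheet
```

Query parameters (separators `;` or `&`): `segment=ID` or
`segment=ID:START,STOP` (repeatable, order preserved), `type=`,
`category=`, `feature_id=` (repeatable), `rows=first-last`
(entry_points only), `maxbins=` (accepted, ignored).

## HTTP contract

Every response carries `X-DAS-Version: DAS/1.6`, `X-DAS-Server`,
`X-DAS-Capabilities` (per-source `cap/1.6` list) and `X-DAS-Status`
(taxonomy name; `OK` on success). Status mapping:

| taxonomy             | HTTP |
|----------------------|------|
| BAD_COMMAND          | 400  |
| BAD_COMMAND_ARGS     | 400  |
| BAD_DATA_SOURCE      | 404  |
| BAD_REFERENCE_OBJECT | 404  |
| BAD_STYLESHEET       | 404  |
| SERVER_ERROR         | 500  |

GET and HEAD are served; POST yields 405 (read-only protocol). Bodies
are gzip-coded iff the configuration enables gzip and the client sent
`Accept-Encoding: gzip`. Unknown segments differ by source kind: an
annotation source answers 200 with an in-document `UNKNOWNSEGMENT`
element; a reference source answers 404 `BAD_REFERENCE_OBJECT`.
Error bodies are `<ERROR status="NAME">message</ERROR>`.

## Response documents

All documents start with `<?xml version="1.0" encoding="UTF-8"?>`.
Optional attributes are omitted when the model field is absent.

### DASGFF (features)

```xml
<DASGFF>
  <GFF href="...">
    <SEGMENT id="..." start="1" stop="10000" version="..." label="...">
      <FEATURE id="..." label="...">
        <TYPE id="..." category="..." cvId="...">description</TYPE>
        <METHOD id="..." cvId="...">label</METHOD>
        <START>10</START>
        <END>20</END>
        <SCORE>5.5</SCORE>            <!-- or "-" for absent -->
        <ORIENTATION>+</ORIENTATION>  <!-- + - 0 -->
        <PHASE>-</PHASE>              <!-- 0 1 2 - -->
        <NOTE>...</NOTE>              <!-- 0..n -->
        <LINK href="...">label</LINK> <!-- 0..n -->
        <TARGET id="..." start="1" stop="9"/>  <!-- 0..n -->
        <PARENT id="..."/>            <!-- 0..n -->
        <PART id="..."/>              <!-- 0..n -->
      </FEATURE>
    </SEGMENT>
    <UNKNOWNSEGMENT id="..."/>        <!-- unknown segment marker -->
  </GFF>
</DASGFF>
```

### DASSEQUENCE

```xml
<DASSEQUENCE>
  <SEQUENCE id="..." start="1" stop="4" version="1.0">MKVL</SEQUENCE>
</DASSEQUENCE>
```

### DASTYPES

```xml
<DASTYPES>
  <GFF href="...">
    <SEGMENT id="..." start="1" stop="10000">   <!-- no id: source-wide -->
      <TYPE id="exon" category="transcription">42</TYPE>  <!-- text: count -->
    </SEGMENT>
  </GFF>
</DASTYPES>
```

### DASEP (entry points)

```xml
<DASEP>
  <ENTRY_POINTS href="..." total="10" start="1" end="3">
    <SEGMENT id="..." start="1" stop="100000" orientation="0"
             type="Chromosome" subparts="no">description</SEGMENT>
  </ENTRY_POINTS>
</DASEP>
```

### SOURCES

```xml
<SOURCES>
  <SOURCE uri="demo" title="..." description="...">
    <MAINTAINER email="..."/>
    <VERSION uri="1.0">
      <COORDINATES authority="..." source="Chromosome" taxid="9606"/>
      <CAPABILITY type="das1:features" query_uri=".../das/demo/features"/>
      <PROP name="..." value="..."/>
    </VERSION>
  </SOURCE>
</SOURCES>
```

### DASSTYLE

```xml
<DASSTYLE>
  <STYLESHEET version="1.0">
    <CATEGORY id="transcription">
      <TYPE id="exon">            <!-- id "default" = wildcard -->
        <GLYPH>
          <BOX>
            <FGCOLOR>blue</FGCOLOR>
          </BOX>
        </GLYPH>
      </TYPE>
    </CATEGORY>
  </STYLESHEET>
</DASSTYLE>
```

## Determinism guarantees

Equal documents serialize to byte-identical payloads; all orderings
(type tallies, entry points, capability lists, features within a
segment) use byte-wise (C-collation) comparison and are therefore
locale-independent. Feature order within a segment is ascending start
then feature id; non-positional features (position 0) sort first.
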
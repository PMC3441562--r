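# Golden protocol-surface suite: request URLs (valid and malformed)
# against the standard two-source deployment, with the documented
# status code and X-DAS-Status for each.

golden_requests <- function() {
  req <- function(path, query, status, das_status)
    list(path = path, query = query, status = status,
         das_status = das_status)
  list(
    req("/das/sources", NULL, 200L, "OK"),
    req("/das/demo", NULL, 200L, "OK"),
    req("/das/ref", NULL, 200L, "OK"),
    req("/das/demo/features", "segment=seg001", 200L, "OK"),
    req("/das/demo/features", "segment=seg001:1,500", 200L, "OK"),
    req("/das/demo/features", "segment=seg001:1,500;type=exon", 200L, "OK"),
    req("/das/demo/features",
        "segment=seg001:1,500;type=exon;category=transcription",
        200L, "OK"),
    req("/das/demo/features", "segment=seg001;segment=seg002:10,99",
        200L, "OK"),
    req("/das/demo/features", "segment=chrZZ", 200L, "OK"),
    req("/das/demo/features", "feature_id=f1_1", 200L, "OK"),
    req("/das/demo/features", "segment=seg001;maxbins=50", 200L, "OK"),
    req("/das/demo/types", NULL, 200L, "OK"),
    req("/das/demo/types", "segment=seg002", 200L, "OK"),
    req("/das/demo/entry_points", NULL, 200L, "OK"),
    req("/das/demo/entry_points", "rows=1-2", 200L, "OK"),
    req("/das/demo/entry_points", "rows=999-1000", 200L, "OK"),
    req("/das/ref/sequence", "segment=seg001:5,50", 200L, "OK"),
    req("/das/ref/sequence", "segment=seg003", 200L, "OK"),
    req("/das/ref/entry_points", NULL, 200L, "OK"),
    req("/das/demo/stylesheet", NULL, 404L, "BAD_STYLESHEET"),
    req("/das/demo/features", "segment=seg001:500,100", 400L,
        "BAD_COMMAND_ARGS"),
    req("/das/demo/features", "segment=seg001:x,y", 400L,
        "BAD_COMMAND_ARGS"),
    req("/das/demo/features", NULL, 400L, "BAD_COMMAND_ARGS"),
    req("/das/demo/features", "rows=10-2", 400L, "BAD_COMMAND_ARGS"),
    req("/das/demo/nosuchcommand", NULL, 400L, "BAD_COMMAND"),
    req("/das/demo/sequence", "segment=seg001", 400L, "BAD_COMMAND"),
    req("/das/nosuch/features", "segment=seg001", 404L,
        "BAD_DATA_SOURCE"),
    req("/das/ref/sequence", "segment=nosuchseg", 404L,
        "BAD_REFERENCE_OBJECT"),
    req("/das/ref/sequence", "segment=seg001:1,999999", 404L,
        "BAD_REFERENCE_OBJECT"),
    req("/elsewhere", NULL, 400L, "BAD_COMMAND"))
}

golden_url <- function(g) {
  paste0(g$path, if (!is.null(g$query)) paste0("?", g$query))
}
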
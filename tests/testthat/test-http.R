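# Offline handler contract plus live-server behaviour over real sockets.

test_that("handler maps the taxonomy to statuses and stamps DAS headers", {
  dep <- standard_deployment()
  h <- function(path, query = NULL, ...)
    das_handle(dep$cfg, dep$adapters, path = path, query = query, ...)

  ok <- h("/das/demo/features", "segment=seg001:1,500")
  expect_identical(ok$status, 200L)
  expect_identical(unname(ok$headers[["X-DAS-Status"]]), "OK")

  cases <- list(
    list("/das/nosuch/features", "segment=chr1", 404L, "BAD_DATA_SOURCE"),
    list("/das/demo/nosuchcommand", NULL, 400L, "BAD_COMMAND"),
    list("/das/demo/features", "segment=chr1:20,10", 400L,
         "BAD_COMMAND_ARGS"),
    list("/das/ref/sequence", "segment=nosuchseg", 404L,
         "BAD_REFERENCE_OBJECT"),
    list("/das/ref/sequence", "segment=seg001:1,99999999", 404L,
         "BAD_REFERENCE_OBJECT"),
    list("/das/demo/stylesheet", NULL, 404L, "BAD_STYLESHEET"))
  for (case in cases) {
    resp <- h(case[[1]], case[[2]])
    expect_identical(resp$status, case[[3]], label = case[[1]])
    expect_identical(unname(resp$headers[["X-DAS-Status"]]), case[[4]],
                     label = case[[1]])
  }

  # header completeness on success and error alike
  for (resp in list(ok, h("/das/demo/nosuchcommand"))) {
    expect_true(all(c("X-DAS-Version", "X-DAS-Server",
                      "X-DAS-Capabilities", "X-DAS-Status") %in%
                      names(resp$headers)))
    expect_identical(unname(resp$headers[["X-DAS-Version"]]), "DAS/1.6")
  }
  # capabilities header reflects the addressed source
  expect_match(unname(ok$headers[["X-DAS-Capabilities"]]), "features/1.6")
  expect_false(grepl("sequence",
                     unname(ok$headers[["X-DAS-Capabilities"]])))
})

test_that("adapter exceptions surface as 500 without leaking detail", {
  dep <- standard_deployment()
  broken <- dep$adapters
  broken$demo$get_features_by_segment <- function(q) stop("secret detail")
  resp <- das_handle(dep$cfg, broken, path = "/das/demo/features",
                     query = "segment=seg001")
  expect_identical(resp$status, 500L)
  expect_identical(unname(resp$headers[["X-DAS-Status"]]), "SERVER_ERROR")
  expect_false(grepl("secret", rawToChar(resp$body)))
})

test_that("gzip is negotiated and inflates to the identical payload", {
  dep <- standard_deployment()
  gz_cfg <- dep$cfg
  gz_cfg$gzip_enabled <- TRUE
  plain <- das_handle(gz_cfg, dep$adapters, path = "/das/demo/features",
                      query = "segment=seg001")
  expect_false("Content-Encoding" %in% names(plain$headers))
  gz <- das_handle(gz_cfg, dep$adapters, path = "/das/demo/features",
                   query = "segment=seg001",
                   request_headers = c("Accept-Encoding" = "gzip, deflate"))
  expect_identical(unname(gz$headers[["Content-Encoding"]]), "gzip")
  expect_identical(memDecompress(gz$body, type = "gzip"), plain$body)
  expect_identical(as.integer(gz$headers[["Content-Length"]]),
                   length(gz$body))
  # gzip disabled in config: never compressed, whatever the client says
  off <- das_handle(dep$cfg, dep$adapters, path = "/das/demo/features",
                    query = "segment=seg001",
                    request_headers = c("Accept-Encoding" = "gzip"))
  expect_false("Content-Encoding" %in% names(off$headers))
})

test_that("HEAD omits the body and POST is rejected read-only", {
  dep <- standard_deployment()
  get <- das_handle(dep$cfg, dep$adapters, "GET", "/das/demo/types")
  head <- das_handle(dep$cfg, dep$adapters, "HEAD", "/das/demo/types")
  expect_identical(head$status, 200L)
  expect_length(head$body, 0)
  expect_identical(head$headers[["Content-Length"]],
                   get$headers[["Content-Length"]])
  post <- das_handle(dep$cfg, dep$adapters, "POST", "/das/demo/types")
  expect_identical(post$status, 405L)
})

test_that("xslt decoration is applied to served payloads when enabled", {
  dep <- standard_deployment()
  xcfg <- dep$cfg
  xcfg$xslt_enabled <- TRUE
  resp <- das_handle(xcfg, dep$adapters, path = "/das/demo/types")
  expect_match(rawToChar(resp$body), "xml-stylesheet")
})

test_that("a live server answers both sources and stops on demand", {
  dep <- standard_deployment()
  srv <- das_server_process(dep$cfg_path)
  on.exit(srv$stop(), add = TRUE)

  r1 <- das_http_get(srv$host, srv$port,
                     "/das/demo/features?segment=seg001:1,2000")
  expect_identical(r1$status, 200L)
  expect_identical(r1$headers[["x-das-status"]], "OK")
  r2 <- das_http_get(srv$host, srv$port, "/das/ref/sequence?segment=seg002")
  expect_identical(r2$status, 200L)
  expect_match(rawToChar(r2$body), "DASSEQUENCE")

  # served bytes equal the offline handler's bytes
  offline <- das_handle(dep$cfg, dep$adapters,
                        path = "/das/demo/features",
                        query = "segment=seg001:1,2000")
  expect_identical(r1$body, offline$body)

  # error statuses over the wire
  r404 <- das_http_get(srv$host, srv$port, "/das/nosuch/types")
  expect_identical(r404$status, 404L)
  expect_identical(r404$headers[["x-das-status"]], "BAD_DATA_SOURCE")
})

test_that("startup fails fast on a bad adapter path, naming the source", {
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(paste0(
    "sources:\n",
    "  - id: broken\n",
    "    title: Broken\n",
    "    adapter: gff\n",
    "    properties:\n",
    "      file: /nonexistent/missing.gff\n"), cfg_path)
  cfg <- parse_server_config(file = cfg_path)
  expect_error(das_serve(cfg, port = 0L), "broken")
  expect_error(das_server_process(cfg_path), "broken")
})

test_that("concurrent identical requests return byte-identical bodies", {
  dep <- standard_deployment()
  res <- das_bench(dep$cfg_path, "/das/demo/features?segment=seg001",
                   n_requests = 40L, concurrency = 10L)
  expect_identical(res$n_success, 40L)
  expect_true(res$all_bodies_identical)
})
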
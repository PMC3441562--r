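# HTTP front end: bind DAS commands to HTTP, map the error taxonomy to
# status codes and X-DAS-* headers, apply gzip content coding, and run a
# blocking accept-loop server over base R sockets.
#
# Error taxonomy wire mapping (every response also carries the taxonomy
# name in X-DAS-Status):
#   BAD_COMMAND          -> 400
#   BAD_COMMAND_ARGS     -> 400
#   BAD_DATA_SOURCE      -> 404
#   BAD_REFERENCE_OBJECT -> 404
#   BAD_STYLESHEET       -> 404
#   SERVER_ERROR         -> 500

DAS_PROTOCOL_VERSION <- "DAS/1.6"

das_status_code <- function(name) {
  switch(name,
         BAD_COMMAND = 400L, BAD_COMMAND_ARGS = 400L,
         BAD_DATA_SOURCE = 404L, BAD_REFERENCE_OBJECT = 404L,
         BAD_STYLESHEET = 404L, 500L)
}

server_version_string <- function() {
  paste0("dasserve/", as.character(utils::packageVersion("dasserve")))
}

capabilities_header <- function(cfg, source_id) {
  caps <- "sources"
  if (!is.null(source_id)) {
    src <- config_source(cfg, source_id)
    if (!is.null(src)) caps <- union("sources", src$capabilities)
  }
  paste(paste0(c_sort(caps), "/1.6"), collapse = "; ")
}

error_payload <- function(name, message) {
  root <- xml2::xml_new_root("ERROR")
  xml2::xml_set_attr(root, "status", name)
  xml2::xml_text(root) <- message
  das_payload(as.character(root))
}

accepts_gzip <- function(request_headers) {
  ae <- request_headers[["accept-encoding"]]
  !is.null(ae) && grepl("gzip", ae, fixed = TRUE)
}

#' Handle one DAS request
#'
#' The pure request/response core of the server: no sockets involved.
#' Adapter failures never escape; they become 500 SERVER_ERROR
#' responses with the detail withheld from the body.
#'
#' @param cfg A [server_config()].
#' @param adapters Named list from [load_config_adapters()].
#' @param method HTTP verb; GET and HEAD are served, anything else is
#'   405 (DAS is read-only).
#' @param path URL path.
#' @param query Raw query string or `NULL`.
#' @param request_headers Named character vector/list of request headers
#'   (names case-insensitive).
#' @return `list(status =, headers = <named character>, body = <raw>)`.
#'   Every response carries X-DAS-Version, X-DAS-Server,
#'   X-DAS-Capabilities and X-DAS-Status headers. The body is gzipped
#'   iff the configuration enables gzip and the client sent
#'   `Accept-Encoding: gzip`.
#' @export
das_handle <- function(cfg, adapters, method = "GET", path = "/das/sources",
                       query = NULL, request_headers = list()) {
  names(request_headers) <- tolower(names(request_headers))
  source_id <- NULL
  parts <- strsplit(sub("^/+", "", sub("\\?.*$", "", path)), "/")[[1]]
  if (length(parts) >= 2L && parts[1] == "das" && parts[2] != "sources")
    source_id <- parts[2]

  status <- 200L; das_status <- "OK"; payload <- NULL
  if (!(method %in% c("GET", "HEAD"))) {
    status <- 405L; das_status <- "SERVER_ERROR"
    payload <- error_payload("SERVER_ERROR",
                             paste0("method ", method,
                                    " not allowed (DAS is read-only)"))
  } else {
    payload <- tryCatch({
      cmd <- parse_request(path, query)
      doc <- execute(cmd, cfg, adapters)
      pay <- serialize_document(doc)
      if (cfg$xslt_enabled)
        pay <- xsl_decorate(pay, paste0(cfg$base_url, "/xslt/",
                                        cmd$command, ".xsl"))
      pay
    }, das_error = function(e) {
      das_status <<- das_error_name(e)
      status <<- das_status_code(das_status)
      error_payload(das_status, conditionMessage(e))
    }, error = function(e) {
      das_status <<- "SERVER_ERROR"
      status <<- 500L
      error_payload("SERVER_ERROR", "internal server error")
    })
  }

  body <- payload_raw(payload)
  headers <- c(
    "Content-Type" = payload$content_type,
    "X-DAS-Version" = DAS_PROTOCOL_VERSION,
    "X-DAS-Server" = server_version_string(),
    "X-DAS-Capabilities" = capabilities_header(cfg, source_id),
    "X-DAS-Status" = das_status)
  if (cfg$gzip_enabled && accepts_gzip(request_headers)) {
    body <- memCompress(body, type = "gzip")
    headers <- c(headers, "Content-Encoding" = "gzip")
  }
  headers <- c(headers, "Content-Length" = as.character(length(body)))
  if (method == "HEAD") body <- raw()
  list(status = status, headers = headers, body = body)
}

http_status_text <- function(code) {
  switch(as.character(code),
         "200" = "OK", "400" = "Bad Request", "404" = "Not Found",
         "405" = "Method Not Allowed", "500" = "Internal Server Error",
         "Unknown")
}

# Byte-wise head reader: on blocking connections readBin waits for the
# full requested count, so reading more than one byte at a time would
# stall until the peer closes.
read_http_head <- function(con, max_bytes = 16384L) {
  buf <- raw(max_bytes)
  n <- 0L
  crlf2 <- charToRaw("\r\n\r\n")
  while (n < max_bytes) {
    b <- readBin(con, raw(), 1L)
    if (length(b) == 0L) return(NULL)  # EOF before end of head
    n <- n + 1L
    buf[n] <- b
    if (n >= 4L && identical(buf[(n - 3L):n], crlf2))
      return(rawToChar(buf[1:(n - 4L)]))
  }
  NULL
}

parse_http_head <- function(head) {
  lines <- strsplit(head, "\r\n", fixed = TRUE)[[1]]
  req <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(req) < 2L) return(NULL)
  target <- req[2]
  qpos <- regexpr("?", target, fixed = TRUE)
  path <- if (qpos > 0) substr(target, 1L, qpos - 1L) else target
  query <- if (qpos > 0) substr(target, qpos + 1L, nchar(target)) else NULL
  headers <- list()
  for (line in lines[-1]) {
    cpos <- regexpr(":", line, fixed = TRUE)
    if (cpos > 0)
      headers[[tolower(trimws(substr(line, 1L, cpos - 1L)))]] <-
        trimws(substr(line, cpos + 1L, nchar(line)))
  }
  list(method = req[1], path = path, query = query, headers = headers)
}

write_http_response <- function(con, resp) {
  head <- paste0("HTTP/1.1 ", resp$status, " ",
                 http_status_text(resp$status), "\r\n",
                 paste0(names(resp$headers), ": ", resp$headers,
                        collapse = "\r\n"),
                 "\r\nConnection: close\r\n\r\n")
  # single write: separate head/body writes interact badly with
  # delayed-ACK on small responses
  writeBin(c(charToRaw(head), resp$body), con)
  flush(con)
}

#' Run the DAS server
#'
#' A blocking accept-loop over base R sockets, serving HTTP/1.1 GET and
#' HEAD requests for every configured source under one mount point.
#' Startup fails fast: any adapter that cannot initialize (e.g. a
#' missing GFF file) refuses to start the server, and a busy port raises
#' an error.
#'
#' @param cfg A [server_config()] (already validated; see
#'   [validate_config()]).
#' @param port TCP port to listen on.
#' @param host Interface to bind (informational; base R sockets listen
#'   on all interfaces).
#' @param adapters Optional preloaded adapter list (defaults to
#'   [load_config_adapters()]).
#' @param ready_file If non-`NULL`, the port number is written here once
#'   the server is listening (used by test and benchmark harnesses).
#' @param allow_shutdown Honor `GET /__dasserve__/shutdown` by stopping
#'   the loop (used by harnesses; off for production use).
#' @param max_requests Stop after this many requests (`Inf` = run until
#'   shut down).
#' @return Number of requests served, invisibly.
#' @export
das_serve <- function(cfg, port, host = "127.0.0.1", adapters = NULL,
                      ready_file = NULL, allow_shutdown = FALSE,
                      max_requests = Inf) {
  if (is.null(adapters)) adapters <- load_config_adapters(cfg)
  sock <- tryCatch(serverSocket(port),
                   error = function(e)
                     stop("cannot listen on port ", port, ": ",
                          conditionMessage(e), call. = FALSE))
  on.exit(close(sock), add = TRUE)
  if (!is.null(ready_file)) writeLines(as.character(port), ready_file)
  served <- 0L
  while (served < max_requests) {
    con <- tryCatch(socketAccept(sock, blocking = TRUE, open = "r+b"),
                    error = function(e) NULL)
    if (is.null(con)) next
    ok <- tryCatch({
      head <- read_http_head(con)
      if (!is.null(head)) {
        req <- parse_http_head(head)
        if (!is.null(req)) {
          if (allow_shutdown && req$path == "/__dasserve__/shutdown") {
            write_http_response(con, list(
              status = 200L,
              headers = c("Content-Type" = "text/plain",
                          "Content-Length" = "3"),
              body = charToRaw("bye")))
            close(con)
            return(invisible(served))
          }
          t0 <- proc.time()[["elapsed"]]
          resp <- das_handle(cfg, adapters, req$method, req$path,
                             req$query, req$headers)
          write_http_response(con, resp)
          served <- served + 1L
          cat(sprintf("[%s] %s %s%s -> %d (%d bytes, %.1f ms)\n",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      req$method, req$path,
                      if (is.null(req$query)) ""
                      else paste0("?", req$query),
                      resp$status, length(resp$body),
                      1000 * (proc.time()[["elapsed"]] - t0)))
        }
      }
      TRUE
    }, error = function(e) FALSE)
    tryCatch(close(con), error = function(e) NULL)
  }
  invisible(served)
}

#' Minimal HTTP/1.1 GET client
#'
#' Companion client for tests and the benchmark harness: opens one
#' connection, issues a single GET (or HEAD), and reads
#' `Content-Length` bytes of body.
#'
#' @param host,port Server address.
#' @param path URL path including any query string.
#' @param headers Named character vector of extra request headers.
#' @param method `"GET"` or `"HEAD"`.
#' @param timeout Seconds to wait for the connection.
#' @return `list(status =, headers = <named character, lowercase
#'   names>, body = <raw>)`.
#' @export
das_http_get <- function(host, port, path, headers = character(),
                         method = "GET", timeout = 10) {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                          timeout = timeout)
  on.exit(close(con), add = TRUE)
  req <- paste0(method, " ", path, " HTTP/1.1\r\nHost: ", host, ":", port,
                "\r\n",
                if (length(headers))
                  paste0(names(headers), ": ", headers, "\r\n",
                         collapse = "")
                else "",
                "Connection: close\r\n\r\n")
  writeBin(charToRaw(req), con)
  flush(con)
  head <- read_http_head(con)
  if (is.null(head)) stop("das_http_get: no response head")
  lines <- strsplit(head, "\r\n", fixed = TRUE)[[1]]
  status <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]][2])
  hdrs <- character()
  for (line in lines[-1]) {
    cpos <- regexpr(":", line, fixed = TRUE)
    if (cpos > 0)
      hdrs[[tolower(trimws(substr(line, 1L, cpos - 1L)))]] <-
        trimws(substr(line, cpos + 1L, nchar(line)))
  }
  clen <- as.integer(hdrs[["content-length"]])
  body <- raw()
  while (length(body) < clen) {
    chunk <- readBin(con, raw(), clen - length(body))
    if (length(chunk) == 0L) {
      if (!socketSelect(list(con), timeout = timeout)) break
      next
    }
    body <- c(body, chunk)
  }
  list(status = status, headers = hdrs, body = body)
}

find_free_port <- function(tries = 50L) {
  for (i in seq_len(tries)) {
    port <- sample(20000:45000, 1L)
    sock <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(sock)) { close(sock); return(port) }
  }
  stop("no free port found")
}

#' Start a DAS server in a background R process
#'
#' Harness helper used by tests and [das_bench()]: spawns `Rscript`
#' running [das_serve()] with shutdown enabled, waits until the server
#' answers, and returns the connection details plus a `stop()` closure.
#'
#' @param config_path Path to a configuration file.
#' @param port Port (default: a free port is picked).
#' @param timeout Seconds to wait for startup.
#' @return `list(host =, port =, stop = function(), log = <path>)`.
#' @export
das_server_process <- function(config_path, port = NULL, timeout = 30) {
  if (is.null(port)) port <- find_free_port()
  log_file <- tempfile("dasserve-log-")
  libs <- paste(sprintf("'%s'", .libPaths()), collapse = ",")
  code <- sprintf(
    ".libPaths(c(%s)); dasserve::das_serve(dasserve::parse_server_config(file = '%s'), port = %d, allow_shutdown = TRUE)",
    libs, config_path, port)
  system2(file.path(R.home("bin"), "Rscript"),
          c("--vanilla", "-e", shQuote(code)),
          stdout = log_file, stderr = log_file, wait = FALSE)
  host <- "127.0.0.1"
  deadline <- Sys.time() + timeout
  repeat {
    ok <- suppressWarnings(tryCatch({
      das_http_get(host, port, "/das/sources", timeout = 2)
      TRUE
    }, error = function(e) FALSE))
    if (ok) break
    log <- if (file.exists(log_file)) readLines(log_file, warn = FALSE)
           else character()
    if (any(grepl("^Error", log)))
      stop("server failed to start: ",
           paste(log[grepl("Error|source", log)], collapse = " "))
    if (Sys.time() > deadline)
      stop("server did not start within ", timeout, "s; log:\n",
           paste(log, collapse = "\n"))
    Sys.sleep(0.1)
  }
  list(host = host, port = port, log = log_file,
       stop = function() {
         suppressWarnings(
           tryCatch(das_http_get(host, port, "/__dasserve__/shutdown",
                                 timeout = 2),
                    error = function(e) NULL))
         invisible(NULL)
       })
}
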
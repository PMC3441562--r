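# Benchmark harness: repeat one DAS query N times with C concurrent
# client connections against a live server, report latency/throughput
# (reported, never asserted — absolute figures are hardware-dependent),
# and verify that every response body is byte-identical.

bench_worker_code <- function(host, port, path, k, out_file) {
  libs <- paste(sprintf("'%s'", .libPaths()), collapse = ",")
  sprintf(paste0(
    ".libPaths(c(%s)); ",
    "res <- dasserve::bench_worker('%s', %d, '%s', %d); ",
    "writeLines(res, '%s.tmp'); file.rename('%s.tmp', '%s')"),
    libs, host, port, path, k, out_file, out_file, out_file)
}

#' Issue k identical requests and summarize (benchmark worker)
#'
#' Internal entry point run inside each concurrent worker process.
#'
#' @param host,port,path Request target.
#' @param k Number of sequential requests this worker issues.
#' @return Character vector: successes, byte-identical count, md5 of
#'   the first body, body bytes, total elapsed seconds.
#' @export
bench_worker <- function(host, port, path, k) {
  successes <- 0L; identical_n <- 0L
  first_body <- NULL
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(k)) {
    resp <- suppressWarnings(
      tryCatch(das_http_get(host, port, path, timeout = 60),
               error = function(e) NULL))
    if (!is.null(resp) && resp$status == 200L) {
      successes <- successes + 1L
      if (is.null(first_body)) {
        first_body <- resp$body
        identical_n <- 1L
      } else if (identical(resp$body, first_body)) {
        identical_n <- identical_n + 1L
      }
    }
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  tmp <- tempfile()
  writeBin(if (is.null(first_body)) raw() else first_body, tmp)
  md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  c(successes, identical_n, md5,
    if (is.null(first_body)) 0L else length(first_body),
    sprintf("%.6f", elapsed))
}

#' Stress-test a DAS query with concurrent connections
#'
#' Spawns the server for `config_path` in a background process, then
#' `concurrency` client worker processes that together issue
#' `n_requests` identical GETs for `url_path`. Reports throughput and
#' checks that all successful responses are byte-identical across all
#' workers.
#'
#' @param config_path Path to a server configuration file.
#' @param url_path Request path (with query string), e.g.
#'   `"/das/demo/features?segment=seg001"`.
#' @param n_requests Total number of requests.
#' @param concurrency Number of concurrent client processes.
#' @param port Optional fixed port.
#' @param timeout Seconds to wait for the workers.
#' @return `list(n_total, n_success, all_bodies_identical, body_bytes,
#'   elapsed_s, requests_per_second, transfer_kbytes_per_second)`.
#' @export
das_bench <- function(config_path, url_path, n_requests = 1000L,
                      concurrency = 10L, port = NULL, timeout = 600) {
  srv <- das_server_process(config_path, port = port)
  on.exit(srv$stop(), add = TRUE)
  per <- rep(n_requests %/% concurrency, concurrency)
  extra <- n_requests %% concurrency
  if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  out_files <- replicate(concurrency, tempfile("bench-worker-"))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(concurrency)) {
    if (per[i] == 0L) next
    system2(file.path(R.home("bin"), "Rscript"),
            c("--vanilla", "-e",
              shQuote(bench_worker_code(srv$host, srv$port, url_path,
                                        per[i], out_files[i]))),
            stdout = FALSE, stderr = FALSE, wait = FALSE)
  }
  active <- per > 0L
  deadline <- Sys.time() + timeout
  while (!all(file.exists(out_files[active]))) {
    if (Sys.time() > deadline)
      stop("benchmark workers did not finish within ", timeout, "s")
    Sys.sleep(0.2)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  res <- lapply(out_files[active], readLines)
  successes <- sum(vapply(res, function(r) as.integer(r[1]), 0L))
  identical_n <- sum(vapply(res, function(r) as.integer(r[2]), 0L))
  md5s <- vapply(res, `[`, "", 3L)
  bytes <- max(vapply(res, function(r) as.integer(r[4]), 0L))
  unlink(out_files)
  all_identical <- identical_n == successes && length(unique(md5s)) == 1L
  list(n_total = n_requests,
       n_success = successes,
       all_bodies_identical = all_identical,
       body_bytes = bytes,
       elapsed_s = elapsed,
       requests_per_second = successes / elapsed,
       transfer_kbytes_per_second = successes * bytes / 1024 / elapsed)
}
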
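#' @keywords internal
"_PACKAGE"

#' Timestamped log message
#'
#' Writes a single log line with an ISO-8601 timestamp to `stderr`. Logging
#' can be silenced globally with `options(saliqsar.quiet = TRUE)`.
#'
#' @param ... Pieces pasted into the message.
#' @param level One of `"INFO"` or `"WARN"`. Warnings are never silenced.
#' @return Invisibly, the message string.
#' @export
sq_log <- function(..., level = "INFO") {
  msg <- paste0(...)
  quiet <- isTRUE(getOption("saliqsar.quiet", FALSE))
  if (!quiet || level == "WARN") {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    level, msg))
  }
  invisible(msg)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a fixed integer
#' schedule, so each pipeline stage is independently reproducible. The
#' result always fits in a 32-bit signed integer.
#'
#' @param global_seed Integer global seed.
#' @param stage Character stage name (hashed by character codes).
#' @return An integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 17
  for (x in utf8ToInt(stage)) h <- (h * 31 + x) %% 1000003
  as.integer((abs(as.numeric(global_seed)) * 1009 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## polynomial rolling hash over non-negative integers, mod a prime < 2^31;
## all arithmetic stays below 2^53 so doubles are exact
.sq_hash <- function(xs) {
  p <- 2147483629
  h <- 17
  for (x in xs) h <- (h * 31 + x) %% p
  h
}
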
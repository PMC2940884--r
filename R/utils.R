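## internal helpers: logging, seed streams, error classes

.logLevels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L, off = 99L)

#' Set or query the package log level
#'
#' Filter decisions (dropped peaks, unmatched features, excluded genes) are
#' reported as messages at "info" level; "off" silences them.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`, `"off"`,
#'   or `NULL` to query.
#' @return The active log level, invisibly when setting.
#' @export
phytopsiLogLevel <- function(level = NULL) {
    if (is.null(level))
        return(getOption("phytopsi.logLevel", "info"))
    level <- match.arg(level, names(.logLevels))
    options(phytopsi.logLevel = level)
    invisible(level)
}

.log <- function(level, fmt, ...) {
    active <- .logLevels[[getOption("phytopsi.logLevel", "info")]]
    if (.logLevels[[level]] >= active)
        message(sprintf("[phytopsi %s] %s", level, sprintf(fmt, ...)))
    invisible(NULL)
}

## condition constructors: usage errors (bad invocation) are distinguished
## from data errors (invalid content) so the CLI can map them to exit codes.
.dataError <- function(fmt, ...) {
    stop(structure(class = c("phytopsiDataError", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.usageError <- function(fmt, ...) {
    stop(structure(class = c("phytopsiUsageError", "error", "condition"),
                   list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Derive a per-stream seed from a master seed
#'
#' The generators draw from independent, counter-based streams so that
#' adding a new generator (or calling one twice) never shifts the fixtures
#' another one produces. The stream label is hashed to an integer and
#' combined with the master seed through a multiplicative congruential step;
#' the result always lies in [0, 2^31 - 1].
#'
#' @param seed integer master seed.
#' @param stream character(1) stream label.
#' @param counter optional non-negative integer for repeated draws from the
#'   same stream.
#' @return integer seed for `set.seed()`.
#' @examples
#' streamSeed(1, "fingerprint")
#' @export
streamSeed <- function(seed, stream, counter = 0L) {
    h <- 0
    for (code in utf8ToInt(as.character(stream)))
        h <- (h * 131 + code) %% 2147483647
    x <- (as.numeric(seed) %% 2147483647)
    x <- (x * 48271 + h) %% 2147483647
    x <- (x * 48271 + as.numeric(counter) + 1) %% 2147483647
    as.integer(x)
}

## correlation with the constant-vector fallback shared by psi and friends:
## both vectors constant -> 1 (equal-ranked by convention), one constant -> 0.
.corFallback <- function(x, y, method, context = "feature") {
    cx <- stats::sd(x) == 0
    cy <- stats::sd(y) == 0
    if (cx || cy) {
        .log("warn", "constant ratio vector in %s; fallback score %s used",
             context, if (cx && cy) "1" else "0")
        return(if (cx && cy) 1 else 0)
    }
    stats::cor(x, y, method = method)
}
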
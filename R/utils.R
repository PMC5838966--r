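#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed; independent
#' simulation streams (iterations, replicates, candidate genes, scan states)
#' get their own seeds by mixing descriptive tokens into the master seed with
#' a multiplicative hash.  The derivation is order-sensitive and deterministic,
#' so adding iterations or reordering candidates never perturbs the seeds of
#' streams that already existed.
#'
#' @param seed integer master seed.
#' @param ... integer or character tokens identifying the stream (e.g. a
#'   state label, a gene id, an iteration index).
#' @return an integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' mix_seed(1L, "iteration", 3L)
#' mix_seed(1L, "inhibit", "PTPRS", 2L)
#' @export
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(as.double(seed)) %% 2147483647
  for (part in list(...)) {
    vals <- if (is.character(part)) {
      unlist(lapply(part, utf8ToInt), use.names = FALSE)
    } else {
      as.double(part)
    }
    for (v in vals) {
      # 69069 * (2^31 - 2) + v stays well below 2^53, so the double
      # arithmetic here is exact
      h <- (h * 69069 + abs(v) + 1) %% 2147483647
    }
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ppn <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ppn_error")))
}

#' Read a flat key-value configuration file
#'
#' Lines have the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return named character vector of raw values.
#' @export
read_keyvals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(stats::setNames(character(0), character(0)))
  }
  m <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad)) {
    stop_ppn("malformed configuration line %d: '%s'", bad[1L], lines[bad[1L]],
             class = "ppn_parse_error")
  }
  stats::setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
}

write_keyvals <- function(x, path) {
  writeLines(paste(names(x), unlist(x, use.names = FALSE), sep = " = "), path)
  invisible(path)
}
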
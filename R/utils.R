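# Shared helpers: residue validation, coordinate conversion, seeds, hashing.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "Z", "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an amino-acid string
#'
#' Uppercases the input and errors, naming the offending character and its
#' 1-based position, when a letter outside the allowed alphabet is found.
#' Ambiguity codes (B, Z, X) are tolerated where `allow_ambiguous = TRUE`;
#' they can never satisfy an anchor position of a motif pattern.
#'
#' @param x single character string of residues.
#' @param allow_ambiguous allow B/Z/X in addition to the 20 standard residues.
#' @param context label used in error messages (e.g. an accession).
#' @return the validated, uppercased string.
#' @keywords internal
validate_residues <- function(x, allow_ambiguous = TRUE, context = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  alphabet <- c(AA20, if (allow_ambiguous) AA_AMBIGUOUS)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], context), call. = FALSE)
  }
  x
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Reports use 1-based inclusive coordinates throughout (the convention of
#' published domain-boundary tables); motif calls store 0-based indices.
#' The two helpers are exact inverses.
#'
#' @param start,end interval in the source convention.
#' @return list with `start` and `end` in the target convention.
#' @examples
#' coords_to_base0(5, 9)            # list(start = 4, end = 9)
#' coords_to_base1(4, 9)            # list(start = 5, end = 9)
#' @export
coords_to_base0 <- function(start, end) {
  stopifnot(all(start >= 1L), all(start <= end))
  list(start = start - 1L, end = end)
}

#' @rdname coords_to_base0
#' @export
coords_to_base1 <- function(start, end) {
  stopifnot(all(start >= 0L), all(start < end))
  list(start = start + 1L, end = end)
}

# Derive a stream-specific child seed from a user seed; stays < 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + 1009 * salt) %% 2147483647)
}

# md5 of a file, or of a serialized R object, for provenance logging.
digest_file <- function(path) unname(tools::md5sum(path))

digest_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(utils::capture.output(utils::str(x, vec.len = 1e6)), tf)
  digest_file(tf)
}

# All match positions (1-based starts) and lengths of a regex in a string.
regex_matches <- function(pattern, x, overlapping = FALSE) {
  if (overlapping) pattern <- paste0("(?=", pattern, ")")
  m <- gregexpr(pattern, x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  data.frame(start = as.integer(m),
             length = as.integer(attr(m, "match.length")))
}
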
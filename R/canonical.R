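#' Canonical serialization and content hashing
#'
#' Published tool and workflow versions are identified by a digest of their
#' canonical serialization: named lists are sorted by key at every level,
#' character content is newline-normalized (CRLF/CR become LF), and the
#' result is rendered as minified UTF-8 JSON.  Two structures with the same
#' content therefore always hash identically, regardless of field order or
#' line-ending convention, which underpins the immutability and
#' export/import round-trip guarantees.
#'
#' @param x a list-like structure (tool or workflow content).
#' @return `canonical_json()` returns a single JSON string;
#'   `content_hash()` returns its lowercase hex SHA-256 digest.
#' @examples
#' content_hash(list(b = 1, a = "x"))
#' identical(canonical_json(list(a = 1, b = 2)), canonical_json(list(b = 2, a = 1)))
#' @export
canonical_json <- function(x) {
  jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname canonical_json
#' @export
content_hash <- function(x) {
  sha256_hex(canonical_json(x))
}

sha256_hex <- function(text) {
  unclass(as.character(openssl::sha256(charToRaw(enc2utf8(as.character(text))))))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, logical(1))]
    nms <- names(x)
    if (!is.null(nms) && all(nzchar(nms))) {
      x <- x[order(nms, method = "radix")]
    }
    lapply(x, canonicalize)
  } else if (is.character(x)) {
    gsub("\r\n|\r", "\n", enc2utf8(x))
  } else {
    x
  }
}
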
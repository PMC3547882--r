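# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for an unordered protein pair
#'
#' Pairs are stored unordered; the key concatenates the two ids in
#' lexicographic order with a separator that cannot occur in an id.
#' @param a,b character vectors of protein ids (recycled together)
#' @return character vector of keys
#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp outputs with a short config fingerprint; not
# cryptographic.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor with the low byte, done in doubles (h can exceed .Machine$integer.max)
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619; split h to keep
    # every intermediate product below 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Fingerprint of an R object via its deparsed form (order-stable for lists
# built by our constructors).
object_hash <- function(x) {
  fnv1a_hash(paste(deparse(x, control = "exact"), collapse = "\n"))
}

# Clamp scores to the [0,1] reporting scale from below (negative
# correlations carry no linkage evidence on this scale).
clamp_low <- function(x) pmax(x, 0)

# Lightweight logger: writes to stderr, silenced via
# options(linkmark.log_level = "quiet").
lk_log <- function(..., level = "info") {
  opt <- getOption("linkmark.log_level", "info")
  if (identical(opt, "quiet")) return(invisible(NULL))
  if (identical(level, "debug") && !identical(opt, "debug")) return(invisible(NULL))
  message(sprintf("[linkmark %s] %s", level, paste0(...)))
}

# Pearson correlation by the definitional formula; returns NA when either
# vector has zero variance.  Kept separate from stats::cor so clamping and
# undefined-handling decisions stay in the callers.
pcc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# Upper-triangle (excluding diagonal) of a square matrix as a vector, in a
# fixed column-major order shared by all callers.
upper_tri_vec <- function(m) m[upper.tri(m)]

assert_file_exists <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s: file not found: %s", what, path), call. = FALSE)
  }
  invisible(path)
}

# Read a tab-separated file, dropping '#' comment lines.
read_tsv_plain <- function(path, header = TRUE, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = header, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "", check.names = FALSE,
                    colClasses = colClasses)
}
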
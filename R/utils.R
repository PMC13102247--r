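#' @keywords internal
"_PACKAGE"

# Normalize unicode minus (U+2212) to ASCII "-" so tables copied from
# publisher PDFs parse as ordinary numerics.
normalize_minus <- function(x) gsub("−", "-", x, fixed = TRUE)

# Parse a character vector to numeric; errors carry row/column coordinates.
parse_numeric_strict <- function(x, column, id_hint = NULL) {
  x <- trimws(normalize_minus(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("NA", "")))
  if (length(bad) > 0L) {
    where <- if (is.null(id_hint)) paste0("row ", bad[1L]) else
      paste0("row ", bad[1L], " (", id_hint[bad[1L]], ")")
    stop("non-numeric cell '", x[bad[1L]], "' at ", where,
         ", column '", column, "'", call. = FALSE)
  }
  out
}

# Split "a ± b" cells into c(mean, sd); plain numeric cells get sd NA.
parse_pm <- function(x) {
  x <- normalize_minus(x)
  parts <- strsplit(x, "±", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) == 1L) c(as.numeric(p), NA_real_)
    else c(as.numeric(p[1L]), as.numeric(p[2L]))
  }, numeric(2)))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# FNV-1a hash of a character scalar, for lightweight provenance digests.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)  # xor touches the low byte
    # 32-bit multiply by 16777619 = 2^24 + 403, kept within double precision
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
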
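#' @keywords internal
"_PACKAGE"

# Derive a stream-specific RNG seed from the master seed. Keeps the result
# strictly inside 32-bit integer range whatever the master seed is.
.derive_seed <- function(seed, stream) {
  as.integer((abs(as.numeric(seed)) * 48271 + 1e4 * stream) %% 2147483629) + 1L
}

# Run `expr` under a temporary RNG state seeded from (seed, stream), then
# restore the caller's RNG so generators are order-independent.
.with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(.derive_seed(seed, stream))
  expr
}

# FNV-1a 32-bit hash of a character scalar; used for the run-manifest
# config fingerprint (hex string).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # (h * p) mod 2^32 in two 16-bit halves to stay inside double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Reverse complement of an RNA string
#'
#' @param x character scalar over the RNA alphabet (A, C, G, U; T is
#'   accepted and treated as U).
#' @return character scalar, the reverse complement on the RNA alphabet.
#' @export
rna_revcomp <- function(x) {
  x <- .as_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Normalize to upper-case RNA; error on alphabet violations.
.as_rna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (grepl("[^ACGU]", x)) {
    stop("invalid ", what, ": characters outside the RNA alphabet {A,C,G,U}")
  }
  x
}

# Vectorized row variances (used by the Welch test over whole matrices).
.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 columns for a variance")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
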
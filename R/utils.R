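# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard amino-acid alphabet
#'
#' The 20 canonical residues; peptides and decoys are restricted to this
#' alphabet throughout the package.
#' @keywords internal
AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic string -> uniform(0,1) via a polynomial rolling hash mod
# 2^31 - 1.  Used by the mock predictor so that scores depend only on
# (peptide, allele, seed), never on batch composition or RNG state.
# Strings are right-padded to a fixed width so the loop vectorizes over
# positions instead of strings.
str_hash_uniform <- function(x, width = 64L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (any(nchar(x) > width)) stop("hash input longer than ", width, " characters")
  p <- 2147483647
  padded <- formatC(x, width = -width)  # right-pad with spaces
  codes <- utf8ToInt(paste(padded, collapse = ""))
  dim(codes) <- c(width, n)
  h <- rep(7, n)
  for (i in seq_len(width)) h <- (h * 131 + codes[i, ]) %% p
  (h + 0.5) / p
}

# Read a delimited text table, choosing the separator from the extension
# (.csv -> comma, otherwise tab).
read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

write_delim_auto <- function(x, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::write.table(x, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
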
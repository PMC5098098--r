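# Small utilities: provenance hashing and CSV/JSON writers shared by the
# analysis drivers.

#' Stable hash of a configuration object
#'
#' FNV-1a (64-bit, reported as 16 hex digits) over the object's
#' canonical serialization. Used to stamp output tables so reruns with an
#' identical configuration are recognizable.
#'
#' @param x Any R object.
#' @return A 16-character hex string.
#' @export
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 3))
  fnv32 <- function(bytes, offset) {
    p <- 16777619
    two32 <- 2^32
    h <- offset
    for (byte in bytes) {
      lo16 <- h %% 65536
      hi16 <- (h - lo16) / 65536
      # xor affects only the low 16 bits since byte < 256
      lo16 <- bitwXor(as.integer(lo16), byte)
      # (hi16*2^16 + lo16)*p mod 2^32, kept exact in doubles
      h <- (((hi16 * p) %% 65536) * 65536 + lo16 * p) %% two32
    }
    h
  }
  hex8 <- function(h) {
    lo <- h %% 65536
    sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
  }
  paste0(hex8(fnv32(raw, 2166136261)), hex8(fnv32(raw, 1294967291)))
}

#' Write a data frame as CSV with full double precision
#'
#' Deterministic plain-text output: `write.csv` with 17 significant
#' digits, no row names. Identical inputs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) format(v, digits = 17,
                                                 trim = TRUE,
                                                 scientific = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
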
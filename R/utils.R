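# Internal helpers: deterministic hashing, seed scoping, small numerics.

# 32-bit FNV-1a over the UTF-8 bytes of a string, done in doubles to avoid
# integer overflow (R integers are 32-bit signed).
fnv1a32 <- function(x, offset = 2166136261) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- offset
  for (b in bytes) {
    h <- bitwXor2(h, b)
    # h * 16777619 mod 2^32, via 16-bit splits
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

# bitwXor for doubles holding unsigned 32-bit values
bitwXor2 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    ra <- a %% 2; rb <- b %% 2
    if (ra != rb) r <- r + p
    a <- (a - ra) / 2; b <- (b - rb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

# Deterministic digit string for UID construction (two FNV variants glued).
hash_digits <- function(x) {
  paste0(sprintf("%.0f", fnv1a32(x)), sprintf("%.0f", fnv1a32(x, offset = 31478921)))
}

# Deterministic DICOM UID under a private root.
make_uid <- function(...) {
  key <- paste(..., sep = "|")
  uid <- paste0("1.2.826.0.1.3680043.9.7431.", hash_digits(key))
  substr(uid, 1, 64)
}

# Derive a child seed from a base seed, kept inside 32-bit signed range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + i * 9973) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Dice overlap of two logical/0-1 arrays on the same grid.
dice_overlap <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}
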
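## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic rounding rule used when converting scaled z-scores to
#' integers: ties (x.5) move away from zero, unlike [base::round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

## 32-bit xor on doubles in [0, 2^32): R's bitwXor only takes signed ints
xor32 <- function(a, b) {
  al <- a %% 65536; ah <- (a - al) / 65536
  bl <- b %% 65536; bh <- (b - bl) / 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

fnv1a_update <- function(h, bytes) {
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible sub-stream seed
#'
#' Folds a base seed and a sequence of integer/character labels into a new
#' seed below 2^31 via an FNV-1a style hash, so that every generated unit
#' (dyad, site, task, role) gets an independent, stable random stream:
#' adding dyads never perturbs the streams of existing ones.
#'
#' @param seed integer base seed.
#' @param ... integers or strings identifying the sub-stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)), vapply(list(...), as.character, ""))
  key <- paste(parts, collapse = "\x1f")
  ## FNV-1a over the key bytes, folded below 2^31 (R seeds are 32-bit ints)
  h <- fnv1a_update(2166136261, utf8ToInt(key))
  as.integer(h %% 2147483645) + 1L
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' generator functions are pure functions of their seed argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

## FNV-1a hash of a string, returned as 8-digit hex; used to fingerprint
## pipeline configurations in reports.
fnv1a_hex <- function(s) {
  h <- fnv1a_update(2166136261, utf8ToInt(s))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## data.frame constructor without the checking overhead of data.frame();
## columns must be equal-length atomic vectors
fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}
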
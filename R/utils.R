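#' Derive a reproducible stream seed from a master seed
#'
#' Stage and subject seeds are split off a single master seed by FNV-1a
#' hashing of a label string, so that independent pipeline stages never share
#' a random stream and the whole analysis is reproducible from one integer.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stream (e.g. stage
#'   name, subject index); concatenated with `/`.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "simulate", 3)
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(label)
  # FNV-1a over the label bytes, kept in double precision below 2^53 and
  # folded into the 31-bit range R's RNG seeds accept
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  code
}

# round-half-away-from-zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
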
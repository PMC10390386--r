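#' Derive a reproducible child seed from a master seed
#'
#' Stage- and participant-level RNG streams are derived from one master seed so
#' that adding participants or stages never perturbs existing streams. The
#' derivation is a small multiplicative hash over the master seed and a string
#' tag, reduced modulo 2^31 - 2 (R seeds are 32-bit integers).
#'
#' @param master integer master seed.
#' @param ... character or numeric tags identifying the substream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "sessions", 3)
derive_seed <- function(master, ...) {
  mod <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% mod
  for (tag in list(...)) {
    for (ch in utf8ToInt(paste0(":", paste(tag, collapse = ",")))) {
      h <- (h * 31 + ch) %% mod
    }
  }
  as.integer(h %% (mod - 1) + 1)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}
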
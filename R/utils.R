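# Internal helpers shared across modules.

# Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
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
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit string/integer hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive independent, reproducible per-field seeds; documented so the
# seeding scheme is portable.
stable_hash <- function(...) {
  parts <- vapply(list(...), function(x) paste0(as.character(x), collapse = ","),
                  character(1))
  s <- paste(parts, collapse = "\x1f")
  codes <- utf8ToInt(s)
  h <- 0
  m <- 2147483647
  for (k in codes) h <- (h * 31 + k) %% m
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (length(x) == 0L) abort(sprintf("`%s` has zero pixels.", arg))
  invisible(x)
}

assert_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must share dimensions (got %s vs %s).", what,
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(NULL)
}

# Gaussian smoothing that tolerates sigma = 0 and keeps matrix class.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  # cap the kernel so it never exceeds the image (EBImage requires this);
  # for sigma large relative to the image this approaches a global mean
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  limit <- min(dim(x))
  if (size > limit) size <- limit - (1L - limit %% 2L)
  out <- EBImage::gblur(x, sigma = sigma, radius = size)
  matrix(as.numeric(out), nrow(x), ncol(x))
}
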
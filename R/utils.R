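#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a multi-stage run flows from one top-level seed; each
#' stage draws from its own stream, seeded by a deterministic hash of the
#' top-level seed and the stage name. Stages can therefore be re-run in
#' isolation and still reproduce the full pipeline bit-for-bit.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name (e.g. `"synth"`, `"split"`, `"forest"`).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "synth")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps seeds inside R's integer range
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_bad_arg <- function(name, why) {
  stop(sprintf("invalid `%s`: %s", name, why), call. = FALSE)
}

check_finite_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_bad_arg(name, "must be a single finite number")
  }
  if (strict_min && x <= min) {
    stop_bad_arg(name, sprintf("must be > %g", min))
  }
  if (!strict_min && x < min) {
    stop_bad_arg(name, sprintf("must be >= %g", min))
  }
  invisible(x)
}
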
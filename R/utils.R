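# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, expr) {
  # run expr under set.seed(seed) without disturbing the caller's RNG stream
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

# derive an independent sub-seed from a user seed; stays below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 10007) %% (2^31 - 1))
}

soft_threshold <- function(z, gamma) {
  sign(z) * pmax(abs(z) - gamma, 0)
}

# population (1/n) standard deviation of each row
row_pop_sd <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans((m - mu)^2))
}

pop_var <- function(x) mean((x - mean(x))^2)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

format_full <- function(x) sprintf("%.17g", x)
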
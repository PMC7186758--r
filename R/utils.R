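# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# wrap an angle (degrees) into [0, 360)
wrap_deg <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

# rolling sum of x over windows of length k, aligned so that element i is
# sum(x[i:(i + k - 1)]); last k - 1 elements are NA
roll_sum_forward <- function(x, k) {
  n <- length(x)
  if (n < k) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  out[seq_len(n - k + 1)] <- cs[(k + 1):(n + 1)] - cs[seq_len(n - k + 1)]
  out
}

# Greedy temporal de-duplication: keep the earliest candidate, then skip all
# later candidates within `min_gap` seconds. Shared by the walking-onset
# detector and the generator's latent-state truth so both apply the same
# resolution rule to their respective candidate lists.
resolve_candidates <- function(times, min_gap) {
  if (length(times) == 0) return(numeric(0))
  times <- sort(times)
  kept <- times[1]
  last <- times[1]
  for (t in times[-1]) {
    if (t - last >= min_gap) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

stopf <- function(fmt, ..., class = "beesocial_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stopf("`%s` must be a single number in [%s, %s]", name,
          format(lower), format(upper), class = "beesocial_config_error")
  }
  invisible(x)
}
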
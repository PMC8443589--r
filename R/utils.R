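`%||%` <- function(a, b) if (is.null(a)) b else a

# Configuration errors always name the offending field so a bad spec is
# actionable from the message alone.
abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

abort_input <- function(msg, ...) {
  stop(sprintf(paste0("invalid input: ", msg), ...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.  All generators route their randomness through this so
# that no fixture call perturbs (or depends on) global state.
with_seed <- function(seed, code) {
  if (!is_count(seed)) abort_config("seed", "must be a non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed for a named sub-stream (e.g. the intensity
# draws of a z-stack vs its pixel noise) from a parent seed.  Plain string
# hash (FNV-1a folded into the positive 31-bit range); independent streams
# keep the base-amplitude draws identical across specs that differ only in
# noise or fold settings.
child_seed <- function(seed, stream) {
  h <- 2166136261 %% 2147483648  # FNV offset basis folded below 2^31
  for (b in utf8ToInt(paste0(stream, ":", seed))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483647)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv`; cv = 0 returns exact ones.
lognormal_noise <- function(n, cv) {
  if (cv < 0) abort_config("noise_cv", "must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
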
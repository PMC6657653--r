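#' @keywords internal
#' @importFrom stats plogis
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. When `seed` is NULL the current stream is used
# (and advanced), so unseeded calls remain stochastic.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed, keeping the result a valid 32-bit
# integer. Used so that one pipeline seed fans out deterministically to the
# stages without reusing the identical stream.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + as.double(k) * 12289L) %% 2147483647L)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# All permutations of 1..n as rows (n! x n). Only used for small n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + r
    out[idx, pos] <- n
    out[idx, setdiff(seq_len(n), pos)] <- sub
    r <- r + nrow(sub)
  }
  out
}

# Stable hash of an R object for run provenance: serialize to a canonical
# JSON string and fold into hex with a simple polynomial rolling hash.
# Not cryptographic; only used to tag outputs of a config.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}
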
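# Internal helpers: errors, RNG scoping, polynomial arithmetic, hashing.

nq_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "nq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Evaluate all RNG draws under `seed` without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-fish seed from (cohort seed, fish index). Two rounds of
# a Lehmer-style mix keep everything exact in double arithmetic and the
# result strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m)
  h <- (h * 48271 + as.numeric(index) * 9349 + 1) %% m
  h <- (h * 48271 + 12345) %% m
  as.integer(h)
}

# Polynomial helpers; coefficients ascending (c0, c1, ...).
poly_eval <- function(coeffs, x) {
  y <- rep(0, length(x))
  for (i in rev(seq_along(coeffs))) y <- y * x + coeffs[i]
  y
}

poly_deriv <- function(coeffs) {
  n <- length(coeffs)
  if (n <= 1) return(0)
  coeffs[-1] * seq_len(n - 1)
}

poly_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Coefficients of p(alpha * x + beta) given coefficients of p(t).
poly_compose_affine <- function(coeffs, alpha, beta) {
  out <- 0
  lin <- c(beta, alpha)
  pow <- 1
  for (i in seq_along(coeffs)) {
    term <- coeffs[i] * pow
    n <- max(length(out), length(term))
    out <- c(out, rep(0, n - length(out))) + c(term, rep(0, n - length(term)))
    pow <- poly_mul(pow, lin)
  }
  out
}

# FNV-1a over a string, reported as 8 hex digits; used to stamp outputs
# with a config fingerprint (exact arithmetic in doubles, < 2^32).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor_dbl <- function(a, b) {
  # a < 2^32, b < 256: xor via the low 31 bits plus the top bit by hand
  hi_a <- a >= 2147483648
  la <- a - if (hi_a) 2147483648 else 0
  r <- bitwXor(as.integer(la), as.integer(b))
  as.numeric(r) + if (hi_a) 2147483648 else 0
}

is_count <- function(n) {
  is.numeric(n) && all(is.finite(n)) && all(n >= 0) && all(n == round(n))
}
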
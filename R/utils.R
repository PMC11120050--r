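# Internal numerical helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded operations stay pure.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a sub-stream seed that stays inside 32-bit
# integer range whatever the parent seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 94906249 * 7919 + as.numeric(k)) %% 2147483629)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Probability clipping before any log; eps keeps losses finite.
PROB_EPS <- 1e-8

clip_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Row-wise softmax, numerically stabilised.
softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

as_num_matrix <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  }
  x
}

check_same_shape <- function(a, b, names = c("first", "second")) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s is %s, %s is %s",
                 names[1], paste(dim(a), collapse = "x"),
                 names[2], paste(dim(b), collapse = "x")), call. = FALSE)
  }
  invisible(TRUE)
}

check_binary_mask <- function(M) {
  M <- as_num_matrix(M, "M")
  if (anyNA(M) || !all(M %in% c(0, 1))) {
    stop("mask entries must all be 0 or 1", call. = FALSE)
  }
  M
}
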
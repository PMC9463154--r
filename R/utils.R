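# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. `seed = NULL` runs as-is.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' @keywords internal
#' @noRd
l2_normalize_rows <- function(m) {
  m <- as.matrix(m)
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Cosine similarity between rows of a and rows of b.
#' @keywords internal
#' @noRd
cosine_sim <- function(a, b = a) {
  tcrossprod(l2_normalize_rows(a), l2_normalize_rows(b))
}

# Rank (Mann-Whitney) AUROC: probability that a positive score exceeds a
# negative score, ties counted 1/2. Higher score must mean "more positive".
#' @keywords internal
#' @noRd
rank_auroc <- function(pos, neg) {
  np <- as.numeric(length(pos)); nn <- as.numeric(length(neg))
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Deterministic order by decreasing value with ties broken by id (ascending).
#' @keywords internal
#' @noRd
order_desc_by_value_then_id <- function(value, id) {
  order(-value, xtfrm(id))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}
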
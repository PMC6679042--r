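# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed from a base seed plus arbitrary string/number
# tokens.  Used to give each (breed, chromosome, tract) its own RNG stream so
# that simulated blocks are independent of one another: changing one breed's
# size never perturbs another breed's genotypes.
subseed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  tokens <- vapply(list(...), function(x) paste0(as.character(x), collapse = ","),
                   character(1))
  for (tok in tokens) {
    for (code in utf8ToInt(paste0("|", tok))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporarily-seeded RNG, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (commercial rounding); round() in R rounds half
# to even, which would make carrier counts at exact .5 fractions ambiguous.
round_half_up <- function(x) floor(x + 0.5)

# Closed-interval intersection test on bp coordinates: shared span of >= 1 bp.
intervals_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) <= pmin(e1, e2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
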
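## Seed plumbing: every stochastic stage draws from a sub-stream derived from
## the single top-level seed, so stages are individually reproducible.

subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

## round half away from zero (base round() rounds half to even)
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

.checkContext <- function(context) {
  if (length(context) != 1L || !context %in% c("CG", "CHG", "CHH"))
    stop("context must be one of 'CG', 'CHG', 'CHH'", call. = FALSE)
  context
}
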
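# Classed conditions so callers (and the CLI) can distinguish bad files,
# bad configuration and broken contracts.

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("anrs_parse_error", "anrs_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("anrs_config_error", "anrs_error")))
}

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("anrs_contract_error", "anrs_error")))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded entry points do not perturb the session stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
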
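# Internal helpers shared across modules.

# Deterministic per-(unit, subunit) substream seed derived from a master seed,
# so that adding lots/wells never perturbs the draws of existing ones.
.substreamSeed <- function(master, unit, subunit = 0L) {
  as.integer((as.numeric(master) * 10007 + unit * 101 + subunit) %% 2147483647)
}

.assertCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

.assertPositive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  invisible(x)
}

# linear ramp clamped to [0, 1]
.ramp01 <- function(t, from, to) pmin(1, pmax(0, (t - from) / (to - from)))
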
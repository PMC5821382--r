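# shared helpers for the lvfeas test suite

# independent acyclicity check: repeatedly strip species with no prey;
# the predation graph is acyclic iff everything can be stripped.
is_acyclic <- function(alpha) {
  remaining <- seq_len(nrow(alpha))
  a <- alpha
  repeat {
    sinks <- remaining[rowSums(a[remaining, remaining, drop = FALSE]) == 0]
    if (length(sinks) == 0) break
    remaining <- setdiff(remaining, sinks)
    if (length(remaining) == 0) return(TRUE)
  }
  FALSE
}

# intervality oracle: every predator's prey set must be contiguous in the
# niche ordering (species are stored sorted by niche value).
is_interval_web <- function(alpha) {
  for (i in seq_len(nrow(alpha))) {
    prey <- which(alpha[i, ] == 1)
    if (length(prey) > 1 && !all(diff(prey) == 1)) return(FALSE)
  }
  TRUE
}

# baseline study conditions: C = 0.25, sigma = 0.4, theta = -1
baseline_config <- function(model, S, delta, ...) {
  community_config(model, S = S, C = 0.25, delta = delta, theta = -1,
                   sigma = 0.4, ...)
}
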
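# All permutations of a small vector (for exhaustive-ordering oracles).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exhaustive collector-curve oracle: one sample per site, every ordering of
# the sites enumerated. Returns per-k population mean, median, and sd of
# cumulative richness over orderings.
oracle_collector <- function(inc) {
  inc <- as.matrix(inc)
  K <- nrow(inc)
  vals <- vapply(all_perms(seq_len(K)), function(ord) {
    seen <- numeric(ncol(inc))
    vapply(ord, function(s) {
      seen <<- pmax(seen, inc[s, ])
      sum(seen)
    }, numeric(1))
  }, numeric(K))
  vals <- matrix(vals, nrow = K)
  list(
    mean = rowMeans(vals),
    median = apply(vals, 1L, stats::median),
    sd = apply(vals, 1L, stats::sd)
  )
}

# Bernoulli records reproducing exact cell proportions, for comparing GLM
# cell fits against closed-form empirical logits.
records_from_counts <- function(cells) {
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      site_id = cells$site_id[i],
      method = cells$method[i],
      detected = rep(c(1, 0), c(cells$hits[i], cells$n[i] - cells$hits[i]))
    )
  }))
}
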
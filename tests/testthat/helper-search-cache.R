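# The reduced design-space exploration shared by the catalog-level
# acceptance checks.  One run, memoized for the session: 16 chains x 8000
# steps (the package's reduced study scale; the full-scale study uses
# 500 x 50000).
reduced_search <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- search_config(n_chains = 16, steps_per_chain = 8000,
                           seed = 20260924)
      cache <<- run_search(cfg)
    }
    cache
  }
})
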
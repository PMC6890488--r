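# Heavy benchmark runs shared between acceptance test blocks.  Computed
# lazily on first use and reused within the session.
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, fn) {
  if (!exists(key, envir = .study_cache, inherits = FALSE)) {
    assign(key, fn(), envir = .study_cache)
  }
  get(key, envir = .study_cache, inherits = FALSE)
}
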
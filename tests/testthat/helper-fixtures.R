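# Shared fixtures, built once per test run. All are generated in code; no
# data files are stored.

# reference with bimodal library sizes and long-tailed peak sums
.fx_cache <- new.env()

fixture_ref <- function(npeak = 2000, ncell = 500, n_types = 2, seed = 7) {
  key <- paste(npeak, ncell, n_types, seed, sep = "_")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_fixture(npeak, ncell, n_types, seed)
  .fx_cache[[key]]
}

fixture_fit <- function(mode = "discrete", npeak = 2000, ncell = 500,
                        n_types = 2, seed = 7) {
  key <- paste("fit", mode, npeak, ncell, n_types, seed, sep = "_")
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- cas_fit(fixture_ref(npeak, ncell, n_types, seed), mode)
  .fx_cache[[key]]
}

# small dense matrix wrapped as count_matrix
cm_from <- function(m, ...) count_matrix(as.matrix(m), ...)

# brute-force two-sample KS via an explicit ECDF sweep (independent oracle)
ks_bruteforce <- function(x, y) {
  g <- sort(c(x, y))
  d <- 0
  for (t in g) d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  d
}
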
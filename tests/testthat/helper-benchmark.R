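# Shared end-to-end fixture: the full benchmark (20 complete, 20 fragments,
# 60 decoys) plus detection results, generated once per test run.

.bench_cache <- new.env(parent = emptyenv())

get_benchmark <- function(seed = 20240101L) {
  key <- paste0("b", seed)
  if (is.null(.bench_cache[[key]])) {
    bench <- generate_benchmark(generator_config(seed = seed))
    det <- detect_elements(bench$contigs, bench$profiles)
    .bench_cache[[key]] <- list(bench = bench, det = det)
  }
  .bench_cache[[key]]
}
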
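# Independent brute-force oracles, kept deliberately naive.

# literal cursor tiling: slide a window from the region start until the
# next slide would pass the region end; the remainder (shorter than one
# slide) is absorbed into the last window
oracle_tile <- function(region_len, window_len, slide_len) {
  if (region_len <= window_len) {
    return(data.frame(start = 0L, end = as.integer(region_len)))
  }
  starts <- integer()
  s <- 0L
  while (s + window_len <= region_len) {
    starts <- c(starts, s)
    s <- s + slide_len
  }
  ends <- starts + window_len
  ends[length(ends)] <- as.integer(region_len)
  data.frame(start = starts, end = ends)
}

oracle_count <- function(region_len, window_len, slide_len) {
  nrow(oracle_tile(region_len, window_len, slide_len))
}

# enumeration oracle for pool membership: explicit sliding groups
oracle_pools <- function(ids, K) {
  lapply(seq_len(length(ids) - K + 1L), function(j) ids[j:(j + K - 1L)])
}
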
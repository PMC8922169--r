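# Build a seg object from raw vectors, via the public CSV-schema path.
make_seg <- function(concentration, worker = seq_along(concentration),
                     date = as.Date("2020-01-01") + seq_along(concentration) - 1,
                     seg_id = "S1") {
  df <- data.frame(seg_id = seg_id,
                   worker_id = paste0("w", worker),
                   sample_date = as.Date(date),
                   concentration = concentration,
                   stringsAsFactors = FALSE)
  build_segs(df)[[1]]
}

# Write a measurements data frame to a temp CSV, returning the path.
write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# n log-values with exact sample mean m and sample sd s (scale trick), so
# tests can target precise lognormal fits through the public API.
values_with_log_stats <- function(n, m, s) {
  z <- as.vector(scale(seq_len(n)))  # mean 0, sd 1 exactly
  exp(m + s * z)
}
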
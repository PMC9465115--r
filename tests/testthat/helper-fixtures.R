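# shared fixtures, built in code at test time

write_generic_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  header <- paste(names(df), collapse = "\t")
  rows <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

# a steep, thin trapezoid: its diagonal rise over half the m/z range
# exceeds its height, so a k = 2 scheme built on it covers a cloud
# confined to it completely
recovery_area <- function() scan_area(0.7, 1.1, 0.85, 1.25)

recovery_library <- function(n = 2000, seed = 3) {
  generate_within_trapezoid(recovery_area(), c(300, 1200), n, seed = seed)
}

proteome_library <- function(n = 5000, seed = 1) {
  generate_library(cloud_model(seed = seed), n)
}

# naive per-record / per-window loop, the independent coverage oracle;
# same half-open m/z convention with the highest window closed right
naive_covered <- function(lib, scheme) {
  rec <- lib$records
  w <- scheme$windows
  last_edge <- max(w$mz_end)
  out <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(w))) {
      in_mz <- rec$mz[i] >= w$mz_start[j] &&
        (rec$mz[i] < w$mz_end[j] ||
           (w$mz_end[j] >= last_edge - 1e-9 && rec$mz[i] <= w$mz_end[j]))
      if (in_mz && rec$im[i] >= w$im_low[j] && rec$im[i] <= w$im_high[j]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}
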
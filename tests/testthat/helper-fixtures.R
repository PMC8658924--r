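# Shared fixture builders. Everything is generated in code; nothing binary.

make_em <- function(values, condition = rep("treated", ncol(values)),
                    time_h = seq_len(ncol(values))) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, condition = condition, time_h = time_h)
}

# Treated arm of a synthetic dataset with a detectable but sub-dominant
# planted trend (the column standardization caps every sample's variance, so
# an overwhelming trend would flatten the loading vector instead of helping).
# Planted probe ids are attached as attribute "planted".
make_trend_em <- function(seed = 42, n_probes = 2000, slope_scale = 0.125) {
  ds <- generate_synthetic(synthetic_spec(n_probes = n_probes,
                                          slope_scale = slope_scale,
                                          seed = seed))
  em <- ds$treated
  attr(em, "planted") <- ds$truth$planted_probe_ids
  em
}

# Write a series-matrix file from explicit header/body lines.
write_series_lines <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# Hand-written 3 probes x 2 samples fixture in the series-matrix dialect.
tiny_series_fixture <- function(path = tempfile(fileext = ".txt")) {
  write_series_lines(c(
    "!Series_title\t\"tiny fixture\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
    "\"1007_s_at\"\t1.5\t2.5",
    "\"1053_at\"\t-0.25\t0.75",
    "\"117_at\"\t3\t4",
    "!series_matrix_table_end"), path)
}

tiny_annotation <- function(sample_ids = c("GSM1", "GSM2"),
                            condition = c("treated", "treated"),
                            time_h = c(1, 48)) {
  data.frame(sample_id = sample_ids, condition = condition, time_h = time_h,
             stringsAsFactors = FALSE)
}

# Independent brute-force BH step-up: for each hypothesis the smallest
# q = n p_(j) / j over all ranks j at or above its own, evaluated by explicit
# enumeration (no cummin).
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    adj[i] <- min(1, min(sapply(k:n, function(j) n * p[ord[j]] / j)))
  }
  adj
}
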
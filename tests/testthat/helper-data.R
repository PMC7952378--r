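# small programmatic fixtures

toy_fm <- function(values, batch, ..., scale_flag = "log2") {
  m <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  feature_matrix(m, batch = batch, ..., scale_flag = scale_flag)
}

# n-batch random dataset with per-(feature,batch) offsets, no drift/QC
random_batched <- function(n_per_batch, n_batches, n_features, gamma_sd = 3,
                           noise_sd = 1, seed = 1) {
  set.seed(seed)
  batch <- rep(paste0("b", seq_len(n_batches)), each = n_per_batch)
  gam <- matrix(rnorm(n_features * n_batches, 0, gamma_sd),
                n_batches, n_features)
  y <- gam[rep(seq_len(n_batches), each = n_per_batch), ] +
    matrix(rnorm(length(batch) * n_features, 0, noise_sd),
           length(batch), n_features)
  feature_matrix(y + 15, batch = batch, scale_flag = "log2")
}

# write a feature_matrix pair of CSVs into a temp dir, return the paths
write_tmp_tables <- function(int_lines, meta_lines) {
  ip <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeLines(int_lines, ip); writeLines(meta_lines, mp)
  list(intensity = ip, metadata = mp)
}
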
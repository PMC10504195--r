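# Small shared helpers.

# Round half away from zero (tables print integers; R's round() is
# round-half-even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Write a data frame as CSV with doubles at full round-trip precision
# (%.17g), so a table rebuilt from an exported file is bit-identical.
write_full_precision_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
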
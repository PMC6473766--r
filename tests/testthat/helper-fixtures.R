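# Shared fixture builders: everything is generated in code at test time.

# A random valid specificity matrix (Dirichlet columns).
rand_spec <- function(id = "sm", concentration = 0.3) {
  m <- matrix(stats::rgamma(80, concentration), 20, 4,
              dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
  specificity_matrix(id, sweep(m, 2, colSums(m), "/"))
}

# A random valid 20x4 frequency matrix (bare).
rand_freq <- function(concentration = 0.5) {
  m <- matrix(stats::rgamma(80, concentration), 20, 4,
              dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
  sweep(m, 2, colSums(m), "/")
}

# Long-format specificity TSV from named per-position count vectors.
write_spec_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Minimal quant table data frame.
qt_df <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(peptide_seq = "ACDEF", protein_id = "p1",
                   group = "G1", replicate = 1L, area = 1,
                   confidence = 1, shared = FALSE)
  for (nm in names(defaults)) if (is.null(d[[nm]])) d[[nm]] <- defaults[[nm]]
  d
}
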
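#' @keywords internal
"_PACKAGE"

#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in fixed alphabetical one-letter order. All
#' 20x4 matrices in the package (specificity and terminome) use this row
#' order; nonstandard letters (B, J, O, U, X, Z) are rejected wherever
#' residues are read.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Cleavage-context positions
#'
#' Column order of all 20x4 matrices: the two residues N-terminal of the
#' scissile bond (P2, P1) and the two C-terminal of it (P1', P2'), serialized
#' ASCII-safe as "P1p"/"P2p".
#'
#' @format Character vector of length 4.
#' @export
CONTEXT_POSITIONS <- c("P2", "P1", "P1p", "P2p")

# Validate a character vector of sequences against the 20-letter alphabet.
is_valid_aa <- function(x) {
  grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

# Weighted amino-acid appearance-frequency matrix over the four context
# positions. residues: list of 4 character vectors (P2, P1, P1p, P2p);
# weights: one nonnegative weight per event. Each column is normalized by the
# total weight of events with a defined (non-NA) residue at that position.
weighted_context_matrix <- function(p2, p1, p1p, p2p, weights) {
  stopifnot(length(p2) == length(weights), length(p1) == length(weights),
            length(p1p) == length(weights), length(p2p) == length(weights))
  if (length(weights) == 0L) stop("no cleavage events supplied")
  if (any(weights < 0)) stop("negative event weights")
  cols <- list(P2 = p2, P1 = p1, P1p = p1p, P2p = p2p)
  m <- matrix(0, nrow = 20L, ncol = 4L,
              dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
  for (j in seq_along(cols)) {
    res <- cols[[j]]
    keep <- !is.na(res)
    if (!all(res[keep] %in% AA_ALPHABET))
      stop("residue outside the 20-letter alphabet at position ",
           CONTEXT_POSITIONS[j])
    tot <- sum(weights[keep])
    if (tot <= 0) stop("total event weight is zero at position ",
                       CONTEXT_POSITIONS[j])
    tab <- tapply(weights[keep], factor(res[keep], levels = AA_ALPHABET), sum)
    tab[is.na(tab)] <- 0
    m[, j] <- as.numeric(tab) / tot
  }
  m
}

# Assert a 20x4 frequency matrix: nonnegative, columns sum to 1 +- tol.
check_freq_matrix <- function(m, tol = 1e-9, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != 20L || ncol(m) != 4L)
    stop(what, " must be 20 x 4")
  if (!identical(rownames(m), AA_ALPHABET))
    stop(what, " rows must be the 20 canonical amino acids in order")
  if (any(m < -tol)) stop(what, " has negative entries")
  cs <- colSums(m)
  if (any(abs(cs - 1) > tol))
    stop(what, " columns must each sum to 1 (got ",
         paste(signif(cs, 12), collapse = ", "), ")")
  invisible(TRUE)
}
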
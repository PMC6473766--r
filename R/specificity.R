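#' Protease cleavage-site specificity matrix
#'
#' A `specificity_matrix` holds one protease's appearance frequencies of the
#' 20 canonical amino acids at the four positions flanking its cleavage sites
#' (P2, P1, P1', P2'; the scissile bond lies between P1 and P1'). Each
#' position column is a probability vector.
#'
#' @param protease_id Character scalar identifying the protease.
#' @param matrix Numeric 20x4 matrix, rows the canonical alphabet
#'   ([AA_ALPHABET]), columns `P2, P1, P1p, P2p`; entries nonnegative with
#'   each column summing to 1 (within 1e-9).
#' @param ec_number Optional EC number, e.g. `"3.4.22.52"`; `""` if unknown.
#' @return An object of class `specificity_matrix`.
#' @examples
#' m <- matrix(1 / 20, 20, 4, dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
#' specificity_matrix("uniformase", m)
#' @export
specificity_matrix <- function(protease_id, matrix, ec_number = "") {
  stopifnot(is.character(protease_id), length(protease_id) == 1L,
            nzchar(protease_id))
  check_freq_matrix(matrix, what = paste0("specificity matrix '",
                                          protease_id, "'"))
  structure(list(protease_id = protease_id,
                 ec_number = as.character(ec_number),
                 matrix = matrix),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("Protease specificity matrix:", x$protease_id,
      if (nzchar(x$ec_number)) paste0("(EC ", x$ec_number, ")") else "",
      "\n")
  top <- apply(x$matrix, 2, function(v) {
    i <- which.max(v)
    sprintf("%s(%.2f)", rownames(x$matrix)[i], v[i])
  })
  cat("  top residue per position:",
      paste(paste0(CONTEXT_POSITIONS, "=", top), collapse = " "), "\n")
  invisible(x)
}

#' Load protease specificity matrices from a long-format TSV
#'
#' Reads a table with columns `protease_id`, `ec_number`, `position` (one of
#' `P2, P1, P1p, P2p`), `residue` (one-letter code) and `value` (count or
#' frequency, >= 0), and assembles one [specificity_matrix] per distinct
#' `protease_id`. This flat dialect is how curated cleavage-site data (e.g.
#' matrices hand-reconstituted from the MEROPS peptidase database) enter the
#' pipeline.
#'
#' Rows with a residue outside the canonical 20-letter alphabet are dropped
#' with a warning. A position column whose entries are all zero is replaced
#' by the uniform distribution (0.05 per residue), loudly, so sparse curated
#' data remain usable.
#'
#' @param path Path to the TSV file.
#' @param normalize If `TRUE` (default) each position column is divided by
#'   its sum, so raw counts and frequencies are both accepted; already
#'   normalized input is unchanged (idempotent).
#' @return List of [specificity_matrix], in order of first appearance.
#' @seealso [write_specificity_table()]
#' @export
load_specificity_table <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("specificity table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(value = "numeric"))
  need <- c("protease_id", "ec_number", "position", "residue", "value")
  if (!all(need %in% names(df)))
    stop("specificity table must have columns ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty specificity table: ", path)
  bad_pos <- !df$position %in% CONTEXT_POSITIONS
  if (any(bad_pos)) stop("unknown positions in ", path, ": ",
                         paste(unique(df$position[bad_pos]), collapse = ", "))
  bad_res <- !df$residue %in% AA_ALPHABET
  if (any(bad_res)) {
    warning(sum(bad_res), " row(s) with nonstandard residue letter(s) (",
            paste(unique(df$residue[bad_res]), collapse = ", "),
            ") dropped")
    df <- df[!bad_res, , drop = FALSE]
    if (nrow(df) == 0L) stop("no usable rows in ", path)
  }
  if (any(df$value < 0)) stop("negative values in ", path)

  ids <- unique(df$protease_id)
  lapply(ids, function(id) {
    sub <- df[df$protease_id == id, , drop = FALSE]
    ec <- sub$ec_number[1]
    m <- matrix(0, 20L, 4L, dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
    idx <- cbind(match(sub$residue, AA_ALPHABET),
                 match(sub$position, CONTEXT_POSITIONS))
    # duplicated (position, residue) rows accumulate
    for (r in seq_len(nrow(sub))) m[idx[r, 1], idx[r, 2]] <-
        m[idx[r, 1], idx[r, 2]] + sub$value[r]
    zero <- colSums(m) == 0
    if (any(zero)) {
      warning("protease '", id, "': all-zero position column(s) ",
              paste(CONTEXT_POSITIONS[zero], collapse = ", "),
              " set to uniform (0.05 each)")
      m[, zero] <- 1 / 20
    }
    if (normalize) m <- sweep(m, 2, colSums(m), "/")
    specificity_matrix(id, m, ec)
  })
}

#' Write protease specificity matrices to the long TSV dialect
#'
#' Inverse of [load_specificity_table()]: frequencies round-trip to within
#' 1e-9.
#'
#' @param mats List of [specificity_matrix].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_specificity_table <- function(mats, path) {
  rows <- lapply(mats, function(sm) {
    data.frame(protease_id = sm$protease_id,
               ec_number = sm$ec_number,
               position = rep(CONTEXT_POSITIONS, each = 20L),
               residue = rep(AA_ALPHABET, times = 4L),
               value = as.vector(sm$matrix),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic MEROPS-like example specificity panel
#'
#' Deterministically generates a panel of `n` protease specificity matrices
#' in the style of matrices hand-reconstituted from the MEROPS peptidase
#' database (moderately sharp Dirichlet position columns, EC 3.4.x.x
#' identifiers). Entirely synthetic — a stand-in for curated data used in
#' examples and tests; 45 matches the size of a typical muscle-expressed
#' protease panel.
#'
#' @param n Panel size (default 45).
#' @param seed Seed (default 20).
#' @param concentration Dirichlet concentration per column (default 0.3).
#' @return List of [specificity_matrix] with EC numbers set.
#' @export
example_specificity_panel <- function(n = 45L, seed = 20L,
                                      concentration = 0.3) {
  set.seed(seed)
  subclass <- c("3.4.21", "3.4.22", "3.4.23", "3.4.24", "3.4.25")
  lapply(seq_len(n), function(k) {
    m <- matrix(stats::rgamma(80L, shape = concentration), 20L, 4L,
                dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
    m <- sweep(m, 2, colSums(m), "/")
    specificity_matrix(sprintf("protease_%02d", k), m,
                       sprintf("%s.%d", subclass[(k - 1L) %% 5L + 1L], k))
  })
}

#' Build a specificity matrix from observed cleavage events
#'
#' Turns a set of weighted cleavage contexts (as produced by
#' [extract_contexts()] or the digestion simulator) into an appearance
#' frequency matrix: entry (i, p) is the weight-fraction of events whose
#' residue at position p is amino acid i. Shares one code path with
#' [compute_terminome_matrix()].
#'
#' @param events Data frame of cleavage events with columns `p2`, `p1`,
#'   `p1prime`, `p2prime` (one-letter residues, `NA` allowed when a position
#'   falls outside the protein) and `weight` (nonnegative).
#' @param protease_id Identifier for the resulting matrix.
#' @param ec_number Optional EC number.
#' @return A [specificity_matrix].
#' @export
build_specificity_from_cleavages <- function(events, protease_id,
                                             ec_number = "") {
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("events must be a non-empty data frame")
  if (sum(events$weight) <= 0) stop("total event weight is zero")
  m <- weighted_context_matrix(events$p2, events$p1, events$p1prime,
                               events$p2prime, events$weight)
  specificity_matrix(protease_id, m, ec_number)
}
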
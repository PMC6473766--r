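#' Map a peptide to all exact occurrences in a protein
#'
#' Exhaustive exact-substring search, overlapping occurrences included
#' (e.g. `"AA"` in `"AAA"` yields spans (1,2) and (2,3)).
#'
#' @param protein_seq Protein sequence (single string, 20-letter alphabet).
#' @param peptide_seq Peptide sequence.
#' @return Data frame with 1-based inclusive columns `start`, `end`; zero
#'   rows when the peptide is absent.
#' @export
map_peptide <- function(protein_seq, peptide_seq) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L,
            is.character(peptide_seq), length(peptide_seq) == 1L)
  loc <- stringi::stri_locate_all_fixed(protein_seq, peptide_seq,
                                        overlap = TRUE,
                                        omit_no_match = TRUE)[[1]]
  data.frame(start = as.integer(loc[, 1]), end = as.integer(loc[, 2]))
}

#' Extract cleavage contexts at a mapped peptide's termini
#'
#' A peptide spanning residues `start..end` witnesses up to two cleavage
#' events: at its N terminus the bond (start-1, start) and at its C terminus
#' the bond (end, end+1). Residue positions follow Schechter-Berger
#' nomenclature: P2, P1 run N-terminally from the scissile bond and P1', P2'
#' C-terminally, so the N-terminal event has P1 = residue start-1 and
#' P1' = residue start. An event is emitted only when all four residues lie
#' inside the protein; truncated contexts (peptides reaching a protein
#' terminus) are dropped entirely rather than padded, so mature-protein
#' termini never count as cleavage events.
#'
#' @param protein_seq Protein sequence.
#' @param start,end 1-based inclusive peptide span within the protein.
#' @param weight Nonnegative abundance weight attached to each event.
#' @param protein_id Identifier copied into the events.
#' @return Data frame of 0-2 rows with columns `protein_id`,
#'   `cleaved_bond_position` (bond between residues p and p+1), `p2`, `p1`,
#'   `p1prime`, `p2prime`, `weight`, `terminus` (`"N"`/`"C"`).
#' @export
extract_contexts <- function(protein_seq, start, end, weight = 1,
                             protein_id = "") {
  n <- nchar(protein_seq)
  start <- as.integer(start)
  end <- as.integer(end)
  if (start < 1L || end > n || start > end)
    stop("peptide span (", start, ", ", end, ") outside protein of length ",
         n)
  if (weight < 0) stop("negative weight")
  res <- function(i) substr(protein_seq, i, i)
  rows <- list()
  if (start - 2L >= 1L) # N-terminal event: bond (start-1, start)
    rows$N <- data.frame(protein_id = protein_id,
                         cleaved_bond_position = start - 1L,
                         p2 = res(start - 2L), p1 = res(start - 1L),
                         p1prime = res(start), p2prime = res(start + 1L),
                         weight = weight, terminus = "N",
                         stringsAsFactors = FALSE)
  if (end + 2L <= n) # C-terminal event: bond (end, end+1)
    rows$C <- data.frame(protein_id = protein_id,
                         cleaved_bond_position = end,
                         p2 = res(end - 1L), p1 = res(end),
                         p1prime = res(end + 1L), p2prime = res(end + 2L),
                         weight = weight, terminus = "C",
                         stringsAsFactors = FALSE)
  # the P2' of the N event (start+1) and P2 of the C event (end-1) always
  # exist because start <= end; only the outside residues can be missing
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(0),
                      cleaved_bond_position = integer(0),
                      p2 = character(0), p1 = character(0),
                      p1prime = character(0), p2prime = character(0),
                      weight = numeric(0), terminus = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cleavage events for a whole quantified peptidome
#'
#' Maps every peptide of a (filtered, normalized) [quant_table] to its
#' parent protein and extracts both terminal cleavage contexts, weighting
#' each event by the peptide's normalized area. Peptides that map to no
#' position, to multiple positions, or (when `proteins` are searched
#' globally) to multiple proteins are excluded by default, consistent with
#' the exclusion of shared peptides upstream; exclusions are reported.
#'
#' @param table A [quant_table]; areas should already be run-normalized.
#' @param proteins Named character vector of protein sequences (names =
#'   `protein_id`).
#' @param multi_mapping `"exclude"` (default) drops peptides with more than
#'   one exact match in their parent protein; `"all"` keeps every match,
#'   splitting the weight equally across matches.
#' @return Data frame of cleavage events (see [extract_contexts()]) with an
#'   extra `group` column.
#' @export
peptidome_cleavage_events <- function(table, proteins,
                                      multi_mapping = c("exclude", "all")) {
  multi_mapping <- match.arg(multi_mapping)
  stopifnot(inherits(table, "quant_table"))
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    stop("proteins must be a named character vector")
  missing_prot <- setdiff(unique(table$protein_id), names(proteins))
  if (length(missing_prot))
    stop("protein sequence(s) not supplied: ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  if (nrow(table) == 0L) stop("no cleavage events could be extracted")
  pseq <- unname(proteins[table$protein_id])
  loc <- stringi::stri_locate_all_fixed(pseq, table$peptide_seq,
                                        overlap = TRUE,
                                        omit_no_match = TRUE)
  nhits <- vapply(loc, nrow, integer(1))
  n_unmapped <- sum(nhits == 0L)
  n_multi <- sum(nhits > 1L)
  if (n_unmapped) warning(n_unmapped, " peptide record(s) did not map to ",
                          "their parent protein and were skipped")
  if (n_multi) message(n_multi, " peptide record(s) mapped to multiple ",
                       "positions (policy: ", multi_mapping, ")")
  keep <- if (multi_mapping == "exclude") nhits == 1L else nhits >= 1L
  if (!any(keep)) stop("no cleavage events could be extracted")
  idx <- rep(which(keep), nhits[keep]) # record index per mapped span
  locm <- do.call(rbind, loc[keep])
  s <- locm[, 1]
  e <- locm[, 2]
  pid <- table$protein_id[idx]
  grp <- table$group[idx]
  w <- table$area[idx] / nhits[idx] # weight split across multiple matches
  seqs <- unname(proteins[pid])
  n <- nchar(seqs)
  res <- function(i) {
    out <- substr(seqs, i, i)
    out[i < 1L | i > n] <- NA_character_
    out
  }
  # N-terminal event at bond (s-1, s); C-terminal event at bond (e, e+1)
  mk <- function(bond, p2, p1, p1p, p2p, terminus, ok)
    data.frame(protein_id = pid[ok], cleaved_bond_position = bond[ok],
               p2 = p2[ok], p1 = p1[ok], p1prime = p1p[ok],
               p2prime = p2p[ok], weight = w[ok], terminus = terminus,
               group = grp[ok], stringsAsFactors = FALSE)
  okN <- s >= 3L & s + 1L <= n
  okC <- e + 2L <= n & e >= 2L
  ev <- rbind(mk(s - 1L, res(s - 2L), res(s - 1L), res(s), res(s + 1L),
                 "N", okN),
              mk(e, res(e - 1L), res(e), res(e + 1L), res(e + 2L),
                 "C", okC))
  if (nrow(ev) == 0L) stop("no cleavage events could be extracted")
  rownames(ev) <- NULL
  ev
}

#' Observed terminome matrix of one sample group
#'
#' Pools weighted cleavage events into the observed 20x4 appearance
#' frequency matrix X_p: entry (i, p) is the abundance-weighted frequency of
#' amino acid i at position p over all cleavage sites witnessed by the
#' group's peptide termini. Columns are normalized to sum to 1, so the
#' result is invariant to rescaling all weights.
#'
#' @param events Data frame of cleavage events (columns `p2`, `p1`,
#'   `p1prime`, `p2prime`, `weight`, and `group` unless `group` is given).
#' @param group Group label; when `NULL` and `events$group` is present with
#'   a single level, that label is used.
#' @return Object of class `terminome_matrix`: list with `group`, `matrix`
#'   (20x4), `total_weight`.
#' @export
compute_terminome_matrix <- function(events, group = NULL) {
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("events must be a non-empty data frame")
  if (is.null(group)) {
    gl <- unique(events$group)
    if (length(gl) != 1L)
      stop("events span ", length(gl), " groups; pass `group` explicitly")
    group <- gl
  } else if (!is.null(events$group)) {
    events <- events[events$group == group, , drop = FALSE]
    if (nrow(events) == 0L) stop("no events for group '", group, "'")
  }
  tw <- sum(events$weight)
  if (tw <= 0) stop("total event weight is zero")
  m <- weighted_context_matrix(events$p2, events$p1, events$p1prime,
                               events$p2prime, events$weight)
  structure(list(group = group, matrix = m, total_weight = tw),
            class = "terminome_matrix")
}

#' @export
print.terminome_matrix <- function(x, ...) {
  cat("Terminome matrix for group:", x$group,
      "(total event weight", signif(x$total_weight, 6), ")\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write terminome matrices to long-format TSV
#'
#' Columns `group`, `position`, `residue`, `frequency`.
#'
#' @param tms List of `terminome_matrix` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_terminome_table <- function(tms, path) {
  if (inherits(tms, "terminome_matrix")) tms <- list(tms)
  rows <- lapply(tms, function(tm)
    data.frame(group = tm$group,
               position = rep(CONTEXT_POSITIONS, each = 20L),
               residue = rep(AA_ALPHABET, times = 4L),
               frequency = as.vector(tm$matrix),
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read terminome matrices from long-format TSV
#'
#' @param path TSV written by [write_terminome_table()].
#' @return List of `terminome_matrix`, one per group.
#' @export
read_terminome_table <- function(path) {
  if (!file.exists(path)) stop("terminome table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(unique(df$group), function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    m <- matrix(0, 20L, 4L, dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
    m[cbind(match(sub$residue, AA_ALPHABET),
            match(sub$position, CONTEXT_POSITIONS))] <- sub$frequency
    check_freq_matrix(m, tol = 1e-6, what = paste0("terminome '", g, "'"))
    m <- sweep(m, 2, colSums(m), "/")
    structure(list(group = g, matrix = m, total_weight = NA_real_),
              class = "terminome_matrix")
  })
}
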
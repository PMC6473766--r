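#' Quantified peptide table
#'
#' A `quant_table` is a validated data frame of quantified peptides, one row
#' per peptide observation in one run (a run = one sample group x one
#' replicate individual), emulating a DIA/SWATH peak-area export. Columns:
#'
#' * `peptide_seq` — amino-acid string over the canonical alphabet
#' * `protein_id` — parent protein identifier
#' * `group` — sample group label (e.g. `Decap`, `AirEx1`, ...)
#' * `replicate` — integer >= 1 within group
#' * `area` — nonnegative peak area (summed fragment-ion XICs)
#' * `confidence` — identification confidence in \[0, 1\]
#' * `shared` — logical, peptide attributed to more than one protein
#'
#' @param records Data frame with the columns above (`shared` may be 0/1).
#' @param groups Optional ordered group labels; defaults to order of first
#'   appearance.
#' @return The data frame with class `quant_table` and a `groups` attribute.
#' @export
quant_table <- function(records, groups = NULL) {
  need <- c("peptide_seq", "protein_id", "group", "replicate", "area",
            "confidence", "shared")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("quant table must have columns ", paste(need, collapse = ", "))
  records <- records[, need]
  records$shared <- as.logical(records$shared)
  if (nrow(records) > 0L) {
    if (!all(is_valid_aa(records$peptide_seq)))
      stop("peptide sequences must be non-empty over the 20-letter alphabet")
    if (any(records$area < 0)) stop("negative peptide areas")
    if (any(records$confidence < 0 | records$confidence > 1))
      stop("confidence must lie in [0, 1]")
    if (any(records$replicate < 1)) stop("replicate indices must be >= 1")
  }
  if (is.null(groups)) groups <- unique(records$group)
  structure(records, class = c("quant_table", "data.frame"),
            groups = groups)
}

#' Read a quantified peptide table from TSV
#'
#' @param path TSV with the `quant_table` columns (`shared` coded 0/1).
#' @return A [quant_table].
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  quant_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a quantified peptide table to TSV
#'
#' @param table A [quant_table].
#' @param path Output path; `shared` is serialized as 0/1.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  df <- as.data.frame(table)
  df$shared <- as.integer(df$shared)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter peptides by confidence and sharedness
#'
#' Removes shared peptides and peptides identified below the confidence
#' cutoff, mirroring standard DIA post-processing ("shared peptides and
#' peptides below 80% confidence excluded"). The cutoff is inclusive:
#' confidence exactly at `min_confidence` is retained.
#'
#' @param table A [quant_table].
#' @param min_confidence Minimum confidence retained, in \[0, 1\].
#'   Default 0.80.
#' @return A filtered [quant_table]; the input is not modified.
#' @export
filter_peptides <- function(table, min_confidence = 0.80) {
  stopifnot(inherits(table, "quant_table"),
            min_confidence >= 0, min_confidence <= 1)
  keep <- !table$shared & table$confidence >= min_confidence
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(table) > 0L)
    warning("all peptides removed by filtering")
  quant_table(as.data.frame(out), groups = attr(table, "groups"))
}

#' Normalize each run's areas to sum to 1
#'
#' Within every (group, replicate) run, areas are divided by the run total,
#' so each run's elements sum to 1. Idempotent; relative within-run ratios
#' are preserved.
#'
#' @param table A [quant_table].
#' @return The normalized [quant_table].
#' @export
normalize_runs <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (nrow(table) == 0L) return(table)
  run <- interaction(table$group, table$replicate, drop = TRUE)
  totals <- tapply(table$area, run, sum)
  if (any(totals <= 0))
    stop("run(s) with zero total area: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  table$area <- table$area / as.numeric(totals[run])
  table
}

#' Aggregate normalized peptide areas to per-protein group areas
#'
#' Per protein and run, peptide areas are summed to a protein area; per
#' protein and group, the protein area is the arithmetic mean of the
#' per-replicate protein areas (so a group's value does not scale with its
#' replicate count). Proteins absent from a run contribute 0 there.
#'
#' @param table A filtered, normalized [quant_table].
#' @return Data frame: `protein_id` plus one numeric area column per group,
#'   group columns in the table's group order.
#' @export
aggregate_protein_areas <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  groups <- attr(table, "groups")
  proteins <- unique(table$protein_id)
  out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- table[table$group == g, , drop = FALSE]
    reps <- unique(sub$replicate)
    acc <- numeric(length(proteins))
    for (r in reps) {
      rs <- sub[sub$replicate == r, , drop = FALSE]
      s <- tapply(rs$area, factor(rs$protein_id, levels = proteins), sum)
      s[is.na(s)] <- 0
      acc <- acc + as.numeric(s)
    }
    out[[g]] <- if (length(reps)) acc / length(reps) else 0
  }
  out
}

#' Fold changes of cleaved-protein areas against a reference group
#'
#' For each non-reference group, fold change = group area / reference area.
#' When the reference area is 0 the fold change is undefined (`NA`), not
#' infinite, and is excluded from significance. Significance is the strict
#' inequality fold change > `threshold`.
#'
#' @param areas Output of [aggregate_protein_areas()].
#' @param reference_group Name of the reference group column.
#' @param threshold Significance threshold (default 2.0).
#' @return Data frame with, per non-reference group `g`, columns `fc_<g>`
#'   (numeric, `NA` when undefined) and `sig_<g>` (logical).
#' @export
fold_changes <- function(areas, reference_group, threshold = 2.0) {
  stopifnot(is.data.frame(areas), threshold > 0)
  if (!reference_group %in% names(areas))
    stop("reference group '", reference_group, "' not present")
  groups <- setdiff(names(areas), c("protein_id", reference_group))
  ref <- areas[[reference_group]]
  out <- areas["protein_id"]
  for (g in groups) {
    fc <- ifelse(ref > 0, areas[[g]] / ref, NA_real_)
    out[[paste0("fc_", g)]] <- fc
    out[[paste0("sig_", g)]] <- !is.na(fc) & fc > threshold
  }
  out
}

#' Count significantly changed proteins per group
#'
#' Counts, per column of a protein x group fold-change matrix, the values
#' strictly greater than the threshold. `NA` (undefined) fold changes are
#' never counted. Monotone nonincreasing in `threshold`.
#'
#' @param fc Data frame or matrix of fold-change values (non-numeric columns
#'   such as `protein_id` are ignored).
#' @param threshold Strict threshold (default 2.0).
#' @return Named integer vector, one count per fold-change column.
#' @examples
#' path <- system.file("extdata", "fish_muscle_fold_changes.tsv",
#'                     package = "terminomix")
#' count_significant(utils::read.delim(path))  # AirEx1_Decap count is 19
#' @export
count_significant <- function(fc, threshold = 2.0) {
  df <- as.data.frame(fc)
  num <- vapply(df, is.numeric, logical(1))
  vapply(df[num], function(v) sum(!is.na(v) & v > threshold), integer(1))
}

#' Render a textual peptide coverage map of a protein
#'
#' Annotates each residue of a protein with the best confidence tier of any
#' covering peptide: tier 1 (`#`) confidence >= 0.95, tier 2 (`+`) in
#' \[0.50, 0.95), tier 3 (`.`) < 0.50, uncovered (`-`). Where peptides of
#' different tiers overlap, the best tier wins. Peptides that do not map to
#' the protein are skipped with a warning.
#'
#' @param protein_seq Protein sequence string.
#' @param peptides Data frame with columns `peptide_seq` and `confidence`.
#' @param width Residues per output line (default 60).
#' @return Character string of interleaved sequence/coverage lines, with a
#'   `tiers` attribute holding the per-residue tier (1-3, 4 = uncovered).
#' @export
render_peptide_map <- function(protein_seq, peptides, width = 60L) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  n <- nchar(protein_seq)
  tier <- rep(4L, n) # 4 = uncovered
  sym <- c("#", "+", ".", "-")
  if (nrow(peptides) > 0L) for (i in seq_len(nrow(peptides))) {
    hits <- map_peptide(protein_seq, peptides$peptide_seq[i])
    if (nrow(hits) == 0L) {
      warning("peptide '", peptides$peptide_seq[i],
              "' does not map to the protein; skipped")
      next
    }
    conf <- peptides$confidence[i]
    t <- if (conf >= 0.95) 1L else if (conf >= 0.50) 2L else 3L
    for (h in seq_len(nrow(hits))) {
      span <- hits$start[h]:hits$end[h]
      tier[span] <- pmin(tier[span], t)
    }
  }
  lines <- character(0)
  for (off in seq(1L, n, by = width)) {
    to <- min(off + width - 1L, n)
    lines <- c(lines,
               sprintf("%6d %s", off, substr(protein_seq, off, to)),
               sprintf("       %s",
                       paste(sym[tier[off:to]], collapse = "")))
  }
  structure(paste(lines, collapse = "\n"), tiers = tier)
}

#' Packaged example fold-change table
#'
#' A published quantitative-peptidomics result: fold changes of 135 cleaved
#' proteins in fish (jack mackerel) skeletal muscle under air-exposure
#' stress, three experimental groups (AirEx1, AirEx5, AirEx10) each relative
#' to a decapitated control (Decap). Used as a worked example for
#' [count_significant()].
#'
#' @return Data frame with columns `protein`, `AirEx1_Decap`, `AirEx5_Decap`,
#'   `AirEx10_Decap`.
#' @export
example_fold_changes <- function() {
  utils::read.delim(system.file("extdata", "fish_muscle_fold_changes.tsv",
                                package = "terminomix", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
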
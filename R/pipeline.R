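#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector (first whitespace-delimited token of each
#'   header is the protein id).
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Paths and thresholds for [run_pipeline()]. A JSON file with the same
#' field names can be loaded with `pipeline_config_from_json()`; flags given
#' on the command line override file values.
#'
#' @param proteins Path to the protein FASTA.
#' @param peptides Path to the quantified peptide TSV.
#' @param specificity Path to the protease specificity TSV.
#' @param out_dir Output directory (created if absent).
#' @param reference_group Reference group for fold changes.
#' @param fold_change_threshold Strict significance threshold (default 2.0).
#' @param min_confidence Peptide confidence cutoff, inclusive
#'   (default 0.80).
#' @param multi_mapping Policy for multiply mapping peptides
#'   (`"exclude"`/`"all"`).
#' @param seed Seed recorded in the run manifest.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, peptides, specificity, out_dir,
                            reference_group, fold_change_threshold = 2.0,
                            min_confidence = 0.80,
                            multi_mapping = "exclude", seed = 1L) {
  stopifnot(fold_change_threshold > 0,
            min_confidence >= 0, min_confidence <= 1)
  for (p in c(proteins, peptides, specificity))
    if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(proteins = proteins, peptides = peptides,
                 specificity = specificity, out_dir = out_dir,
                 reference_group = reference_group,
                 fold_change_threshold = fold_change_threshold,
                 min_confidence = min_confidence,
                 multi_mapping = multi_mapping, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file whose fields mirror the `pipeline_config()`
#'   arguments.
#' @param overrides Named list of fields overriding the file's values.
#' @export
pipeline_config_from_json <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full terminome analysis pipeline
#'
#' Executes, in order: peptide filtering, per-run normalization,
#' protein-area aggregation and fold changes against the reference group,
#' cleavage-context extraction, per-group terminome matrices,
#' simplex-constrained contribution fitting against the specificity panel,
#' cross-group log normalization, and TSV exports. A JSON run manifest
#' (package version, seed, config, file list) is written alongside the
#' outputs; reruns with identical inputs produce identical outputs.
#'
#' @param config A [pipeline_config].
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, a list with the in-memory results (`quant`,
#'   `protein_areas`, `fold_changes`, `terminomes`, `contributions`,
#'   `normalized`) and `files` (paths written).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[terminomix] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  proteins <- stage("load inputs", {
    read_proteins(config$proteins)
  })
  qt <- stage("read peptide quantification",
              read_quant_table(config$peptides))
  panel <- stage("load specificity panel",
                 load_specificity_table(config$specificity))
  qt <- stage("filter peptides",
              filter_peptides(qt, config$min_confidence))
  qt <- stage("normalize runs", normalize_runs(qt))
  areas <- stage("aggregate protein areas", aggregate_protein_areas(qt))
  fc <- stage("fold changes", {
    x <- fold_changes(areas, config$reference_group,
                      config$fold_change_threshold)
    utils::write.table(x, out("fold_changes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    x
  })
  ev <- stage("extract cleavage contexts",
              peptidome_cleavage_events(qt, proteins,
                                        config$multi_mapping))
  groups <- attr(qt, "groups")
  tms <- stage("terminome matrices", {
    x <- lapply(groups, function(g) compute_terminome_matrix(ev, g))
    write_terminome_table(x, out("terminome_matrices.tsv"))
    x
  })
  contribs <- stage("fit protease contributions", {
    x <- lapply(tms, function(tm) fit_contributions(tm, panel))
    df <- do.call(rbind, lapply(x, function(cv)
      data.frame(group = cv$group, protease_id = cv$protease_ids,
                 f = cv$f, Z = cv$objective_Z,
                 stringsAsFactors = FALSE)))
    utils::write.table(df, out("contributions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    x
  })
  norm <- stage("normalize across groups", {
    x <- normalize_contributions(contribs)
    export_heatmap(x, out("contributions_normalized.tsv"))
    x
  })
  files <- c("fold_changes.tsv", "terminome_matrices.tsv",
             "contributions.tsv", "contributions_normalized.tsv")
  stage("write manifest", {
    manifest <- list(
      package = "terminomix",
      version = as.character(utils::packageVersion("terminomix")),
      seed = config$seed,
      config = unclass(config),
      outputs = files,
      n_peptides_used = nrow(qt),
      groups = groups)
    jsonlite::write_json(manifest, out("run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  say("done; outputs in ", config$out_dir)
  invisible(list(quant = qt, protein_areas = areas, fold_changes = fc,
                 terminomes = tms, contributions = contribs,
                 normalized = norm,
                 files = file.path(config$out_dir,
                                   c(files, "run_manifest.json"))))
}
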
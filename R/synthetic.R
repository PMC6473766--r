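#' Configuration of a synthetic digestion experiment
#'
#' Describes the ground-truth world the simulator emulates: a proteome
#' digested by a panel of proteases with known per-group contribution
#' weights `f_star`, observed as a quantified peptidome with a 4-group x
#' 3-replicate design and log-normal abundance noise. Defaults mirror a
#' small air-exposure stress study on fish skeletal muscle (groups Decap,
#' AirEx1, AirEx5, AirEx10; three individuals per group).
#'
#' @param seed Master seed; every stream is derived from it.
#' @param n_proteins Number of proteins in the proteome.
#' @param protein_length_range Integer pair, lengths drawn uniformly.
#' @param n_proteases Panel size N.
#' @param specificity_concentration Symmetric Dirichlet concentration for
#'   each position column of each specificity matrix. Small values (0.05)
#'   give sharp, nearly one-hot specificities; large values approach the
#'   uniform column.
#' @param groups Ordered group labels.
#' @param replicates Individuals per group; each (group, replicate) is one
#'   quantification run.
#' @param f_star Ground-truth contribution matrix (n_proteases x groups,
#'   columns on the simplex), or `NULL` to draw one flat-Dirichlet vector
#'   per group from the master seed.
#' @param n_events_per_group Cleavage sites sampled per group.
#' @param abundance_noise_sigma Log-normal sigma of the multiplicative
#'   abundance noise (0 = noiseless).
#' @param fragment_length_range Peptide lengths emitted, mimicking a 5 kDa
#'   molecular-weight-cutoff peptidome window (default 5-30 residues).
#' @param residue_composition Optional length-20 probability vector over
#'   [AA_ALPHABET] for proteome composition; default uniform.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 12000L,
                       protein_length_range = c(100L, 300L),
                       n_proteases = 5L,
                       specificity_concentration = 0.05,
                       groups = c("Decap", "AirEx1", "AirEx5", "AirEx10"),
                       replicates = 3L,
                       f_star = NULL,
                       n_events_per_group = 20000L,
                       abundance_noise_sigma = 0.2,
                       fragment_length_range = c(5L, 30L),
                       residue_composition = NULL) {
  stopifnot(length(protein_length_range) == 2L,
            protein_length_range[1] >= 20L,
            protein_length_range[1] <= protein_length_range[2],
            n_proteins >= 1L, n_proteases >= 1L,
            specificity_concentration > 0,
            n_events_per_group >= 1L, abundance_noise_sigma >= 0,
            replicates >= 1L, length(groups) >= 1L,
            fragment_length_range[1] >= 2L,
            fragment_length_range[1] <= fragment_length_range[2])
  if (is.null(residue_composition)) residue_composition <- rep(1 / 20, 20)
  stopifnot(length(residue_composition) == 20L,
            abs(sum(residue_composition) - 1) < 1e-9)
  if (!is.null(f_star)) {
    f_star <- as.matrix(f_star)
    stopifnot(nrow(f_star) == n_proteases, ncol(f_star) == length(groups),
              all(f_star >= 0), all(abs(colSums(f_star) - 1) < 1e-9))
    colnames(f_star) <- groups
  } else {
    set.seed(derive_seed(seed, 97L))
    f_star <- matrix(stats::rgamma(n_proteases * length(groups), 1), # flat Dirichlet
                     n_proteases, dimnames = list(NULL, groups))
    f_star <- sweep(f_star, 2, colSums(f_star), "/")
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 n_proteases = as.integer(n_proteases),
                 specificity_concentration = specificity_concentration,
                 groups = groups, replicates = as.integer(replicates),
                 f_star = f_star,
                 n_events_per_group = as.integer(n_events_per_group),
                 abundance_noise_sigma = abundance_noise_sigma,
                 fragment_length_range = as.integer(fragment_length_range),
                 residue_composition = residue_composition),
            class = "sim_config")
}

# Deterministic 31-bit sub-seed from a master seed and a stream offset.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %%
               2147483647) + 1L
}

#' Generate a random proteome
#'
#' Sequences are i.i.d. over the configured residue composition (uniform by
#' default), lengths uniform in `protein_length_range`. Reproducible for a
#' fixed config seed.
#'
#' @param cfg A [sim_config].
#' @return Named character vector of protein sequences
#'   (`protein_001`, ...).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  len_choices <- seq.int(cfg$protein_length_range[1],
                         cfg$protein_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), cfg$n_proteins,
                                 replace = TRUE)]
  big <- paste(sample(AA_ALPHABET, sum(lens), replace = TRUE,
                      prob = cfg$residue_composition), collapse = "")
  offset <- c(0L, cumsum(lens))
  seqs <- substring(big, offset[-length(offset)] + 1L, offset[-1])
  names(seqs) <- sprintf("protein_%05d", seq_len(cfg$n_proteins))
  seqs
}

#' Generate a panel of random protease specificity matrices
#'
#' Each position column of each matrix is drawn from a symmetric
#' Dirichlet(`specificity_concentration`): small concentrations give sharp,
#' well-separated specificities, large ones approach uniform.
#'
#' @param cfg A [sim_config].
#' @return List of [specificity_matrix] (`protease_01`, ...).
#' @export
generate_protease_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  lapply(seq_len(cfg$n_proteases), function(k) {
    m <- matrix(0, 20L, 4L, dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
    for (j in 1:4) {
      repeat { # guard against full-column gamma underflow at tiny shape
        col <- stats::rgamma(20L, shape = cfg$specificity_concentration)
        if (sum(col) > 0) break
      }
      m[, j] <- col / sum(col)
    }
    specificity_matrix(sprintf("protease_%02d", k), m)
  })
}

#' Sample cleavage events directly from a specificity matrix
#'
#' Draws `n` cleavage contexts with residues at P2, P1, P1', P2'
#' independently distributed per the matrix's position columns — the
#' sampling distribution that [build_specificity_from_cleavages()] inverts
#' (law of large numbers: the rebuilt matrix converges to the source).
#'
#' @param sm A [specificity_matrix].
#' @param n Number of events.
#' @param weights Event weights (recycled; default 1).
#' @return Cleavage-event data frame (columns `p2`, `p1`, `p1prime`,
#'   `p2prime`, `weight`).
#' @export
sample_cleavage_events <- function(sm, n, weights = 1) {
  stopifnot(inherits(sm, "specificity_matrix"), n >= 1)
  draw <- function(j) AA_ALPHABET[sample.int(20L, n, replace = TRUE,
                                             prob = sm$matrix[, j])]
  data.frame(p2 = draw(1), p1 = draw(2), p1prime = draw(3),
             p2prime = draw(4), weight = rep_len(weights, n),
             stringsAsFactors = FALSE)
}

#' Simulate digestion of a proteome by a protease panel
#'
#' Implements the generative model behind terminome deconvolution: the
#' observed terminome is a mixture of the panel's cleavage-context
#' distributions with weights `f_star`. Per group, each of the
#' `n_events_per_group` events is one peptide delimited by two cleavage
#' sites: a protease is drawn from `f_star` independently for each
#' terminus, and the site's context residues (P2, P1, P1', P2') are drawn
#' from that protease's specificity columns — the limiting distribution of
#' choosing bonds of an ever-larger random proteome with probability
#' proportional to the product of X_k frequencies. Every event's site pair
#' is implanted at its own location in the proteome scaffold (fragment
#' length uniform within `fragment_length_range`), so the returned FASTA,
#' peptide table and ground truth are mutually consistent and both termini
#' of every peptide are genuine mixture-drawn cleavage sites. Peptide
#' areas are 1 x LogNormal(0, sigma^2); events are assigned to replicates
#' cyclically; confidence is 1.0 and shared is FALSE.
#'
#' @param proteome Named character vector from [generate_proteome()]; it
#'   must be large enough to host one 9-34 residue template per event
#'   (`sim_capacity()` reports the capacity).
#' @param panel List of [specificity_matrix] from
#'   [generate_protease_panel()].
#' @param cfg A [sim_config].
#' @return List with `quant` (a [quant_table]), `proteome` (the input
#'   sequences with implanted site contexts — use this, not the input, for
#'   downstream mapping), and `truth` (list: `f_star` and an `events`
#'   audit data frame with group, terminal proteases, protein, bond
#'   positions and weight 1 per event).
#' @export
simulate_digestion <- function(proteome, panel, cfg) {
  stopifnot(inherits(cfg, "sim_config"), length(panel) == cfg$n_proteases)
  N <- length(panel)
  minlen <- cfg$fragment_length_range[1]
  maxlen <- cfg$fragment_length_range[2]
  lens <- nchar(proteome)
  if (any(lens < minlen + 8L))
    stop("protein(s) too short for any valid fragment")

  ## -- allocate one template slot per event -------------------------------
  n_total <- cfg$n_events_per_group * length(cfg$groups)
  set.seed(derive_seed(cfg$seed, 3L))
  # tile each protein with non-overlapping slots [t, t + len + 3] plus one
  # spacer residue; slot lengths are drawn per protein in one batch
  acc <- vector("list", length(proteome))
  n_acc <- 0L
  for (j in seq_along(proteome)) {
    cap <- lens[j] %/% (minlen + 5L) + 1L
    ln <- sample.int(maxlen - minlen + 1L, cap, replace = TRUE) +
      minlen - 1L
    ts <- 1L + cumsum(c(0L, utils::head(ln, -1L) + 5L))
    ok <- ts + ln + 3L <= lens[j]
    acc[[j]] <- cbind(j, ts[ok], ln[ok])
    n_acc <- n_acc + sum(ok)
    if (n_acc >= n_total) break
  }
  if (n_acc < n_total)
    stop("proteome can host only ", n_acc, " cleavage-site templates ",
         "but ", n_total, " events are requested; increase n_proteins ",
         "(see sim_capacity())")
  tpl <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  tpl_protein <- tpl[seq_len(n_total), 1]
  tpl_t <- tpl[seq_len(n_total), 2]
  tpl_len <- tpl[seq_len(n_total), 3]

  ## -- draw proteases and contexts per group, implant --------------------
  offset <- c(0L, cumsum(lens))[seq_along(lens)] # per-protein offset in the
  big <- strsplit(paste(unname(proteome), collapse = ""), "")[[1]]
  ids <- vapply(panel, function(sm) sm$protease_id, character(1))
  quant <- vector("list", length(cfg$groups))
  audit <- vector("list", length(cfg$groups))
  draw_ctx <- function(k_of_event, col) {
    # residues at one context position for all events, protease-stratified
    out <- integer(length(k_of_event))
    for (k in seq_len(N)) {
      idx <- which(k_of_event == k)
      if (length(idx))
        out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                               prob = panel[[k]]$matrix[, col])
    }
    out
  }
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[gi]
    set.seed(derive_seed(cfg$seed, 10L + gi))
    n <- cfg$n_events_per_group
    sel <- ((gi - 1L) * n + 1L):(gi * n) # this group's template slots
    fs <- cfg$f_star[, gi]
    e1 <- sample.int(N, n, replace = TRUE, prob = fs)
    e2 <- sample.int(N, n, replace = TRUE, prob = fs)
    gpos <- offset[tpl_protein[sel]] + tpl_t[sel] # global P2 position
    glen <- tpl_len[sel]
    for (col in 1:4) { # start-site context at t .. t+3
      big[gpos + col - 1L] <- AA_ALPHABET[draw_ctx(e1, col)]
      big[gpos + glen + col - 1L] <- AA_ALPHABET[draw_ctx(e2, col)]
    }
    area <- stats::rlnorm(n, 0, cfg$abundance_noise_sigma)
    quant[[gi]] <- data.frame(
      protein_id = names(proteome)[tpl_protein[sel]],
      group = g,
      replicate = rep_len(seq_len(cfg$replicates), n),
      area = area, confidence = 1.0, shared = FALSE,
      start = tpl_t[sel] + 2L, end = tpl_t[sel] + glen + 1L,
      stringsAsFactors = FALSE)
    audit[[gi]] <- data.frame(
      group = g, protease_start = ids[e1], protease_end = ids[e2],
      protein_id = names(proteome)[tpl_protein[sel]],
      start_bond = tpl_t[sel] + 1L, end_bond = tpl_t[sel] + glen + 1L,
      weight = 1, stringsAsFactors = FALSE)
  }
  bigstr <- paste(big, collapse = "")
  proteome_out <- substring(bigstr, offset + 1L, offset + lens)
  names(proteome_out) <- names(proteome)
  qdf <- do.call(rbind, quant)
  qdf$peptide_seq <- substr(proteome_out[qdf$protein_id], qdf$start,
                            qdf$end)
  qdf$start <- qdf$end <- NULL
  list(quant = quant_table(qdf, groups = cfg$groups),
       proteome = proteome_out,
       truth = list(f_star = cfg$f_star, events = do.call(rbind, audit)))
}

#' Number of cleavage-site templates a proteome can host
#'
#' Upper bound used by [simulate_digestion()]'s capacity check; the total
#' events across groups must not exceed it.
#'
#' @param proteome Named character vector of sequences.
#' @param cfg A [sim_config] (for the fragment length range).
#' @return Integer: expected hostable template count (approximate).
#' @export
sim_capacity <- function(proteome, cfg) {
  pitch <- mean(cfg$fragment_length_range) + 5
  sum(pmax(0, floor((nchar(proteome) - 4) / pitch)))
}

#' Write the ground-truth contribution sidecar
#'
#' @param truth The `truth` element of [simulate_digestion()] output.
#' @param path Output TSV (columns group, protease_id, f_star).
#' @param panel The protease panel (for identifiers).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, panel, path) {
  ids <- vapply(panel, function(sm) sm$protease_id, character(1))
  df <- data.frame(group = rep(colnames(truth$f_star), each = length(ids)),
                   protease_id = rep(ids, times = ncol(truth$f_star)),
                   f_star = as.vector(truth$f_star),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end contribution recovery experiment
#'
#' For each seed: generate a fresh proteome and protease panel, simulate a
#' digestion with known `f_star`, run the full analysis pipeline (peptide
#' filtering, run normalization, peptide mapping, terminal context
#' extraction, per-group terminome matrices, simplex-constrained fitting)
#' and compare the fitted contributions to the truth.
#'
#' @param cfg A [sim_config]; its seed anchors the first replicate world.
#' @param n_seeds Number of independent simulated worlds.
#' @return List with `per_group` (data frame: seed, group, rmse, spearman),
#'   `mean_rmse`, `mean_spearman`.
#' @export
recovery_experiment <- function(cfg, n_seeds = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  res <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 1000L + i)
    # fresh f_star per world unless the config pinned one explicitly
    set.seed(derive_seed(cfg_i$seed, 97L))
    fsm <- matrix(stats::rgamma(cfg$n_proteases * length(cfg$groups), 1),
                  cfg$n_proteases, dimnames = list(NULL, cfg$groups))
    cfg_i$f_star <- sweep(fsm, 2, colSums(fsm), "/")
    proteome <- generate_proteome(cfg_i)
    panel <- generate_protease_panel(cfg_i)
    sim <- simulate_digestion(proteome, panel, cfg_i)
    qt <- normalize_runs(filter_peptides(sim$quant))
    ev <- suppressMessages(peptidome_cleavage_events(qt, sim$proteome))
    res[[i]] <- do.call(rbind, lapply(seq_along(cfg$groups), function(gi) {
      g <- cfg$groups[gi]
      xp <- compute_terminome_matrix(ev, group = g)
      fit <- fit_contributions(xp, panel)
      fstar <- cfg_i$f_star[, gi]
      data.frame(seed = cfg_i$seed, group = g,
                 rmse = sqrt(mean((fit$f - fstar)^2)),
                 spearman = stats::cor(fit$f, fstar, method = "spearman"),
                 stringsAsFactors = FALSE)
    }))
  }
  per_group <- do.call(rbind, res)
  list(per_group = per_group, mean_rmse = mean(per_group$rmse),
       mean_spearman = mean(per_group$spearman))
}
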
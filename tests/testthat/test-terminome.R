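test_that("map_peptide reports all occurrences, including overlaps", {
  expect_equal(map_peptide("MKLVTAGW", "LVTA"),
               data.frame(start = 3L, end = 6L))
  expect_equal(map_peptide("AAA", "AA"),
               data.frame(start = c(1L, 2L), end = c(2L, 3L)))
  expect_identical(nrow(map_peptide("MKLVTAGW", "WWW")), 0L)
})

test_that("extract_contexts follows the Schechter-Berger convention", {
  prot <- "MKLVTAGW"
  ev <- extract_contexts(prot, 3, 6, weight = 2, protein_id = "p")
  expect_identical(nrow(ev), 2L)
  n <- ev[ev$terminus == "N", ]
  expect_identical(unlist(n[c("p2", "p1", "p1prime", "p2prime")],
                          use.names = FALSE), c("M", "K", "L", "V"))
  expect_identical(n$cleaved_bond_position, 2L)
  c_ <- ev[ev$terminus == "C", ]
  expect_identical(unlist(c_[c("p2", "p1", "p1prime", "p2prime")],
                          use.names = FALSE), c("T", "A", "G", "W"))
  expect_identical(c_$cleaved_bond_position, 6L)
  expect_identical(ev$weight, c(2, 2))

  # truncated contexts are dropped, not padded
  ev14 <- extract_contexts(prot, 1, 4)
  expect_identical(ev14$terminus, "C")
  evfull <- extract_contexts(prot, 1, nchar(prot))
  expect_identical(nrow(evfull), 0L)
  expect_error(extract_contexts(prot, 0, 4), "outside")
  expect_error(extract_contexts(prot, 3, 99), "outside")
})

test_that("compute_terminome_matrix gives weighted frequencies per column", {
  ev1 <- data.frame(p2 = "A", p1 = "K", p1prime = "L", p2prime = "V",
                    weight = 1, group = "G")
  tm <- compute_terminome_matrix(ev1)
  expect_identical(tm$group, "G")
  expect_equal(tm$matrix["A", "P2"], 1)
  expect_equal(sum(tm$matrix == 1), 4)

  ev2 <- data.frame(p2 = "A", p1 = c("K", "R"), p1prime = "L",
                    p2prime = "V", weight = c(0.25, 0.75), group = "G")
  tm2 <- compute_terminome_matrix(ev2)
  expect_equal(tm2$matrix["K", "P1"], 0.25)
  expect_equal(tm2$matrix["R", "P1"], 0.75)

  # weight-scale invariance
  ev2b <- ev2
  ev2b$weight <- ev2$weight * 2
  expect_equal(compute_terminome_matrix(ev2b)$matrix, tm2$matrix)

  expect_error(compute_terminome_matrix(ev1[0, ]), "non-empty")
  ev0 <- ev1
  ev0$weight <- 0
  expect_error(compute_terminome_matrix(ev0), "zero")
})

test_that("a sampled two-protease mixture reproduces the mixture matrix", {
  set.seed(33)
  x1 <- rand_spec("x1", 0.2)
  x2 <- rand_spec("x2", 0.2)
  n <- 50000
  n1 <- stats::rbinom(1, n, 0.3)
  ev <- rbind(sample_cleavage_events(x1, n1),
              sample_cleavage_events(x2, n - n1))
  ev$group <- "G"
  tm <- compute_terminome_matrix(ev)
  expect_lt(max(abs(tm$matrix - (0.3 * x1$matrix + 0.7 * x2$matrix))),
            0.02)
})

test_that("peptidome events pool into a valid group matrix end to end", {
  # tiny hand-built world: one protein, two peptides per group
  prot <- c(p1 = "MKLVTAGWQRSTANDYKEVW")
  qt <- quant_table(qt_df(
    peptide_seq = c("LVTA", "STAND", "LVTA", "TAGWQ"),
    protein_id = "p1",
    group = c("A", "A", "B", "B"),
    replicate = 1L,
    area = c(2, 2, 1, 3)))
  qt <- normalize_runs(qt)
  ev <- peptidome_cleavage_events(qt, prot)
  expect_true(all(ev$weight > 0))
  for (g in c("A", "B")) {
    tm <- compute_terminome_matrix(ev, group = g)
    expect_true(all(tm$matrix >= 0))
    expect_equal(unname(colSums(tm$matrix)), rep(1, 4), tolerance = 1e-9)
  }
  # multi-mapping peptides are excluded under the default policy
  prot2 <- c(p1 = "AAKLVWAAKLVWDDDDDDAA")
  qt2 <- quant_table(qt_df(peptide_seq = c("AKLVW", "DDDDDD"),
                           protein_id = "p1", group = "A",
                           area = c(1, 1)))
  expect_message(ev2 <- peptidome_cleavage_events(qt2, prot2),
                 "multiple positions")
  expect_true(all(ev2$cleaved_bond_position >= 12)) # only DDDDDD's events
  ev3 <- suppressMessages(
    peptidome_cleavage_events(qt2, prot2, multi_mapping = "all"))
  expect_gt(nrow(ev3), nrow(ev2))
})

test_that("terminome tables round-trip through the long TSV dialect", {
  set.seed(5)
  tms <- lapply(c("G1", "G2"), function(g) {
    ev <- sample_cleavage_events(rand_spec(), 200)
    ev$group <- g
    compute_terminome_matrix(ev)
  })
  path <- tempfile(fileext = ".tsv")
  write_terminome_table(tms, path)
  back <- read_terminome_table(path)
  expect_identical(vapply(back, `[[`, "", "group"), c("G1", "G2"))
  expect_equal(back[[2]]$matrix, tms[[2]]$matrix, tolerance = 1e-9)
})

test_that("single-protease digests converge to the protease's matrix", {
  cfg <- sim_config(seed = 9, n_proteins = 900, n_proteases = 2,
                    groups = "G", replicates = 1,
                    f_star = matrix(c(1, 0)),
                    abundance_noise_sigma = 0,
                    n_events_per_group = 5000)
  proteome <- generate_proteome(cfg)
  panel <- generate_protease_panel(cfg)
  sim <- simulate_digestion(proteome, panel, cfg)
  qt <- normalize_runs(sim$quant)
  ev <- suppressMessages(peptidome_cleavage_events(qt, sim$proteome))
  tm <- compute_terminome_matrix(ev, "G")
  expect_lt(max(abs(tm$matrix - panel[[1]]$matrix)), 0.03)
})
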
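test_that("degenerate and exact-member fits are solved to tolerance", {
  set.seed(21)
  x1 <- rand_spec("x1")
  x2 <- rand_spec("x2")
  # N = 1: the constraint forces f = 1
  f1 <- fit_contributions(x2$matrix, list(x1))
  expect_equal(f1$f, 1)
  expect_equal(f1$objective_Z, sum((x1$matrix - x2$matrix)^2),
               tolerance = 1e-12)
  # X_p equal to one dictionary member
  f2 <- fit_contributions(x2$matrix, list(x1, x2))
  expect_equal(f2$f, c(0, 1), tolerance = 1e-8)
  expect_lt(f2$objective_Z, 1e-12)
})

test_that("exact mixtures are recovered and dominate the grid oracle", {
  set.seed(22)
  x1 <- rand_spec("x1")
  x2 <- rand_spec("x2")
  xp <- 0.3 * x1$matrix + 0.7 * x2$matrix
  fit <- fit_contributions(xp, list(x1, x2))
  expect_equal(fit$f, c(0.3, 0.7), tolerance = 1e-6)
  expect_lt(fit$objective_Z, 1e-10)
  g <- grid_oracle(xp, list(x1, x2), step = 0.01)
  expect_lte(fit$objective_Z, g$Z + 1e-8)
})

test_that("grid oracle enumerates the simplex lattice exactly", {
  set.seed(23)
  xks <- list(rand_spec("a"), rand_spec("b"))
  xp <- rand_freq()
  expect_identical(grid_oracle(xp, xks, step = 0.5)$n_points, 3L)
  xks3 <- c(xks, list(rand_spec("c")))
  expect_identical(grid_oracle(xp, xks3, step = 0.1)$n_points, 66L)
  expect_error(grid_oracle(xp, xks3, step = 0.001, max_points = 1000),
               "budget")
  expect_error(grid_oracle(xp, xks, step = 0.3), "divide")
})

test_that("fitted contributions always satisfy the simplex constraints", {
  set.seed(24)
  for (i in 1:20) {
    N <- sample(2:6, 1)
    xks <- lapply(seq_len(N), function(k)
      rand_spec(paste0("p", k), concentration = stats::runif(1, 0.1, 1)))
    fit <- fit_contributions(rand_freq(), xks)
    expect_equal(sum(fit$f), 1, tolerance = 1e-9)
    expect_true(all(fit$f >= 0))
    expect_gte(fit$objective_Z, 0)
  }
})

test_that("the fit is permutation-equivariant in the dictionary order", {
  set.seed(25)
  xks <- lapply(1:4, function(k) rand_spec(paste0("p", k)))
  xp <- rand_freq()
  fit <- fit_contributions(xp, xks)
  perm <- c(3, 1, 4, 2)
  fitp <- fit_contributions(xp, xks[perm])
  expect_equal(fitp$f, fit$f[perm], tolerance = 1e-8)
  expect_equal(fitp$objective_Z, fit$objective_Z, tolerance = 1e-10)
})

test_that("near-identical dictionary members trigger a collinearity warning", {
  set.seed(26)
  x1 <- rand_spec("dup1")
  x2 <- specificity_matrix("dup2", x1$matrix)
  expect_warning(fit <- fit_contributions(rand_freq(), list(x1, x2)),
                 "dup1 ~ dup2")
  expect_equal(sum(fit$f), 1, tolerance = 1e-9)
})

test_that("cross-group normalization matches its closed forms", {
  N <- 45
  ids <- sprintf("p%02d", 1:N)
  mk <- function(g, f) structure(list(group = g, protease_ids = ids,
                                      f = f, objective_Z = 0),
                                 class = "contribution_vector")
  # 4 groups of uniform f: every cell log10(1/4)
  u <- lapply(c("g1", "g2", "g3", "g4"), mk, f = rep(1 / N, N))
  norm <- normalize_contributions(u)
  expect_equal(unname(as.vector(norm$fprime)),
               rep(log10(0.25), N * 4), tolerance = 1e-9)
  # single group, f = e1: first cell log10(N), others masked
  e1 <- c(1, rep(0, N - 1))
  n1 <- normalize_contributions(list(mk("g1", e1)))
  expect_equal(n1$fprime[1, 1], log10(45), tolerance = 1e-9)
  expect_true(all(is.na(n1$fprime[-1, 1])))
  # N f invariance: doubling N with f halved leaves f' unchanged
  ids2 <- sprintf("q%02d", 1:(2 * N))
  mk2 <- function(g, f) structure(list(group = g, protease_ids = ids2,
                                       f = f, objective_Z = 0),
                                  class = "contribution_vector")
  u2 <- lapply(c("g1", "g2", "g3", "g4"), mk2, f = rep(1 / (2 * N), 2 * N))
  expect_equal(normalize_contributions(u2)$fprime[1, 1],
               norm$fprime[1, 1], tolerance = 1e-12)

  expect_error(normalize_contributions(list()), "no contribution")
  expect_error(normalize_contributions(list(mk("a", rep(1 / N, N)),
                                            mk2("b", rep(1 / 90, 90)))),
               "same proteases")
})

test_that("heatmap export writes masked TSV that round-trips", {
  ids <- c("pA", "pB")
  mk <- function(g, f) structure(list(group = g, protease_ids = ids,
                                      f = f, objective_Z = 0),
                                 class = "contribution_vector")
  norm <- normalize_contributions(list(mk("g1", c(1, 0)),
                                       mk("g2", c(0.4, 0.6))))
  path <- tempfile(fileext = ".tsv")
  export_heatmap(norm, path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_identical(dim(raw), c(2L, 3L))
  expect_true(is.na(raw$g1[2])) # masked f = 0 cell
  back <- read_heatmap_table(path)
  expect_equal(back$g2, norm$fprime[, "g2"], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$g1[1], norm$fprime[1, "g1"], tolerance = 1e-5)
  # optional raster rendering
  png_path <- tempfile(fileext = ".png")
  export_heatmap(norm, tempfile(fileext = ".tsv"), png = png_path)
  expect_true(file.exists(png_path))
})
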
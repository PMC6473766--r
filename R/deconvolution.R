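#' Decompose an observed terminome into protease contributions
#'
#' Fits the observed 20x4 terminome matrix X_p of a sample group as a convex
#' combination of protease specificity matrices X_k: the contribution vector
#' f minimizes
#'
#'   Z(f) = sum over all 80 cells of ( sum_k f_k X_k(i,p) - X_p(i,p) )^2
#'
#' subject to sum(f) = 1 and f >= 0. Each f_k is a composite of protease
#' amount, activity and specificity overlap; it indexes proteolytic
#' regulation but is not an activity measurement.
#'
#' The problem is a strictly convex quadratic program (a small ridge term,
#' default 1e-9 * ||f||^2, guarantees strict convexity when specificity
#' matrices are collinear) solved exactly by a primal active-set method on
#' the nonnegativity constraints with the equality constraint kept in the
#' KKT system. The solver is deterministic: fixed inputs give bit-stable
#' results. Near-duplicate specificity matrices trigger a collinearity
#' warning naming the offending proteases, since the split of weight between
#' them is then data-driven only through the ridge term.
#'
#' @param xp A `terminome_matrix` (or bare 20x4 frequency matrix).
#' @param xks List of [specificity_matrix] (or bare 20x4 matrices), length
#'   N >= 1.
#' @param ridge Ridge coefficient added to the Gram matrix (default 1e-9).
#' @param tol Convergence/feasibility tolerance (default 1e-10).
#' @return Object of class `contribution_vector`: list with `group`,
#'   `protease_ids`, `f` (length N, nonnegative, summing to 1),
#'   `objective_Z` (value of Z at the optimum, excluding the ridge term).
#' @examples
#' a <- matrix(1 / 20, 20, 4, dimnames = list(AA_ALPHABET, CONTEXT_POSITIONS))
#' b <- a; b[, "P1"] <- 0; b["K", "P1"] <- 1  # trypsin-like P1 = K
#' xp <- 0.5 * a + 0.5 * b
#' fit_contributions(xp, list(specificity_matrix("uniformase", a),
#'                            specificity_matrix("lysase", b)))$f
#' @export
fit_contributions <- function(xp, xks, ridge = 1e-9, tol = 1e-10) {
  if (length(xks) == 0L) stop("need at least one specificity matrix")
  group <- if (inherits(xp, "terminome_matrix")) xp$group else ""
  b <- as.vector(if (inherits(xp, "terminome_matrix")) xp$matrix else xp)
  if (length(b) != 80L) stop("X_p must be a 20 x 4 matrix")
  ids <- vapply(seq_along(xks), function(k) {
    x <- xks[[k]]
    if (inherits(x, "specificity_matrix")) x$protease_id else paste0("k", k)
  }, character(1))
  A <- vapply(xks, function(x) {
    m <- if (inherits(x, "specificity_matrix")) x$matrix else x
    if (length(m) != 80L) stop("every X_k must be a 20 x 4 matrix")
    as.vector(m)
  }, numeric(80))
  A <- matrix(A, nrow = 80L)
  warn_collinear(A, ids)
  f <- solve_simplex_ls(A, b, ridge = ridge, tol = tol)
  structure(list(group = group, protease_ids = ids, f = f,
                 objective_Z = sum((A %*% f - b)^2)),
            class = "contribution_vector")
}

# Warn when two dictionary matrices are numerically near-identical.
warn_collinear <- function(A, ids, tol = 1e-6) {
  N <- ncol(A)
  if (N < 2L) return(invisible())
  pairs <- character(0)
  for (k in seq_len(N - 1L)) {
    d <- abs(A[, (k + 1L):N, drop = FALSE] - A[, k])
    hit <- which(apply(d, 2, max) < tol)
    if (length(hit))
      pairs <- c(pairs, paste0(ids[k], " ~ ", ids[k + hit]))
  }
  if (length(pairs))
    warning("near-identical specificity matrices (contribution split ",
            "between them is not identifiable): ",
            paste(pairs, collapse = "; "))
  invisible()
}

# Exact minimization of ||A f - b||^2 + ridge ||f||^2 over the probability
# simplex, by a primal active-set method. Start from the feasible uniform
# point; repeatedly solve the equality-constrained subproblem on the free
# variables via its KKT system, step to the boundary when a free variable
# would go negative, and release a bound variable while its Lagrange
# multiplier is negative.
solve_simplex_ls <- function(A, b, ridge = 1e-9, tol = 1e-10) {
  N <- ncol(A)
  H <- 2 * (crossprod(A) + diag(ridge, N))
  g <- 2 * drop(crossprod(A, b))
  f <- rep(1 / N, N)
  bound <- rep(FALSE, N) # variables fixed at zero
  for (iter in seq_len(10L * N + 100L)) {
    free <- which(!bound)
    kkt <- rbind(cbind(H[free, free, drop = FALSE], 1),
                 c(rep(1, length(free)), 0))
    sol <- solve(kkt, c(g[free], 1))
    x <- sol[seq_along(free)]
    lambda <- sol[length(sol)]
    if (all(x >= -tol)) {
      f[] <- 0
      f[free] <- pmax(x, 0)
      f <- f / sum(f)
      # multipliers of the active bounds; release while any is negative.
      # the KKT system encodes H f + lambda = g, so mu = H f - g + lambda
      mu <- drop(H %*% f) - g + lambda
      viol <- which(bound & mu < -sqrt(tol))
      if (length(viol) == 0L) return(f)
      bound[viol[which.min(mu[viol])]] <- FALSE
    } else {
      # step from the current feasible point toward x, stop at the first
      # variable hitting zero, and fix it there
      d <- x - f[free]
      neg <- which(x < -tol)
      ratios <- f[free][neg] / (f[free][neg] - x[neg])
      blk <- which.min(ratios)
      f[free] <- f[free] + ratios[blk] * d
      hit <- free[neg[blk]]
      f[hit] <- 0
      bound[hit] <- TRUE
    }
  }
  stop("active-set solver failed to converge")
}

#' @export
print.contribution_vector <- function(x, ...) {
  cat("Protease contributions",
      if (nzchar(x$group)) paste0("(group ", x$group, ")") else "",
      "- Z =", format(x$objective_Z, digits = 6), "\n")
  ord <- order(x$f, decreasing = TRUE)
  top <- utils::head(ord, 5L)
  cat("  top:", paste(sprintf("%s=%.3f", x$protease_ids[top], x$f[top]),
                      collapse = " "), "\n")
  invisible(x)
}

#' Brute-force simplex grid oracle for the deconvolution objective
#'
#' Independent verifier for [fit_contributions()]: evaluates Z(f) at every
#' point of the lattice \{ f : f_k in \{0, step, ..., 1\}, sum f = 1 \} and
#' returns the best lattice point. Intended for small N; the lattice has
#' choose(1/step + N - 1, N - 1) points.
#'
#' @inheritParams fit_contributions
#' @param step Lattice spacing; 1/step must be (near-)integer.
#' @param max_points Evaluation budget; exceeding it is an error.
#' @return List with `f` (best lattice point) and `Z`.
#' @export
grid_oracle <- function(xp, xks, step = 0.02, max_points = 2e6) {
  b <- as.vector(if (inherits(xp, "terminome_matrix")) xp$matrix else xp)
  A <- vapply(xks, function(x)
    as.vector(if (inherits(x, "specificity_matrix")) x$matrix else x),
    numeric(80))
  A <- matrix(A, nrow = 80L)
  N <- ncol(A)
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("step must divide 1")
  n_points <- choose(m + N - 1, N - 1)
  if (n_points > max_points)
    stop("lattice of ", n_points, " points exceeds budget ", max_points)
  comp <- compositions(m, N) # N x n_points integer matrix
  Fmat <- comp / m
  Z <- colSums((A %*% Fmat - b)^2)
  best <- which.min(Z)
  list(f = Fmat[, best], Z = Z[best], n_points = ncol(Fmat))
}

# All compositions of integer m into N nonnegative parts, as an N x count
# integer matrix.
compositions <- function(m, N) {
  if (N == 1L) return(matrix(m, nrow = 1L))
  cols <- lapply(0:m, function(first)
    rbind(first, compositions(m - first, N - 1L)))
  do.call(cbind, cols)
}

#' Log-normalized contributions across sample groups
#'
#' Pools fitted contribution vectors of several groups into the heatmap
#' quantity f'(k, s) = log10( N * f(k, s) / sum over groups and proteases of
#' f ). The denominator is computed literally (it equals the number of
#' groups when every vector sums to 1, but partially fitted group sets
#' remain correct). Cells with f = 0 are masked (`NA`), not -Inf.
#'
#' @param contribs List of `contribution_vector`, one per group; all must
#'   share the same proteases in the same order.
#' @return Object of class `normalized_contributions`: list with `groups`,
#'   `protease_ids`, `fprime` (N x groups matrix, `NA` where masked) and
#'   `f` (the raw contributions).
#' @export
normalize_contributions <- function(contribs) {
  if (length(contribs) == 0L) stop("no contribution vectors supplied")
  ids <- contribs[[1]]$protease_ids
  for (cv in contribs)
    if (!identical(cv$protease_ids, ids))
      stop("all groups must share the same proteases in the same order")
  groups <- vapply(contribs, function(cv) cv$group, character(1))
  fmat <- vapply(contribs, function(cv) cv$f, numeric(length(ids)))
  fmat <- matrix(fmat, nrow = length(ids),
                 dimnames = list(ids, groups))
  N <- length(ids)
  grand <- sum(fmat)
  fp <- log10(N * fmat / grand)
  fp[fmat <= 0] <- NA_real_
  structure(list(groups = groups, protease_ids = ids, fprime = fp,
                 f = fmat),
            class = "normalized_contributions")
}

#' Export normalized contributions as a heatmap table (and optional image)
#'
#' Writes the proteases x groups matrix of f' values to TSV (5 decimals,
#' masked cells as literal `NA`) and optionally renders a PNG heatmap.
#'
#' @param norm A `normalized_contributions`.
#' @param path Output TSV path.
#' @param png Optional PNG path; when non-`NULL` a heatmap image is drawn
#'   with masked cells blank.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(norm, path, png = NULL) {
  stopifnot(inherits(norm, "normalized_contributions"))
  df <- data.frame(protease_id = norm$protease_ids,
                   stringsAsFactors = FALSE)
  for (j in seq_along(norm$groups))
    df[[norm$groups[j]]] <- ifelse(is.na(norm$fprime[, j]), NA,
                                   sprintf("%.5f", norm$fprime[, j]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(png)) {
    grDevices::png(png, width = 200 + 120 * length(norm$groups),
                   height = 150 + 18 * length(norm$protease_ids))
    on.exit(grDevices::dev.off())
    m <- norm$fprime[rev(seq_len(nrow(norm$fprime))), , drop = FALSE]
    graphics::par(mar = c(2, 10, 3, 1))
    graphics::image(t(m), axes = FALSE,
                    col = grDevices::hcl.colors(64, "Blue-Red 2"),
                    main = "normalized protease contributions (f')")
    graphics::axis(3, at = seq(0, 1, length.out = ncol(m)),
                   labels = colnames(m), tick = FALSE)
    graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                   labels = rownames(m), las = 2, tick = FALSE,
                   cex.axis = 0.7)
  }
  invisible(path)
}

#' Read an exported f' heatmap table
#'
#' @param path TSV written by [export_heatmap()].
#' @return Data frame: `protease_id` plus one numeric column per group
#'   (`NA` for masked cells).
#' @export
read_heatmap_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  df
}
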
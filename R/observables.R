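## Structural observables and ensemble-quality scores. Coordinates are
## n_atoms x 3 matrices (nm), masses in amu; batches of structures are
## lists of coordinate matrices.

#' Construct a molecular structure
#'
#' @param coordinates n_atoms x 3 matrix (nm).
#' @param masses positive atomic masses (amu); default all 1.
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(coordinates, masses = NULL, bonds = NULL) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 3L)
  n <- nrow(coordinates)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    stopifnot(all(bonds >= 1L), all(bonds <= n))
  }
  structure(list(coordinates = coordinates, masses = masses, bonds = bonds),
            class = "structure3d")
}

as_coords <- function(s) if (inherits(s, "structure3d")) s$coordinates else as.matrix(s)

#' Radius of gyration
#'
#' sqrt( sum_i m_i |x_i - x_COM|^2 / sum_i m_i ) with the mass-weighted
#' center of mass; translation invariant.
#'
#' @param s a `structure3d` (or bare coordinate matrix, unit masses).
#' @return scalar (nm).
#' @export
radius_of_gyration <- function(s) {
  x <- as_coords(s)
  m <- if (inherits(s, "structure3d")) s$masses else rep(1, nrow(x))
  if (sum(m) <= 0) stop("total mass must be positive")
  com <- colSums(x * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(x, 2L, com, "-")^2)) / sum(m))
}

#' Root-mean-squared deviation from a reference
#'
#' sqrt( (1/N) sum_i |x_i - x_ref,i|^2 ), literally, with no optimal
#' superposition (the molecular frame is assumed fixed by pinned atoms);
#' set `superpose = TRUE` for a Kabsch-aligned variant.
#'
#' @param s,ref structures or coordinate matrices with equal atom counts.
#' @param superpose apply optimal rigid-body superposition first.
#' @return scalar (nm).
#' @export
rmsd <- function(s, ref, superpose = FALSE) {
  a <- as_coords(s); b <- as_coords(ref)
  if (nrow(a) != nrow(b)) stop("atom counts differ: ", nrow(a), " vs ", nrow(b))
  if (superpose) a <- kabsch(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca, "-"); b0 <- sweep(b, 2L, cb, "-")
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a0 %*% t(R), 2L, cb, "+")
}

bond_lengths <- function(coords, bonds) {
  sqrt(rowSums((coords[bonds[, 1L], , drop = FALSE] -
                coords[bonds[, 2L], , drop = FALSE])^2))
}

#' Bond score of a generated ensemble
#'
#' Fraction of (structure, bond) pairs whose bond length lies within +/-10%
#' of the reference bond length.
#'
#' @param generated list of structures / coordinate matrices.
#' @param bonds two-column matrix of bonded atom index pairs.
#' @param ref_lengths reference bond lengths (one per bond row).
#' @param tol relative tolerance (default 0.10).
#' @return fraction in \[0, 1\].
#' @export
bond_score <- function(generated, bonds, ref_lengths, tol = 0.10) {
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) == 0L) stop("bond list is empty")
  stopifnot(length(ref_lengths) == nrow(bonds))
  hits <- vapply(generated, function(s) {
    len <- bond_lengths(as_coords(s), bonds)
    sum(abs(len - ref_lengths) <= tol * ref_lengths)
  }, numeric(1))
  sum(hits) / (length(generated) * nrow(bonds))
}

#' Diversity score of a generated ensemble
#'
#' |1 - mean pairwise RMSD within generated / mean RMSD generated-vs-
#' reference|, clipped to \[0, 1\]. A score near zero indicates an ensemble
#' that is both diverse and faithful to the reference. Pairwise means use
#' all pairs excluding self-pairs; batches larger than `max_structures`
#' are deterministically subsampled for the O(n^2) terms.
#'
#' @param generated,reference lists (>= 2 each) of structures / matrices.
#' @param max_structures subsampling cap for the pairwise terms.
#' @return scalar in \[0, 1\].
#' @export
diversity_score <- function(generated, reference, max_structures = 500L) {
  stopifnot(length(generated) >= 2L, length(reference) >= 2L)
  sub <- function(lst) {
    if (length(lst) > max_structures)
      lst[round(seq(1L, length(lst), length.out = max_structures))]
    else lst
  }
  g <- lapply(sub(generated), as_coords)
  r <- lapply(sub(reference), as_coords)
  ng <- length(g)
  acc <- 0
  for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) acc <- acc + rmsd(g[[i]], g[[j]])
  within <- acc / (ng * (ng - 1L) / 2L)
  acc <- 0
  for (i in seq_len(ng)) for (j in seq_along(r)) acc <- acc + rmsd(g[[i]], r[[j]])
  between <- acc / (ng * length(r))
  if (between <= 0) stop("zero generated-vs-reference RMSD; score undefined")
  clamp(abs(1 - within / between), 0, 1)
}

## --- mode-coverage diagnostics for mixture targets ---------------------------

#' Assign samples to mixture modes by nearest mean
#'
#' @param xz matrix of slow-block coordinates (n x dim_xz).
#' @param means mode means (K x dim_xz).
#' @return integer vector of mode indices.
#' @export
assign_modes <- function(xz, means) {
  d2 <- vapply(seq_len(nrow(means)), function(k)
    rowSums(sweep(xz, 2L, means[k, ], "-")^2), numeric(nrow(xz)))
  max.col(-d2)
}

#' Mode populations and within-mode variances
#'
#' Clusters samples by nearest mode mean and reports cluster populations,
#' the number of "covered" modes (population >= `min_frac`), and the mean
#' per-dimension within-cluster variance.
#'
#' @param xz matrix of slow-block samples.
#' @param means mode means.
#' @param min_frac coverage threshold on cluster population.
#' @return list with `populations`, `n_covered`, `within_var`.
#' @export
mode_coverage <- function(xz, means, min_frac = 0.05) {
  idx <- assign_modes(xz, means)
  K <- nrow(means)
  pop <- tabulate(idx, nbins = K) / nrow(xz)
  vars <- vapply(seq_len(K), function(k) {
    sel <- idx == k
    if (sum(sel) < 2L) return(NA_real_)
    mean(apply(xz[sel, , drop = FALSE], 2L, var))
  }, numeric(1))
  list(populations = pop, n_covered = sum(pop >= min_frac),
       within_var = mean(vars[pop >= min_frac], na.rm = TRUE))
}

#' Histogram table (bin edges and counts) as a data frame
#'
#' CSV-friendly histogram representation for bond lengths, energies, Rg,
#' RMSD and similar scalar observables.
#'
#' @param values numeric vector.
#' @param breaks number of bins or explicit break points.
#' @return data frame with `lower`, `upper`, `count`.
#' @export
histogram_table <- function(values, breaks = 50) {
  h <- hist(values, breaks = breaks, plot = FALSE)
  data.frame(lower = head(h$breaks, -1L), upper = tail(h$breaks, -1L),
             count = h$counts)
}

#' @importFrom graphics hist
NULL
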
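# Bondi van-der-Waals radii (Å) by element; overridable per call.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
                 SE = 1.90, ZN = 1.39, MG = 1.73, K = 2.75, "NA" = 2.27)

#' Construct an atom set
#'
#' A labeled 3-D point set with van-der-Waals radii: the container for all
#' steric computations. Radii default to Bondi values by element.
#'
#' @param df Data frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `x`, `y`, `z`, `element`, and optionally `radius` (Å).
#' @param radii Named vector of per-element radii overriding the Bondi
#'   table.
#' @return Tibble of class `atom_set`.
#' @export
atom_set <- function(df, radii = NULL) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z", "element")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atom set lacks columns: ", paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates")
  if (!"radius" %in% names(df)) df$radius <- NA_real_
  fill <- is.na(df$radius)
  if (any(fill)) {
    tab <- BONDI_RADII
    if (!is.null(radii)) tab[names(radii)] <- radii
    df$radius[fill] <- unname(tab[toupper(df$element[fill])])
    if (anyNA(df$radius))
      stop("no van-der-Waals radius for element(s): ",
           paste(unique(df$element[is.na(df$radius)]), collapse = ", "))
  }
  if (any(df$radius <= 0)) stop("radii must be positive")
  class(df) <- c("atom_set", class(df))
  df
}

.xyz <- function(A) as.matrix(A[, c("x", "y", "z")])

#' Read atomic coordinates from PDB or mmCIF into an atom set
#'
#' @param path Coordinate file; format chosen by extension (`.pdb` /
#'   `.cif`).
#' @param radii Optional per-element radius overrides.
#' @return An [atom_set()].
#' @export
read_atoms <- function(path, radii = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9' ]", "", a$elety), 1L, 1L)
  elem[is.na(elem) | elem == ""] <-
    substr(gsub("[0-9' ]", "", a$elety[is.na(elem) | elem == ""]), 1L, 1L)
  atom_set(tibble::tibble(chain = a$chain, resno = a$resno,
                          resname = a$resid, elety = a$elety,
                          x = a$x, y = a$y, z = a$z, element = elem),
           radii = radii)
}

#' Select atoms by chain, residue range and atom names
#'
#' @param A An [atom_set()].
#' @param chain Chain id(s), or `NULL` for all.
#' @param resno Residue numbers, or `NULL` for all.
#' @param elety Atom names, or `NULL` for all.
#' @return The filtered [atom_set()].
#' @export
select_atoms <- function(A, chain = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, nrow(A))
  if (!is.null(chain)) keep <- keep & A$chain %in% chain
  if (!is.null(resno)) keep <- keep & A$resno %in% resno
  if (!is.null(elety)) keep <- keep & A$elety %in% elety
  A[keep, ]
}

# per-set padded bounding box: per-atom sphere extents
.sphere_bbox <- function(A) {
  xyz <- .xyz(A)
  r <- A$radius
  list(lo = apply(xyz - r, 2L, min), hi = apply(xyz + r, 2L, max))
}

.inside_any <- function(pts, xyz, r2) {
  inside <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(xyz))) {
    todo <- which(!inside)
    if (!length(todo)) break
    d2 <- (pts[todo, 1L] - xyz[j, 1L])^2 + (pts[todo, 2L] - xyz[j, 2L])^2 +
      (pts[todo, 3L] - xyz[j, 3L])^2
    inside[todo[d2 <= r2[j]]] <- TRUE
  }
  inside
}

#' Monte-Carlo van-der-Waals overlap volume between two atom sets
#'
#' Estimates the volume of the intersection of the two union-of-spheres
#' bodies (each atom a sphere of its van-der-Waals radius). Points are
#' sampled uniformly over the intersection of the two sphere-padded
#' bounding boxes — a region that contains every overlap point and makes
#' the estimator exactly symmetric in its arguments — and the estimate is
#' the region volume times the fraction of points lying inside at least one
#' sphere of each set. The binomial standard error is reported.
#'
#' @param A,B [atom_set()]s in a common coordinate frame.
#' @param n_samples Number of Monte-Carlo points (default 1e6).
#' @param seed Integer seed (required: estimates are reproducible).
#' @param chunk Points evaluated per block.
#' @return List: `volume` (Å³), `se` (Å³), `n_samples`, `box_volume`.
#' @examples
#' s <- make_sphere_set(rbind(c(0, 0, 0)), 1)
#' mc_overlap_volume(s, s, n_samples = 1e5, seed = 1)$volume  # ~ 4*pi/3
#' @export
mc_overlap_volume <- function(A, B, n_samples = 1e6, seed, chunk = 2e5) {
  stopifnot(inherits(A, "atom_set"), inherits(B, "atom_set"),
            nrow(A) > 0, nrow(B) > 0)
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (missing(seed)) stop("an explicit seed is required")
  ba <- .sphere_bbox(A)
  bb <- .sphere_bbox(B)
  lo <- pmax(ba$lo, bb$lo)
  hi <- pmin(ba$hi, bb$hi)
  if (any(hi <= lo))
    return(list(volume = 0, se = 0, n_samples = n_samples, box_volume = 0))
  box_vol <- prod(hi - lo)
  xa <- .xyz(A); ra2 <- A$radius^2
  xb <- .xyz(B); rb2 <- B$radius^2
  hits <- withr::with_seed(seed, {
    done <- 0; nhit <- 0
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      pts <- cbind(runif(m, lo[1L], hi[1L]), runif(m, lo[2L], hi[2L]),
                   runif(m, lo[3L], hi[3L]))
      in_a <- .inside_any(pts, xa, ra2)
      if (any(in_a))
        nhit <- nhit + sum(.inside_any(pts[in_a, , drop = FALSE], xb, rb2))
      done <- done + m
    }
    nhit
  })
  frac <- hits / n_samples
  list(volume = box_vol * frac,
       se = box_vol * sqrt(frac * (1 - frac) / n_samples),
       n_samples = n_samples, box_volume = box_vol)
}

#' Truncate a residue's sidechain in silico (to Ala or Gly)
#'
#' Ala keeps N, CA, C, O and CB; Gly keeps only the backbone. All other
#' atoms of the residue are removed and the residue is renamed. Since atoms
#' are only removed, any overlap volume can only decrease or stay equal.
#'
#' @param model An [atom_set()].
#' @param chain Chain id of the residue.
#' @param resno Residue number.
#' @param target `"ALA"` or `"GLY"`.
#' @return The mutated [atom_set()].
#' @export
mutate_sidechain <- function(model, chain, resno, target = c("ALA", "GLY")) {
  target <- match.arg(target)
  stopifnot(inherits(model, "atom_set"))
  in_res <- model$chain == chain & model$resno == resno
  if (!any(in_res)) stop("residue ", resno, " chain ", chain, " not found")
  backbone <- c("N", "CA", "C", "O")
  if (!all(backbone %in% model$elety[in_res]))
    stop("residue lacks standard backbone atoms")
  keep_atoms <- if (target == "ALA") c(backbone, "CB") else backbone
  drop <- in_res & !(model$elety %in% keep_atoms)
  out <- model[!drop, ]
  out$resname[out$chain == chain & out$resno == resno] <- target
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD between paired
#' atoms, via the SVD solution with reflection correction. The transform
#' maps mobile coordinates as `x %*% t(R) + t` (rows).
#'
#' @param mobile,reference [atom_set()]s.
#' @param pairs Optional list with integer vectors `mobile` and
#'   `reference` selecting the paired atoms; by default all atoms pair in
#'   order (sets must then be equally sized).
#' @return List: `R` (3x3 rotation), `t` (translation), `rmsd` (Å over the
#'   paired atoms), `mobile_transformed` (the full mobile set moved).
#' @export
superpose <- function(mobile, reference, pairs = NULL) {
  stopifnot(inherits(mobile, "atom_set"), inherits(reference, "atom_set"))
  if (is.null(pairs))
    pairs <- list(mobile = seq_len(nrow(mobile)),
                  reference = seq_len(nrow(reference)))
  if (length(pairs$mobile) != length(pairs$reference))
    stop("paired selections differ in length")
  X <- .xyz(mobile)[pairs$mobile, , drop = FALSE]
  Y <- .xyz(reference)[pairs$reference, , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  s <- svd(crossprod(Xc, Yc))
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2L)
    stop("paired atoms are collinear; superposition is degenerate")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - as.vector(R %*% cx)
  fit <- sweep(Xc %*% t(R), 2L, cy, "+")
  rmsd <- sqrt(mean(rowSums((fit - Y)^2)))
  moved <- mobile
  new_xyz <- sweep(.xyz(mobile) %*% t(R), 2L, tr, "+")
  moved$x <- new_xyz[, 1L]; moved$y <- new_xyz[, 2L]; moved$z <- new_xyz[, 3L]
  list(R = R, t = tr, rmsd = rmsd, mobile_transformed = moved)
}

#' Census of i to i+4 backbone hydrogen bonds
#'
#' Counts residue pairs (i, i+4) whose carbonyl oxygen O(i) lies within
#' `max_ON_dist` of the backbone nitrogen N(i+4) — the permissive geometric
#' criterion for helical hydrogen bonding, evaluated without explicit
#' hydrogens. Pairs with missing atoms are skipped with a warning.
#'
#' @param model An [atom_set()].
#' @param chain Chain id (`NULL`: all atoms considered one chain).
#' @param residues Residue-number range to scan; default all residues of
#'   the chain.
#' @param max_ON_dist O...N distance cutoff in Å (default 3.5).
#' @return List: `count` and `pairs` (tibble resno_i, resno_i4,
#'   distance).
#' @export
count_i4_hbonds <- function(model, chain = NULL, residues = NULL,
                            max_ON_dist = 3.5) {
  stopifnot(inherits(model, "atom_set"))
  A <- if (is.null(chain)) model else model[model$chain %in% chain, ]
  if (is.null(residues)) residues <- sort(unique(A$resno))
  res_i <- residues[(residues + 4L) %in% residues]
  out <- list()
  for (i in res_i) {
    o <- A[A$resno == i & A$elety == "O", ]
    n <- A[A$resno == i + 4L & A$elety == "N", ]
    if (nrow(o) != 1L || nrow(n) != 1L) {
      warning("skipping pair (", i, ", ", i + 4L, "): missing backbone atom")
      next
    }
    d <- sqrt((o$x - n$x)^2 + (o$y - n$y)^2 + (o$z - n$z)^2)
    if (d <= max_ON_dist)
      out[[length(out) + 1L]] <- tibble::tibble(resno_i = i,
                                                resno_i4 = i + 4L,
                                                distance = d)
  }
  pairs <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(resno_i = integer(), resno_i4 = integer(),
                   distance = numeric())
  list(count = nrow(pairs), pairs = pairs)
}

#' Length of a fully extended peptide chain
#'
#' @param n_residues Number of residues (>= 0).
#' @param rise Rise per residue in Å (default 3.5, the extended-chain
#'   value; 27 residues span 94.5 Å).
#' @return Length in Å.
#' @export
extended_length <- function(n_residues, rise = 3.5) {
  stopifnot(n_residues >= 0)
  n_residues * rise
}
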
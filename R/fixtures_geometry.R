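# Internal chain builder: place atom D from three predecessors A-B-C given
# bond length |C-D|, bond angle B-C-D and torsion A-B-C-D (degrees).
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an ideal polyalanine-like helix backbone
#'
#' Constructs backbone atoms (N, CA, C, O) residue by residue from standard
#' bond geometry at the ideal alpha-helical dihedrals (phi = -57, psi =
#' -47, omega = 180 degrees), which yields the canonical ~1.5 Å rise and
#' ~100 degrees turn per residue and i to i+4 O...N distances near 3 Å.
#' Used as the fixture for hydrogen-bond censuses and steric computations.
#'
#' @param n_res Number of residues (>= 1).
#' @param phi,psi Backbone dihedrals in degrees.
#' @param chain Chain id for the output.
#' @return An [atom_set()] with Bondi radii.
#' @export
make_helix_coords <- function(n_res, phi = -57, psi = -47, chain = "A") {
  stopifnot(n_res >= 1)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8
  rows <- list()
  add <- function(resno, elety, p, element) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      chain = chain, resno = resno, resname = "ALA", elety = elety,
      x = p[1], y = p[2], z = p[3], element = element)
  }
  # first residue in an arbitrary frame
  N <- c(0, 0, 0)
  CA <- c(b_NCA, 0, 0)
  ang <- a_NCAC * pi / 180
  C <- CA + b_CAC * c(cos(pi - ang), sin(pi - ang), 0)
  add(1L, "N", N, "N"); add(1L, "CA", CA, "C"); add(1L, "C", C, "C")
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n_res)) {
    # carbonyl O of residue i sits opposite the next N (torsion psi + 180)
    O <- .place_atom(prevN, prevCA, prevC, b_CO, a_CACO, psi + 180)
    add(i, "O", O, "O")
    if (i == n_res) break
    Nn <- .place_atom(prevN, prevCA, prevC, b_CN, a_CACN, psi)
    CAn <- .place_atom(prevCA, prevC, Nn, b_NCA, a_CNCA, 180)  # omega
    Cn <- .place_atom(prevC, Nn, CAn, b_CAC, a_NCAC, phi)
    add(i + 1L, "N", Nn, "N"); add(i + 1L, "CA", CAn, "C")
    add(i + 1L, "C", Cn, "C")
    prevN <- Nn; prevCA <- CAn; prevC <- Cn
  }
  df <- dplyr::bind_rows(rows)
  df <- df[order(df$resno, match(df$elety, c("N", "CA", "C", "O"))), ]
  atom_set(df)
}

#' Build an atom set from explicit sphere centers and radii
#'
#' @param centers Numeric matrix (n x 3) of sphere centers, or a single
#'   center as a length-3 vector.
#' @param radii Sphere radii (recycled).
#' @param chain,resname Labels for the output.
#' @return An [atom_set()].
#' @examples
#' make_sphere_set(c(0, 0, 0), 1)  # one unit sphere, volume 4*pi/3
#' @export
make_sphere_set <- function(centers, radii, chain = "S", resname = "SPH") {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3L)
  stopifnot(ncol(centers) == 3L)
  n <- nrow(centers)
  atom_set(tibble::tibble(chain = chain, resno = seq_len(n),
                          resname = resname, elety = "X",
                          x = centers[, 1L], y = centers[, 2L],
                          z = centers[, 3L], element = "X",
                          radius = rep_len(radii, n)))
}

#' Closed-form intersection volume of two spheres
#'
#' The lens volume of two spheres of radii `r1`, `r2` at center distance
#' `d`; the analytic oracle for the Monte-Carlo estimator. For equal radii
#' `r` and `0 <= d <= 2r` it reduces to `pi (4 r + d)(2 r - d)^2 / 12`.
#'
#' @param r1,r2 Sphere radii.
#' @param d Center distance.
#' @return Intersection volume.
#' @export
sphere_lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 * pi * min(r1, r2)^3 / 3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}
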
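#' Signed torsion (dihedral) angle of four points
#'
#' Standard IUPAC signed dihedral of the planes (p1,p2,p3) and (p2,p3,p4),
#' computed with the atan2 formulation.  Looking down the p2->p3 bond, a
#' clockwise rotation of p4 relative to p1 gives a positive angle.  The
#' result lies in (-180, 180]: a planar zig-zag (anti) chain gives 180
#' (trans), a planar U-turn gives 0 (cis).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstrom or any common unit).
#' @return the torsion angle in degrees, in (-180, 180].
#' @export
#' @examples
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180
#' torsion_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # 0
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("degenerate geometry: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 * sum(b1^2) * sum(b2^2) ||
      sum(n2^2) < 1e-20 * sum(b2^2) * sum(b3^2))
    stop("degenerate geometry: collinear triple of points")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # map -180 -> 180 so the range is (-180, 180]
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Classify a dihedral angle as cis, trans or gauche-like
#'
#' @param angle angle(s) in degrees.
#' @param tolerance half-width in degrees (default 30): |angle| <= tol is
#'   cis, |angle| >= 180 - tol is trans, anything else gauche-like.
#' @return character vector in `c("cis", "trans", "gauche")`.
#' @export
classify_cis_trans <- function(angle, tolerance = 30) {
  if (!is.finite(tolerance) || tolerance <= 0 || tolerance >= 90)
    stop("tolerance must lie in (0, 90) degrees")
  a <- abs(wrap_angle(angle))
  ifelse(a <= tolerance, "cis",
         ifelse(a >= 180 - tolerance, "trans", "gauche"))
}

# wrap any angle (degrees) into (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y <= -180] <- y[y <= -180] + 360
  y[x == 180 | (x %% 360) == 180] <- 180
  y
}

#' Enumerate cis/trans conformers and their symmetry classes
#'
#' For a symmetric linear chromophore with `n_sites` rotatable single bonds
#' (three for DPH: the two phenyl torsions and the central one discussed in
#' the torsional analysis), each site is cis (c) or trans (t), giving
#' 2^n_sites conformers.  End-for-end flipping of the molecule reverses the
#' code string, so conformers pair up into symmetry classes: palindromic
#' codes form singleton classes (degeneracy 1), all others pair with their
#' reversal (degeneracy 2).  With three sites this yields 8 conformers in 6
#' energetically distinct classes.
#'
#' @param n_sites number of rotatable sites (default 3).
#' @return data.frame with one row per class: `class` (lexicographically
#'   smallest member), `members` (slash-separated codes), `degeneracy`.
#'   Degeneracies sum to 2^n_sites.
#' @export
#' @examples
#' enumerate_conformers()         # 6 classes, degeneracy total 8
enumerate_conformers <- function(n_sites = 3) {
  stopifnot(n_sites >= 1)
  grid <- do.call(expand.grid, rep(list(c("t", "c")), n_sites))
  codes <- apply(grid, 1, paste0, collapse = "")
  rev_code <- vapply(strsplit(codes, ""), function(ch)
    paste0(rev(ch), collapse = ""), character(1))
  class_of <- pmin(codes, rev_code)
  classes <- sort(unique(class_of))
  members <- vapply(classes, function(cl)
    paste(sort(unique(c(cl, rev_code[codes == cl]))), collapse = "/"),
    character(1))
  data.frame(class = classes, members = members,
             degeneracy = as.integer(table(class_of)[classes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Boltzmann populations of conformer classes
#'
#' p_i = g_i exp(-E_i / kT) / sum_j g_j exp(-E_j / kT) with
#' k = 0.0019872 kcal mol^-1 K^-1.
#'
#' @param energy relative energies in kcal/mol (finite).
#' @param degeneracy positive integer degeneracies (default all 1).
#' @param temperature temperature in K (> 0, default 298).
#' @return numeric vector of populations summing to 1.
#' @export
#' @examples
#' boltzmann_populations(c(0, 4))           # minor state ~0.117%
boltzmann_populations <- function(energy, degeneracy = rep(1, length(energy)),
                                  temperature = 298) {
  if (length(energy) == 0) stop("empty conformer table")
  if (any(!is.finite(energy))) stop("energies must be finite (kcal/mol)")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 (K)")
  if (length(degeneracy) != length(energy) || any(degeneracy <= 0))
    stop("degeneracies must be positive and match the energies")
  kB <- 0.0019872  # kcal mol^-1 K^-1
  # subtract the minimum for numerical stability; cancels in the ratio
  w <- degeneracy * exp(-(energy - min(energy)) / (kB * temperature))
  w / sum(w)
}

#' Circular summary of the seven backbone dihedrals across frames
#'
#' Angles live on the circle, so means and spreads use the resultant-vector
#' (circular) statistics: mean = atan2(mean sin, mean cos); spread =
#' sqrt(-2 log Rbar) in degrees (0 for perfectly aligned angles).  Class
#' fractions come from [classify_cis_trans()].
#'
#' @param frames list of `frame_record` objects.
#' @param tolerance cis/trans tolerance in degrees (default 30).
#' @return data.frame with one row per dihedral dh1..dh7: circular mean,
#'   circular spread (degrees), and cis/trans/gauche fractions.
#' @export
dihedral_report <- function(frames, tolerance = 30) {
  if (length(frames) < 1) stop("need at least one frame")
  ang <- t(vapply(frames, function(fr) fr$dihedrals, numeric(7)))
  out <- lapply(1:7, function(j) {
    a <- ang[, j] * pi / 180
    C <- mean(cos(a)); S <- mean(sin(a))
    rbar <- sqrt(C^2 + S^2)
    cmean <- wrap_angle(atan2(S, C) * 180 / pi)
    spread <- if (rbar >= 1 - 1e-12) 0 else sqrt(-2 * log(rbar)) * 180 / pi
    cls <- classify_cis_trans(ang[, j], tolerance)
    data.frame(dihedral = paste0("dh", j), circ_mean = cmean,
               circ_spread = spread,
               frac_cis = mean(cls == "cis"),
               frac_trans = mean(cls == "trans"),
               frac_gauche = mean(cls == "gauche"))
  })
  do.call(rbind, out)
}

#' Read molecular geometry in XYZ format
#'
#' Standard XYZ: first line the atom count, second a comment, then
#' `element x y z` in angstrom.
#'
#' @param path path to a `.xyz` file.
#' @return data.frame with columns `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("xyz file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2)
    stop("malformed xyz file: ", path)
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  data.frame(element = vapply(rows, `[`, character(1), 1),
             x = as.numeric(vapply(rows, `[`, character(1), 2)),
             y = as.numeric(vapply(rows, `[`, character(1), 3)),
             z = as.numeric(vapply(rows, `[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Backbone torsions from atomic coordinates
#'
#' Computes the probe's dihedral angles from an XYZ geometry and a list of
#' atom-index quadruples.  The default quadruples follow the consecutive
#' backbone numbering in which dh_k is the torsion over atoms
#' (k, k+1, k+2, k+3).
#'
#' @param xyz data.frame from [read_xyz()] (or any with x, y, z columns).
#' @param quadruples list of integer 4-vectors of atom indices; default
#'   `lapply(1:7, function(k) k:(k + 3))`.
#' @return named numeric vector of torsion angles in degrees.
#' @export
dihedrals_from_xyz <- function(xyz,
                               quadruples = lapply(1:7, function(k) k:(k + 3))) {
  coords <- as.matrix(xyz[, c("x", "y", "z")])
  ang <- vapply(quadruples, function(q) {
    if (any(q < 1 | q > nrow(coords)))
      stop("atom index out of range in quadruple [",
           paste(q, collapse = ","), "]")
    torsion_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ],
                  coords[q[4], ])
  }, numeric(1))
  names(ang) <- paste0("dh", seq_along(quadruples))
  ang
}

#' A reference torsional energy profile
#'
#' Container for externally supplied torsional scans (relative energies on
#' an angle grid) for one dihedral; the analysis treats these barrier
#' profiles as input data.  Energies are shifted so the global minimum is
#' exactly zero.
#'
#' @param dihedral label, e.g. `"dh1"`.
#' @param angle strictly increasing angle grid in degrees.
#' @param energy relative energies in kcal/mol.
#' @return data.frame of class `torsion_profile`.
#' @export
torsion_profile <- function(dihedral, angle, energy) {
  if (length(angle) != length(energy) || length(angle) < 2)
    stop("angle and energy grids must match and have length >= 2")
  if (is.unsorted(angle, strictly = TRUE))
    stop("angle grid must be strictly increasing")
  if (any(!is.finite(energy))) stop("energies must be finite")
  out <- data.frame(dihedral = dihedral, angle = angle,
                    energy = energy - min(energy))
  class(out) <- c("torsion_profile", "data.frame")
  out
}
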
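## Molecular structures, mass-weighted coordinates, path alignment, and the
## rigid-body (translation/rotation) momentum projection operators.

# standard atomic weights (amu) for the elements that show up in small
# molecule work; config may override per atom
.isotope_masses <- c(
  H = 1.00782503207, D = 2.01410177785, C = 12.0, N = 14.0030740048,
  O = 15.9949146196, F = 18.99840322, P = 30.97376163, S = 31.97207100,
  Cl = 34.96885268, X = 1.0
)

#' Construct a molecule
#'
#' A molecule is element labels, Cartesian coordinates in Angstrom and
#' per-atom masses in amu. Masses default to standard isotope masses looked
#' up from the labels.
#'
#' @param labels character vector of element symbols.
#' @param coords N x 3 numeric matrix of positions (Angstrom).
#' @param masses optional numeric vector of per-atom masses (amu).
#' @return object of class `sbg_molecule`.
#' @export
molecule <- function(labels, coords, masses = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (length(labels) != n)
    stop("number of labels (", length(labels), ") != number of atoms (", n, ")")
  if (is.null(masses)) {
    masses <- .isotope_masses[labels]
    if (anyNA(masses))
      stop("no built-in mass for element(s): ",
           paste(unique(labels[is.na(masses)]), collapse = ", "))
    masses <- unname(masses)
  }
  if (length(masses) != n) stop("number of masses != number of atoms")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be positive and finite")
  structure(list(labels = as.character(labels), coords = coords,
                 masses = as.numeric(masses)),
            class = "sbg_molecule")
}

#' @export
print.sbg_molecule <- function(x, ...) {
  cat("<sbg_molecule> ", nrow(x$coords), " atoms: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Mass-weighted coordinate vector of a molecule
#'
#' Maps Cartesian positions (Angstrom, amu) to the 3N-dimensional
#' mass-weighted vector in atomic units: component (A,k) equals
#' sqrt(m_A) * x_{A,k} with masses in electron masses and lengths in bohr.
#'
#' @param mol an `sbg_molecule`.
#' @return numeric vector of length 3N (a.u.).
#' @export
to_mass_weighted <- function(mol) {
  stopifnot(inherits(mol, "sbg_molecule"))
  m_au <- mol$masses * sbg_units[["amu_to_me"]]
  x_au <- mol$coords * sbg_units[["ang_to_bohr"]]
  as.numeric(t(x_au * sqrt(m_au)))   # atom-major: (A1x,A1y,A1z,A2x,...)
}

#' Inverse of [to_mass_weighted()]
#'
#' @param q mass-weighted vector (a.u.), length 3N.
#' @param mol template molecule supplying labels and masses.
#' @return an `sbg_molecule` with coordinates recovered in Angstrom.
#' @export
from_mass_weighted <- function(q, mol) {
  stopifnot(inherits(mol, "sbg_molecule"), length(q) == 3L * nrow(mol$coords))
  m_au <- mol$masses * sbg_units[["amu_to_me"]]
  x_au <- matrix(q, ncol = 3, byrow = TRUE) / sqrt(m_au)
  molecule(mol$labels, x_au / sbg_units[["ang_to_bohr"]], mol$masses)
}

# mass-weighted center: sqrt(m)-weighted mean per Cartesian component,
# zero iff the centre of mass sits at the origin
.mw_center <- function(q, m_au) {
  x <- matrix(q, ncol = 3, byrow = TRUE) / sqrt(m_au)
  colSums(x * m_au) / sum(m_au)
}

# weighted Kabsch: rotation R minimizing sum_A m_A |R x_A - y_A|^2
.kabsch <- function(x, y, w) {
  h <- t(x * w) %*% y
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Align a sequence of structures into a reaction path
#'
#' Removes overall translation (centre of mass to the origin) from every
#' frame and sequentially rotates each frame onto its predecessor by
#' mass-weighted least-squares superposition, so that frame-to-frame shifts
#' carry no linear or angular momentum. Arc length is the cumulative
#' Euclidean norm of successive mass-weighted displacements.
#'
#' @param structures list of `sbg_molecule` with identical atoms, in path
#'   order (typically minimum - transition state - minimum).
#' @param energies optional per-frame potential energies (hartree).
#' @return an `sbg_path`: matrix `points` (frames in rows, mass-weighted
#'   a.u.), `arc`, `energies`, unit `tangent` per frame, and the template
#'   `molecule`.
#' @export
align_path <- function(structures, energies = NULL) {
  if (length(structures) < 2) stop("need at least 2 structures")
  n <- nrow(structures[[1]]$coords)
  m <- structures[[1]]$masses
  for (s in structures) {
    if (!inherits(s, "sbg_molecule") || nrow(s$coords) != n)
      stop("all structures must be molecules with identical atom counts")
    if (max(abs(s$masses - m)) > 0) stop("masses differ between frames")
  }
  m_au <- m * sbg_units[["amu_to_me"]]
  frames <- lapply(structures, function(s) {
    x <- s$coords * sbg_units[["ang_to_bohr"]]
    sweep(x, 2, colSums(x * m_au) / sum(m_au))   # COM to origin (bohr)
  })
  w <- m_au / sum(m_au)
  for (k in seq_along(frames)[-1]) {
    r <- .kabsch(frames[[k]], frames[[k - 1]], w)
    frames[[k]] <- frames[[k]] %*% t(r)
  }
  pts <- t(vapply(frames, function(x) as.numeric(t(x * sqrt(m_au))),
                  numeric(3L * n)))
  sbg_path(pts, energies = energies, molecule = structures[[1]])
}

#' Construct a path object from mass-weighted points
#'
#' Lower-level companion to [align_path()], also used for abstract
#' (non-molecular) systems of arbitrary dimension.
#'
#' @param points matrix, one mass-weighted structure per row (a.u.).
#' @param energies optional per-point energies (hartree).
#' @param molecule optional template `sbg_molecule`.
#' @return an `sbg_path`.
#' @export
sbg_path <- function(points, energies = NULL, molecule = NULL) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (nrow(points) < 2) stop("a path needs at least 2 points")
  steps <- diff(points)
  seglen <- sqrt(rowSums(steps^2))
  arc <- c(0, cumsum(seglen))
  # central-difference unit tangents, one-sided at the ends
  np <- nrow(points)
  tang <- matrix(0, np, ncol(points))
  for (l in seq_len(np)) {
    lo <- max(1L, l - 1L); hi <- min(np, l + 1L)
    v <- points[hi, ] - points[lo, ]
    tang[l, ] <- v / sqrt(sum(v^2))
  }
  structure(list(points = points, arc = arc, energies = energies,
                 tangent = tang, molecule = molecule),
            class = "sbg_path")
}

#' @export
print.sbg_path <- function(x, ...) {
  cat("<sbg_path> ", nrow(x$points), " points, dim ", ncol(x$points),
      ", length ", format(max(x$arc), digits = 6), " a.u.\n", sep = "")
  invisible(x)
}

#' Translational and rotational momentum projection operators
#'
#' Builds the symmetric idempotent matrices projecting mass-weighted momenta
#' onto rigid-body translations (rank 3) and rotations (rank 3, or 2 for a
#' collinear reference). Translation vectors have components
#' sqrt(m_A) delta_jk; rotation vectors sqrt(m_A) (e_k x x_A)_j are
#' Gram-Schmidt orthonormalized against the translations and each other.
#'
#' @param reference mass-weighted reference structure (a.u.), zero
#'   mass-weighted centre.
#' @param masses per-atom masses in amu.
#' @param tol tolerance for the centre-of-mass precondition and for dropping
#'   zero-norm rotation vectors.
#' @return list with `o_tra`, `o_rot` (D x D), `o_vib` (their complement),
#'   `rank_rot` and the `reference`.
#' @export
projection_operators <- function(reference, masses, tol = 1e-8) {
  d <- length(reference)
  n <- length(masses)
  if (d != 3L * n) stop("reference length must be 3 * length(masses)")
  m_au <- masses * sbg_units[["amu_to_me"]]
  com <- .mw_center(reference, m_au)
  if (max(abs(com)) > tol * max(1, max(abs(reference))))
    stop("reference has nonzero mass-weighted centre of mass: ",
         paste(format(com, digits = 3), collapse = " "))
  sm <- rep(sqrt(m_au), each = 3L)
  tvec <- matrix(0, d, 3L)
  for (k in 1:3) tvec[seq(k, d, by = 3L), k] <- sqrt(m_au)
  tvec <- apply(tvec, 2, function(v) v / sqrt(sum(v^2)))
  x <- matrix(reference, ncol = 3, byrow = TRUE) / sqrt(m_au)  # bohr positions
  ei <- diag(3)
  basis <- tvec
  rvec <- matrix(0, d, 0)
  for (k in 1:3) {
    rx <- t(vapply(seq_len(n), function(a) pracma::cross(ei[k, ], x[a, ]),
                   numeric(3)))
    v <- as.numeric(t(rx * sqrt(m_au)))
    v <- v - basis %*% (t(basis) %*% v)       # orthogonalize vs t's and prior r's
    nv <- sqrt(sum(v^2))
    if (nv > tol * max(1, sqrt(sum(reference^2)))) {
      v <- v / nv
      basis <- cbind(basis, v)
      rvec <- cbind(rvec, v)
    }
  }
  o_tra <- tvec %*% t(tvec)
  o_rot <- if (ncol(rvec)) rvec %*% t(rvec) else matrix(0, d, d)
  list(o_tra = o_tra, o_rot = o_rot,
       o_vib = diag(d) - o_tra - o_rot,
       rank_rot = ncol(rvec), reference = reference)
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ: atom count, comment line (may carry `E=<hartree>`), then
#' one `label x y z` line per atom; frames concatenated.
#'
#' @param file path.
#' @param masses optional per-atom mass override (amu).
#' @return list with `structures` (list of `sbg_molecule`) and `energies`
#'   (numeric, `NA` where absent).
#' @export
read_xyz <- function(file, masses = NULL) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0]
  structures <- list(); energies <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    e <- NA_real_
    em <- regmatches(comment, regexec("E\\s*=\\s*([-+0-9.eEdD]+)", comment))[[1]]
    if (length(em) == 2) e <- as.numeric(gsub("[dD]", "e", em[2]))
    rows <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rows), "\\s+")
    labels <- vapply(tok, `[[`, "", 1L)
    coords <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    structures[[length(structures) + 1L]] <- molecule(labels, coords, masses)
    energies <- c(energies, e)
    i <- i + 2L + n
  }
  list(structures = structures, energies = energies)
}

#' Write structures to a multi-frame XYZ file
#'
#' @param structures list of `sbg_molecule`.
#' @param file path.
#' @param energies optional per-frame energies written as `E=` comments.
#' @export
write_xyz <- function(structures, file, energies = NULL) {
  con <- file(file, "w"); on.exit(close(con))
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    writeLines(as.character(nrow(s$coords)), con)
    cm <- if (!is.null(energies) && is.finite(energies[k]))
      sprintf("E=%.12e", energies[k]) else ""
    writeLines(cm, con)
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", s$labels,
                       s$coords[, 1], s$coords[, 2], s$coords[, 3]), con)
  }
  invisible(file)
}
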
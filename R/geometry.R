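#' Molecular geometry container
#'
#' Holds a molecular structure as an element list plus Cartesian
#' coordinates, together with the mapping of the four azo-core roles
#' (C1, N1, N2, C2) onto atom indices. The core mapping is what the rest
#' of the workflow uses to measure the mechanism-defining internal
#' coordinates omega (CNNC dihedral) and alpha / alpha' (the two CNN
#' angles).
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian positions in angstrom.
#' @param core optional named integer vector with entries C1, N1, N2, C2.
#' @param charge integer molecular charge.
#' @param tag free-text label (e.g. "cis", "trans", "ts_rot_plus").
#' @param check if TRUE (default) validate invariants, including the
#'   minimum interatomic distance of 0.4 angstrom.
#' @return an object of class `azo_geometry`.
#' @export
geometry <- function(elements, coords, core = NULL, charge = 0L,
                     tag = "", check = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix")
  elements <- as.character(elements)
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)")
  if (!is.null(core)) {
    core <- vapply(core[c("C1", "N1", "N2", "C2")], as.integer, integer(1))
    if (anyNA(core) || any(core < 1L) || any(core > length(elements)))
      stop("core indices must name C1, N1, N2, C2 and be in range")
    if (anyDuplicated(core))
      stop("core indices must be distinct")
  }
  g <- structure(
    list(elements = elements, coords = coords, core = core,
         charge = as.integer(charge), tag = as.character(tag)),
    class = "azo_geometry")
  if (check && nrow(coords) > 1L) {
    d <- stats::dist(coords)
    if (min(d) < 0.4)
      stop(sprintf("atoms closer than 0.4 angstrom (min %.3f)", min(d)))
  }
  g
}

#' @export
print.azo_geometry <- function(x, ...) {
  cat(sprintf("<azo_geometry> %d atoms (%s)%s\n", length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ","),
              if (nzchar(x$tag)) paste0(" tag=", x$tag) else ""))
  if (!is.null(x$core)) {
    mc <- measure_cnnc(x)
    cat(sprintf("  core C1,N1,N2,C2 = %s; omega=%.1f alpha=%.1f alpha'=%.1f\n",
                paste(x$core, collapse = ","), mc$omega, mc$alpha,
                mc$alpha_prime))
  }
  invisible(x)
}

# --- connectivity -----------------------------------------------------------

#' Infer bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their covalent radii (default scale 1.3).
#'
#' @param geom an `azo_geometry`.
#' @param scale multiplier on the covalent-radius sum.
#' @return two-column integer matrix of bonded atom-index pairs (i < j).
#' @export
infer_bonds <- function(geom, scale = 1.3) {
  r <- .covalent_radii[geom$elements]
  if (anyNA(r))
    stop("unknown element(s): ",
         paste(unique(geom$elements[is.na(r)]), collapse = ", "))
  n <- nrow(geom$coords)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  d <- as.matrix(stats::dist(geom$coords))
  thr <- outer(r, r, "+") * scale
  idx <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# detect the single C-N=N-C azo core from connectivity; error if the count
# of azo linkages is not exactly one
.detect_core <- function(elements, coords, scale = 1.3) {
  g <- geometry(elements, coords, check = FALSE)
  bonds <- infer_bonds(g, scale)
  nb <- lapply(seq_along(elements), function(i) {
    j <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    sort(j)
  })
  isN <- elements == "N"
  linkages <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (isN[i] && isN[j]) {
      ci <- nb[[i]][elements[nb[[i]]] == "C"]
      cj <- nb[[j]][elements[nb[[j]]] == "C"]
      if (length(ci) >= 1 && length(cj) >= 1)
        linkages[[length(linkages) + 1L]] <-
          c(C1 = min(ci), N1 = i, N2 = j, C2 = min(cj))
    }
  }
  if (length(linkages) != 1L)
    stop(sprintf(
      "expected exactly one carbon-flanked N=N azo linkage, found %d",
      length(linkages)))
  linkages[[1]]
}

# --- XYZ i/o ----------------------------------------------------------------

#' Write a geometry in XYZ format
#'
#' @param geom an `azo_geometry`.
#' @param path optional file path; when NULL the XYZ text is returned.
#' @param digits number of coordinate decimals (default 8).
#' @return XYZ text, invisibly when written to a file.
#' @export
write_xyz <- function(geom, path = NULL, digits = 8) {
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  lines <- c(
    as.character(length(geom$elements)),
    geom$tag,
    sprintf(fmt, geom$elements, geom$coords[, 1], geom$coords[, 2],
            geom$coords[, 3]))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(txt)
}

.parse_xyz_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!(seq_along(lines) > 2 & !nzchar(trimws(lines)))]
  if (length(lines) < 3)
    stop("XYZ format error: need count line, comment line, and atoms")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ format error: first line must be the atom count")
  body <- lines[-(1:2)]
  if (length(body) != n)
    stop(sprintf("XYZ format error: header says %d atoms, found %d",
                 n, length(body)))
  toks <- strsplit(trimws(body), "[[:space:]]+")
  if (any(vapply(toks, length, 1L) < 4))
    stop("XYZ format error: each atom line needs element x y z")
  elements <- vapply(toks, `[[`, "", 1)
  coords <- suppressWarnings(
    t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))))
  if (anyNA(coords)) stop("XYZ format error: non-numeric coordinate")
  list(elements = elements, coords = coords, comment = lines[2])
}

# --- parsing ----------------------------------------------------------------

#' Parse a molecular structure from SMILES or XYZ
#'
#' For SMILES input a 3-D embedding is generated (via Open Babel through
#' ChemmineOB, a deterministic distance-geometry/forcefield builder) and
#' the azo core is auto-detected from the resulting connectivity. The
#' embedding seed is recorded in the returned object for provenance. For
#' XYZ input the coordinates are taken verbatim and the core is detected
#' from covalent-radius connectivity.
#'
#' Inputs must contain exactly one N=N linkage flanked by carbons;
#' anything else is rejected (derivatives with several azo groups are
#' ambiguous and refused rather than guessed at).
#'
#' @param source SMILES string, XYZ text, or a path to an .xyz file.
#' @param kind one of "smiles", "xyz", "xyz_file".
#' @param seed embedding seed recorded for SMILES builds (default 1734).
#' @param bond_scale connectivity threshold multiplier (default 1.3).
#' @param tag label stored on the geometry.
#' @return an `azo_geometry` with a valid core mapping.
#' @export
parse_structure <- function(source, kind = c("smiles", "xyz", "xyz_file"),
                            seed = 1734L, bond_scale = 1.3, tag = "") {
  kind <- match.arg(kind)
  if (!is.character(source) || length(source) != 1L || !nzchar(source))
    stop("source must be a nonempty string")
  if (kind == "xyz_file") {
    source <- paste(readLines(source, warn = FALSE), collapse = "\n")
    kind <- "xyz"
  }
  if (kind == "xyz") {
    p <- .parse_xyz_text(source)
    core <- .detect_core(p$elements, p$coords, bond_scale)
    return(geometry(p$elements, p$coords, core = core,
                    tag = if (nzchar(tag)) tag else p$comment))
  }
  # SMILES path
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES input requires the ChemmineOB package")
  sdf <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", source = source,
      options = data.frame(names = "gen3D", args = "")),
    error = function(e) stop("SMILES parse error for '", source, "': ",
                             conditionMessage(e)))
  p <- .parse_sdf_block(sdf)
  if (nrow(p$coords) == 0 || all(abs(p$coords) < 1e-8))
    stop("SMILES parse error for '", source, "': no 3-D embedding produced")
  core <- .detect_core(p$elements, p$coords, bond_scale)
  g <- geometry(p$elements, p$coords, core = core, charge = 0L,
                tag = if (nzchar(tag)) tag else source)
  g$embed_seed <- as.integer(seed)
  g
}

.parse_sdf_block <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("SMILES parse error: empty converter output")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(natoms) || natoms < 1)
    stop("SMILES parse error: no atoms in converter output")
  at <- lines[4 + seq_len(natoms)]
  coords <- cbind(as.numeric(substr(at, 1, 10)),
                  as.numeric(substr(at, 11, 20)),
                  as.numeric(substr(at, 21, 30)))
  elements <- trimws(substr(at, 31, 34))
  list(elements = elements, coords = coords)
}

# --- JSON serialization -----------------------------------------------------

#' Serialize / deserialize a geometry as JSON
#' @param geom an `azo_geometry`.
#' @return JSON string (geometry_to_json) or `azo_geometry` (geometry_from_json).
#' @export
geometry_to_json <- function(geom) {
  jsonlite::toJSON(list(
    elements = geom$elements,
    coords = geom$coords,
    core = as.list(geom$core),
    charge = geom$charge,
    tag = geom$tag,
    embed_seed = geom$embed_seed
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname geometry_to_json
#' @param json JSON string produced by [geometry_to_json()].
#' @export
geometry_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  core <- if (length(x$core)) unlist(x$core) else NULL
  g <- geometry(x$elements, x$coords, core = core,
                charge = x$charge, tag = x$tag)
  if (!is.null(x$embed_seed)) g$embed_seed <- as.integer(x$embed_seed)
  g
}

# --- internal coordinates ---------------------------------------------------

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed dihedral p1-p2-p3-p4 in degrees, IUPAC convention:
# looking p2 -> p3, clockwise rotation of the far bond is positive.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-7 || sqrt(sum(n2^2)) < 1e-7) return(NaN)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Measure the mechanism-defining azo internal coordinates
#'
#' Returns the CNNC dihedral omega (signed, IUPAC convention, in
#' (-180, 180]; 180 for planar trans, 0 for planar cis), and the two CNN
#' bond angles alpha (C1-N1-N2) and alpha' (N1-N2-C2) in [0, 180].
#'
#' When the three atoms defining either dihedral half-plane are collinear
#' (angle within 1e-6 degrees of 180), omega is undefined: NaN is
#' returned with `omega_defined = FALSE`; the angles are still reported.
#'
#' @param geom an `azo_geometry` with a valid core mapping.
#' @return list with omega, alpha, alpha_prime (degrees), omega_defined.
#' @export
measure_cnnc <- function(geom) {
  if (is.null(geom$core)) stop("geometry has no core mapping")
  p <- geom$coords[geom$core, , drop = FALSE]
  alpha <- .bond_angle(p[1, ], p[2, ], p[3, ])
  alpha_prime <- .bond_angle(p[2, ], p[3, ], p[4, ])
  collinear <- (180 - alpha) < 1e-6 || (180 - alpha_prime) < 1e-6
  omega <- if (collinear) NaN else .dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  list(omega = omega, alpha = alpha, alpha_prime = alpha_prime,
       omega_defined = !collinear && is.finite(omega))
}
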
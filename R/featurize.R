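#' Signed dihedral angle of four points
#'
#' IUPAC sign convention (right-hand rule about the p2->p3 axis), result in
#' degrees in the half-open interval `[-180, 180)`; a planar trans
#' arrangement is reported as -180, cis as 0.
#'
#' @param p1,p2,p3,p4 Length-3 numeric vectors, or T x 3 matrices for a
#'   series of frames.
#' @return Signed angle(s) in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  as.vector(dihedral_series(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

#' @rdname dihedral
#' @export
dihedral_series <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  nrm <- function(m) sqrt(rowSums(m^2))
  if (any(nrm(b1) < 1e-10) || any(nrm(b2) < 1e-10) || any(nrm(b3) < 1e-10))
    stop("degenerate geometry: consecutive points coincide")
  bad1 <- nrm(n1) < 1e-10 * nrm(b1) * nrm(b2)
  bad2 <- nrm(n2) < 1e-10 * nrm(b2) * nrm(b3)
  if (any(bad1)) stop("degenerate geometry: points p1, p2, p3 are collinear")
  if (any(bad2)) stop("degenerate geometry: points p2, p3, p4 are collinear")
  m <- cross(b2 / nrm(b2), n1)     # in-plane axis completing n1, b2hat
  x <- rowSums(n1 * n2)
  y <- rowSums(m * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Residue specification for dihedral featurization
#'
#' @param residues Integer residue numbers; defaults to the 17
#'   selectivity-filter residues of [sf_residues()].
#' @param angles Angle kinds to compute, subset of
#'   `c("phi", "psi", "chi1", "chi2")`.
#' @return Object of class `residue_spec`.
#' @export
residue_spec <- function(residues = sf_residues(),
                         angles = c("phi", "psi", "chi1", "chi2")) {
  angles <- match.arg(angles, several.ok = TRUE)
  structure(list(residues = as.integer(residues), angles = angles),
            class = "residue_spec")
}

# IUPAC chi1/chi2 atom quadruples by residue type.  Fourth chi1 atom and
# fourth chi2 atom vary by side chain; residues missing an entry have no such
# angle (GLY, ALA for chi1; short side chains for chi2).
chi_atom_table <- function() {
  chi1 <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
            GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
            MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
            TRP = "CG", TYR = "CG", VAL = "CG1")
  chi2 <- c(ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD",
            HIS = "ND1", ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD",
            PHE = "CD1", PRO = "CD", TRP = "CD1", TYR = "CD1")
  list(chi1 = chi1, chi2 = chi2)
}

#' Compute dihedral feature matrices from a multi-model structure
#'
#' One row per model/frame; columns in residue-major, angle-kind-minor order
#' (phi, psi, chi1, chi2 per residue).  Backbone feature names span the two
#' residues the dihedral connects (e.g. `"psi:I170-G169"` is psi of G169).
#' Residues lacking a requested side-chain angle (e.g. glycine chi1) are
#' dropped from that angle kind with a message.
#'
#' @param pdb Path to a (multi-model) PDB file, or a `bio3d` `pdb` object.
#' @param spec A [residue_spec()].
#' @param chain Optional chain identifier to restrict to.
#' @return A `feature_matrix` (frames x features, degrees).
#' @export
featurize_trajectory <- function(pdb, spec = residue_spec(), chain = NULL) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, multi = TRUE)
  at <- pdb$atom
  in_chain <- if (is.null(chain)) rep(TRUE, nrow(at)) else at$chain %in% chain
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)

  res_name <- function(r) {
    i <- which(in_chain & at$resno == r)[1]
    if (is.na(i)) NA_character_ else at$resid[i]
  }
  aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  tag <- function(r) {
    rn <- res_name(r)
    code <- if (!is.na(rn) && rn %in% names(aa1)) aa1[[rn]] else "X"
    paste0(code, r)
  }
  coords <- function(r, atom_name, frame_context) {
    i <- which(in_chain & at$resno == r & at$elety == atom_name)
    if (length(i) < 1)
      stop(sprintf("missing atom %s of residue %d (%s)", atom_name, r,
                   frame_context))
    i <- i[1]
    xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  }
  chi <- chi_atom_table()

  cols <- list(); nms <- character(0)
  for (r in spec$residues) {
    rn <- res_name(r)
    if (is.na(rn)) stop(sprintf("residue %d not present in structure", r))
    for (kind in spec$angles) {
      quad <- switch(kind,
        phi = if (!is.na(res_name(r - 1L)))
          list(coords(r - 1L, "C", "phi"), coords(r, "N", "phi"),
               coords(r, "CA", "phi"), coords(r, "C", "phi")),
        psi = if (!is.na(res_name(r + 1L)))
          list(coords(r, "N", "psi"), coords(r, "CA", "psi"),
               coords(r, "C", "psi"), coords(r + 1L, "N", "psi")),
        chi1 = if (rn %in% names(chi$chi1))
          list(coords(r, "N", "chi1"), coords(r, "CA", "chi1"),
               coords(r, "CB", "chi1"), coords(r, chi$chi1[[rn]], "chi1")),
        chi2 = if (rn %in% names(chi$chi2))
          list(coords(r, "CA", "chi2"), coords(r, "CB", "chi2"),
               coords(r, "CG", "chi2"), coords(r, chi$chi2[[rn]], "chi2")))
      if (is.null(quad)) {
        if (kind %in% c("chi1", "chi2"))
          message(sprintf("residue %d (%s) has no %s angle; dropped", r, rn,
                          kind))
        next
      }
      nm <- switch(kind,
        phi = sprintf("phi:%s-%s", tag(r), tag(r - 1L)),
        psi = sprintf("psi:%s-%s", tag(r + 1L), tag(r)),
        chi1 = sprintf("chi1:%s", tag(r)),
        chi2 = sprintf("chi2:%s", tag(r)))
      cols[[length(cols) + 1]] <-
        dihedral_series(quad[[1]], quad[[2]], quad[[3]], quad[[4]])
      nms <- c(nms, nm)
    }
  }
  if (!length(cols))
    stop("no dihedral features could be computed for this specification")
  m <- do.call(cbind, cols)
  dimnames(m) <- list(NULL, nms)
  feature_matrix(m)
}

#' Feature matrix container
#'
#' A frames x features numeric matrix of signed dihedral angles in degrees.
#' Enforces the wrap invariant (`[-180, 180)`), unique column names, and no
#' missing values.
#'
#' @param m Numeric matrix with column names.
#' @param traj_id Optional trajectory identifier.
#' @param frame_ns Optional physical time per frame (nanoseconds).
#' @return The matrix with class `feature_matrix`.
#' @export
feature_matrix <- function(m, traj_id = NULL, frame_ns = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("feature matrix requires unique column names")
  if (anyNA(m)) stop("feature matrix contains missing values")
  if (any(m < -180 | m >= 180))
    stop("angles out of range: all values must lie in [-180, 180)")
  structure(m, class = c("feature_matrix", class(m)),
            traj_id = traj_id, frame_ns = frame_ns)
}

#' Write a feature matrix to CSV
#'
#' Plain CSV with a schema-version comment line, header of feature names, and
#' angles at six decimal places.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# msmgating-features v1", con)
  writeLines(paste(colnames(fm), collapse = ","), con)
  apply_fmt <- function(row) paste(sprintf("%.6f", row), collapse = ",")
  writeLines(vapply(seq_len(nrow(fm)), function(i) apply_fmt(fm[i, ]),
                    character(1)), con)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Round-trips bit-exactly with [write_features()] at the stored precision.
#' Rejects malformed headers, ragged rows, out-of-range angles, and empty
#' files.
#'
#' @param path Input path.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("no frames: file is empty")
  if (startsWith(lines[1], "#")) {
    if (!grepl("msmgating-features v1", lines[1]))
      stop("schema mismatch: expected 'msmgating-features v1', got: ", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("no frames: file has a header but no data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) == 0 || any(header == ""))
    stop("malformed header in ", path)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header)))
    stop(sprintf("ragged rows: row %d has %d fields, expected %d",
                 which(nf != length(header))[1], nf[nf != length(header)][1],
                 length(header)))
  m <- matrix(as.numeric(unlist(rows)), ncol = length(header), byrow = TRUE,
              dimnames = list(NULL, header))
  if (anyNA(m)) stop("non-numeric values in ", path)
  feature_matrix(m)
}

#' Write/read discrete microstate trajectories as integer CSV
#'
#' @param dtrajs List of integer vectors.
#' @param path Output path.
#' @return `write_dtrajs` returns `path` invisibly; `read_dtrajs` returns the
#'   list of integer vectors.
#' @export
write_dtrajs <- function(dtrajs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# msmgating-dtrajs v1", con)
  for (d in dtrajs) writeLines(paste(d, collapse = ","), con)
  invisible(path)
}

#' @rdname write_dtrajs
#' @export
read_dtrajs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lapply(lines, function(l) as.integer(strsplit(l, ",", fixed = TRUE)[[1]]))
}
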
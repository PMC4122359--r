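## Coordinate handling: PDB reading (via bio3d), NH-vector extraction for
## the diffusion and model-free stages, Kabsch superposition / backbone RMSD
## for ensemble comparison, and per-residue value maps in the B-factor
## column.

#' Read a (possibly multi-model) PDB structure
#'
#' Thin wrapper over [bio3d::read.pdb()] keeping all models. Heteroatom
#' records (e.g. the FMN cofactor) are retained but flagged non-protein.
#'
#' @param path Path to a PDB file.
#' @return Object of class `structure3d`: list with `pdb` (the bio3d
#'   object), `n_models`, and `is_protein` (logical per atom).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  structure(list(pdb = pdb, n_models = n_models,
                 is_protein = pdb$atom$type == "ATOM"),
            class = "structure3d")
}

## atom coordinates of one model as an n x 3 matrix (bio3d row layout)
.model_xyz <- function(s, model = 1) {
  xyz <- s$pdb$xyz
  if (is.matrix(xyz)) {
    if (model > nrow(xyz)) stop("model index out of range")
    xyz <- xyz[model, ]
  } else if (model != 1) stop("model index out of range")
  matrix(xyz, ncol = 3, byrow = TRUE)
}

#' Extract unit N-H bond vectors
#'
#' Unit vectors from backbone N to amide H (atom name `H` or `HN`) for every
#' non-proline residue of one conformer. Prolines and residues lacking an
#' amide proton are omitted (their ids are attached as attribute
#' `omitted`). For structures without amide protons (e.g. X-ray models),
#' `idealize = TRUE` places an ideal H 1.02 Angstrom from N along the
#' bisector of the C'(i-1)-N and CA-N directions (planar amide geometry);
#' without it such structures are an explicit error.
#'
#' @param s A `structure3d`.
#' @param model Conformer index (default 1).
#' @param idealize Build ideal amide protons when none are present.
#' @return An [nh_vectors()] object.
#' @export
extract_nh_vectors <- function(s, model = 1, idealize = FALSE) {
  stopifnot(inherits(s, "structure3d"))
  at <- s$pdb$atom
  xyz <- .model_xyz(s, model)
  prot <- s$is_protein
  isN <- prot & at$elety == "N"
  isH <- prot & at$elety %in% c("H", "HN")
  isCA <- prot & at$elety == "CA"
  isC <- prot & at$elety == "C"
  key <- paste(at$chain, at$resno)
  res <- unique(key[isN])

  if (!any(isH) && !idealize)
    stop("no amide protons in structure; supply a protonated model or ",
         "call with idealize = TRUE for ideal amide-H placement")

  ids <- integer(0); vecs <- NULL; omitted <- integer(0)
  for (r in res) {
    iN <- which(isN & key == r)[1]
    if (at$resid[iN] == "PRO") next
    iH <- which(isH & key == r)
    if (length(iH) >= 1) {
      v <- xyz[iH[1], ] - xyz[iN, ]
    } else if (idealize) {
      iCA <- which(isCA & key == r)
      ## preceding residue's carbonyl carbon, same chain
      prev <- paste(at$chain[iN], at$resno[iN] - 1L)
      iCp <- which(isC & key == prev)
      if (length(iCA) == 0 || length(iCp) == 0) {
        omitted <- c(omitted, at$resno[iN]); next
      }
      u1 <- xyz[iN, ] - xyz[iCp[1], ]
      u2 <- xyz[iN, ] - xyz[iCA[1], ]
      u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
      v <- u1 + u2
    } else {
      omitted <- c(omitted, at$resno[iN]); next
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-6) { omitted <- c(omitted, at$resno[iN]); next }
    ids <- c(ids, at$resno[iN])
    vecs <- rbind(vecs, v / nv)
  }
  if (length(ids) == 0) stop("no N-H vectors could be extracted")
  out <- nh_vectors(ids, vecs)
  attr(out, "omitted") <- omitted
  out
}

## paired coordinate matrices for a selection over the common residue set
.paired_coords <- function(a, b, model_a, model_b, atoms) {
  pick <- function(s, model) {
    at <- s$pdb$atom
    sel <- s$is_protein & at$elety %in% atoms
    xyz <- .model_xyz(s, model)[sel, , drop = FALSE]
    data.frame(key = paste(at$resno[sel], at$elety[sel]), xyz)
  }
  A <- pick(a, model_a); B <- pick(b, model_b)
  common <- intersect(A$key, B$key)
  if (length(common) < 3) stop("fewer than 3 paired atoms in selection")
  list(A = as.matrix(A[match(common, A$key), -1]),
       B = as.matrix(B[match(common, B$key), -1]))
}

## Kabsch: proper rotation (reflection branch rejected) + translation
.kabsch_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P <- sweep(P, 2, cp); Q <- sweep(Q, 2, cq)
  S <- svd(crossprod(P, Q))
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  Pr <- P %*% t(R)
  sqrt(mean(rowSums((Pr - Q)^2)))
}

#' Optimal superposition RMSD
#'
#' Least-squares rigid-body superposition (Kabsch SVD, proper rotation
#' enforced) of one conformer onto another and the RMSD over the selection.
#' Atoms are paired by (residue number, atom name) over the common residue
#' set. Selections: `"backbone"` = N, CA, C (O optional), `"ca"` = CA only.
#'
#' @param a,b `structure3d` objects (may be the same object).
#' @param selection `"backbone"` or `"ca"`.
#' @param model_a,model_b Conformer indices (default 1; ensemble-vs-ensemble
#'   comparisons default to representative model 1 of each).
#' @param include_O Include backbone O in the backbone selection.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b, selection = c("backbone", "ca"),
                           model_a = 1, model_b = 1, include_O = FALSE) {
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"))
  selection <- match.arg(selection)
  atoms <- if (selection == "ca") "CA" else
    c("N", "CA", "C", if (include_O) "O")
  pc <- .paired_coords(a, b, model_a, model_b, atoms)
  .kabsch_rmsd(pc$A, pc$B)
}

#' Mean pairwise RMSD across an ensemble
#'
#' @param s A multi-model `structure3d`.
#' @param selection As in [superpose_rmsd()].
#' @return Mean over all conformer pairs of the pairwise superposition RMSD.
#' @export
ensemble_rmsd <- function(s, selection = "backbone") {
  if (s$n_models < 2) stop("need at least 2 models")
  pairs <- utils::combn(s$n_models, 2)
  mean(apply(pairs, 2, function(p)
    superpose_rmsd(s, s, selection, model_a = p[1], model_b = p[2])))
}

#' Write per-residue values into the B-factor column
#'
#' Maps per-residue values (order parameters, Rex, composite shifts, ...)
#' onto a structure by writing them into the B column of every atom of the
#' residue; residues without a value receive the sentinel, recorded in a
#' REMARK header. Values outside the fixed-width PDB column range
#' \[-999.99, 999.99\] are clamped with a warning.
#'
#' @param s A `structure3d`.
#' @param values Named numeric vector; names are residue numbers.
#' @param path Output PDB path.
#' @param sentinel Value for unmapped residues (default -1).
#' @return `path`, invisibly.
#' @export
write_value_map <- function(s, values, path, sentinel = -1) {
  stopifnot(inherits(s, "structure3d"))
  v <- as.numeric(values)
  ids <- as.integer(names(values))
  clamp <- v < -999.99 | v > 999.99
  if (any(clamp)) {
    warning("values clamped to the PDB B-column range [-999.99, 999.99]")
    v <- pmin(pmax(v, -999.99), 999.99)
  }
  at <- s$pdb$atom
  b <- v[match(at$resno, ids)]
  b[is.na(b)] <- sentinel
  pdb <- s$pdb
  xyz1 <- if (is.matrix(pdb$xyz)) pdb$xyz[1, ] else pdb$xyz
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(pdb, xyz = xyz1, b = b, file = tmp)
  header <- c(
    sprintf("REMARK   3 PER-RESIDUE VALUE MAP IN B COLUMN; SENTINEL %.2f", sentinel),
    sprintf("REMARK   3 MAPPED RESIDUES %d OF %d", sum(!is.na(match(unique(at$resno), ids))),
            length(unique(at$resno))))
  writeLines(c(header, readLines(tmp)), path)
  unlink(tmp)
  invisible(path)
}

#' Read a value map back from the B-factor column
#'
#' @param path PDB file written by [write_value_map()].
#' @return Named numeric vector of per-residue B values (first atom of each
#'   residue).
#' @export
read_value_map <- function(path) {
  s <- read_structure(path)
  at <- s$pdb$atom
  first <- !duplicated(at$resno)
  stats::setNames(at$b[first], at$resno[first])
}
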
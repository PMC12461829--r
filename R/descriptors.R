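#' Trajectory frames container
#'
#' Plain-array representation of an MD trajectory restricted to what the
#' descriptor calculations need: coordinates, atom names, residue indices
#' and (optionally) masses.
#'
#' @param coords numeric array `frames x atoms x 3` (angstrom), or an
#'   `atoms x 3` matrix for a single frame.
#' @param atom_names character vector of per-atom names (e.g. "CA").
#' @param residue_ids integer vector of per-atom residue indices.
#' @param masses optional per-atom masses (amu); when absent, geometric
#'   centers are used wherever a center of mass is required.
#' @return an object of class `allodyn_traj`.
#' @export
trajectory_frames <- function(coords, atom_names, residue_ids, masses = NULL) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, c(1L, dim(coords)))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) abort("trajectory coordinates must be finite")
  n_atoms <- dim(coords)[2]
  if (length(atom_names) != n_atoms || length(residue_ids) != n_atoms) {
    abort("atom_names and residue_ids must have one entry per atom")
  }
  if (!is.null(masses)) {
    stopifnot(length(masses) == n_atoms, all(is.finite(masses)), all(masses > 0))
  }
  structure(
    list(coords = coords, atom_names = as.character(atom_names),
         residue_ids = as.integer(residue_ids), masses = masses),
    class = "allodyn_traj")
}

n_frames <- function(traj) dim(traj$coords)[1]

BACKBONE_ATOMS <- c("C", "CA", "N")

#' Residue selection for descriptor calculations
#'
#' @param residue_ids exactly six distinct residue indices, in the order
#'   that fixes the pairwise-distance row order.
#' @param atom_set `"all_atoms"` or `"backbone"` (backbone = atoms named
#'   C, CA, N).
#' @return an object of class `allodyn_selection`.
#' @export
residue_selection <- function(residue_ids, atom_set = c("all_atoms", "backbone")) {
  atom_set <- match.arg(atom_set)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != 6L || anyDuplicated(residue_ids)) {
    abort("a residue selection must contain exactly six distinct residues")
  }
  structure(list(residue_ids = residue_ids, atom_set = atom_set),
            class = "allodyn_selection")
}

atom_mask <- function(traj, residue_id, atom_set) {
  m <- traj$residue_ids == residue_id
  if (atom_set == "backbone") m <- m & traj$atom_names %in% BACKBONE_ATOMS
  which(m)
}

# Kabsch: rotation R minimizing || Pc %*% R - Qc ||_F (rows = atoms);
# returns the rotation and the two centroids
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  C <- crossprod(Pc, Qc)
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, center_p = cp, center_q = cq)
}

superpose_coords <- function(P, Q) {
  k <- kabsch(P, Q)
  sweep(sweep(P, 2, k$center_p) %*% k$R, 2, k$center_q, `+`)
}

#' Map reference residues onto a target structure
#'
#' Rigid-body least-squares superposition of the target's first frame onto
#' the reference's first frame over matched backbone atoms (atoms named C,
#' CA, N of residues present in both structures, matched by residue id and
#' atom name), followed by nearest-center-of-mass assignment: each
#' reference residue is mapped to the target residue whose center of mass
#' lies closest after superposition.
#'
#' @param target,reference `allodyn_traj` objects (first frame is used).
#' @param reference_residues six residue ids in the reference structure.
#' @param atom_set atom set recorded on the returned selection.
#' @return an [residue_selection()] of six distinct target residues, in
#'   the order of `reference_residues`.
#' @export
map_reference_residues <- function(target, reference, reference_residues,
                                   atom_set = "all_atoms") {
  stopifnot(inherits(target, "allodyn_traj"), inherits(reference, "allodyn_traj"))
  reference_residues <- as.integer(reference_residues)
  if (length(reference_residues) != 6L) {
    abort("exactly six reference residues are required")
  }
  if (!all(reference_residues %in% reference$residue_ids)) {
    abort("some reference residues are absent from the reference structure")
  }
  tgt <- target$coords[1, , , drop = TRUE]
  ref <- reference$coords[1, , , drop = TRUE]
  # match backbone atoms by (residue id, atom name)
  key_t <- paste(target$residue_ids, target$atom_names)
  key_r <- paste(reference$residue_ids, reference$atom_names)
  bb_t <- target$atom_names %in% BACKBONE_ATOMS
  bb_r <- reference$atom_names %in% BACKBONE_ATOMS
  common <- intersect(key_t[bb_t], key_r[bb_r])
  if (length(common) >= 3L) {
    it <- match(common, key_t); ir <- match(common, key_r)
    k <- kabsch(tgt[it, , drop = FALSE], ref[ir, , drop = FALSE])
    tgt_all <- sweep(sweep(tgt, 2, k$center_p) %*% k$R, 2, k$center_q, `+`)
  } else {
    # too few shared backbone atoms: assume frames share a coordinate system
    tgt_all <- tgt
  }
  com_of <- function(coords, traj, rid) {
    idx <- which(traj$residue_ids == rid)
    w <- if (is.null(traj$masses)) rep(1, length(idx)) else traj$masses[idx]
    colSums(coords[idx, , drop = FALSE] * w) / sum(w)
  }
  target_res <- sort(unique(target$residue_ids))
  tgt_coms <- t(vapply(target_res, function(r) com_of(tgt_all, target, r),
                       numeric(3)))
  mapped <- integer(6)
  for (i in seq_along(reference_residues)) {
    rc <- com_of(ref, reference, reference_residues[i])
    d2 <- rowSums(sweep(tgt_coms, 2, rc)^2)
    mapped[i] <- target_res[which.min(d2)]
  }
  if (anyDuplicated(mapped)) {
    dup <- mapped[duplicated(mapped)][1]
    abort(sprintf(
      "residue mapping collision: target residue %d is nearest to more than one reference residue",
      dup))
  }
  residue_selection(mapped, atom_set)
}

#' Center-of-mass series of one residue
#'
#' Mass-weighted mean position of the residue's atoms (restricted to the
#' atom set) in every frame; geometric center when the trajectory carries
#' no masses.
#'
#' @param frames an `allodyn_traj`.
#' @param residue_id residue index.
#' @param atom_set `"all_atoms"` or `"backbone"`.
#' @return a `frames x 3` matrix.
#' @export
center_of_mass_series <- function(frames, residue_id,
                                  atom_set = c("all_atoms", "backbone")) {
  atom_set <- match.arg(atom_set)
  idx <- atom_mask(frames, residue_id, atom_set)
  if (length(idx) == 0L) {
    abort(sprintf("residue %d has no atoms in atom set '%s'",
                  residue_id, atom_set))
  }
  w <- if (is.null(frames$masses)) rep(1, length(idx)) else frames$masses[idx]
  w <- w / sum(w)
  Tn <- n_frames(frames)
  out <- matrix(0, Tn, 3L)
  for (k in 1:3) {
    out[, k] <- matrix(frames$coords[, idx, k], Tn, length(idx)) %*% w
  }
  out
}

#' Pairwise residue center-of-mass distance series
#'
#' Euclidean distance between the centers of mass of each of the 15
#' unordered residue pairs, per frame. Row order is fixed by position in
#' the selection: (1,2), (1,3), ..., (5,6).
#'
#' @param frames an `allodyn_traj`.
#' @param selection an [residue_selection()].
#' @return a 15 x frames matrix with rows `d_i_j`.
#' @export
pairwise_distance_series <- function(frames, selection) {
  stopifnot(inherits(selection, "allodyn_selection"))
  coms <- lapply(selection$residue_ids, center_of_mass_series,
                 frames = frames, atom_set = selection$atom_set)
  pairs <- utils::combn(6, 2)
  out <- matrix(0, 15L, n_frames(frames))
  rownames(out) <- sprintf("d_%d_%d", pairs[1, ], pairs[2, ])
  for (p in seq_len(15L)) {
    delta <- coms[[pairs[1, p]]] - coms[[pairs[2, p]]]
    out[p, ] <- sqrt(rowSums(delta^2))
  }
  out
}

#' RMSD series relative to the first frame
#'
#' Per-frame RMSD of the selected atoms with respect to frame 1, after
#' least-squares rigid superposition (Kabsch) by default.
#'
#' @param frames an `allodyn_traj`.
#' @param selection an [residue_selection()].
#' @param fit superpose each frame onto the reference before measuring
#'   (default `TRUE`); `FALSE` gives the no-fit RMSD.
#' @return numeric vector of length `frames`; the first entry is 0.
#' @export
rmsd_series <- function(frames, selection, fit = TRUE) {
  stopifnot(inherits(selection, "allodyn_selection"))
  idx <- unlist(lapply(selection$residue_ids, atom_mask, traj = frames,
                       atom_set = selection$atom_set))
  if (length(idx) < 3L) {
    abort("RMSD superposition needs at least three selected atoms")
  }
  Tn <- n_frames(frames)
  ref <- frames$coords[1, idx, , drop = TRUE]
  out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    P <- frames$coords[t, idx, , drop = TRUE]
    if (fit) P <- superpose_coords(P, ref)
    out[t] <- sqrt(mean(rowSums((P - ref)^2)))
  }
  out
}

#' Z-score each row of a descriptor matrix
#'
#' Each row is independently standardized to zero mean and unit standard
#' deviation. Rows whose standard deviation falls below a 1e-12 floor
#' (constant rows) map to all zeros instead of NaN.
#'
#' @param m numeric matrix (rows = descriptors).
#' @return the standardized matrix, with attribute `normalized = TRUE`.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m))
  if (!all(is.finite(m))) abort("descriptor matrix contains non-finite values")
  if (ncol(m) < 2L) abort("z-scoring needs at least two frames")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s < 1e-12  # sd floor: (near-)constant rows map to exact zeros
  s[const] <- 1
  out <- (m - mu) / s
  out[const, ] <- 0
  attr(out, "normalized") <- TRUE
  out
}

#' Assemble the 16-row descriptor matrix of one trajectory
#'
#' Row 1 is the best-fit RMSD of the six selected residues to the first
#' frame; rows 2-16 are the 15 pairwise center-of-mass distances. Rows are
#' z-scored per row. With 2000 frames saved every 0.05 ns this covers a
#' 100 ns production run.
#'
#' @param frames an `allodyn_traj`.
#' @param selection an [residue_selection()].
#' @param frame_interval ns between saved frames (default 0.05).
#' @param fit passed to [rmsd_series()].
#' @param normalize z-score the rows (default `TRUE`).
#' @return a 16 x frames matrix with attributes `atom_set`,
#'   `frame_interval`, `coverage_ns` and `normalized`.
#' @export
assemble_descriptor_matrix <- function(frames, selection,
                                       frame_interval = 0.05, fit = TRUE,
                                       normalize = TRUE) {
  m <- rbind(RMSD = rmsd_series(frames, selection, fit = fit),
             pairwise_distance_series(frames, selection))
  if (normalize) m <- zscore_rows(m)
  attr(m, "atom_set") <- selection$atom_set
  attr(m, "frame_interval") <- frame_interval
  attr(m, "coverage_ns") <- ncol(m) * frame_interval
  m
}
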
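#' Heavy-atom residue-group contacts in one frame
#'
#' A residue group is in contact when ANY heavy ligand bead and ANY heavy
#' bead of the group are within the cutoff (boundary inclusive; the
#' protocol's criterion is 5 Angstrom). Hydrogens and waters never count.
#'
#' @param frame list with `ligand` and `receptor` coordinate matrices (nm),
#'   as returned by [get_frame()]
#' @param complex the `toy_complex` (bead flags and group definitions)
#' @param cutoff_A contact cutoff in Angstrom
#' @return character vector of group names in contact
#' @export
heavy_atom_contacts <- function(frame, complex, cutoff_A = 5) {
  lig <- frame$ligand[complex$ligand_heavy, , drop = FALSE]
  if (nrow(lig) == 0) stop("no heavy ligand beads selected")
  if (length(complex$groups) == 0) stop("no receptor groups defined")
  cut_nm <- A_to_nm(cutoff_A)
  hit <- vapply(complex$groups, function(idx) {
    idx <- idx[complex$receptor_heavy[idx]]
    if (length(idx) == 0) return(FALSE)
    rec <- frame$receptor[idx, , drop = FALSE]
    d2 <- outer(rowSums(lig^2), rowSums(rec^2), "+") -
      2 * lig %*% t(rec)
    min(d2) <= cut_nm^2
  }, logical(1))
  names(complex$groups)[hit]
}

#' Contact frequency table over a trajectory
#'
#' Per residue group: contact frame count, total frames and percentage
#' (`100 x frames-with-contact / total`), sorted by descending percentage
#' with alphabetical tie-break — the ordering used for reporting binding-mode
#' contacts.
#'
#' @param traj a `toy_trajectory` (or list with `n_frames`, `complex` and
#'   frames accessible via [get_frame()])
#' @param cutoff_A contact cutoff in Angstrom
#' @return data.frame: `group`, `count`, `total`, `percentage`
#' @export
contact_frequency_table <- function(traj, cutoff_A = 5) {
  stopifnot(traj$n_frames >= 1)
  gn <- names(traj$complex$groups)
  counts <- setNames(integer(length(gn)), gn)
  for (f in seq_len(traj$n_frames)) {
    hit <- heavy_atom_contacts(get_frame(traj, f), traj$complex, cutoff_A)
    counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(group = gn, count = as.integer(counts),
                    total = traj$n_frames,
                    percentage = 100 * as.integer(counts) / traj$n_frames)
  out <- out[order(-out$percentage, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Water-mediated contact fractions by distance tier
#'
#' For each residue-group contact and each tier distance (protocol tiers:
#' 4, 3.3, 2.6 Angstrom), the fraction of CONTACT frames in which at least
#' one water bead lies within the tier distance of the nearest heavy atom
#' of BOTH partners simultaneously. Fractions are monotone non-increasing
#' from the loosest to the tightest tier by construction of the criterion.
#' Groups with no contact frames are flagged empty (`NA` fractions).
#'
#' @param traj a `toy_trajectory`
#' @param tiers tier distances in Angstrom, strictly decreasing
#' @param cutoff_A contact cutoff in Angstrom
#' @return data.frame: `group`, `n_contact_frames`, one `frac_<tier>` column
#'   per tier
#' @export
water_mediated_fraction <- function(traj, tiers = c(4, 3.3, 2.6),
                                    cutoff_A = 5) {
  if (any(diff(tiers) >= 0)) stop("tiers must be strictly decreasing")
  gn <- names(traj$complex$groups)
  nt <- length(tiers)
  ncontact <- setNames(integer(length(gn)), gn)
  nmed <- matrix(0L, length(gn), nt, dimnames = list(gn, NULL))
  tier_nm <- A_to_nm(tiers)
  for (f in seq_len(traj$n_frames)) {
    fr <- get_frame(traj, f)
    hit <- heavy_atom_contacts(fr, traj$complex, cutoff_A)
    for (g in hit) {
      ncontact[g] <- ncontact[g] + 1L
      idx <- traj$complex$groups[[g]]
      idx <- idx[traj$complex$receptor_heavy[idx]]
      lig <- fr$ligand[traj$complex$ligand_heavy, , drop = FALSE]
      rec <- fr$receptor[idx, , drop = FALSE]
      if (nrow(fr$water) == 0) next
      # distance of each water to the NEAREST heavy atom of each partner
      d_lig <- apply(fr$water, 1, function(w)
        sqrt(min(rowSums(sweep(lig, 2, w)^2))))
      d_rec <- apply(fr$water, 1, function(w)
        sqrt(min(rowSums(sweep(rec, 2, w)^2))))
      for (k in seq_len(nt))
        if (any(d_lig <= tier_nm[k] & d_rec <= tier_nm[k]))
          nmed[g, k] <- nmed[g, k] + 1L
    }
  }
  out <- data.frame(group = gn, n_contact_frames = as.integer(ncontact))
  for (k in seq_len(nt))
    out[[paste0("frac_", tiers[k])]] <-
      ifelse(ncontact > 0, nmed[, k] / ncontact, NA_real_)
  rownames(out) <- NULL
  out
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` over a selection, reflections excluded, with the RMSD of the
#' superposed selection in Angstrom. Requires at least 3 non-collinear
#' selected positions.
#'
#' @param mobile,reference n x 3 coordinate matrices in nm
#' @param selection indices used for the fit (default: all rows)
#' @return list: `rotation` (3 x 3, det +1), `translation` (length 3, nm),
#'   `rmsd_A`, and `transform(coords)` applying the fit to arbitrary
#'   coordinates
#' @export
kabsch_align <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selections differ in size")
  if (nrow(P) < 3) stop("need at least 3 selected positions")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(crossprod(P0, Q0))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) selection: rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  transform <- function(x) sweep(sweep(x, 2, cp) %*% t(R), 2, cq, "+")
  rmsd_nm <- sqrt(mean(rowSums((transform(P) - Q)^2)))
  list(rotation = R, translation = cq - drop(R %*% cp),
       rmsd_A = nm_to_A(rmsd_nm), transform = transform)
}

#' Distance to a reference frame after alignment
#'
#' Euclidean distance (Angstrom) between a selected atom or group COM in a
#' frame and in a reference frame, after superposing the frame onto the
#' reference over `align_selection` (`NULL` skips alignment).
#'
#' @param frame,reference n x 3 coordinate matrices in nm
#' @param selection atom index (length 1) or index vector (group COM)
#' @param align_selection indices for the superposition, or `NULL`
#' @param masses optional masses for the group COM (default: equal weights)
#' @return distance in Angstrom
#' @export
reference_distance <- function(frame, reference, selection,
                               align_selection = NULL, masses = NULL) {
  if (any(selection > nrow(frame)) || any(selection > nrow(reference)))
    stop("selection not resolvable in both frames")
  x <- frame
  if (!is.null(align_selection))
    x <- kabsch_align(frame, reference, align_selection)$transform(frame)
  com <- function(m) {
    w <- if (is.null(masses)) rep(1, length(selection)) else masses[selection]
    drop(w %*% m[selection, , drop = FALSE]) / sum(w)
  }
  nm_to_A(sqrt(sum((com(x) - com(reference))^2)))
}

#' Backbone torsion angle from four positions
#'
#' Standard signed dihedral (degrees, in (-180, 180]) about the b-c axis of
#' the chain a-b-c-d.
#'
#' @param a,b,c,d length-3 coordinate vectors
#' @export
torsion_angle <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  # IUPAC sign: atan2((n1 x n2) . b2_hat, n1 . n2)
  atan2(sum(cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles from N, CA, C coordinates
#'
#' @param N,CA,C n_res x 3 matrices of backbone positions (nm or any
#'   consistent unit)
#' @return data.frame with `phi` and `psi` in degrees (`NA` at termini)
#' @export
backbone_dihedrals <- function(N, CA, C) {
  n <- nrow(CA)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) phi[i] <- torsion_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) psi[i] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' Helical fraction from a dihedral window
#'
#' A residue counts as helical when its (phi, psi) pair falls inside the
#' alpha-region window (defaults: phi from -100 to -30 and psi from -77 to
#' -17 degrees — a conventional alpha-helix box, configurable). The percentage
#' is over residues with both angles defined.
#'
#' @param phi,psi backbone dihedrals in degrees (equal length, >= 3 residues)
#' @param phi_window,psi_window inclusive angular windows in degrees
#' @return percent helical (0-100)
#' @export
helicity_fraction <- function(phi, psi, phi_window = c(-100, -30),
                              psi_window = c(-77, -17)) {
  if (length(phi) != length(psi)) stop("phi and psi must have equal length")
  if (length(phi) < 3) stop("need at least 3 residues")
  ok <- !is.na(phi) & !is.na(psi)
  if (!any(ok)) stop("no residue has both dihedrals defined")
  helical <- ok & phi >= phi_window[1] & phi <= phi_window[2] &
    psi >= psi_window[1] & psi <= psi_window[2]
  100 * sum(helical) / sum(ok)
}
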
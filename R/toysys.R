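#' Reference free energy along the funnel axis by quadrature
#'
#' Brute-force oracle: for each z-slice, integrates the Boltzmann factor of
#' the potential over the funnel cross-section,
#' `F(z) = -kT ln( integral_{r <= R(z)} exp(-U/kT) dx dy )`, normalised so
#' the minimum is zero. Radially symmetric potentials reduce exactly to a 1D
#' radial quadrature (`2 pi int_0^R exp(-U/kT) r dr`); general potentials use
#' an adaptive 2D rule. With `walls = "soft"` the harmonic lateral-wall
#' energy is included and the integral extends past R(z), matching what a
#' simulation with soft walls actually samples; the default is the hard
#' cross-section boundary.
#'
#' @param potential a `toy_potential` (3D)
#' @param funnel a `funnel_geometry`
#' @param z_grid axial positions in nm
#' @param temperature temperature in K
#' @param walls `"hard"` or `"soft"`
#' @param rel_tol quadrature relative tolerance
#' @return a `free_energy_surface` over `cv1` with provenance `"reference"`
#' @export
reference_fes <- function(potential, funnel, z_grid, temperature = 310,
                          walls = c("hard", "soft"), rel_tol = 1e-8) {
  walls <- match.arg(walls)
  kTv <- kB * temperature
  soft <- walls == "soft"
  pad <- if (soft) 8 * sqrt(kTv / max(funnel$kappa_funnel, 1e-12)) else 0
  Fz <- vapply(z_grid, function(z) {
    R <- funnel_radius(z, funnel)
    if (potential$radial_xy || potential$kind == "harmonic") {
      f <- function(r) {
        U <- potential$energy(cbind(r, 0, z))
        if (soft) U <- U + ifelse(r > R, 0.5 * funnel$kappa_funnel * (r - R)^2, 0)
        exp(-U / kTv) * r
      }
      q <- tryCatch(
        stats::integrate(f, 0, R + pad, rel.tol = rel_tol,
                         subdivisions = 500L),
        error = function(e) stop(sprintf(
          "quadrature failed at z = %g nm: %s", z, conditionMessage(e))))
      -kTv * log(2 * pi * q$value)
    } else {
      f <- function(x, y) {
        n <- length(x)
        U <- potential$energy(cbind(as.vector(x), as.vector(y), z))
        if (soft) {
          r <- sqrt(as.vector(x)^2 + as.vector(y)^2)
          U <- U + ifelse(r > R, 0.5 * funnel$kappa_funnel * (r - R)^2, 0)
        }
        matrix(exp(-U / kTv), nrow = NROW(x))
      }
      Rp <- R + pad
      q <- tryCatch(
        pracma::integral2(f, -Rp, Rp,
                          function(x) -sqrt(pmax(Rp^2 - x^2, 0)),
                          function(x) sqrt(pmax(Rp^2 - x^2, 0)),
                          reltol = rel_tol),
        error = function(e) stop(sprintf(
          "quadrature failed at z = %g nm: %s", z, conditionMessage(e))))
      -kTv * log(q$Q)
    }
  }, numeric(1))
  free_energy_surface(variables = "cv1", axes = list(cv1 = z_grid),
                      F = Fz - min(Fz), provenance = "reference",
                      temperature = temperature)
}

#' Quadrature basin free-energy difference of the 1D double well
#'
#' Independent oracle for the metadynamics estimates:
#' `dF = F(x > 0) - F(x < 0)` with
#' `F(basin) = -kT ln int_basin exp(-U/kT) dx` for
#' `U = a (x^2 - 1)^2 + b x`. The basin divide is the symmetry point x = 0.
#'
#' @param a,b double-well parameters in kJ/mol
#' @param temperature temperature in K
#' @return basin free-energy difference in kJ/mol (positive for b > 0)
#' @export
double_well_delta_f <- function(a, b, temperature = 310) {
  kTv <- kB * temperature
  U <- function(x) a * (x^2 - 1)^2 + b * x
  Fl <- -kTv * log(stats::integrate(function(x) exp(-U(x) / kTv), -Inf, 0,
                                    rel.tol = 1e-12)$value)
  Fr <- -kTv * log(stats::integrate(function(x) exp(-U(x) / kTv), 0, Inf,
                                    rel.tol = 1e-12)$value)
  Fr - Fl
}

#' Toy ligand-receptor-water complex
#'
#' Bead-level stand-in for a peptide bound at a receptor site: ligand beads
#' with masses and heavy-atom flags, named receptor pseudo-residue groups
#' (each a set of receptor bead indices), and single-bead (oxygen-like)
#' waters. Every receptor bead must belong to exactly one group; group names
#' must be unique; the ligand needs at least one heavy bead.
#'
#' @param ligand_coords ligand bead coordinates, n x 3 nm
#' @param ligand_masses per-bead masses
#' @param ligand_heavy logical heavy-atom flags
#' @param receptor_coords receptor bead coordinates, m x 3 nm
#' @param groups named list of receptor bead index vectors
#' @param receptor_heavy logical flags for receptor beads (default all heavy)
#' @param water_coords water bead coordinates, w x 3 nm (may be 0-row)
#' @param box box dimensions in nm
#' @export
toy_complex <- function(ligand_coords, ligand_masses, ligand_heavy,
                        receptor_coords, groups,
                        receptor_heavy = rep(TRUE, nrow(receptor_coords)),
                        water_coords = matrix(0, 0, 3),
                        box = c(10, 10, 10)) {
  ligand_coords <- matrix(ligand_coords, ncol = 3)
  receptor_coords <- matrix(receptor_coords, ncol = 3)
  water_coords <- matrix(water_coords, ncol = 3)
  if (!any(ligand_heavy)) stop("ligand must contain at least one heavy bead")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be uniquely named")
  idx <- unlist(groups)
  if (anyDuplicated(idx) || !setequal(idx, seq_len(nrow(receptor_coords))))
    stop("every receptor bead must belong to exactly one group")
  structure(list(ligand_coords = ligand_coords, ligand_masses = ligand_masses,
                 ligand_heavy = ligand_heavy,
                 receptor_coords = receptor_coords, groups = groups,
                 receptor_heavy = receptor_heavy,
                 water_coords = water_coords, box = box),
            class = "toy_complex")
}

#' Synthetic contact trajectory with exact ground truth
#'
#' Generates frames of a toy complex in which, independently per frame and
#' residue group, the nearest heavy ligand-receptor pair is placed inside
#' the 5 Angstrom contact cutoff with probability `p_contact`, and a water
#' bead is placed equidistant from both partners inside the deepest
#' mediation tier drawn from nested per-tier probabilities `p_water` (which
#' must therefore be non-increasing from the loosest to the tightest tier,
#' mirroring the geometric nesting of the tiers). All Bernoulli draws are
#' recorded, so downstream contact frequencies and water-mediation fractions
#' have an exact, not merely statistical, ground truth. Reproducible
#' bit-exact under a fixed seed.
#'
#' @param group_names names of the pseudo-residue groups (one receptor bead
#'   and one paired ligand heavy bead each)
#' @param p_contact per-group contact probability, recycled
#' @param p_water per-tier water-mediation probabilities, non-increasing,
#'   same length as `tiers`
#' @param n_frames number of frames (>= 1)
#' @param seed integer seed
#' @param tiers mediation tier distances in Angstrom, strictly decreasing
#' @param contact_dist_A heavy-pair distance in contact frames (< 5)
#' @param apart_dist_A heavy-pair distance in non-contact frames (> 5)
#' @return a `toy_trajectory`: the `toy_complex`, coordinate arrays
#'   `ligand[frame, bead, xyz]` and `water[frame, bead, xyz]` (nm), and
#'   `ground_truth` (frame, group, contact, one logical column per tier)
#' @export
synth_contact_trajectory <- function(group_names, p_contact, p_water,
                                     n_frames, seed = 1L,
                                     tiers = c(4, 3.3, 2.6),
                                     contact_dist_A = 4.0,
                                     apart_dist_A = 6.5) {
  ng <- length(group_names)
  p_contact <- rep(p_contact, length.out = ng)
  if (any(p_contact < 0 | p_contact > 1) || any(p_water < 0 | p_water > 1))
    stop("probabilities must lie in [0, 1]")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (length(p_water) != length(tiers))
    stop("need one water probability per tier")
  if (any(diff(tiers) >= 0)) stop("tiers must be strictly decreasing")
  if (any(diff(p_water) > 0))
    stop("p_water must be non-increasing across tightening tiers (nested draws)")
  if (contact_dist_A >= 5 || apart_dist_A <= 5)
    stop("contact/apart distances must bracket the 5 Angstrom cutoff")
  # geometric feasibility: the water sits on the perpendicular bisector of
  # the contact pair, so tier w needs w >= contact_dist / 2
  if (min(tiers) < contact_dist_A / 2)
    stop(sprintf(
      "tier distance conflict: tightest tier %.2f A cannot be reached equidistant from a pair %.2f A apart",
      min(tiers), contact_dist_A))

  # receptor sites 3 nm apart along x; pair axis along y; water offset in x
  rec <- cbind(3 * (seq_len(ng) - 1), 0, 0)
  cx <- toy_complex(
    ligand_coords = cbind(rec[, 1], A_to_nm(apart_dist_A), 0),
    ligand_masses = rep(12, ng), ligand_heavy = rep(TRUE, ng),
    receptor_coords = rec,
    groups = setNames(as.list(seq_len(ng)), group_names),
    water_coords = cbind(rec[, 1] + 1.5, 0, 0),
    box = c(3 * ng + 10, 10, 10))

  set.seed(seed)
  lig <- array(0, c(n_frames, ng, 3))
  wat <- array(0, c(n_frames, ng, 3))
  nt <- length(tiers)
  gt <- expand.grid(frame = seq_len(n_frames), group = group_names,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gt <- gt[order(gt$frame), , drop = FALSE]
  rownames(gt) <- NULL
  contact <- matrix(FALSE, n_frames, ng)
  wmed <- array(FALSE, c(n_frames, ng, nt))

  # tier placement radii (nm): inside the tightest satisfied tier, outside
  # the next tighter one
  place_A <- vapply(seq_len(nt), function(k) {
    hi <- if (k == nt) 0.5 * contact_dist_A else tiers[k + 1]
    (tiers[k] + max(hi, 0.5 * contact_dist_A)) / 2
  }, numeric(1))

  for (f in seq_len(n_frames)) {
    for (g in seq_len(ng)) {
      cdraw <- stats::runif(1) < p_contact[g]
      contact[f, g] <- cdraw
      d_nm <- A_to_nm(if (cdraw) contact_dist_A else apart_dist_A)
      lig[f, g, ] <- rec[g, ] + c(0, d_nm, 0)
      u <- stats::runif(1)
      sat <- u < p_water                      # nested: monotone by validation
      wmed[f, g, ] <- sat
      if (cdraw && any(sat)) {
        k <- max(which(sat))                  # tightest satisfied tier
        w_nm <- A_to_nm(place_A[k])
        h <- sqrt(max(w_nm^2 - (d_nm / 2)^2, 0))
        wat[f, g, ] <- rec[g, ] + c(h, d_nm / 2, 0)
      } else {
        wat[f, g, ] <- rec[g, ] + c(1.5, 0, 0)  # far from both partners
      }
    }
  }
  for (k in seq_len(nt)) gt[[paste0("water_", tiers[k])]] <-
    as.vector(t(wmed[, , k]))
  gt$contact <- as.vector(t(contact))
  gt <- gt[, c("frame", "group", "contact",
               paste0("water_", tiers)), drop = FALSE]
  structure(list(complex = cx, ligand = lig, water = wat,
                 ground_truth = gt, tiers = tiers, seed = seed,
                 n_frames = n_frames),
            class = "toy_trajectory")
}

#' Extract one frame of a toy trajectory
#'
#' @param traj a `toy_trajectory`
#' @param i frame index (1-based)
#' @return list with `ligand`, `receptor`, `water` coordinate matrices (nm)
#' @export
get_frame <- function(traj, i) {
  list(ligand = matrix(traj$ligand[i, , ], ncol = 3),
       receptor = traj$complex$receptor_coords,
       water = matrix(traj$water[i, , ], ncol = 3))
}
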
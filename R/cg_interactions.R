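# DNA-component interaction statistics on bead trajectories: empirical
# FRET score, tight-binding cutoff, per-residue interaction profiles,
# contact maps and the nonbonded energy decomposition.

#' Empirical FRET score of terminal-bead dynamics
#'
#' E = (alpha / n) * sum_i 1 / (dbar_i * v_i), where dbar_i and v_i are
#' the mean and standard deviation over frames of the distance between the
#' i-th 5'/3' terminal bead pair. Shorter and steadier terminal distances
#' (small dbar, small v) score higher, mimicking the twin requirements for
#' efficient energy transfer: proximity and a stable dye arrangement. The
#' score is relative (alpha is an arbitrary scale, default 1) and is meant
#' for comparisons between ensembles, not as a physical efficiency.
#'
#' @param traj `bead_trajectory` (>= 2 frames).
#' @param terminal_pairs two-column matrix (or list of pairs) of bead
#'   indices, one row per terminal pair.
#' @param alpha scale constant (default 1).
#' @param v_floor lower floor on the distance SD, nm (default 1e-3), so
#'   rigid ensembles give a finite, flagged score.
#' @return object of class `empirical_fret`: list with `E_FRET`, per-pair
#'   `d_bar` and `v` (nm), `n`, `alpha`, `floored` (logical per pair).
#' @export
empirical_fret <- function(traj, terminal_pairs, alpha = 1, v_floor = 1e-3) {
  if (length(traj$frames) < 2L)
    stopf("need >= 2 frames: distance variance is undefined for one frame")
  if (is.list(terminal_pairs) && !is.matrix(terminal_pairs))
    terminal_pairs <- do.call(rbind, terminal_pairs)
  terminal_pairs <- matrix(as.integer(terminal_pairs), ncol = 2L)
  nb <- n_beads(traj)
  if (any(terminal_pairs < 1L) || any(terminal_pairs > nb))
    stopf("terminal pair indices out of range 1..%d", nb)
  dists <- vapply(traj$frames, function(f) {
    sqrt(rowSums((f[terminal_pairs[, 1L], , drop = FALSE] -
                  f[terminal_pairs[, 2L], , drop = FALSE])^2))
  }, numeric(nrow(terminal_pairs)))
  dists <- matrix(dists, nrow = nrow(terminal_pairs))
  d_bar <- rowMeans(dists)
  v <- apply(dists, 1L, sd)
  floored <- v < v_floor
  if (any(floored))
    warnf("%d terminal pair(s) are effectively rigid; SD floored at %g nm",
          sum(floored), v_floor)
  v_eff <- pmax(v, v_floor)
  n <- nrow(terminal_pairs)
  structure(list(E_FRET = alpha / n * sum(1 / (d_bar * v_eff)),
                 d_bar = d_bar, v = v, v_eff = v_eff, n = n,
                 alpha = alpha, floored = floored),
            class = "empirical_fret")
}

#' @export
print.empirical_fret <- function(x, ...) {
  cat(sprintf("Empirical FRET score: %.4g (n = %d pairs, alpha = %g)\n",
              x$E_FRET, x$n, x$alpha))
  invisible(x)
}

# Per-frame, per-residue mean shortest distance (nm) from each residue's
# beads to any bead of the component group. Returns frames x residues.
residue_component_dist <- function(traj, group_A, residues_A, group_B) {
  res_ids <- unique(residues_A)
  vapply(traj$frames, function(f) {
    dAB <- pair_dist(f[group_A, , drop = FALSE],
                     f[group_B, , drop = FALSE], traj$box)
    bead_min <- apply(dAB, 1L, min)          # shortest per DNA bead
    vapply(res_ids, function(r) mean(bead_min[residues_A == r]), numeric(1L))
  }, numeric(length(res_ids)))
}

#' Tight-binding distance cutoff between DNA and a component
#'
#' For every frame t and DNA residue i, the per-residue distance is the
#' mean over the residue's beads of each bead's shortest distance to any
#' component bead; the cutoff is the average of these over residues and
#' frames. It estimates the typical separation of bound partners and is
#' conventionally reported in Angstrom.
#'
#' @param traj `bead_trajectory`.
#' @param group_A DNA bead indices.
#' @param residues_A residue index per DNA bead (same length as
#'   `group_A`).
#' @param group_B component bead indices.
#' @return object of class `interaction_cutoff`: list with `d_cutoff_A`
#'   (Angstrom), `d_cutoff_nm`, `per_frame` (frames x residues matrix of
#'   per-residue distances, nm), `T` (frame count).
#' @export
interaction_cutoff <- function(traj, group_A, residues_A, group_B) {
  if (!length(group_A) || !length(group_B)) stopf("bead groups must be non-empty")
  if (length(residues_A) != length(group_A))
    stopf("`residues_A` must label every bead in `group_A`")
  D <- residue_component_dist(traj, group_A, residues_A, group_B)
  D <- matrix(D, ncol = length(traj$frames))   # residues x frames
  per_frame_mean <- colMeans(D)
  d_nm <- mean(per_frame_mean)
  structure(list(d_cutoff_A = 10 * d_nm, d_cutoff_nm = d_nm,
                 per_frame = t(D), T = length(traj$frames)),
            class = "interaction_cutoff")
}

#' @export
print.interaction_cutoff <- function(x, ...) {
  cat(sprintf("Tight-binding cutoff: %.2f Angstrom (%d frames)\n",
              x$d_cutoff_A, x$T))
  invisible(x)
}

#' Per-residue interaction strength profile
#'
#' For each DNA residue, the mean over frames of the number of component
#' beads lying within `cutoff` of any of the residue's beads. Higher
#' counts flag residues that recruit more of the component.
#'
#' @inheritParams interaction_cutoff
#' @param cutoff interaction distance in Angstrom (default 6).
#' @return named numeric vector, one mean count per residue.
#' @export
interaction_profile <- function(traj, group_A, residues_A, group_B,
                                cutoff = 6) {
  assert_scalar_num(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  if (!length(group_A) || !length(group_B)) stopf("bead groups must be non-empty")
  if (length(residues_A) != length(group_A))
    stopf("`residues_A` must label every bead in `group_A`")
  cutoff_nm <- cutoff / 10
  res_ids <- unique(residues_A)
  counts <- vapply(traj$frames, function(f) {
    dAB <- pair_dist(f[group_A, , drop = FALSE],
                     f[group_B, , drop = FALSE], traj$box)
    vapply(res_ids, function(r) {
      sub <- dAB[residues_A == r, , drop = FALSE]
      sum(apply(sub, 2L, min) <= cutoff_nm)   # component beads near residue r
    }, numeric(1L))
  }, numeric(length(res_ids)))
  counts <- matrix(counts, ncol = length(traj$frames))
  setNames(rowMeans(counts), res_ids)
}

#' Intramolecular contact-probability map
#'
#' P(i, j) = fraction of frames in which any bead of residue i lies within
#' `cutoff` of any bead of residue j. Entries with |i - j| <
#' `min_separation` are masked (NA) to hide trivial backbone contacts.
#'
#' @param traj `bead_trajectory`.
#' @param residues residue index per bead.
#' @param cutoff contact distance, nm.
#' @param min_separation minimum residue separation reported (default 2).
#' @return symmetric residue x residue matrix of contact probabilities.
#' @export
contact_map <- function(traj, residues, cutoff, min_separation = 2L) {
  assert_scalar_num(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  res_ids <- sort(unique(residues))
  nr <- length(res_ids)
  P <- matrix(0, nr, nr, dimnames = list(res_ids, res_ids))
  for (f in traj$frames) {
    D <- pair_dist(f, f, traj$box)
    for (a in seq_len(nr - 1L)) {
      ia <- residues == res_ids[a]
      for (b in (a + 1L):nr) {
        ib <- residues == res_ids[b]
        if (min(D[ia, ib]) <= cutoff) {
          P[a, b] <- P[a, b] + 1
          P[b, a] <- P[b, a] + 1
        }
      }
    }
  }
  P <- P / length(traj$frames)
  mask <- abs(outer(seq_len(nr), seq_len(nr), "-")) < min_separation
  P[mask] <- NA_real_
  P
}

# Pairwise nonbonded energy (kJ/mol) between two bead index sets in one
# frame: Lennard-Jones 12-6 plus reaction-field Coulomb, both truncated at
# `cutoff` (nm). Lorentz-Berthelot combination rules. `f_coul` is the
# electrostatic conversion factor 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
pair_energy <- function(frame, topology, idx_a, idx_b, cutoff = 1.1,
                        eps_r = 15, eps_rf = Inf, box = NULL,
                        f_coul = 138.935458) {
  k_rf <- if (is.infinite(eps_rf)) 1 / (2 * cutoff^3) else
    (eps_rf - eps_r) / (2 * eps_rf + eps_r) / cutoff^3
  c_rf <- 1 / cutoff + k_rf * cutoff^2
  D <- pair_dist(frame[idx_a, , drop = FALSE],
                 frame[idx_b, , drop = FALSE], box)
  same <- identical(idx_a, idx_b)
  sel <- which(D <= cutoff, arr.ind = TRUE)
  if (same) sel <- sel[sel[, 1L] < sel[, 2L], , drop = FALSE]
  if (!nrow(sel)) return(0)
  i <- idx_a[sel[, 1L]]; j <- idx_b[sel[, 2L]]
  r <- D[sel]
  if (any(r < 1e-4))
    stopf("overlapping beads (r = %.2g nm < 1e-4); singular energy", min(r))
  sig <- (topology$sigma[i] + topology$sigma[j]) / 2
  eps <- sqrt(topology$epsilon[i] * topology$epsilon[j])
  sr6 <- (sig / r)^6
  e_lj <- 4 * eps * (sr6^2 - sr6)
  e_coul <- f_coul * topology$charge[i] * topology$charge[j] / eps_r *
    (1 / r + k_rf * r^2 - c_rf)
  sum(e_lj + e_coul)
}

#' Intermolecular nonbonded energy decomposition
#'
#' E_inter(AB) = E(AB) - E(A) - E(B), with each term the pairwise
#' Lennard-Jones 12-6 plus reaction-field Coulomb energy truncated at
#' `cutoff` within the named bead set. The decomposition isolates exactly
#' the A-B cross interactions, so it is zero whenever no A-B pair lies
#' within the cutoff. Energies are averaged over the supplied frames.
#'
#' @param traj `bead_trajectory` (all frames are averaged) or a single
#'   n x 3 coordinate matrix.
#' @param topology `bead_topology` with charges and LJ parameters.
#' @param group_A,group_B disjoint bead index sets.
#' @param cutoff interaction cutoff, nm (default 1.1).
#' @param eps_r medium relative dielectric inside the cutoff (default 15,
#'   the usual coarse-grained screening constant).
#' @param eps_rf reaction-field dielectric beyond the cutoff (default Inf,
#'   a conducting boundary).
#' @return object of class `energy_decomposition`: list with `E_AB`,
#'   `E_A`, `E_B`, `E_inter` (kJ/mol, frame averages).
#' @export
nonbonded_energy <- function(traj, topology, group_A, group_B,
                             cutoff = 1.1, eps_r = 15, eps_rf = Inf) {
  frames <- if (inherits(traj, "bead_trajectory")) traj$frames else
    list(as.matrix(traj))
  box <- if (inherits(traj, "bead_trajectory")) traj$box else NULL
  if (length(intersect(group_A, group_B)))
    stopf("groups A and B must be disjoint")
  need <- c(group_A, group_B)
  if (any(!is.finite(topology$charge[need])) ||
      any(!is.finite(topology$sigma[need])) ||
      any(!is.finite(topology$epsilon[need])))
    stopf("topology is missing charges or LJ parameters for the selected beads")
  gAB <- c(group_A, group_B)
  acc <- c(E_AB = 0, E_A = 0, E_B = 0)
  for (f in frames) {
    acc["E_AB"] <- acc["E_AB"] + pair_energy(f, topology, gAB, gAB, cutoff,
                                             eps_r, eps_rf, box)
    acc["E_A"] <- acc["E_A"] + pair_energy(f, topology, group_A, group_A,
                                           cutoff, eps_r, eps_rf, box)
    acc["E_B"] <- acc["E_B"] + pair_energy(f, topology, group_B, group_B,
                                           cutoff, eps_r, eps_rf, box)
  }
  acc <- acc / length(frames)
  structure(list(E_AB = unname(acc["E_AB"]), E_A = unname(acc["E_A"]),
                 E_B = unname(acc["E_B"]),
                 E_inter = unname(acc["E_AB"] - acc["E_A"] - acc["E_B"]),
                 cutoff = cutoff, eps_r = eps_r, eps_rf = eps_rf,
                 n_frames = length(frames)),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("Nonbonded decomposition (kJ/mol, %d frame%s): E_inter = %.4g (E_AB %.4g, E_A %.4g, E_B %.4g)\n",
              x$n_frames, if (x$n_frames > 1L) "s" else "",
              x$E_inter, x$E_AB, x$E_A, x$E_B))
  invisible(x)
}
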
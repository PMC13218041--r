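# Coarse-grained bead trajectories and topologies, with the two per-frame
# geometric observables (radius of gyration, solvent-accessible surface
# area) that drive the conformational-state analyses.

#' Construct a bead topology
#'
#' Per-bead static parameters of a coarse-grained system: van der Waals
#' radius used for surface calculations, partial charge, Lennard-Jones
#' sigma/epsilon, and molecule/residue labelling.
#'
#' @param bead bead names (character).
#' @param radius bead radii, nm (> 0). Default 0.264 nm, a typical
#'   coarse-grained bead radius.
#' @param charge partial charges, e.
#' @param sigma,epsilon Lennard-Jones parameters (nm, kJ/mol).
#' @param molecule molecule identifier per bead.
#' @param residue residue index per bead (contiguous within a molecule).
#' @return data.frame of class `bead_topology`.
#' @export
bead_topology <- function(bead, radius = 0.264, charge = 0,
                          sigma = 0.47, epsilon = 3.5,
                          molecule = "MOL", residue = seq_along(bead)) {
  n <- length(bead)
  df <- data.frame(bead = as.character(bead),
                   radius = rep_len(as.numeric(radius), n),
                   charge = rep_len(as.numeric(charge), n),
                   sigma = rep_len(as.numeric(sigma), n),
                   epsilon = rep_len(as.numeric(epsilon), n),
                   molecule = rep_len(as.character(molecule), n),
                   residue = rep_len(as.integer(residue), n),
                   stringsAsFactors = FALSE)
  if (any(df$radius <= 0) || any(df$sigma <= 0))
    stopf("bead radii and LJ sigma must be strictly positive")
  class(df) <- c("bead_topology", "data.frame")
  df
}

#' Construct a bead trajectory
#'
#' @param frames list of n_beads x 3 coordinate matrices, nm. All frames
#'   must have the same bead count and finite coordinates.
#' @param dt_ns frame spacing in ns (default 1).
#' @param box optional cubic box edge length, nm; when supplied, distance
#'   calculations use the minimum-image convention.
#' @return object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(frames, dt_ns = 1, box = NULL) {
  if (!is.list(frames) || !length(frames))
    stopf("`frames` must be a non-empty list of coordinate matrices")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stopf("each frame must be an n x 3 matrix")
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  nb <- vapply(frames, nrow, integer(1L))
  if (length(unique(nb)) != 1L)
    stopf("bead count varies across frames (%d vs %d)", nb[1L],
          nb[which(nb != nb[1L])[1L]])
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1L))))
    stopf("non-finite coordinates in trajectory")
  if (!is.null(box)) assert_scalar_num(box, "box", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, dt_ns = dt_ns, box = box),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("Bead trajectory: %d frames x %d beads, dt = %g ns%s\n",
              length(x$frames), nrow(x$frames[[1L]]), x$dt_ns,
              if (is.null(x$box)) "" else sprintf(", box %g nm", x$box)))
  invisible(x)
}

#' @export
length.bead_trajectory <- function(x) length(x$frames)

n_beads <- function(traj) nrow(traj$frames[[1L]])

# Displacement under the minimum-image convention for a cubic box.
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

# Pairwise distances between two coordinate sets, optionally periodic.
pair_dist <- function(a, b, box = NULL) {
  if (is.null(box)) return(cross_dist(a, b))
  dx <- min_image(outer(a[, 1L], b[, 1L], "-"), box)
  dy <- min_image(outer(a[, 2L], b[, 2L], "-"), box)
  dz <- min_image(outer(a[, 3L], b[, 3L], "-"), box)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Radius of gyration of a bead selection
#'
#' Uniform-mass RMS distance of the selected beads from their centroid.
#'
#' @param frame n x 3 coordinate matrix, nm.
#' @param selection bead indices (default: all beads).
#' @return Rg in nm.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @export
radius_of_gyration <- function(frame, selection = NULL) {
  frame <- as.matrix(frame)
  if (!is.null(selection)) frame <- frame[selection, , drop = FALSE]
  if (!nrow(frame)) stopf("empty bead selection")
  ctr <- colMeans(frame)
  sqrt(mean(rowSums(sweep(frame, 2L, ctr)^2)))
}

#' Per-frame radius of gyration series
#'
#' @param traj `bead_trajectory`.
#' @param selection bead indices (default all).
#' @param every compute every `every`-th frame (default 1).
#' @return numeric Rg series, nm.
#' @export
rg_series <- function(traj, selection = NULL, every = 1L) {
  idx <- seq(1L, length(traj$frames), by = every)
  vapply(traj$frames[idx], radius_of_gyration, numeric(1L),
         selection = selection)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical estimate of the area traced by the centre of a probe sphere
#' rolled over the bead union: each bead is expanded by the probe radius,
#' covered with a deterministic quasi-uniform point set, and the fraction
#' of points not buried inside any other expanded bead contributes to the
#' area.
#'
#' @param frame n x 3 coordinate matrix, nm.
#' @param topology `bead_topology` supplying radii, or a numeric radius
#'   vector. A single number is recycled.
#' @param probe probe radius, nm (default 0.14, a water-sized probe).
#' @param n_points quadrature points per bead (default 960).
#' @return SASA in nm^2.
#' @export
sasa <- function(frame, topology, probe = 0.14, n_points = 960L) {
  frame <- as.matrix(frame)
  n <- nrow(frame)
  radii <- if (inherits(topology, "bead_topology")) topology$radius
           else as.numeric(topology)
  radii <- rep_len(radii, n)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stopf("topology must supply a positive radius for every bead")
  R <- radii + probe
  pts <- sphere_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can bury points of sphere i
    d_i <- sqrt(rowSums(sweep(frame, 2L, frame[i, ])^2))
    nb <- which(d_i < R[i] + R & seq_len(n) != i)
    p <- sweep(pts * R[i], 2L, frame[i, ], "+")
    if (length(nb)) {
      d2 <- cross_dist(p, frame[nb, , drop = FALSE])
      buried <- rowSums(d2 < rep(R[nb], each = nrow(d2))) > 0
      acc <- sum(!buried)
    } else acc <- n_points
    total <- total + 4 * pi * R[i]^2 * acc / n_points
  }
  total
}

#' Per-frame SASA series
#'
#' @inheritParams sasa
#' @param traj `bead_trajectory`.
#' @param every frame stride.
#' @return numeric SASA series, nm^2.
#' @export
sasa_series <- function(traj, topology, probe = 0.14, n_points = 960L,
                        every = 1L) {
  idx <- seq(1L, length(traj$frames), by = every)
  vapply(traj$frames[idx], sasa, numeric(1L),
         topology = topology, probe = probe, n_points = n_points)
}
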
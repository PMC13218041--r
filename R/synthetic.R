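# Synthetic data generators. Every generator stores its ground truth in a
# `truth` attribute/field so downstream fits have a recovery target, and
# the same seed always reproduces the same object.

#' Synthetic coarse-grained polymer ensemble
#'
#' Freely jointed chain re-sampled independently per frame, with a
#' compactness contraction emulating confinement: each frame's bead cloud
#' is shrunk towards its centroid by 1/(1 + compactness), so higher
#' compactness strictly lowers Rg, SASA and the terminal end-to-end
#' distance statistics at once (the qualitative signature of a folded
#' versus disordered construct). Optional binder beads emulate a peptide
#' component: with probability `binder_residence` a binder sits ~0.3 nm
#' from a randomly chosen affinity-site bead, otherwise it is placed on a
#' distant shell, which gives interaction profiles a known ground truth.
#'
#' @param n_beads chain length (default 76, a tRNA-length construct).
#' @param compactness confinement strength >= 0; 0 is an ideal chain.
#' @param n_frames frames to generate (default 100).
#' @param bond_length nm (default 0.5, a typical inter-bead spacing).
#' @param binder_count number of binder beads (default 0; 15 emulates the
#'   experimental peptide:DNA stoichiometry).
#' @param binder_affinity_sites chain residue indices the binders target.
#' @param binder_residence probability per frame that a binder is bound.
#' @param seed RNG seed.
#' @return list with `traj` (`bead_trajectory`), `topology`
#'   (`bead_topology`; chain beads charge -1, binders +1), and `truth`
#'   (generator parameters, including the ideal-chain Rg expectation).
#' @export
gen_polymer_ensemble <- function(n_beads = 76L, compactness = 0,
                                 n_frames = 100L, bond_length = 0.5,
                                 binder_count = 0L,
                                 binder_affinity_sites = NULL,
                                 binder_residence = 0.8,
                                 seed = 1L) {
  if (n_beads < 3L) stopf("`n_beads` must be >= 3")
  if (compactness < 0) stopf("`compactness` must be >= 0")
  if (binder_count > 0L && is.null(binder_affinity_sites))
    binder_affinity_sites <- seq_len(n_beads)
  shrink <- 1 / (1 + compactness)
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    # freely jointed chain: unit steps in uniformly random directions
    z <- runif(n_beads - 1L, -1, 1)
    th <- runif(n_beads - 1L, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    steps <- bond_length * cbind(s * cos(th), s * sin(th), z)
    chain <- rbind(0, apply(steps, 2L, cumsum))
    ctr <- colMeans(chain)
    chain <- sweep(chain, 2L, ctr) * shrink
    if (binder_count > 0L) {
      binders <- t(vapply(seq_len(binder_count), function(b) {
        if (runif(1) < binder_residence) {
          # sample() on a length-1 vector would expand to 1:n
          pick <- if (length(binder_affinity_sites) == 1L)
            binder_affinity_sites else sample(binder_affinity_sites, 1L)
          site <- chain[pick, ]
          site + rnorm(3L, sd = 0.1) * 0.3 / sqrt(3)
        } else {
          u <- rnorm(3L); u <- u / sqrt(sum(u^2))
          10 * u          # far shell, well outside any interaction cutoff
        }
      }, numeric(3L)))
      chain <- rbind(chain, binders)
    }
    chain
  }))
  topo <- bead_topology(
    bead = c(sprintf("DNA%03d", seq_len(n_beads)),
             if (binder_count > 0L) sprintf("PEP%03d", seq_len(binder_count))),
    charge = c(rep(-1, n_beads), rep(+1, binder_count)),
    molecule = c(rep("DNA", n_beads), rep("PEP", binder_count)),
    residue = c(seq_len(n_beads), seq_len(binder_count)))
  list(traj = bead_trajectory(frames, dt_ns = 1),
       topology = topo,
       truth = list(n_beads = n_beads, compactness = compactness,
                    bond_length = bond_length, shrink = shrink,
                    ideal_rg = bond_length * sqrt(n_beads / 6) * shrink,
                    binder_count = binder_count,
                    binder_affinity_sites = binder_affinity_sites,
                    binder_residence = binder_residence, seed = seed))
}

#' Synthetic FRAP trace with reference bleaching and background
#'
#' The clean recovery a - b * c^t (0-100 scale) is distorted by a linearly
#' bleaching reference channel and a constant background, constructed so
#' that [frap_double_normalize()] recovers the clean curve exactly at zero
#' noise.
#'
#' @param a,b,c recovery parameters (0 < c < 1).
#' @param noise_sd additive Gaussian noise on the raw bleached channel.
#' @param reference_bleach_frac total fractional loss of the reference
#'   over the trace (e.g. 0.2 = 20% linear bleaching).
#' @param background_level constant background intensity.
#' @param n_points number of time points; `dt` their spacing in s.
#' @param seed RNG seed.
#' @return `frap_trace` with a `truth` attribute (a, b, c and the exact
#'   half time).
#' @export
gen_frap_trace <- function(a = 80, b = 60, c = 0.9, noise_sd = 0,
                           reference_bleach_frac = 0, background_level = 50,
                           n_points = 60L, dt = 0.5, seed = 1L) {
  if (!(c > 0 && c < 1)) stopf("`c` must lie in (0, 1)")
  t <- seq_len(n_points) * dt - dt / 2
  clean <- a - b * c^t
  R2_pre <- 1000
  R3 <- background_level
  R2 <- R2_pre * (1 - reference_bleach_frac * t / max(t)) + R3
  scale <- (R2 - R3) / (R2_pre + R3 - R3)      # reference decay factor
  noise <- with_seed(seed, rnorm(n_points, sd = noise_sd))
  R1 <- clean * scale + R3 + noise
  tr <- frap_trace(t, R1, R2, rep(R3, n_points),
                   I_R1_pre = 100 * 1 + R3,    # prebleach signal = 100 (clean units)
                   I_R2_pre = R2_pre + R3, I_R3_pre = R3)
  ratio <- a / (2 * b)
  attr(tr, "truth") <- list(a = a, b = b, c = c,
                            t_half = if (ratio < 1) log(ratio) / log(c) else 0,
                            noise_sd = noise_sd,
                            reference_bleach_frac = reference_bleach_frac,
                            seed = seed)
  tr
}

#' Synthetic droplet fusion event
#'
#' AR(t) = 1 + (AR0 - 1) exp(-t/tau) sampled at the video frame rate,
#' plus Gaussian noise, floored at 1 (an ellipse fitter never reports
#' AR < 1).
#'
#' @param AR0 initial aspect ratio (>= 1).
#' @param tau fusion time, s.
#' @param frame_rate frames per second (default 7.6, brightfield video).
#' @param duration event length, s.
#' @param noise_sd Gaussian noise SD on AR.
#' @param seed RNG seed.
#' @return data.frame with columns `t`, `AR` and a `truth` attribute.
#' @export
gen_fusion_event <- function(AR0 = 1.8, tau = 5, frame_rate = 7.6,
                             duration = 30, noise_sd = 0, seed = 1L) {
  if (AR0 < 1) stopf("`AR0` must be >= 1")
  if (tau <= 0) stopf("`tau` must be positive")
  t <- seq(0, duration, by = 1 / frame_rate)
  AR <- 1 + (AR0 - 1) * exp(-t / tau) +
    with_seed(seed, rnorm(length(t), sd = noise_sd))
  AR <- pmax(AR, 1)
  out <- data.frame(t = t, AR = AR)
  attr(out, "truth") <- list(AR0 = AR0, tau = tau, frame_rate = frame_rate,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic renaturation melt curve
#'
#' Boltzmann sigmoid y = A2 + (A1 - A2)/(1 + exp((T - Tm)/dT)) plus
#' Gaussian noise.
#'
#' @param Tm melting temperature, degrees C.
#' @param dT transition width, degrees C.
#' @param A1,A2 low/high-temperature plateaus.
#' @param noise_sd Gaussian noise SD (same units as the signal).
#' @param temps temperature grid (default 5..90 by 1, the renaturation
#'   ramp).
#' @param seed RNG seed.
#' @return data.frame with columns `T`, `signal` and a `truth` attribute.
#' @export
gen_melt_curve <- function(Tm = 32.2, dT = 4, A1 = 100, A2 = 0,
                           noise_sd = 0, temps = seq(5, 90, by = 1),
                           seed = 1L) {
  if (Tm <= min(temps) || Tm >= max(temps))
    stopf("`temps` must span the transition (Tm = %g)", Tm)
  y <- A2 + (A1 - A2) / (1 + exp((temps - Tm) / dT)) +
    with_seed(seed, rnorm(length(temps), sd = noise_sd))
  out <- data.frame(T = temps, signal = y)
  attr(out, "truth") <- list(Tm = Tm, dT = dT, A1 = A1, A2 = A2,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic 1-D scattering curve
#'
#' Analytic Debye flexible-chain or homogeneous-sphere form factor on the
#' instrument q-range, with multiplicative Gaussian noise.
#'
#' @param model "debye_chain" (size_param = Rg in nm) or "sphere"
#'   (size_param = radius in nm).
#' @param size_param particle size, nm.
#' @param I0 forward intensity.
#' @param q_grid 1/Angstrom grid (default 300 points over 0.002-0.3).
#' @param noise_frac multiplicative noise fraction.
#' @param seed RNG seed.
#' @return `scattering_curve` with a `truth` attribute.
#' @export
gen_scattering <- function(model = c("debye_chain", "sphere"),
                           size_param = 2, I0 = 1,
                           q_grid = seq(0.002, 0.3, length.out = 300L),
                           noise_frac = 0, seed = 1L) {
  model <- match.arg(model)
  if (size_param <= 0) stopf("`size_param` must be positive")
  size_A <- size_param * 10            # nm -> Angstrom to match q
  P <- switch(model,
    debye_chain = {
      x <- (q_grid * size_A)^2
      2 * (exp(-x) + x - 1) / x^2
    },
    sphere = {
      qR <- q_grid * size_A
      (3 * (sin(qR) - qR * cos(qR)) / qR^3)^2
    })
  I <- I0 * P * (1 + with_seed(seed, rnorm(length(q_grid), sd = noise_frac)))
  curve <- scattering_curve(q_grid, I)
  attr(curve, "truth") <- list(
    model = model, size_param = size_param, I0 = I0,
    Rg_nm = if (model == "sphere") sqrt(3 / 5) * size_param else size_param,
    noise_frac = noise_frac, seed = seed)
  curve
}

#' Synthetic donor-only / donor-acceptor spectrum pair
#'
#' Gaussian donor emission band; in the donor-acceptor spectrum the donor
#' band is scaled by (1 - E_true) and a sensitised acceptor band appears
#' far to the red, so the donor-readout efficiency recovers E_true exactly
#' at zero noise.
#'
#' @param E_true ground-truth efficiency in \[0, 1).
#' @param donor_peak,acceptor_peak band centres, nm.
#' @param donor_sd,acceptor_sd band widths, nm.
#' @param amplitude donor peak intensity.
#' @param noise_sd additive Gaussian noise.
#' @param wavelengths nm grid (default 566-700, the donor-excitation
#'   emission scan).
#' @param seed RNG seed.
#' @return list with `donor` and `fret` (`emission_spectrum`s) and
#'   `truth`.
#' @export
gen_spectra_pair <- function(E_true = 0.3, donor_peak = 568,
                             acceptor_peak = 668, donor_sd = 12,
                             acceptor_sd = 10, amplitude = 1000,
                             noise_sd = 0, wavelengths = 566:700,
                             seed = 1L) {
  if (E_true < 0 || E_true >= 1) stopf("`E_true` must lie in [0, 1)")
  band <- function(mu, s) exp(-(wavelengths - mu)^2 / (2 * s^2))
  donor_band <- amplitude * band(donor_peak, donor_sd)
  acceptor_band <- 0.6 * amplitude * E_true * band(acceptor_peak, acceptor_sd)
  noise <- with_seed(seed, matrix(rnorm(2L * length(wavelengths),
                                        sd = noise_sd), nrow = 2L))
  donor <- emission_spectrum(wavelengths, donor_band + noise[1L, ],
                             label = "donor-only")
  fret <- emission_spectrum(wavelengths,
                            (1 - E_true) * donor_band + acceptor_band +
                              noise[2L, ],
                            label = "donor-acceptor")
  list(donor = donor, fret = fret,
       truth = list(E_true = E_true, donor_peak = donor_peak,
                    noise_sd = noise_sd, seed = seed))
}
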
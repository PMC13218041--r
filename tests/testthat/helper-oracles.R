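# Independent brute-force oracles used to cross-check the package
# implementations on small inputs. These deliberately avoid the package's
# own code paths.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# All maximal reverse-complement palindromes by O(n^2) substring scan:
# every even-length substring is tested for self-complementarity, and a
# hit is maximal when the one-base two-sided extension fails or leaves
# the sequence.
oracle_palindromes <- function(seq, min_len) {
  b <- strsplit(seq, "")[[1L]]
  n <- length(b)
  is_pal <- function(s, l) {
    sub <- b[s:(s + l - 1L)]
    all(sub == rev(unname(COMP[sub])))
  }
  hits <- list()
  for (l in seq(min_len, n, by = 2L)) {
    for (s in seq_len(n - l + 1L)) {
      if (!is_pal(s, l)) next
      extendable <- s > 1L && s + l <= n && is_pal(s - 1L, l + 2L)
      if (!extendable)
        hits[[length(hits) + 1L]] <- data.frame(
          start = s - 1L, length = l,
          segment = paste(b[s:(s + l - 1L)], collapse = ""))
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), length = integer(0),
                      segment = character(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Maximum nested Watson-Crick pairing by exhaustive recursion: position i
# is either unpaired or paired with every admissible k, splitting the
# interval. Exponential, fine for length <= 16.
oracle_fold_count <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1L]]
  wc <- function(x, y) (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    ks <- seq_len(j)
    ks <- ks[ks > i + min_loop]
    for (k in ks) {
      if (wc(b[i], b[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  rec(1L, length(b))
}

# Direct-sum radius of gyration (explicit loop, no matrix algebra).
oracle_rg <- function(coords) {
  n <- nrow(coords)
  ctr <- c(mean(coords[, 1]), mean(coords[, 2]), mean(coords[, 3]))
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + sum((coords[i, ] - ctr)^2)
  sqrt(acc / n)
}

# Dense-grid surface-area oracle for a union of spheres: sample points on
# a fine lat-long grid of each expanded sphere and keep those outside all
# other expanded spheres (area element weighting included).
oracle_union_area <- function(centers, radii, n_theta = 200L) {
  total <- 0
  n <- nrow(centers)
  for (i in seq_len(n)) {
    R <- radii[i]
    theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
    area_i <- 0
    for (th in theta) {
      n_phi <- max(8L, ceiling(2 * n_theta * sin(th)))
      phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
      pts <- cbind(R * sin(th) * cos(phi) + centers[i, 1],
                   R * sin(th) * sin(phi) + centers[i, 2],
                   R * cos(th) + centers[i, 3])
      dA <- R^2 * sin(th) * (pi / n_theta) * (2 * pi / n_phi)
      keep <- rep(TRUE, n_phi)
      for (j in seq_len(n)) {
        if (j == i) next
        dj <- sqrt(rowSums(sweep(pts, 2L, centers[j, ])^2))
        keep <- keep & dj >= radii[j]
      }
      area_i <- area_i + sum(keep) * dA
    }
    total <- total + area_i
  }
  total
}

# Brute-force per-residue mean-of-shortest distances (nm) and the
# resulting tight-binding cutoff, written as plain nested loops.
oracle_cutoff <- function(frames, group_A, residues_A, group_B) {
  per_frame <- numeric(length(frames))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    res_vals <- c()
    for (r in unique(residues_A)) {
      beads <- group_A[residues_A == r]
      dmins <- c()
      for (bd in beads) {
        dd <- Inf
        for (m in group_B)
          dd <- min(dd, sqrt(sum((f[bd, ] - f[m, ])^2)))
        dmins <- c(dmins, dd)
      }
      res_vals <- c(res_vals, mean(dmins))
    }
    per_frame[t] <- mean(res_vals)
  }
  mean(per_frame)
}

# Brute-force per-residue interaction counts.
oracle_profile <- function(frames, group_A, residues_A, group_B, cutoff_nm) {
  res_ids <- unique(residues_A)
  acc <- setNames(numeric(length(res_ids)), res_ids)
  for (f in frames) {
    for (ri in seq_along(res_ids)) {
      beads <- group_A[residues_A == res_ids[ri]]
      cnt <- 0
      for (m in group_B) {
        near <- FALSE
        for (bd in beads)
          if (sqrt(sum((f[bd, ] - f[m, ])^2)) <= cutoff_nm) near <- TRUE
        if (near) cnt <- cnt + 1
      }
      acc[ri] <- acc[ri] + cnt
    }
  }
  acc / length(frames)
}

# Closed-form single-pair LJ + reaction-field energy.
oracle_pair_energy <- function(r, qi, qj, sigi, sigj, epsi, epsj,
                               cutoff = 1.1, eps_r = 15) {
  if (r > cutoff) return(0)
  k_rf <- 1 / (2 * cutoff^3)
  c_rf <- 1 / cutoff + k_rf * cutoff^2
  sig <- (sigi + sigj) / 2
  eps <- sqrt(epsi * epsj)
  4 * eps * ((sig / r)^12 - (sig / r)^6) +
    138.935458 * qi * qj / eps_r * (1 / r + k_rf * r^2 - c_rf)
}
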
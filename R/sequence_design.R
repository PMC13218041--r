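# ssDNA library design: shuffling, palindrome exclusion, stability ranking,
# chimera assembly and charge bookkeeping.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Split a sequence string into a validated uppercase base vector.
# Errors name the first offending position so design scripts can pinpoint
# typos in synthesised construct tables.
dna_bases <- function(seq, what = "seq") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || nchar(seq) == 0L)
    stopf("`%s` must be a single non-empty character string", what)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad))
    stopf("invalid base '%s' at position %d of `%s` (alphabet is A/C/G/T)",
          bases[bad[1L]], bad[1L], what)
  bases
}

#' Reverse complement of a DNA sequence
#'
#' @param seq single character string over the alphabet A/C/G/T
#'   (case-insensitive).
#' @return character string: the reverse complement.
#' @examples
#' reverse_complement("ACGTT")  # "AACGT"
#' @export
reverse_complement <- function(seq) {
  bases <- dna_bases(seq)
  paste(rev(unname(DNA_COMPLEMENT[bases])), collapse = "")
}

#' Find reverse-complement palindromes in a DNA sequence
#'
#' A reverse-complement palindrome is a segment equal to the reverse
#' complement of itself (e.g. GAATTC, GTACGTAC); such segments are
#' necessarily of even length and enable intermolecular dimerisation of
#' single-stranded constructs. All maximal hits of length at least
#' `min_len` are returned; maximal means the segment cannot be extended by
#' one base on both sides and remain self-complementary. Overlapping
#' maximal hits are allowed.
#'
#' @param seq character string over A/C/G/T.
#' @param min_len minimum palindrome length to report, an even integer
#'   (default 6, the usual screening threshold for designed libraries).
#' @return data.frame with columns `start` (0-based offset), `length`
#'   (even nt count) and `segment`, sorted by `start`. Zero rows when the
#'   sequence is palindrome-free.
#' @examples
#' find_palindromes("GTACGTAC", 6)   # one 8-nt hit at start 0
#' find_palindromes("GAATTC", 6)     # canonical EcoRI site
#' @export
find_palindromes <- function(seq, min_len = 6L) {
  if (!is.numeric(min_len) || length(min_len) != 1L || min_len < 2L)
    stopf("`min_len` must be a single integer >= 2")
  if (min_len %% 2L != 0L)
    stopf("`min_len` must be even: reverse-complement palindromes have even length")
  bases <- dna_bases(seq)
  n <- length(bases)
  comp <- unname(DNA_COMPLEMENT[bases])
  starts <- integer(0); lens <- integer(0); segs <- character(0)
  # expand around each even centre (between positions c and c+1)
  for (cen in seq_len(n - 1L)) {
    l <- cen; r <- cen + 1L
    while (l >= 1L && r <= n && bases[l] == comp[r]) {
      l <- l - 1L; r <- r + 1L
    }
    len <- r - l - 1L
    if (len >= min_len) {
      starts <- c(starts, l)          # l is 0-based start after the while loop
      lens <- c(lens, len)
      segs <- c(segs, paste(bases[(l + 1L):(r - 1L)], collapse = ""))
    }
  }
  out <- data.frame(start = starts, length = lens, segment = segs,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Generate a pool of shuffled sequences
#'
#' Mononucleotide shuffling: each output is an independent uniform
#' permutation of the input bases, so base composition is conserved
#' exactly. The same seed always yields a byte-identical library.
#'
#' @param seq character string over A/C/G/T.
#' @param n number of shuffled sequences (default 100, the conventional
#'   pool size for stability screening).
#' @param seed integer RNG seed.
#' @param id label used to derive output ids (`<id>_shuf<k>`).
#' @return named character vector of length `n`.
#' @export
shuffle_library <- function(seq, n = 100L, seed = 1L, id = "seq") {
  if (!is.numeric(n) || length(n) != 1L || n < 1L)
    stopf("`n` must be a single integer >= 1")
  bases <- dna_bases(seq)
  out <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(bases), collapse = ""), character(1L)))
  names(out) <- sprintf("%s_shuf%03d", id, seq_len(n))
  out
}

#' Maximum nested Watson-Crick base pairing (fold stability proxy)
#'
#' Dynamic-programming maximisation of nested A-T/G-C pairs with a minimum
#' hairpin loop, in the Nussinov style. The pair count is an ordinal proxy
#' for fold stability: fewer attainable pairs means less predicted
#' secondary structure (a higher folding free energy), which is the
#' ranking criterion used when selecting minimally structured constructs
#' from a shuffled pool. It is not a thermodynamic free-energy model.
#'
#' @param seq character string over A/C/G/T.
#' @param min_loop minimum number of unpaired bases closing a hairpin
#'   (default 3).
#' @return object of class `fold_prediction`: list with `pair_count`,
#'   `pairs` (two-column matrix of 1-based indices i < j) and `structure`
#'   (dot-bracket string).
#' @export
fold_proxy <- function(seq, min_loop = 3L) {
  if (!is.numeric(min_loop) || length(min_loop) != 1L || min_loop < 0L)
    stopf("`min_loop` must be a single integer >= 0")
  bases <- dna_bases(seq)
  n <- length(bases)
  can_pair <- function(a, b) (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  M <- matrix(0L, n, n)
  if (n > min_loop + 1L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]                       # j unpaired
        for (k in i:(j - min_loop - 1L)) {         # j paired with k
          if (can_pair(bases[k], bases[j])) {
            left <- if (k > i) M[i, k - 1L] else 0L
            inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
            cand <- left + inner + 1L
            if (cand > best) best <- cand
          }
        }
        M[i, j] <- best
      }
    }
  }
  # traceback
  pairs <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (i >= j || j - i < min_loop + 1L || M[i, j] == 0L) next
    if (M[i, j] == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (!can_pair(bases[k], bases[j])) next
      left <- if (k > i) M[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
      if (left + inner + 1L == M[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  structure_chr <- rep(".", n)
  if (nrow(pairs)) {
    structure_chr[pairs[, 1L]] <- "("
    structure_chr[pairs[, 2L]] <- ")"
  }
  out <- list(pair_count = if (n > 1L) M[1L, n] else 0L,
              pairs = pairs,
              structure = paste(structure_chr, collapse = ""))
  class(out) <- "fold_prediction"
  out
}

#' @export
print.fold_prediction <- function(x, ...) {
  cat("Fold prediction:", x$pair_count, "nested Watson-Crick pairs\n")
  cat(x$structure, "\n")
  invisible(x)
}

#' Select a candidate sequence from a library
#'
#' Applies the two-step design rule for minimally structured,
#' dimerisation-free constructs: (1) drop every sequence containing a
#' reverse-complement palindrome of length >= `min_palindrome`; (2) rank
#' survivors by ascending [fold_proxy()] pair count (fewest pairs = least
#' predicted structure) and return the sequence at position `rank`. Ties
#' keep library order (stable sort), so results are reproducible.
#'
#' @param library character vector of sequences (names used as ids).
#' @param min_palindrome palindrome exclusion threshold (default 6).
#' @param rank 1-based rank among survivors (default 1: least structured).
#' @param min_loop passed to [fold_proxy()].
#' @return single named character string.
#' @export
select_candidate <- function(library, min_palindrome = 6L, rank = 1L,
                             min_loop = 3L) {
  if (length(library) < 1L) stopf("`library` must be non-empty")
  keep <- vapply(library, function(s)
    nrow(find_palindromes(s, min_palindrome)) == 0L, logical(1L))
  survivors <- library[keep]
  if (length(survivors) == 0L)
    stopf("all %d sequences contain a palindrome >= %d nt; nothing to select",
          length(library), min_palindrome)
  if (!is.numeric(rank) || length(rank) != 1L || rank < 1L ||
      rank > length(survivors))
    stopf("`rank` must be between 1 and %d (number of survivors)",
          length(survivors))
  counts <- vapply(survivors, function(s) fold_proxy(s, min_loop)$pair_count,
                   integer(1L))
  ord <- order(counts)                 # stable: ties keep library order
  survivors[ord[rank]]
}

#' Assemble a chimeric sequence from two equal-length parents
#'
#' Splices the `ordered` parent's bases into the `disordered` parent over
#' the given intervals, the way hairpin modules are grafted between a
#' structured and an unstructured construct to build intermediates.
#'
#' @param ordered,disordered equal-length sequences.
#' @param regions list of 0-based half-open intervals `c(start, end)` taken
#'   from `ordered`; must be within bounds and non-overlapping. An empty
#'   list returns `disordered` unchanged.
#' @return character string of the same length as the parents.
#' @examples
#' assemble_chimera("AAAAAAAA", "TTTTTTTT", list(c(2, 5)))  # "TTAAATTT"
#' @export
assemble_chimera <- function(ordered, disordered, regions = list()) {
  a <- dna_bases(ordered, "ordered")
  b <- dna_bases(disordered, "disordered")
  if (length(a) != length(b))
    stopf("parents must have equal length (%d vs %d)", length(a), length(b))
  n <- length(a)
  if (!is.list(regions)) regions <- list(regions)
  used <- logical(n)
  out <- b
  for (iv in regions) {
    if (length(iv) != 2L || !is.numeric(iv))
      stopf("each region must be a numeric pair c(start, end)")
    s <- iv[1L]; e <- iv[2L]
    if (s < 0L || e > n || s >= e)
      stopf("region [%g, %g) out of bounds for length-%d sequence", s, e, n)
    idx <- (s + 1L):e
    if (any(used[idx])) stopf("regions overlap at position %d", which(used[idx])[1L] + s)
    used[idx] <- TRUE
    out[idx] <- a[idx]
  }
  paste(out, collapse = "")
}

PEPTIDE_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                      "L","K","M","F","P","S","T","W","Y","V")

#' Net side-chain charge of a peptide at neutral pH
#'
#' count(K, R) - count(D, E); histidine and the termini contribute zero
#' (free N/C termini cancel).
#'
#' @param pep one-letter amino-acid string.
#' @return signed integer.
#' @examples
#' peptide_net_charge("LGKSGRLPGKSGRV")  # +4
#' @export
peptide_net_charge <- function(pep) {
  if (length(pep) != 1L || !is.character(pep) || nchar(pep) == 0L)
    stopf("`pep` must be a single non-empty character string")
  res <- strsplit(toupper(pep), "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% PEPTIDE_ALPHABET)
  if (length(bad))
    stopf("unknown residue code '%s' at position %d", res[bad[1L]], bad[1L])
  sum(res %in% c("K", "R")) - sum(res %in% c("D", "E"))
}

#' Peptide-per-DNA charge stoichiometry
#'
#' Number of cationic peptides needed to neutralise one ssDNA molecule,
#' modelling one negative charge per phosphodiester bond (length - 1).
#'
#' @param dna_length construct length in nucleotides (>= 2).
#' @param peptide_charge positive net peptide charge.
#' @return list with `ratio` (exact peptides per DNA) and `n_peptides`
#'   (nearest integer).
#' @examples
#' charge_stoichiometry(76, 5)  # 15 peptides per 76-mer
#' @export
charge_stoichiometry <- function(dna_length, peptide_charge) {
  assert_scalar_num(dna_length, "dna_length", lower = 2)
  if (!is.numeric(peptide_charge) || length(peptide_charge) != 1L ||
      peptide_charge <= 0)
    stopf("`peptide_charge` must be a positive number")
  ratio <- (dna_length - 1) / peptide_charge
  list(ratio = ratio, n_peptides = as.integer(round(ratio)))
}
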
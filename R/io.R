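# Format readers and writers: FASTA (via Biostrings), multi-frame XYZ,
# fixed-column GRO, topology and measurement tables.

#' Read a FASTA file of DNA sequences
#'
#' Ids are taken from the header up to the first whitespace; lowercase
#' input is upcased with a warning.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stopf("no records in %s", path)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) stopf("empty record in %s", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(grepl("[a-z]", seqs))) {
    warnf("lowercase bases in %s upcased", path)
    seqs <- toupper(seqs)
  }
  seqs
}

#' Write sequences to FASTA (60-column wrapping)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ dialect: bead count line, comment line, then one
#' `name x y z` line per bead; frames concatenated. Coordinates are taken
#' as nm unless `angstrom = TRUE`.
#'
#' @param path XYZ file.
#' @param dt_ns frame spacing, ns.
#' @param box optional cubic box edge, nm.
#' @param angstrom divide coordinates by 10 on input.
#' @return `bead_trajectory`.
#' @export
read_xyz <- function(path, dt_ns = 1, box = NULL, angstrom = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stopf("parse error at line %d of %s: expected a bead count", i, path)
    if (i + 1L + n > length(lines))
      stopf("parse error at line %d of %s: truncated frame (%d beads declared)",
            i, path, n)
    block <- lines[(i + 2L):(i + 1L + n)]
    coords <- t(vapply(seq_along(block), function(k) {
      parts <- strsplit(trimws(block[k]), "\\s+")[[1L]]
      if (length(parts) < 4L)
        stopf("parse error at line %d of %s: expected 'name x y z'",
              i + 1L + k, path)
      v <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(v)))
        stopf("parse error at line %d of %s: non-numeric coordinate",
              i + 1L + k, path)
      v
    }, numeric(3L)))
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  if (!length(frames)) stopf("no frames in %s", path)
  nb <- vapply(frames, nrow, integer(1L))
  if (length(unique(nb)) != 1L)
    stopf("inconsistent bead counts across frames in %s", path)
  if (angstrom) frames <- lapply(frames, function(f) f / 10)
  bead_trajectory(frames, dt_ns = dt_ns, box = box)
}

#' Write a multi-frame XYZ trajectory
#'
#' @param traj `bead_trajectory`.
#' @param path output file.
#' @param names bead names (default B1..Bn).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, names = NULL) {
  n <- n_beads(traj)
  if (is.null(names)) names <- sprintf("B%d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    writeLines(c(as.character(n), sprintf("frame %d", k),
                 sprintf("%s %.6f %.6f %.6f", names, f[, 1L], f[, 2L], f[, 3L])),
               con)
  }
  invisible(path)
}

#' Read a GRO structure/trajectory file
#'
#' Fixed-column GROMACS dialect, nm units: title, atom count, atom lines
#' with positions in columns 21-44 (three F8.3 fields), box line.
#' Multi-frame files (concatenated blocks) are supported.
#'
#' @param path GRO file.
#' @param dt_ns frame spacing, ns.
#' @return `bead_trajectory` with the first frame's cubic box edge (when
#'   the box is cubic) attached.
#' @export
read_gro <- function(path, dt_ns = 1) {
  lines <- readLines(path)
  frames <- list(); box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (i + 1L > length(lines)) stopf("truncated GRO header at line %d", i)
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1L)
      stopf("parse error at line %d of %s: expected an atom count", i + 1L, path)
    if (i + 2L + n > length(lines))
      stopf("parse error at line %d of %s: truncated frame", i, path)
    block <- lines[(i + 2L):(i + 1L + n)]
    coords <- t(vapply(seq_along(block), function(k) {
      ln <- block[k]
      v <- suppressWarnings(as.numeric(c(substr(ln, 21L, 28L),
                                         substr(ln, 29L, 36L),
                                         substr(ln, 37L, 44L))))
      if (any(is.na(v)))
        stopf("parse error at line %d of %s: bad coordinate columns",
              i + 1L + k, path)
      v
    }, numeric(3L)))
    frames[[length(frames) + 1L]] <- coords
    boxv <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1L]]))
    if (is.null(box) && length(boxv) >= 3L && !any(is.na(boxv[1:3])) &&
        boxv[1L] > 0 && isTRUE(all.equal(boxv[1L], boxv[2L])) &&
        isTRUE(all.equal(boxv[1L], boxv[3L])))
      box <- boxv[1L]
    i <- i + 3L + n
  }
  if (!length(frames)) stopf("no frames in %s", path)
  bead_trajectory(frames, dt_ns = dt_ns, box = box)
}

#' Write a (multi-frame) GRO file
#'
#' @param traj `bead_trajectory`.
#' @param path output file.
#' @param topology optional `bead_topology` for residue/atom names.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, topology = NULL) {
  n <- n_beads(traj)
  resid <- if (is.null(topology)) seq_len(n) else topology$residue
  resnm <- if (is.null(topology)) rep("BEAD", n) else
    substr(topology$molecule, 1L, 5L)
  atomnm <- if (is.null(topology)) sprintf("B%d", seq_len(n)) else
    substr(topology$bead, 1L, 5L)
  box <- traj$box %||% 0
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid %% 100000L, resnm, atomnm, seq_len(n) %% 100000L,
                       f[, 1L], f[, 2L], f[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box, box, box), con)
  }
  invisible(path)
}

#' Read a bead topology table
#'
#' Tab- or comma-delimited table with columns bead, radius, charge,
#' sigma, epsilon, molecule, residue (header required; missing optional
#' columns take the [bead_topology()] defaults).
#'
#' @param path table file.
#' @return `bead_topology`.
#' @export
read_topology <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!"bead" %in% names(df)) stopf("topology table needs a `bead` column")
  args <- list(bead = df$bead)
  for (col in c("radius", "charge", "sigma", "epsilon", "molecule", "residue"))
    if (col %in% names(df)) args[[col]] <- df[[col]]
  do.call(bead_topology, args)
}

#' Write a bead topology table
#'
#' @param topology `bead_topology`.
#' @param path output file (TSV).
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  write.table(as.data.frame(topology), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Generic two-or-more-column numeric table; used by the spectrum, melt,
# fusion and FRAP readers.
read_numeric_table <- function(path, required) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  df <- read.delim(path, sep = if (sep == "") "" else sep,
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  df
}

#' Read an emission spectrum table (wavelength, intensity)
#' @param path delimited table with columns `wavelength`, `intensity`.
#' @param label spectrum label (defaults to the file name).
#' @return `emission_spectrum`.
#' @export
read_spectrum <- function(path, label = basename(path)) {
  df <- read_numeric_table(path, c("wavelength", "intensity"))
  emission_spectrum(df$wavelength, df$intensity, label = label)
}

#' Read a melt curve table (temperature, signal)
#' @param path delimited table with columns `temperature`, `signal`.
#' @return data.frame with columns `T`, `signal`.
#' @export
read_melt_curve <- function(path) {
  df <- read_numeric_table(path, c("temperature", "signal"))
  data.frame(T = df$temperature, signal = df$signal)
}

#' Read a FRAP trace table
#'
#' Delimited table with columns `t`, `R1`, `R2`, `R3`; prebleach values
#' come either from `#pre` comment header lines (`#pre R1 <v>` etc.) or
#' from rows with negative `t` (averaged per channel).
#'
#' @param path table file.
#' @return `frap_trace`.
#' @export
read_frap_table <- function(path) {
  lines <- readLines(path)
  pre_lines <- grep("^#pre", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"),
                   sep = if (grepl(",", body[1L])) "," else "")
  miss <- setdiff(c("t", "R1", "R2", "R3"), names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  pre <- c(R1 = NA_real_, R2 = NA_real_, R3 = NA_real_)
  for (pl in pre_lines) {
    parts <- strsplit(trimws(pl), "\\s+")[[1L]]
    if (length(parts) >= 3L && parts[2L] %in% names(pre))
      pre[parts[2L]] <- as.numeric(parts[3L])
  }
  neg <- df$t < 0
  if (any(neg)) {
    for (ch in c("R1", "R2", "R3"))
      if (is.na(pre[ch])) pre[ch] <- mean(df[[ch]][neg])
    df <- df[!neg, , drop = FALSE]
  }
  if (any(is.na(pre)))
    stopf("%s has no prebleach information (#pre lines or negative-t rows)",
          path)
  frap_trace(df$t, df$R1, df$R2, df$R3,
             I_R1_pre = pre["R1"], I_R2_pre = pre["R2"], I_R3_pre = pre["R3"])
}

#' Read a fusion event table
#'
#' Columns `t` plus either `AR` or the axis pair `l_long`, `l_short`.
#'
#' @param path table file.
#' @param trim_precontact drop leading frames with non-finite AR.
#' @return data.frame with columns `t`, `AR`.
#' @export
read_fusion_table <- function(path, trim_precontact = TRUE) {
  df <- read_numeric_table(path, "t")
  if (!"AR" %in% names(df)) {
    if (!all(c("l_long", "l_short") %in% names(df)))
      stopf("%s needs either an AR column or l_long/l_short columns", path)
    df$AR <- aspect_ratio_series(df$l_long, df$l_short)
  }
  if (trim_precontact) {
    ok <- is.finite(df$AR)
    first <- which(ok)[1L]
    if (is.na(first)) stopf("no finite AR frames in %s", path)
    df <- df[seq(first, nrow(df)), , drop = FALSE]
    df <- df[is.finite(df$AR), , drop = FALSE]
    df$t <- df$t - df$t[1L]            # t = 0 at first post-contact frame
  }
  df[, c("t", "AR")]
}

#' Read a 1-D scattering curve table
#' @param path delimited table with columns `q`, `I` (optional `sigma`).
#' @return `scattering_curve`.
#' @export
read_scattering <- function(path) {
  df <- read_numeric_table(path, c("q", "I"))
  scattering_curve(df$q, df$I, sigma = df$sigma)
}
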
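# Structure-file I/O. GRO files are parsed here directly (fixed-column
# GROMACS layout, coordinates in nm converted to Angstrom on read); PDB
# records go through bio3d, with the CRYST1 box handled alongside.

parse_gro_block <- function(lines, offset, path, class_table) {
  title <- lines[1]
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1)
    stopf("%s:%d: invalid atom count '%s'", path, offset + 2L, lines[2])
  if (length(lines) < n + 3L)
    stopf("%s: truncated frame (expected %d atom lines + box)", path, n)
  at <- lines[3:(n + 2L)]
  num <- function(s, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v))
      stopf("%s:%d: malformed %s field", path,
            offset + 2L + which(is.na(v))[1], what)
    v
  }
  resid <- as.integer(num(at, 1, 5, "residue number", 0))
  resname <- trimws(substr(at, 6, 10))
  atname <- trimws(substr(at, 11, 15))
  x <- num(at, 21, 28, "x coordinate", 0) * 10
  y <- num(at, 29, 36, "y coordinate", 0) * 10
  z <- num(at, 37, 44, "z coordinate", 0) * 10
  boxline <- trimws(lines[n + 3L])
  if (!nzchar(boxline))
    stopf("%s:%d: missing box line", path, offset + n + 3L)
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  if (anyNA(bv) || length(bv) < 3)
    stopf("%s:%d: malformed box line '%s'", path, offset + n + 3L, boxline)
  if (length(bv) > 3 && any(abs(bv[4:length(bv)]) > 1e-9))
    stopf("%s: triclinic box is not supported (orthorhombic only)", path)
  ftime <- 0
  tm <- regmatches(title, regexec("t\\s*=\\s*([-0-9.eE+]+)", title))[[1]]
  if (length(tm) == 2) ftime <- as.numeric(tm[2])
  cg_frame(cbind(x, y, z), residue_name = resname, residue_index = resid,
           chain_id = rep("A", n), bead_name = atname,
           box = bv[1:3] * 10, frame_time = ftime, class_table = class_table)
}

read_gro <- function(path, class_table = bead_classification_table()) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1L
  while (pos + 2L <= length(lines) && nzchar(trimws(lines[pos + 1L]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(n)) stopf("%s:%d: invalid atom count", path, pos + 1L)
    if (pos + n + 2L > length(lines))
      stopf("%s: truncated frame (missing atoms or box line)", path)
    frames[[length(frames) + 1L]] <-
      parse_gro_block(lines[pos:(pos + n + 2L)], pos - 1L, path, class_table)
    pos <- pos + n + 3L
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
    if (pos > length(lines)) break
  }
  if (!length(frames)) stopf("%s: no frames found", path)
  frames
}

write_gro <- function(frames, path) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- n_beads(fr)
    writeLines(sprintf("cgmem frame, t= %g ns", fr$frame_time), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       fr$residue_index %% 100000L,
                       substr(fr$residue_name, 1, 5),
                       substr(fr$bead_name, 1, 5),
                       seq_len(n) %% 100000L,
                       fr$coords[, 1] / 10, fr$coords[, 2] / 10,
                       fr$coords[, 3] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10), con)
  }
  invisible(path)
}

read_pdb_frame <- function(path, class_table = bead_classification_table()) {
  cry <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cry)) stopf("%s: missing CRYST1 box record", path)
  bv <- suppressWarnings(as.numeric(c(substr(cry[1], 7, 15),
                                      substr(cry[1], 16, 24),
                                      substr(cry[1], 25, 33))))
  ang <- suppressWarnings(as.numeric(c(substr(cry[1], 34, 40),
                                       substr(cry[1], 41, 47),
                                       substr(cry[1], 48, 54))))
  if (anyNA(bv)) stopf("%s: malformed CRYST1 record", path)
  if (!anyNA(ang) && any(abs(ang - 90) > 1e-3))
    stopf("%s: triclinic box is not supported (orthorhombic only)", path)
  p <- bio3d::read.pdb(path)
  a <- p$atom
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  cg_frame(cbind(a$x, a$y, a$z), residue_name = a$resid,
           residue_index = a$resno, chain_id = chain, bead_name = a$elety,
           box = bv, frame_time = 0, class_table = class_table)
}

# ATOM records are written directly: four-character residue names (DPPC)
# occupy columns 18-21 with the chain identifier in column 22, the layout
# coarse-grained PDB files use
write_pdb_frame <- function(frame, path) {
  cry <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 frame$box[1], frame$box[2], frame$box[3], 90, 90, 90)
  name4 <- ifelse(nchar(frame$bead_name) <= 3,
                  sprintf(" %-3s", frame$bead_name),
                  substr(frame$bead_name, 1, 4))
  atoms <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   seq_len(n_beads(frame)) %% 100000L, name4,
                   substr(frame$residue_name, 1, 4),
                   substr(frame$chain_id, 1, 1),
                   frame$residue_index %% 10000L,
                   frame$coords[, 1], frame$coords[, 2], frame$coords[, 3],
                   1, 0)
  writeLines(c(cry, atoms, "END"), path)
  invisible(path)
}

#' Read a coarse-grained snapshot
#'
#' Reads the first (or only) frame of a GRO or PDB file. GRO coordinates are
#' stored in nm and converted to Angstrom; PDB coordinates are already in
#' Angstrom. Use [read_trajectory()] for multi-frame GRO files.
#'
#' @param path input file.
#' @param format `"gro"` or `"pdb"`; guessed from the extension by default.
#' @param class_table bead classification table.
#' @return a [cg_frame()].
#' @export
read_frame <- function(path, format = c("auto", "gro", "pdb"),
                       class_table = bead_classification_table()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "pdb") read_pdb_frame(path, class_table)
  else read_gro(path, class_table)[[1]]
}

#' Read all frames of a trajectory file
#'
#' @inheritParams read_frame
#' @return list of [cg_frame()] objects in file order.
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "pdb"),
                            class_table = bead_classification_table()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "pdb") list(read_pdb_frame(path, class_table))
  else read_gro(path, class_table)
}

#' Write frame(s) to a structure file
#'
#' @param frames a [cg_frame()] or list of frames (GRO supports multi-frame).
#' @param path output file.
#' @param format `"gro"` or `"pdb"`; guessed from the extension by default.
#' @export
write_frame <- function(frames, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (format == "pdb") {
    if (!inherits(frames, "cg_frame")) frames <- frames[[1]]
    write_pdb_frame(frames, path)
  } else write_gro(frames, path)
}
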
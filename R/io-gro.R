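# Native reader/writer for the fixed-column GRO format (nm, 3 decimals).
# Multi-frame trajectories are plain concatenations of single-frame blocks;
# frame times are parsed from the customary "t= <ns>" tag in the title line.

parse_gro_file <- function(path, first_only = FALSE) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  n_total <- length(lines)
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i])) && i == n_total) break
    title <- lines[i]
    if (i + 1L > n_total) {
      stop("GRO parse error at line ", i + 1L, ": missing atom count",
           call. = FALSE)
    }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms <= 0L) {
      stop("GRO parse error at line ", i + 1L,
           ": expected a positive atom count, got '",
           trimws(lines[i + 1L]), "'", call. = FALSE)
    }
    atom_first <- i + 2L
    atom_last <- atom_first + natoms - 1L
    if (atom_last + 1L > n_total) {
      stop("GRO parse error: frame starting at line ", i,
           " is truncated (needs ", natoms, " atom lines plus a box line)",
           call. = FALSE)
    }
    al <- lines[atom_first:atom_last]
    bad <- which(nchar(al) < 44L)
    if (length(bad)) {
      stop("GRO parse error at line ", atom_first + bad[1L] - 1L,
           ": atom line shorter than the fixed 44-column minimum",
           call. = FALSE)
    }
    resid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
    resname <- trimws(substr(al, 6L, 10L))
    bead_name <- trimws(substr(al, 11L, 15L))
    x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad)) {
      stop("GRO parse error at line ", atom_first + bad[1L] - 1L,
           ": malformed numeric field", call. = FALSE)
    }
    box <- parse_gro_box(lines[atom_last + 1L], atom_last + 1L)
    frames[[length(frames) + 1L]] <- list(
      atoms = tibble::tibble(resid = resid, resname = resname,
                             bead_name = bead_name),
      time = parse_title_time(title),
      positions = cbind(x, y, z, deparse.level = 0L),
      box = box
    )
    if (first_only) break
    i <- atom_last + 2L
  }
  if (!length(frames)) stop("no frames found in '", path, "'", call. = FALSE)
  list(frames = frames)
}

parse_gro_box <- function(line, lineno) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1L]]))
  if (length(vals) < 3L || anyNA(vals)) {
    stop("GRO parse error at line ", lineno, ": malformed box line",
         call. = FALSE)
  }
  if (length(vals) > 3L && any(abs(vals[-(1:3)]) > 1e-9)) {
    stop("triclinic boxes are not supported (off-diagonal box vector ",
         "components found at line ", lineno, ")", call. = FALSE)
  }
  if (any(vals[1:3] <= 0)) {
    stop("GRO parse error at line ", lineno, ": box lengths must be positive",
         call. = FALSE)
  }
  vals[1:3]
}

parse_title_time <- function(title) {
  m <- regmatches(title, regexpr("t\\s*=\\s*[0-9eE.+-]+", title))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("t\\s*=\\s*", "", m))
}

write_gro_file <- function(topology, trajectory, path) {
  b <- topology$beads
  con <- file(path, open = "wt")
  on.exit(close(con))
  nb <- nrow(b)
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_positions(trajectory, f)
    lines <- c(
      sprintf("lipidsites frame %d t= %.5f", f - 1L, trajectory$times[f]),
      sprintf("%5d", nb),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              b$resid %% 100000L, substr(b$resname, 1L, 5L),
              substr(b$bead_name, 1L, 5L), b$bead %% 100000L,
              xyz[, 1L], xyz[, 2L], xyz[, 3L]),
      sprintf("%10.5f%10.5f%10.5f", trajectory$box[f, 1L],
              trajectory$box[f, 2L], trajectory$box[f, 3L])
    )
    writeLines(lines, con)
  }
  invisible(path)
}
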
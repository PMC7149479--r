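# Native reader/writer for multi-MODEL PDB. PDB coordinates are in
# Angstrom; they are converted to nm on read and back on write. The box is
# carried in the CRYST1 record (orthorhombic only).

parse_pdb_file <- function(path, first_only = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  cryst <- which(rec == "CRYST1")
  box <- NULL
  if (length(cryst)) {
    cl <- lines[cryst[1L]]
    abc <- suppressWarnings(as.numeric(c(substr(cl, 7L, 15L),
                                         substr(cl, 16L, 24L),
                                         substr(cl, 25L, 33L))))
    ang <- suppressWarnings(as.numeric(c(substr(cl, 34L, 40L),
                                         substr(cl, 41L, 47L),
                                         substr(cl, 48L, 54L))))
    if (anyNA(abc) || any(abc <= 0)) {
      stop("PDB parse error at line ", cryst[1L], ": malformed CRYST1",
           call. = FALSE)
    }
    if (!anyNA(ang) && any(abs(ang - 90) > 1e-6)) {
      stop("triclinic boxes are not supported (CRYST1 angles != 90)",
           call. = FALSE)
    }
    box <- abc / 10
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM records in '", path, "'", call. = FALSE)

  # frame id per atom line: 1 if no MODEL records, else the enclosing MODEL
  model_id <- cumsum(is_model)
  frame_of_atom <- model_id[is_atom]
  if (all(frame_of_atom == 0L)) frame_of_atom <- rep(1L, sum(is_atom))
  if (any(frame_of_atom == 0L)) {
    stop("PDB parse error: ATOM records outside any MODEL block",
         call. = FALSE)
  }

  al <- lines[is_atom]
  lineno <- which(is_atom)
  name <- trimws(substr(al, 13L, 16L))
  resname <- trimws(substr(al, 18L, 21L))
  resid <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("PDB parse error at line ", lineno[bad[1L]],
         ": malformed ATOM record", call. = FALSE)
  }

  frame_ids <- unique(frame_of_atom)
  if (first_only) frame_ids <- frame_ids[1L]
  frames <- lapply(frame_ids, function(fid) {
    sel <- frame_of_atom == fid
    list(
      atoms = tibble::tibble(resid = resid[sel], resname = resname[sel],
                             bead_name = name[sel]),
      time = NA_real_,
      positions = cbind(x[sel], y[sel], z[sel]) / 10,
      box = box
    )
  })
  list(frames = frames)
}

write_pdb_file <- function(topology, trajectory, path, bfactor = NULL) {
  b <- topology$beads
  nb <- nrow(b)
  bf <- bfactor %||% rep(0, nb)
  stopifnot(length(bf) == nb)
  chain <- rep("A", nb)
  prot <- b$mol_type == "protein"
  if (any(prot)) {
    chain_idx <- (b$copy[prot] - 1L) * max(b$monomer[prot]) + b$monomer[prot]
    chain[prot] <- LETTERS[(chain_idx - 1L) %% 26L + 1L]
  }
  chain[!prot] <- "X"
  con <- file(path, open = "wt")
  on.exit(close(con))
  box <- trajectory$box[1L, ] * 10
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box[1L], box[2L], box[3L], 90, 90, 90), con)
  for (f in seq_len(n_frames(trajectory))) {
    xyz <- frame_positions(trajectory, f) * 10
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      b$bead %% 100000L, substr(b$bead_name, 1L, 4L),
      substr(b$resname, 1L, 4L), chain, b$resid %% 10000L,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, pmin(bf, 99.99)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
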
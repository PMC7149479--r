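#' Coarse-grained system topology
#'
#' A `cg_topology` is the static description of a system: every bead with
#' its residue and molecule assignment, the grouping of protein chains into
#' copies and monomers, and the lipid species table in force. Protein
#' molecules are auto-detected as chains of amino-acid-named residues; every
#' other residue must appear in the species table.
#'
#' @param beads A tibble with columns `bead` (1-based index), `bead_name`,
#'   `resid` (residue id as written in the file; within-monomer for protein),
#'   `resname`, `mol_id`, `mol_type` ("protein" or "lipid"), `species`
#'   (NA for protein beads), `copy`, `monomer` (NA for lipids).
#' @param species_table Species tibble, see [default_species()].
#' @return A `cg_topology` object.
#' @keywords internal
new_cg_topology <- function(beads, species_table) {
  stopifnot(is.data.frame(beads))
  out <- structure(
    list(beads = tibble::as_tibble(beads), species = species_table),
    class = "cg_topology"
  )
  validate_topology(out)
}

validate_topology <- function(topology) {
  b <- topology$beads
  if (anyDuplicated(b$bead)) stop("duplicate bead indices", call. = FALSE)
  if (any(is.na(b$mol_id))) stop("every bead needs a molecule", call. = FALSE)
  per_mol <- dplyr::summarise(
    dplyr::group_by(b, .data$mol_id),
    n_types = dplyr::n_distinct(.data$mol_type),
    .groups = "drop"
  )
  if (any(per_mol$n_types != 1L)) {
    stop("a molecule mixes protein and lipid beads", call. = FALSE)
  }
  prot <- b[b$mol_type == "protein", ]
  if (nrow(prot)) {
    dup <- dplyr::summarise(
      dplyr::group_by(prot, .data$copy, .data$monomer, .data$resid),
      n_names = dplyr::n_distinct(.data$resname),
      .groups = "drop"
    )
    if (any(dup$n_names != 1L)) {
      stop("residue ids within a monomer must be unique", call. = FALSE)
    }
  }
  invisible(topology)
}

#' @export
print.cg_topology <- function(x, ...) {
  b <- x$beads
  prot <- b[b$mol_type == "protein", ]
  lip <- b[b$mol_type == "lipid", ]
  cat("<cg_topology> ", nrow(b), " beads\n", sep = "")
  if (nrow(prot)) {
    cat("  protein: ", dplyr::n_distinct(prot$copy), " copies x ",
        dplyr::n_distinct(prot$monomer), " monomers, ",
        dplyr::n_distinct(prot[, c("copy", "monomer", "resid")]),
        " residues\n", sep = "")
  }
  if (nrow(lip)) {
    counts <- table(lip$species[!duplicated(lip$mol_id)])
    cat("  lipids: ",
        paste(names(counts), counts, sep = ":", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

n_beads <- function(topology) nrow(topology$beads)

protein_beads <- function(topology) {
  topology$beads[topology$beads$mol_type == "protein", ]
}

lipid_beads <- function(topology, species = NULL) {
  b <- topology$beads[topology$beads$mol_type == "lipid", ]
  if (!is.null(species)) b <- b[b$species %in% species, ]
  b
}

#' Table of protein residues
#'
#' One row per protein residue instance with its copy, monomer,
#' within-monomer residue id and name, plus a pooled residue key
#' (`resname` + `resid`) shared by equivalent residues across monomers and
#' copies.
#'
#' @param topology A `cg_topology`.
#' @return A tibble with columns `copy`, `monomer`, `resid`, `resname`,
#'   `res_key` (unique per instance), `pooled_key`.
#' @export
protein_residues <- function(topology) {
  prot <- protein_beads(topology)
  out <- dplyr::distinct(prot, .data$copy, .data$monomer, .data$resid,
                         .data$resname)
  out$res_key <- sprintf("c%d.m%d:%s%d", out$copy, out$monomer,
                         out$resname, out$resid)
  out$pooled_key <- sprintf("%s%d", out$resname, out$resid)
  dplyr::arrange(out, .data$copy, .data$monomer, .data$resid)
}

# headgroup bead rows for one species, with lipid molecule ids
headgroup_beads <- function(topology, spec) {
  b <- lipid_beads(topology, spec$species)
  b[b$bead_name %in% spec$headgroup_beads, ]
}

#' Read a topology from a coordinate file
#'
#' Reads the first frame of a GRO or PDB file and classifies its contents:
#' chains of amino-acid residues become protein monomers (a new monomer
#' starts when the residue id resets), every other residue becomes one lipid
#' molecule and must be present in the species table. Monomers are grouped
#' into protein copies `monomers_per_copy` at a time (default: all monomers
#' form a single copy, the usual case for one multimeric channel).
#'
#' @param path Path to a `.gro` or `.pdb` file.
#' @param format `"gro"` or `"pdb"`; guessed from the extension by default.
#' @param species_table Species tibble, see [default_species()].
#' @param monomers_per_copy Number of chains per protein copy, or `NULL`
#'   for a single copy.
#' @return A `cg_topology`.
#' @export
read_topology <- function(path, format = c("auto", "gro", "pdb"),
                          species_table = default_species(),
                          monomers_per_copy = NULL) {
  format <- resolve_format(match.arg(format), path)
  validate_species_table(species_table)
  frame1 <- switch(format,
    gro = parse_gro_file(path, first_only = TRUE)$frames[[1L]],
    pdb = parse_pdb_file(path, first_only = TRUE)$frames[[1L]]
  )
  build_topology(frame1$atoms, species_table, monomers_per_copy)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gro", "pdb")) return(ext)
  stop("cannot guess format from extension '", ext,
       "'; pass format = \"gro\" or \"pdb\"", call. = FALSE)
}

# atoms: tibble(resid, resname, bead_name) in file order
build_topology <- function(atoms, species_table, monomers_per_copy = NULL) {
  n <- nrow(atoms)
  # residue instances = runs of constant (resid, resname)
  key <- paste(atoms$resid, atoms$resname)
  new_res <- c(TRUE, key[-1L] != key[-n])
  res_idx <- cumsum(new_res)
  res_first <- which(new_res)
  res_name <- atoms$resname[res_first]
  res_id <- atoms$resid[res_first]
  is_prot_res <- res_name %in% AMINO_ACIDS

  unknown <- setdiff(unique(res_name[!is_prot_res]), species_table$resname)
  if (length(unknown)) {
    stop("unclassified molecule(s): residue name(s) ",
         paste(unknown, collapse = ", "),
         " are neither amino acids nor in the species table", call. = FALSE)
  }

  n_res <- length(res_first)
  # protein chains: consecutive protein residues; new chain when resid
  # does not increase (numbering reset) or after a lipid
  chain <- integer(n_res)
  mol_of_res <- integer(n_res)
  mol_counter <- 0L
  chain_counter <- 0L
  prev_prot <- FALSE
  prev_resid <- NA_integer_
  for (i in seq_len(n_res)) {
    if (is_prot_res[i]) {
      if (!prev_prot || res_id[i] <= prev_resid) {
        chain_counter <- chain_counter + 1L
        mol_counter <- mol_counter + 1L
      }
      chain[i] <- chain_counter
      mol_of_res[i] <- mol_counter
      prev_prot <- TRUE
      prev_resid <- res_id[i]
    } else {
      mol_counter <- mol_counter + 1L
      mol_of_res[i] <- mol_counter
      prev_prot <- FALSE
      prev_resid <- NA_integer_
    }
  }

  mpc <- monomers_per_copy %||% max(chain, 1L)
  copy_of_chain <- function(ch) (ch - 1L) %/% mpc + 1L
  monomer_of_chain <- function(ch) (ch - 1L) %% mpc + 1L

  sp_lookup <- stats::setNames(species_table$species, species_table$resname)
  beads <- tibble::tibble(
    bead = seq_len(n),
    bead_name = atoms$bead_name,
    resid = atoms$resid,
    resname = atoms$resname,
    mol_id = mol_of_res[res_idx],
    mol_type = ifelse(is_prot_res[res_idx], "protein", "lipid"),
    species = ifelse(is_prot_res[res_idx], NA_character_,
                     unname(sp_lookup[atoms$resname])),
    copy = as.integer(ifelse(is_prot_res[res_idx],
                             copy_of_chain(chain[res_idx]), NA_integer_)),
    monomer = as.integer(ifelse(is_prot_res[res_idx],
                                monomer_of_chain(chain[res_idx]),
                                NA_integer_))
  )
  new_cg_topology(beads, species_table)
}
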
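#' Lipid species definitions
#'
#' A species table maps lipid residue names to a species label, the set of
#' bead names that constitute the lipid's polar headgroup for contact
#' purposes, and the default contact cutoff. The shipped defaults follow the
#' usual coarse-grained naming: the phosphate plus the choline, ethanolamine
#' or serine moiety for PC, PE and PS respectively; the inositol ring plus
#' all attached phosphates for PIP2; all sugar beads for the ganglioside
#' GM3; and the steroid core plus hydroxyl (not the short tail) for
#' cholesterol. Phospholipids and glycolipids use a 0.65 nm cutoff;
#' cholesterol uses a deliberately conservative 1.0 nm because it stays
#' mobile even while bound at a site.
#'
#' @return A tibble with one row per lipid residue name: `resname`,
#'   `species`, `headgroup_beads` (list column of bead names), `cutoff` (nm).
#' @examples
#' default_species()
#' @export
default_species <- function() {
  tibble::tribble(
    ~resname, ~species, ~headgroup_beads,                               ~cutoff,
    "POPC",   "PC",     c("NC3", "PO4"),                                0.65,
    "POPE",   "PE",     c("NH3", "PO4"),                                0.65,
    "POPS",   "PS",     c("CNO", "PO4"),                                0.65,
    "POP2",   "PIP2",   c("C1", "C2", "C3", "P1", "P2", "P3"),          0.65,
    "DPSM",   "Sph",    c("NC3", "PO4"),                                0.65,
    "DPG3",   "GM3",    c("GM1", "GM2", "GM3", "GM4", "GM5", "GM6"),    0.65,
    "CHOL",   "CHOL",   c("ROH", "R1", "R2", "R3", "R4", "R5"),         1.0
  )
}

#' Read a species table from a YAML file
#'
#' The file maps lipid residue names to species definitions, e.g.
#' ```yaml
#' POPC: {species: PC, headgroup_beads: [NC3, PO4], cutoff: 0.65}
#' ```
#' `cutoff` may be omitted; it then defaults to 0.65 nm (1.0 nm if the
#' species label is CHOL).
#'
#' @param path Path to a YAML species file.
#' @return A species tibble as [default_species()] returns.
#' @export
read_species_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) {
    stop("species table '", path, "' is empty", call. = FALSE)
  }
  purrr::imap_dfr(raw, function(entry, resname) {
    if (is.null(entry$species) || is.null(entry$headgroup_beads)) {
      stop("species entry '", resname,
           "' must declare 'species' and 'headgroup_beads'", call. = FALSE)
    }
    cutoff <- entry$cutoff %||%
      (if (identical(entry$species, "CHOL")) 1.0 else 0.65)
    tibble::tibble(
      resname = resname,
      species = as.character(entry$species),
      headgroup_beads = list(as.character(unlist(entry$headgroup_beads))),
      cutoff = as.numeric(cutoff)
    )
  })
}

validate_species_table <- function(species_table) {
  stopifnot(is.data.frame(species_table))
  needed <- c("resname", "species", "headgroup_beads", "cutoff")
  missing <- setdiff(needed, names(species_table))
  if (length(missing)) {
    stop("species table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(species_table$headgroup_beads) == 0L)) {
    stop("every species needs a non-empty headgroup bead set", call. = FALSE)
  }
  if (any(!is.finite(species_table$cutoff) | species_table$cutoff <= 0)) {
    stop("species cutoffs must be positive", call. = FALSE)
  }
  if (anyDuplicated(species_table$resname)) {
    stop("duplicated residue names in species table", call. = FALSE)
  }
  invisible(species_table)
}

species_spec <- function(topology, species) {
  tab <- topology$species
  row <- tab[tab$species == species, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("species '", species, "' not present in topology (available: ",
         paste(unique(tab$species), collapse = ", "), ")", call. = FALSE)
  }
  list(
    species = species,
    resnames = row$resname,
    headgroup_beads = unique(unlist(row$headgroup_beads)),
    cutoff = row$cutoff[[1L]]
  )
}

# three-letter amino-acid codes used for protein auto-detection
AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
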
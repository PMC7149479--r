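#' Detect residue-lipid headgroup contacts
#'
#' A protein residue and a lipid molecule are in contact in a frame when any
#' bead of the residue (backbone or side chain) lies strictly within the
#' cutoff of any headgroup bead of the lipid, under minimum-image periodic
#' distances. The default cutoff is the species default: 0.65 nm for
#' phospho- and glycolipids, 1.0 nm for cholesterol.
#'
#' The default `"cell"` method bins beads into a periodic cell list; the
#' `"brute"` method checks all bead pairs in plain R. Both return identical
#' contact sets; `"brute"` exists as the reference path for verification.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param species Species label, e.g. `"PIP2"`.
#' @param cutoff Contact cutoff in nm; `NULL` for the species default.
#' @param method `"cell"` (cell list, compiled) or `"brute"` (all pairs).
#' @return A `contact_records` tibble with one row per (frame, residue,
#'   lipid) contact: `frame` (0-based), `copy`, `monomer`, `resid`,
#'   `resname`, `pooled_key`, `lipid_id`. Attributes: `species`, `cutoff`
#'   (nm), `n_frames`, `frame_interval` (ns).
#' @export
contact_events <- function(trajectory, topology, species, cutoff = NULL,
                           method = c("cell", "brute")) {
  method <- match.arg(method)
  spec <- species_spec(topology, species)
  cutoff <- cutoff %||% spec$cutoff
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive length in nm", call. = FALSE)
  }
  pb <- protein_beads(topology)
  if (!nrow(pb)) stop("topology has no protein beads", call. = FALSE)
  hb <- headgroup_beads(topology, spec)
  if (!nrow(hb)) {
    stop("no headgroup beads for species '", species, "'", call. = FALSE)
  }
  res_tab <- protein_residues(topology)
  res_of_bead <- match(
    sprintf("c%d.m%d:%s%d", pb$copy, pb$monomer, pb$resname, pb$resid),
    res_tab$res_key
  )

  nf <- n_frames(trajectory)
  per_frame <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_positions(trajectory, f)
    box <- trajectory$box[f, ]
    pairs <- if (method == "cell") {
      contact_pairs_cpp(xyz[pb$bead, , drop = FALSE],
                        xyz[hb$bead, , drop = FALSE], box, cutoff)
    } else {
      brute_force_pairs(xyz[pb$bead, , drop = FALSE],
                        xyz[hb$bead, , drop = FALSE], box, cutoff)
    }
    if (nrow(pairs)) {
      hits <- unique(cbind(res_of_bead[pairs[, 1L]], hb$mol_id[pairs[, 2L]]))
      per_frame[[f]] <- cbind(f - 1L, hits)
    }
  }
  hits <- do.call(rbind, per_frame)
  if (is.null(hits)) hits <- matrix(integer(0), ncol = 3L)
  out <- tibble::tibble(
    frame = as.integer(hits[, 1L]),
    copy = res_tab$copy[hits[, 2L]],
    monomer = res_tab$monomer[hits[, 2L]],
    resid = res_tab$resid[hits[, 2L]],
    resname = res_tab$resname[hits[, 2L]],
    pooled_key = res_tab$pooled_key[hits[, 2L]],
    lipid_id = as.integer(hits[, 3L])
  )
  new_contact_records(out, species = species, cutoff = cutoff,
                      n_frames = nf,
                      frame_interval = trajectory$frame_interval)
}

new_contact_records <- function(data, species, cutoff, n_frames,
                                frame_interval) {
  structure(
    data,
    species = species, cutoff = cutoff, n_frames = n_frames,
    frame_interval = frame_interval,
    class = c("contact_records", class(tibble::tibble()))
  )
}

# all-pairs minimum-image reference path (plain R)
brute_force_pairs <- function(A, B, box, cutoff) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  which(d2 < cutoff^2, arr.ind = TRUE)
}

#' Per-residue interaction frequencies (contact hotspots)
#'
#' Counts, for every protein residue, the number of (frame, lipid) pairs in
#' which it is contacted, and expresses each count as a percentage of the
#' total over all residues. With `pool_monomers = TRUE` (default) the
#' counts of equivalent residues — same residue name and within-monomer id —
#' are summed over monomers and protein copies before percentages are taken,
#' which is how per-residue frequencies are usually reported for a
#' multimeric channel.
#'
#' @param records A `contact_records` tibble from [contact_events()].
#' @param pool_monomers Pool equivalent residues across monomers/copies.
#' @return A `hotspot_table` tibble sorted by descending percent:
#'   `resid`, `resname`, `pooled_key` (plus `copy`, `monomer` when not
#'   pooling), `count`, `percent`. Percentages sum to 100 when any contact
#'   exists. Zero contacts give an empty table with a warning.
#' @export
interaction_frequency <- function(records, pool_monomers = TRUE) {
  grp <- if (pool_monomers) {
    c("resid", "resname", "pooled_key")
  } else {
    c("copy", "monomer", "resid", "resname", "pooled_key")
  }
  if (nrow(records) == 0L) {
    warning("no contacts recorded; hotspot table is empty", call. = FALSE)
    out <- tibble::tibble(resid = integer(), resname = character(),
                          pooled_key = character(), count = integer(),
                          percent = numeric())
  } else {
    out <- dplyr::count(dplyr::as_tibble(records),
                        dplyr::across(dplyr::all_of(grp)), name = "count")
    out$percent <- 100 * out$count / sum(out$count)
    out <- dplyr::arrange(out, dplyr::desc(.data$percent), .data$resid)
  }
  structure(out,
            species = attr(records, "species"),
            cutoff = attr(records, "cutoff"),
            pooled = pool_monomers,
            class = c("hotspot_table", class(tibble::tibble())))
}

#' Residues above a display threshold
#'
#' Filters a hotspot table to residues whose interaction frequency is
#' strictly greater than `threshold` percent of the total (default 2.5%,
#' the customary display threshold for surface-rendering figures), sorted
#' by descending percent.
#'
#' @param table A `hotspot_table`.
#' @param threshold Percent threshold (strict inequality).
#' @return The filtered tibble.
#' @export
flag_display_residues <- function(table, threshold = 2.5) {
  out <- dplyr::filter(dplyr::as_tibble(table), .data$percent > threshold)
  dplyr::arrange(out, dplyr::desc(.data$percent))
}

#' Simultaneous contacts of one lipid at a site
#'
#' For every (frame, lipid) pair in which the lipid touches at least one
#' residue of the site, counts how many site residues it touches
#' simultaneously, and returns the normalised histogram over counts
#' `1..length(site residues)`.
#'
#' @param records A `contact_records`.
#' @param site An `interaction_site` (see [detect_sites()]) or a character
#'   vector of pooled residue keys such as `c("LYS62", "ARG78")`.
#' @return A tibble `n_residues`, `fraction` (sums to 1 when any site
#'   contact exists), `n_events`.
#' @export
simultaneous_contact_counts <- function(records, site) {
  keys <- site_residue_keys(site)
  if (!length(keys)) stop("site has no residues", call. = FALSE)
  hits <- dplyr::filter(dplyr::as_tibble(records), .data$pooled_key %in% keys)
  counts <- dplyr::summarise(
    dplyr::group_by(hits, .data$frame, .data$lipid_id),
    k = dplyr::n_distinct(.data$pooled_key), .groups = "drop"
  )
  tab <- table(factor(counts$k, levels = seq_along(keys)))
  tibble::tibble(
    n_residues = seq_along(keys),
    n_events = as.integer(tab),
    fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab) else 0
  )
}

#' Per-lipid site occupancy time series
#'
#' A lipid occupies a site in a frame when it contacts at least one residue
#' of the site. The resulting boolean series per lipid is the sole input of
#' the residence-time kinetics. Lipids that never touch the site are
#' excluded (they do not enter the survival-function normalisation).
#'
#' @param records A `contact_records`.
#' @param site An `interaction_site` or character vector of pooled residue
#'   keys; `NULL` means the whole protein surface (any residue).
#' @return A `site_occupancy` logical matrix (lipids x frames, frame columns
#'   0-based) with lipid ids as row names and the frame interval (ns) as an
#'   attribute.
#' @export
site_occupancy <- function(records, site = NULL) {
  hits <- dplyr::as_tibble(records)
  if (!is.null(site)) {
    keys <- site_residue_keys(site)
    if (!length(keys)) stop("site has no residues", call. = FALSE)
    hits <- dplyr::filter(hits, .data$pooled_key %in% keys)
  }
  nf <- attr(records, "n_frames")
  lipids <- sort(unique(hits$lipid_id))
  occ <- matrix(FALSE, length(lipids), nf,
                dimnames = list(lipids, NULL))
  if (nrow(hits)) {
    occ[cbind(match(hits$lipid_id, lipids), hits$frame + 1L)] <- TRUE
  }
  structure(occ, frame_interval = attr(records, "frame_interval"),
            species = attr(records, "species"),
            class = c("site_occupancy", "matrix", "array"))
}

site_residue_keys <- function(site) {
  if (is.character(site)) return(unique(site))
  if (inherits(site, "interaction_site")) return(site$residues)
  if (is.list(site) && !is.null(site$residues)) return(site$residues)
  stop("cannot interpret 'site'; give an interaction_site or residue keys",
       call. = FALSE)
}

#' Write a hotspot-coloured PDB
#'
#' Writes a single-frame PDB in which every protein bead carries its
#' residue's interaction percentage (rescaled into the 0-99.99 B-factor
#' range) for surface colouring; all other beads get 0.
#'
#' @param topology A `cg_topology`.
#' @param trajectory A `cg_trajectory`; its `frame` is written.
#' @param table A `hotspot_table`.
#' @param path Output path.
#' @param frame 1-based frame to write.
#' @return `path`, invisibly.
#' @export
write_hotspot_pdb <- function(topology, trajectory, table, path,
                              frame = 1L) {
  b <- topology$beads
  bf <- rep(0, nrow(b))
  prot <- b$mol_type == "protein"
  key <- sprintf("%s%d", b$resname, b$resid)
  pct <- table$percent[match(key, table$pooled_key)]
  pct[is.na(pct) | !prot] <- 0
  bf <- pmin(pct, 99.99)
  traj1 <- new_cg_trajectory(
    trajectory$positions[frame, , , drop = FALSE],
    trajectory$box[frame, , drop = FALSE],
    trajectory$times[frame]
  )
  write_pdb_file(topology, traj1, path, bfactor = bf)
  invisible(path)
}
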
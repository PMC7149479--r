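#' Lateral radial distribution of a lipid species around the protein
#'
#' A two-dimensional (xy-plane) radial distribution function of lipid
#' headgroup centres of geometry about the lateral centre of geometry of
#' each protein copy, averaged over copies and frames, for one species in
#' one leaflet. Normalisation divides the count in each annulus by the
#' count expected for a laterally uniform density (species molecules in the
#' leaflet divided by the lateral box area), so g -> 1 far from the protein.
#' Leaflets are re-assigned every frame.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param species Species label.
#' @param leaflet `"outer"` or `"inner"`.
#' @param bin_width Annulus width, nm.
#' @param r_max Largest distance, nm; must not exceed half the smallest
#'   lateral box length (minimum-image overlap). Default: that bound.
#' @return An `rdf_profile` tibble: `r_min`, `r_max`, `r_mid` (nm), `g`
#'   (unitless), `n` (raw samples per bin). Attributes record species,
#'   leaflet, and the reference-point convention.
#' @export
lateral_rdf <- function(trajectory, topology, species,
                        leaflet = c("outer", "inner"),
                        bin_width = 0.1, r_max = NULL) {
  leaflet <- match.arg(leaflet)
  spec <- species_spec(topology, species)
  pb <- protein_beads(topology)
  if (!nrow(pb)) stop("no protein copy in topology", call. = FALSE)
  half_box <- min(trajectory$box[, 1:2]) / 2
  r_max <- r_max %||% half_box
  if (r_max > half_box + 1e-9) {
    stop("r_max (", r_max, " nm) exceeds half the smallest lateral box ",
         "length (", signif(half_box, 6), " nm); periodic images overlap",
         call. = FALSE)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max - 1e-12) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  expected <- numeric(nb)
  area <- pi * diff(edges^2)

  copies <- split(pb$bead, pb$copy)
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    xyz <- frame_positions(trajectory, f)
    box <- trajectory$box[f, ]
    lf <- assign_leaflets_quiet(trajectory, topology, f)
    sel <- lf$species == species & lf$leaflet == leaflet
    if (!any(sel)) next
    hg <- headgroup_cogs(xyz, topology, species)
    hxyz <- hg$xyz[hg$mol_id %in% lf$mol_id[sel], , drop = FALSE]
    rho <- nrow(hxyz) / (box[1L] * box[2L])
    for (beads in copies) {
      centre <- cog(xyz[beads, , drop = FALSE])
      r <- lateral_mi_distance(hxyz, centre, box)
      idx <- findInterval(r, edges, rightmost.closed = TRUE,
                          left.open = FALSE)
      idx <- idx[idx >= 1L & idx <= nb]
      counts <- counts + tabulate(idx, nb)
      expected <- expected + rho * area
    }
  }
  if (all(expected == 0)) {
    warning("species '", species, "' never found in the ", leaflet,
            " leaflet", call. = FALSE)
  }
  g <- ifelse(expected > 0, counts / expected, NA_real_)
  structure(
    tibble::tibble(
      r_min = edges[-length(edges)], r_max = edges[-1L],
      r_mid = (edges[-1L] + edges[-length(edges)]) / 2,
      g = g, n = as.integer(counts)
    ),
    species = species, leaflet = leaflet, bin_width = bin_width,
    reference = "protein lateral centre of geometry per copy; lipid headgroup centre of geometry",
    class = c("rdf_profile", class(tibble::tibble()))
  )
}

assign_leaflets_quiet <- function(trajectory, topology, frame) {
  withCallingHandlers(
    assign_leaflets(trajectory, topology, frame),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' First-annular-shell enrichment of a lipid species
#'
#' Ratio of the species' share among first-shell lipids to its share in the
#' whole leaflet. The first shell contains the lipids whose headgroup centre
#' of geometry lies within `shell_cutoff` of the nearest protein bead;
#' counts are pooled over frames. A value above 1 means the species is
#' enriched against the annular ring around the protein.
#'
#' @inheritParams lateral_rdf
#' @param shell_cutoff First-shell distance from the nearest protein bead,
#'   nm.
#' @return A one-row tibble: `species`, `leaflet`, `enrichment`,
#'   `shell_fraction`, `bulk_fraction`, `n_shell` (pooled shell
#'   observations). `enrichment` is `NA` with a warning when the shell is
#'   empty in every frame.
#' @export
shell_enrichment <- function(trajectory, topology, species,
                             leaflet = c("outer", "inner"),
                             shell_cutoff = 1.0) {
  leaflet <- match.arg(leaflet)
  spec <- species_spec(topology, species)
  pb <- protein_beads(topology)
  if (!nrow(pb)) stop("no protein copy in topology", call. = FALSE)

  shell_total <- 0L
  shell_species <- 0L
  leaflet_total <- 0L
  leaflet_species <- 0L
  nf <- n_frames(trajectory)
  for (f in seq_len(nf)) {
    xyz <- frame_positions(trajectory, f)
    box <- trajectory$box[f, ]
    lf <- assign_leaflets_quiet(trajectory, topology, f)
    in_leaf <- lf$mol_id[lf$leaflet == leaflet]
    if (!length(in_leaf)) next
    hg <- headgroup_cogs(xyz, topology)
    sel <- hg$mol_id %in% in_leaf
    hxyz <- hg$xyz[sel, , drop = FALSE]
    hsp <- hg$species[sel]
    pairs <- contact_pairs_cpp(hxyz, xyz[pb$bead, , drop = FALSE],
                               box, shell_cutoff)
    in_shell <- unique(pairs[, 1L])
    shell_total <- shell_total + length(in_shell)
    shell_species <- shell_species + sum(hsp[in_shell] == species)
    leaflet_total <- leaflet_total + length(hsp)
    leaflet_species <- leaflet_species + sum(hsp == species)
  }
  if (shell_total == 0L) {
    warning("first shell is empty in every frame; enrichment undefined",
            call. = FALSE)
    enr <- NA_real_
    shell_frac <- NA_real_
  } else {
    shell_frac <- shell_species / shell_total
    bulk_frac <- leaflet_species / leaflet_total
    enr <- shell_frac / bulk_frac
  }
  bulk_frac <- if (leaflet_total > 0) {
    leaflet_species / leaflet_total
  } else {
    NA_real_
  }
  tibble::tibble(
    species = species, leaflet = leaflet, enrichment = enr,
    shell_fraction = shell_frac, bulk_fraction = bulk_frac,
    n_shell = shell_total
  )
}
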
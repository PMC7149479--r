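#' Minimum-image distance under orthorhombic periodicity
#'
#' @param p,q Points in nm: length-3 vectors or `n x 3` matrices (recycled
#'   row-wise against each other).
#' @param box Length-3 box lengths (nm).
#' @return Numeric vector of distances (nm).
#' @examples
#' minimum_image_distance(c(0.1, 0, 0), c(9.9, 0, 0), c(10, 10, 10)) # 0.2
#' @export
minimum_image_distance <- function(p, q, box) {
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  p <- if (is.null(dim(p))) matrix(p, ncol = 3L) else p
  q <- if (is.null(dim(q))) matrix(q, ncol = 3L) else q
  if (nrow(p) != nrow(q)) {
    n <- max(nrow(p), nrow(q))
    if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
    if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  }
  d <- p - q
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d * d))
}

# lateral (xy) minimum-image distance
lateral_mi_distance <- function(p, q, box) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 3L) else p
  q <- if (is.null(dim(q))) matrix(q, ncol = 3L) else q
  if (nrow(p) != nrow(q)) {
    n <- max(nrow(p), nrow(q))
    if (nrow(p) == 1L) p <- p[rep(1L, n), , drop = FALSE]
    if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  }
  d <- p[, 1:2, drop = FALSE] - q[, 1:2, drop = FALSE]
  for (k in 1:2) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d * d))
}

# per-lipid headgroup centre of geometry for one frame
# returns list(mol_id, species, xyz) in lipid molecule order
headgroup_cogs <- function(xyz, topology, species = NULL) {
  lb <- lipid_beads(topology, species)
  tab <- topology$species
  head_names <- unique(unlist(tab$headgroup_beads[
    tab$species %in% (species %||% tab$species)]))
  hb <- lb[lb$bead_name %in% head_names, ]
  sp <- hb$species[!duplicated(hb$mol_id)]
  mol <- hb$mol_id[!duplicated(hb$mol_id)]
  g <- rowsum(xyz[hb$bead, , drop = FALSE], hb$mol_id, reorder = TRUE)
  cnt <- as.vector(table(factor(hb$mol_id, levels = sort(unique(hb$mol_id)))))
  ord <- order(mol)
  list(mol_id = mol[ord], species = sp[ord], xyz = g / cnt)
}

#' Assign lipids to bilayer leaflets
#'
#' Each lipid is assigned by the z coordinate of its headgroup centre of
#' geometry relative to the bilayer midplane, taken as the mean z of all
#' lipid headgroup beads in the frame. The bilayer normal is assumed to lie
#' along z. The assignment is deterministic; an empty leaflet raises a
#' warning, not an error.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param frame 1-based frame number to assign from.
#' @return A tibble with columns `mol_id`, `species`, `leaflet`
#'   (`"outer"` above the midplane, `"inner"` below).
#' @export
assign_leaflets <- function(trajectory, topology, frame = 1L) {
  xyz <- frame_positions(trajectory, frame)
  hg <- headgroup_cogs(xyz, topology)
  if (!length(hg$mol_id)) stop("no lipid headgroup beads found", call. = FALSE)
  hg$mol_id <- unname(hg$mol_id)
  hg$species <- unname(hg$species)
  lb <- lipid_beads(topology)
  tab <- topology$species
  head_names <- unique(unlist(tab$headgroup_beads))
  hb <- lb[lb$bead_name %in% head_names, ]
  midplane <- mean(xyz[hb$bead, 3L])
  leaflet <- unname(ifelse(hg$xyz[, 3L] >= midplane, "outer", "inner"))
  if (!any(leaflet == "outer") || !any(leaflet == "inner")) {
    warning("one leaflet is empty", call. = FALSE)
  }
  tibble::tibble(mol_id = hg$mol_id, species = hg$species, leaflet = leaflet)
}
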
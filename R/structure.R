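#' Per-residue root-mean-square fluctuations
#'
#' RMSF of every protein bead about its time-mean position, after removing
#' each copy's per-frame centre of geometry (membrane proteins drift
#' laterally; no rotational superposition is applied, as the copies are
#' membrane-embedded). Residue values are the mean over the residue's
#' beads, then averaged over protein copies and monomers onto
#' within-monomer residue ids.
#'
#' @param trajectory A `cg_trajectory` with at least two frames.
#' @param topology The matching `cg_topology`.
#' @return An `rmsf_table` tibble: `resid`, `resname`, `rmsf` (nm).
#' @export
rmsf_profile <- function(trajectory, topology) {
  nf <- n_frames(trajectory)
  if (nf < 2L) stop("RMSF needs at least two frames", call. = FALSE)
  pb <- protein_beads(topology)
  if (!nrow(pb)) stop("no protein beads", call. = FALSE)

  centred <- array(NA_real_, dim = c(nf, nrow(pb), 3L))
  copies <- split(seq_len(nrow(pb)), pb$copy)
  for (f in seq_len(nf)) {
    xyz <- frame_positions(trajectory, f)[pb$bead, , drop = FALSE]
    for (rows in copies) {
      centre <- cog(xyz[rows, , drop = FALSE])
      centred[f, rows, ] <- sweep(xyz[rows, , drop = FALSE], 2L, centre)
    }
  }
  mean_pos <- apply(centred, c(2L, 3L), mean)
  dev2 <- sweep(centred, c(2L, 3L), mean_pos)^2
  bead_rmsf <- sqrt(apply(dev2, 2L, sum) / nf)

  per_bead <- tibble::tibble(
    resid = pb$resid, resname = pb$resname, rmsf = bead_rmsf
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_bead, .data$resid, .data$resname),
    rmsf = mean(.data$rmsf), .groups = "drop"
  )
  structure(dplyr::arrange(out, .data$resid),
            class = c("rmsf_table", class(tibble::tibble())))
}

#' Residue-pair distance distribution
#'
#' Minimum-image distance between the side-chain centres of geometry of two
#' residues, per frame, copy and monomer. Charged side chains reorient, so
#' the side-chain rule is the default; `bead_rule = "all"` uses every bead
#' of the residue. Reports the per-observation series, a histogram, summary
#' quantiles and the sample bimodality coefficient
#' (skewness^2 + 1) / (kurtosis + small-sample term), which exceeds ~0.55
#' for clearly two-state distributions.
#'
#' @param trajectory A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param res_a,res_b Pooled residue keys, e.g. `"LYS62"`.
#' @param bead_rule `"sidechain"` (all beads except the backbone bead BB)
#'   or `"all"`.
#' @param bin_width Histogram bin width, nm.
#' @return A list with `series` (tibble: `frame`, `copy`, `monomer`,
#'   `distance` nm), `histogram` (tibble: `mid`, `count`, `density`),
#'   `stats` (tibble: quantiles, mean, bimodality coefficient).
#' @export
pair_distance_distribution <- function(trajectory, topology, res_a, res_b,
                                       bead_rule = c("sidechain", "all"),
                                       bin_width = 0.05) {
  bead_rule <- match.arg(bead_rule)
  pb <- protein_beads(topology)
  pb$pooled_key <- sprintf("%s%d", pb$resname, pb$resid)
  pick <- function(key) {
    rows <- pb[pb$pooled_key == key, ]
    if (!nrow(rows)) stop("residue '", key, "' not found", call. = FALSE)
    if (bead_rule == "sidechain") {
      sc <- rows[rows$bead_name != "BB", ]
      if (nrow(sc)) rows <- sc  # glycine-like residues keep the backbone
    }
    rows
  }
  a <- pick(res_a)
  b <- pick(res_b)
  instances <- dplyr::distinct(pb, .data$copy, .data$monomer)
  miss_a <- nrow(dplyr::distinct(a, .data$copy, .data$monomer)) <
    nrow(instances)
  miss_b <- nrow(dplyr::distinct(b, .data$copy, .data$monomer)) <
    nrow(instances)
  if (miss_a) stop("residue '", res_a, "' missing from some monomer",
                   call. = FALSE)
  if (miss_b) stop("residue '", res_b, "' missing from some monomer",
                   call. = FALSE)

  nf <- n_frames(trajectory)
  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    xyz <- frame_positions(trajectory, f)
    box <- trajectory$box[f, ]
    d <- vapply(seq_len(nrow(instances)), function(i) {
      cp <- instances$copy[i]
      mn <- instances$monomer[i]
      pa <- cog(xyz[a$bead[a$copy == cp & a$monomer == mn], , drop = FALSE])
      qb <- cog(xyz[b$bead[b$copy == cp & b$monomer == mn], , drop = FALSE])
      minimum_image_distance(pa, qb, box)
    }, numeric(1L))
    rows[[f]] <- tibble::tibble(
      frame = f - 1L, copy = instances$copy, monomer = instances$monomer,
      distance = d
    )
  }
  series <- dplyr::bind_rows(rows)
  edges <- seq(floor(min(series$distance) / bin_width) * bin_width,
               max(series$distance) + bin_width, by = bin_width)
  h <- graphics::hist(series$distance, breaks = edges, plot = FALSE)
  histogram <- tibble::tibble(mid = h$mids, count = h$counts,
                              density = h$density)
  x <- series$distance
  n <- length(x)
  g1 <- mean((x - mean(x))^3) / stats::sd(x)^3
  g2 <- mean((x - mean(x))^4) / stats::sd(x)^4 - 3
  bc <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  stats <- tibble::tibble(
    mean = mean(x), q05 = stats::quantile(x, 0.05, names = FALSE),
    median = stats::median(x),
    q95 = stats::quantile(x, 0.95, names = FALSE),
    bimodality = bc
  )
  list(series = series, histogram = histogram, stats = stats)
}
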
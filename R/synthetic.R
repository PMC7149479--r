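#' Specification for a synthetic membrane-protein system
#'
#' Describes a minimal coarse-grained system used to validate the analysis
#' chain: one or more static multimeric protein scaffolds embedded in a
#' two-leaflet lipid bath, with lipids performing a lateral random walk and
#' binding at planted residue sites by a two-state Markov process with
#' per-species on/off rates. Default leaflet compositions mirror a
#' mammalian plasma-membrane mixture: outer PC/PE/Sph/GM3/CHOL at
#' 40:10:15:10:25, inner PC/PE/PS/PIP2/CHOL at 10:40:15:10:25.
#'
#' Each planted site is realised once per monomer. Site residues sit at the
#' headgroup plane of their leaflet; all other residues sit at the bilayer
#' core, out of reach of headgroups. A bound lipid's headgroup is placed
#' within 0.9 x 0.65 nm of a randomly chosen site residue each frame, and
#' displaced well beyond the cutoff on release, so ground-truth bound
#' intervals coincide exactly with detected contacts.
#'
#' @param box Box lengths (nm).
#' @param n_frames Number of frames (the first frame is the initial
#'   configuration).
#' @param frame_interval Frame spacing, ns.
#' @param n_copies Protein copies, laid out on a lateral grid.
#' @param monomers Monomers per copy.
#' @param residues_per_monomer Residues per monomer (two beads each:
#'   backbone BB and side chain SC1).
#' @param lipids_per_leaflet Lipid count per leaflet.
#' @param outer,inner Named composition vectors (species proportions).
#' @param sites List of planted sites; each a list with `residues`
#'   (within-monomer residue ids), `leaflet`, and `affinity`, a named list
#'   mapping species to `c(k_on, k_off)` per-frame rates. The default
#'   plants a two-lipid competition site (PIP2 strong vs PS weak) and a
#'   second PS-only site, both facing the inner leaflet.
#' @param diffusion_step Std. dev. of the lateral random-walk step,
#'   nm/frame.
#' @param capture_radius Lateral distance (nm) within which an unbound
#'   lipid may attempt binding.
#' @param exclusive One lipid per site instance at a time.
#' @param seed Mandatory integer master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(box = c(30, 30, 12),
                           n_frames = 200L,
                           frame_interval = 1,
                           n_copies = 1L,
                           monomers = 4L,
                           residues_per_monomer = 12L,
                           lipids_per_leaflet = 150L,
                           outer = c(PC = 40, PE = 10, Sph = 15,
                                     GM3 = 10, CHOL = 25),
                           inner = c(PC = 10, PE = 40, PS = 15,
                                     PIP2 = 10, CHOL = 25),
                           sites = NULL,
                           diffusion_step = 0.3,
                           capture_radius = 1.8,
                           exclusive = TRUE,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  sites <- sites %||% list(
    list(residues = 1:3, leaflet = "inner",
         affinity = list(PIP2 = c(k_on = 0.5, k_off = 0.02),
                         PS = c(k_on = 0.2, k_off = 0.10))),
    list(residues = 7:9, leaflet = "inner",
         affinity = list(PS = c(k_on = 0.5, k_off = 0.05)))
  )
  for (s in sites) {
    if (any(s$residues > residues_per_monomer)) {
      stop("site residues exceed residues_per_monomer", call. = FALSE)
    }
    rates <- unlist(s$affinity)
    if (any(rates < 0 | rates > 1)) {
      stop("binding rates must lie in [0, 1]", call. = FALSE)
    }
  }
  if (box[1] * box[2] / lipids_per_leaflet < 0.4) {
    stop("overfilled leaflet: area per lipid below 0.4 nm^2", call. = FALSE)
  }
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  structure(
    list(box = box, n_frames = as.integer(n_frames),
         frame_interval = frame_interval, n_copies = as.integer(n_copies),
         monomers = as.integer(monomers),
         residues_per_monomer = as.integer(residues_per_monomer),
         lipids_per_leaflet = as.integer(lipids_per_leaflet),
         outer = outer, inner = inner, sites = sites,
         diffusion_step = diffusion_step, capture_radius = capture_radius,
         exclusive = exclusive, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# species -> single headgroup bead name used by the minimal lipid model
synthetic_head_bead <- function(species) {
  unname(c(PC = "PO4", PE = "PO4", PS = "PO4", PIP2 = "P1", Sph = "PO4",
           GM3 = "GM1", CHOL = "ROH")[species])
}
synthetic_resname <- function(species) {
  unname(c(PC = "POPC", PE = "POPE", PS = "POPS", PIP2 = "POP2",
           Sph = "DPSM", DPG3 = "DPG3", GM3 = "DPG3", CHOL = "CHOL")[species])
}

LEAFLET_Z <- c(outer = 1.8, inner = -1.8)

# deterministic scaffold layout: per copy, monomers on a ring; site
# residues clustered at the leaflet plane, others buried at the core
build_scaffold <- function(spec) {
  grid_n <- ceiling(sqrt(spec$n_copies))
  centres <- cbind(
    ((seq_len(spec$n_copies) - 1L) %% grid_n + 0.5) * spec$box[1] / grid_n,
    ((seq_len(spec$n_copies) - 1L) %/% grid_n + 0.5) * spec$box[2] / grid_n
  )
  site_of_res <- rep(NA_integer_, spec$residues_per_monomer)
  for (s in seq_along(spec$sites)) {
    site_of_res[spec$sites[[s]]$residues] <- s
  }
  n_sites <- length(spec$sites)
  # spread site anchors evenly within each leaflet so instances of
  # different sites stay out of each other's contact range
  site_leaflet <- vapply(spec$sites, `[[`, character(1L), "leaflet")
  site_offset <- numeric(n_sites)
  for (lf in unique(site_leaflet)) {
    grp <- which(site_leaflet == lf)
    k <- seq_along(grp)
    site_offset[grp] <- (k - (length(grp) + 1) / 2) *
      (2 * pi / spec$monomers) / length(grp)
  }
  beads <- list()
  anchors <- list()
  z_mid <- 0
  for (cp in seq_len(spec$n_copies)) {
    for (mn in seq_len(spec$monomers)) {
      ang0 <- (mn - 1L) * 2 * pi / spec$monomers
      for (s in seq_len(max(n_sites, 0L))) {
        lf <- spec$sites[[s]]$leaflet
        anchors[[length(anchors) + 1L]] <- tibble::tibble(
          site = s, copy = cp, monomer = mn, leaflet = lf,
          x = centres[cp, 1L] + 2.6 * cos(ang0 + site_offset[s]),
          y = centres[cp, 2L] + 2.6 * sin(ang0 + site_offset[s]),
          z = LEAFLET_Z[[lf]]
        )
      }
      for (r in seq_len(spec$residues_per_monomer)) {
        s <- site_of_res[r]
        if (!is.na(s)) {
          a <- anchors[[length(anchors) - n_sites + s]]
          k <- match(r, spec$sites[[s]]$residues)
          nk <- length(spec$sites[[s]]$residues)
          th <- 2 * pi * (k - 1L) / nk
          pos <- c(a$x + 0.2 * cos(th), a$y + 0.2 * sin(th), a$z)
          sc_off <- 0.12   # keep site residues inside the anchor cluster
        } else {
          th <- ang0 + 1.2 * (r / spec$residues_per_monomer - 0.5)
          pos <- c(centres[cp, 1L] + 2.2 * cos(th),
                   centres[cp, 2L] + 2.2 * sin(th), z_mid)
          sc_off <- 0.3
        }
        ori <- atan2(pos[2L] - centres[cp, 2L], pos[1L] - centres[cp, 1L])
        beads[[length(beads) + 1L]] <- tibble::tibble(
          copy = cp, monomer = mn, resid = r,
          resname = AMINO_ACIDS[(r - 1L) %% length(AMINO_ACIDS) + 1L],
          bead_name = c("BB", "SC1"),
          x = pos[1L] + c(0, sc_off * cos(ori)),
          y = pos[2L] + c(0, sc_off * sin(ori)),
          z = pos[3L]
        )
      }
    }
  }
  list(beads = dplyr::bind_rows(beads),
       anchors = dplyr::bind_rows(anchors),
       centres = centres)
}

#' Generate a synthetic system with known binding kinetics
#'
#' Realises a [synthetic_spec()]: a static protein scaffold, lipids on a
#' lateral Gaussian random walk (periodically wrapped, fixed leaflet z),
#' and two-state Markov binding at the planted sites. While bound, a
#' lipid's headgroup sits within 0.9 x 0.65 nm of a randomly chosen site
#' residue; on release it is displaced beyond 1.5 x the cutoff. Unbound
#' lipids are kept outside contact range of all site residues, so the
#' ground-truth bound intervals are exactly the frames in which the lipid
#' contacts the site. Fully reproducible from the master seed.
#'
#' @param spec A `synthetic_spec`.
#' @return A list: `topology` (`cg_topology`), `trajectory`
#'   (`cg_trajectory`), `truth` (list: `sites` tibble of planted residue
#'   keys per site, `intervals` tibble of realised bound intervals with
#'   0-based inclusive frame bounds, `expected_dwell` tibble (ns),
#'   `seeds`).
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- derive_seeds(spec$seed, 2L)
  scaffold <- build_scaffold(spec)
  pb <- scaffold$beads
  anchors <- scaffold$anchors

  # lipid bookkeeping ------------------------------------------------------
  comp_counts <- function(comp, n) {
    cnt <- round(n * comp / sum(comp))
    while (sum(cnt) > n) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    while (sum(cnt) < n) cnt[which.min(cnt)] <- cnt[which.min(cnt)] + 1L
    cnt[cnt > 0]
  }
  set.seed(seeds[1L])
  lipids <- dplyr::bind_rows(lapply(c("outer", "inner"), function(lf) {
    cnt <- comp_counts(spec[[lf]], spec$lipids_per_leaflet)
    tibble::tibble(
      species = rep(names(cnt), cnt),
      leaflet = lf,
      x = stats::runif(sum(cnt), 0, spec$box[1]),
      y = stats::runif(sum(cnt), 0, spec$box[2]),
      z = LEAFLET_Z[[lf]]
    )
  }))
  nl <- nrow(lipids)
  lipids$mol_id <- spec$n_copies * spec$monomers + seq_len(nl)

  # topology ---------------------------------------------------------------
  sp_table <- default_species()
  head_bead <- synthetic_head_bead(lipids$species)
  tail_sign <- ifelse(lipids$leaflet == "outer", -1, 1)
  prot_beads <- tibble::tibble(
    bead_name = pb$bead_name, resid = pb$resid, resname = pb$resname,
    mol_id = (pb$copy - 1L) * spec$monomers + pb$monomer,
    mol_type = "protein", species = NA_character_,
    copy = pb$copy, monomer = pb$monomer
  )
  lip_beads <- tibble::tibble(
    bead_name = as.vector(rbind(head_bead, "T1", "T2")),
    resid = rep(seq_len(nl), each = 3L),
    resname = rep(synthetic_resname(lipids$species), each = 3L),
    mol_id = rep(lipids$mol_id, each = 3L),
    mol_type = "lipid",
    species = rep(lipids$species, each = 3L),
    copy = NA_integer_, monomer = NA_integer_
  )
  beads <- dplyr::bind_rows(prot_beads, lip_beads)
  beads$bead <- seq_len(nrow(beads))
  topology <- new_cg_topology(beads, sp_table)

  n_prot <- nrow(pb)
  head_rows <- n_prot + 3L * (seq_len(nl) - 1L) + 1L

  # site instances ---------------------------------------------------------
  inst <- anchors
  inst$instance <- seq_len(nrow(inst))
  res_xy <- lapply(inst$instance, function(i) {
    a <- inst[i, ]
    rs <- spec$sites[[a$site]]$residues
    sel <- pb$copy == a$copy & pb$monomer == a$monomer &
      pb$resid %in% rs & pb$bead_name == "BB"
    cbind(pb$x[sel], pb$y[sel])
  })
  aff <- lapply(inst$instance, function(i) spec$sites[[inst$site[i]]]$affinity)

  # dynamics ---------------------------------------------------------------
  set.seed(seeds[2L])
  cutoff <- 0.65
  place_r <- c(0.15, 0.9 * cutoff - 0.05)
  excl_r <- 1.1          # keep unbound lipids this far from site anchors
  nF <- spec$n_frames
  pos <- array(NA_real_, dim = c(nF, nrow(beads), 3L))
  box <- matrix(rep(spec$box, each = nF), nF, 3L)
  occupant <- integer(nrow(inst))          # lipid row per instance, 0 = free
  bound_inst <- integer(nl)                # instance per lipid, 0 = unbound
  bound_log <- matrix(0L, nl, nF)

  anchor_dist <- function(lip, i) {
    dx <- lip$x - inst$x[i]
    dy <- lip$y - inst$y[i]
    dx <- dx - spec$box[1] * round(dx / spec$box[1])
    dy <- dy - spec$box[2] * round(dy / spec$box[2])
    list(dx = dx, dy = dy, d = sqrt(dx^2 + dy^2))
  }
  push_out <- function(lip) {
    # displace unbound lipids that drifted into any site's contact zone;
    # iterate because neighbouring sites' zones can touch, then teleport
    # any stubborn violator to a clear random position
    for (pass in 1:6) {
      moved <- FALSE
      for (i in inst$instance) {
        ad <- anchor_dist(lip, i)
        hit <- which(lip$leaflet == inst$leaflet[i] & bound_inst == 0L &
                       ad$d < excl_r)
        if (length(hit)) {
          moved <- TRUE
          scl <- (excl_r + 0.2) / pmax(ad$d[hit], 1e-6)
          lip$x[hit] <- (inst$x[i] + ad$dx[hit] * scl) %% spec$box[1]
          lip$y[hit] <- (inst$y[i] + ad$dy[hit] * scl) %% spec$box[2]
        }
      }
      if (!moved) return(lip)
    }
    for (l in which(bound_inst == 0L)) {
      near <- any(vapply(inst$instance, function(i) {
        inst$leaflet[i] == lip$leaflet[l] &&
          anchor_dist(lip[l, ], i)$d < excl_r
      }, logical(1L)))
      tries <- 0L
      while (near && tries < 100L) {
        lip$x[l] <- stats::runif(1L, 0, spec$box[1])
        lip$y[l] <- stats::runif(1L, 0, spec$box[2])
        near <- any(vapply(inst$instance, function(i) {
          inst$leaflet[i] == lip$leaflet[l] &&
            anchor_dist(lip[l, ], i)$d < excl_r
        }, logical(1L)))
        tries <- tries + 1L
      }
    }
    lip
  }
  place_bound <- function(lip, l, i) {
    xy <- res_xy[[i]]
    k <- sample.int(nrow(xy), 1L)
    r <- stats::runif(1L, place_r[1L], place_r[2L])
    th <- stats::runif(1L, 0, 2 * pi)
    lip$x[l] <- (xy[k, 1L] + r * cos(th)) %% spec$box[1]
    lip$y[l] <- (xy[k, 2L] + r * sin(th)) %% spec$box[2]
    lip
  }

  lipids <- push_out(lipids)
  for (f in seq_len(nF)) {
    if (f > 1L) {
      released <- integer(0L)   # refractory: no rebinding in release frame
      # 1) release / re-place bound lipids
      for (i in inst$instance) {
        l <- occupant[i]
        if (l == 0L) next
        k_off <- aff[[i]][[lipids$species[l]]][["k_off"]]
        if (stats::runif(1L) < k_off) {
          occupant[i] <- 0L
          bound_inst[l] <- 0L
          released <- c(released, l)
          th <- stats::runif(1L, 0, 2 * pi)
          lipids$x[l] <- (inst$x[i] + 1.6 * cutoff * cos(th)) %% spec$box[1]
          lipids$y[l] <- (inst$y[i] + 1.6 * cutoff * sin(th)) %% spec$box[2]
        } else {
          lipids <- place_bound(lipids, l, i)
        }
      }
      # 2) unbound lipids diffuse
      free <- bound_inst == 0L
      lipids$x[free] <- (lipids$x[free] +
        stats::rnorm(sum(free), 0, spec$diffusion_step)) %% spec$box[1]
      lipids$y[free] <- (lipids$y[free] +
        stats::rnorm(sum(free), 0, spec$diffusion_step)) %% spec$box[2]
      # 3) binding attempts at free instances
      for (i in inst$instance) {
        if (spec$exclusive && occupant[i] != 0L) next
        for (sp in names(aff[[i]])) {
          k_on <- aff[[i]][[sp]][["k_on"]]
          if (k_on <= 0) next
          dx <- lipids$x - inst$x[i]
          dy <- lipids$y - inst$y[i]
          dx <- dx - spec$box[1] * round(dx / spec$box[1])
          dy <- dy - spec$box[2] * round(dy / spec$box[2])
          cand <- which(bound_inst == 0L & lipids$species == sp &
                          lipids$leaflet == inst$leaflet[i] &
                          dx^2 + dy^2 < spec$capture_radius^2)
          cand <- setdiff(cand, released)
          if (!length(cand)) next
          cand <- cand[sample.int(length(cand))]
          ok <- cand[stats::runif(length(cand)) < k_on]
          if (length(ok)) {
            l <- ok[1L]
            occupant[i] <- l
            bound_inst[l] <- i
            lipids <- place_bound(lipids, l, i)
            if (spec$exclusive) break
          }
        }
      }
      # 4) keep remaining unbound lipids clear of every site
      lipids <- push_out(lipids)
    }
    bound_log[, f] <- bound_inst
    pos[f, seq_len(n_prot), 1L] <- pb$x
    pos[f, seq_len(n_prot), 2L] <- pb$y
    pos[f, seq_len(n_prot), 3L] <- pb$z
    pos[f, head_rows, ] <- cbind(lipids$x, lipids$y, lipids$z)
    pos[f, head_rows + 1L, ] <- cbind(lipids$x, lipids$y,
                                      lipids$z + 0.6 * tail_sign)
    pos[f, head_rows + 2L, ] <- cbind(lipids$x, lipids$y,
                                      lipids$z + 1.2 * tail_sign)
  }

  trajectory <- new_cg_trajectory(
    pos, box, (seq_len(nF) - 1L) * spec$frame_interval
  )

  # ground truth -----------------------------------------------------------
  truth_sites <- tibble::tibble(
    site = seq_along(spec$sites),
    leaflet = vapply(spec$sites, `[[`, character(1L), "leaflet"),
    residues = lapply(spec$sites, function(s) {
      sort(sprintf("%s%d",
                   AMINO_ACIDS[(s$residues - 1L) %% length(AMINO_ACIDS) + 1L],
                   s$residues))
    })
  )
  intervals <- list()
  for (l in seq_len(nl)) {
    r <- rle(bound_log[l, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values > 0L)
    if (length(sel)) {
      intervals[[length(intervals) + 1L]] <- tibble::tibble(
        lipid_id = lipids$mol_id[l], species = lipids$species[l],
        instance = r$values[sel],
        site = inst$site[r$values[sel]],
        copy = inst$copy[r$values[sel]],
        monomer = inst$monomer[r$values[sel]],
        start_frame = starts[sel] - 1L, end_frame = ends[sel] - 1L
      )
    }
  }
  intervals <- if (length(intervals)) {
    dplyr::bind_rows(intervals)
  } else {
    tibble::tibble(lipid_id = integer(), species = character(),
                   instance = integer(), site = integer(), copy = integer(),
                   monomer = integer(), start_frame = integer(),
                   end_frame = integer())
  }
  expected <- dplyr::bind_rows(lapply(seq_along(spec$sites), function(s) {
    aff_s <- spec$sites[[s]]$affinity
    tibble::tibble(
      site = s, species = names(aff_s),
      k_on = vapply(aff_s, `[[`, numeric(1L), "k_on"),
      k_off = vapply(aff_s, `[[`, numeric(1L), "k_off"),
      expected_dwell = spec$frame_interval /
        vapply(aff_s, `[[`, numeric(1L), "k_off")
    )
  }))
  list(
    topology = topology, trajectory = trajectory,
    truth = list(sites = truth_sites, intervals = intervals,
                 expected_dwell = expected,
                 seeds = list(master = spec$seed, init = seeds[1L],
                              dynamics = seeds[2L]))
  )
}

#' Two-state Markov site-occupancy series
#'
#' Simulates the occupancy indicator of a single site directly: each lipid
#' independently alternates unbound and bound periods with geometric
#' durations (per-frame binding probability `k_on`, unbinding probability
#' `k_off`), so bound dwells have mean `frame_interval / k_off` ns. This is
#' the occupancy-level counterpart of [generate_system()], convenient for
#' residence-time recovery studies that need hundreds of binding events.
#'
#' With `short_fraction > 0`, each binding event is short-lived (off rate
#' `k_off_short`) with that probability, long-lived (off rate `k_off`)
#' otherwise — the two interaction populations the biexponential residence
#' model assumes: grazing encounters that fail to engage the site, and
#' tight binding.
#'
#' @param n_lipids Number of lipids.
#' @param n_frames Number of frames.
#' @param k_on,k_off Per-frame transition probabilities.
#' @param short_fraction Probability that a binding event belongs to the
#'   short-lived population.
#' @param k_off_short Per-frame off rate of the short-lived population.
#' @param frame_interval Frame spacing, ns.
#' @param seed Integer seed.
#' @return A `site_occupancy` logical matrix (lipids x frames).
#' @export
simulate_site_occupancy <- function(n_lipids, n_frames, k_on, k_off,
                                    short_fraction = 0, k_off_short = 0.5,
                                    frame_interval = 1, seed) {
  stopifnot(k_on > 0, k_on <= 1, k_off > 0, k_off <= 1,
            short_fraction >= 0, short_fraction <= 1)
  set.seed(as.integer(seed))
  occ <- matrix(FALSE, n_lipids, n_frames)
  for (l in seq_len(n_lipids)) {
    t <- 0L
    bound <- FALSE
    while (t < n_frames) {
      rate <- if (!bound) {
        k_on
      } else if (short_fraction > 0 &&
                   stats::runif(1L) < short_fraction) {
        k_off_short
      } else {
        k_off
      }
      len <- stats::rgeom(1L, rate) + 1L
      len <- min(len, n_frames - t)
      if (bound) occ[l, (t + 1L):(t + len)] <- TRUE
      t <- t + len
      bound <- !bound
    }
  }
  structure(occ, frame_interval = frame_interval,
            class = c("site_occupancy", "matrix", "array"))
}
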
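# Hand-built miniature systems and independent oracles shared by the tests.

# topology with `n_res` single-bead protein residues (one monomer) and
# `n_lipids` single-headgroup-bead lipids of one species
toy_topology <- function(n_res, n_lipids, species = "PC") {
  resname <- c(PC = "POPC", PS = "POPS", PIP2 = "POP2", CHOL = "CHOL")[[species]]
  head_bead <- c(PC = "PO4", PS = "PO4", PIP2 = "P1", CHOL = "ROH")[[species]]
  beads <- dplyr::bind_rows(
    tibble::tibble(
      bead_name = "BB", resid = seq_len(n_res),
      resname = lipidsites:::AMINO_ACIDS[(seq_len(n_res) - 1L) %% 20L + 1L],
      mol_id = 1L, mol_type = "protein", species = NA_character_,
      copy = 1L, monomer = 1L
    ),
    tibble::tibble(
      bead_name = head_bead, resid = seq_len(n_lipids),
      resname = resname, mol_id = 1L + seq_len(n_lipids),
      mol_type = "lipid", species = species,
      copy = NA_integer_, monomer = NA_integer_
    )
  )
  beads$bead <- seq_len(nrow(beads))
  lipidsites:::new_cg_topology(beads, default_species())
}

# trajectory from a list of n_beads x 3 matrices
toy_trajectory <- function(frames, box, dt = 1) {
  nf <- length(frames)
  pos <- array(NA_real_, dim = c(nf, nrow(frames[[1L]]), 3L))
  for (f in seq_len(nf)) pos[f, , ] <- frames[[f]]
  lipidsites:::new_cg_trajectory(
    pos, matrix(rep(box, each = nf), nf, 3L), (seq_len(nf) - 1L) * dt
  )
}

# random periodic system for contact-oracle checks
random_contact_system <- function(seed, n_res = 20L, n_lipids = 50L,
                                  n_frames = 10L) {
  set.seed(seed)
  box <- stats::runif(3L, 4, 12)
  topo <- toy_topology(n_res, n_lipids)
  frames <- lapply(seq_len(n_frames), function(f) {
    cbind(stats::runif(n_res + n_lipids, -box[1L], 2 * box[1L]),
          stats::runif(n_res + n_lipids, -box[2L], 2 * box[2L]),
          stats::runif(n_res + n_lipids, -box[3L], 2 * box[3L]))
  })
  list(topology = topo, trajectory = toy_trajectory(frames, box), box = box)
}

# build a site_occupancy matrix from a plain logical matrix
as_occupancy <- function(m, dt = 1) {
  structure(m, frame_interval = dt,
            class = c("site_occupancy", "matrix", "array"))
}

# independent double-loop enumeration of the survival function
sigma_oracle <- function(occ, dt = 1, gap_tolerance = 0L) {
  occ <- unclass(occ)
  occ <- occ[rowSums(occ) > 0L, , drop = FALSE]
  nj <- nrow(occ)
  nF <- ncol(occ)
  if (gap_tolerance > 0L) {
    for (j in seq_len(nj)) {
      r <- rle(occ[j, ])
      inner <- seq_along(r$values)[-c(1L, length(r$values))]
      fill <- inner[!r$values[inner] & r$lengths[inner] <= gap_tolerance]
      if (length(fill)) {
        r$values[fill] <- TRUE
        occ[j, ] <- inverse.rle(r)
      }
    }
  }
  ks <- 0:(nF - 2L)
  raw <- vapply(ks, function(k) {
    total <- 0
    for (j in seq_len(nj)) {
      for (v in seq_len(nF - k)) {
        if (all(occ[j, v:(v + k)])) total <- total + 1
      }
    }
    total / (nj * (nF - k))
  }, numeric(1L))
  tibble::tibble(t = ks * dt, sigma = raw / raw[1L])
}

# interaction_graph tibble from a symmetric weight matrix
graph_from_matrix <- function(W, species = "PC") {
  n <- nrow(W)
  nodes <- sprintf("RES%02d", seq_len(n))
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  structure(
    tibble::tibble(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                   weight = W[idx]),
    species = species, n_frames = 1L, pooled = TRUE, normalized = FALSE,
    class = c("interaction_graph", class(tibble::tibble()))
  )
}

random_weight_matrix <- function(seed, n_min = 4L, n_max = 12L) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  p <- stats::runif(1L, 0.25, 0.8)
  W <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      if (stats::runif(1L) < p) W[a, b] <- W[b, a] <- stats::runif(1L, 0.1, 10)
    }
  }
  if (sum(W) == 0) W[1L, 2L] <- W[2L, 1L] <- 1
  W
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# survival-curve tibble from an analytic sigma(t), for fit tests
analytic_curve <- function(t, sigma, dt = t[2L] - t[1L]) {
  structure(
    tibble::tibble(t = t, sigma = sigma, n_pairs = 1e6),
    N_j = 1L, T = max(t), frame_interval = dt, sigma0_raw = 1,
    gap_tolerance = 0L, convention = "analytic",
    class = c("survival_curve", class(tibble::tibble()))
  )
}
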
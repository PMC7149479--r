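test_that("contacts respect the strict distance cutoff", {
  topo <- toy_topology(1L, 2L)
  xyz <- rbind(c(0, 0, 0),        # residue bead
               c(0.60, 0, 0),     # inside 0.65
               c(0.66, 0, 0))     # outside
  traj <- toy_trajectory(list(xyz), box = c(10, 10, 10))
  rec <- contact_events(traj, topo, "PC")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$lipid_id, 2L)  # lipid mol_ids start after the protein
  # exactly at the cutoff: excluded (strict inequality)
  xyz[2L, ] <- c(0.65, 0, 0)
  rec2 <- contact_events(toy_trajectory(list(xyz), c(10, 10, 10)), topo, "PC")
  expect_equal(nrow(rec2), 0L)
})

test_that("cell-list contacts equal the all-pairs oracle on random systems", {
  for (seed in 1:25) {
    s <- random_contact_system(seed)
    cell <- contact_events(s$trajectory, s$topology, "PC", method = "cell")
    brute <- contact_events(s$trajectory, s$topology, "PC", method = "brute")
    key <- function(r) sort(paste(r$frame, r$pooled_key, r$lipid_id))
    expect_identical(key(cell), key(brute))
  }
})

test_that("contacts are invariant under rigid translation modulo the box", {
  s <- random_contact_system(99L)
  shift <- c(3.1, -8.2, 14.5)
  shifted <- s$trajectory
  shifted$positions <- sweep(s$trajectory$positions, 3L, -shift)
  a <- contact_events(s$trajectory, s$topology, "PC")
  b <- contact_events(shifted, s$topology, "PC")
  key <- function(r) sort(paste(r$frame, r$pooled_key, r$lipid_id))
  expect_identical(key(a), key(b))
})

test_that("interaction frequencies count (frame, lipid) pairs and sum to 100%", {
  topo <- toy_topology(2L, 2L)
  # residue 1 contacted by both lipids in frame 1 and one lipid in frame 2;
  # residue 2 contacted once
  f1 <- rbind(c(0, 0, 0), c(5, 5, 5), c(0.3, 0, 0), c(0, 0.3, 0))
  f2 <- rbind(c(0, 0, 0), c(5, 5, 5), c(0.3, 0, 0), c(5, 5.3, 5))
  traj <- toy_trajectory(list(f1, f2), box = c(10, 10, 10))
  rec <- contact_events(traj, topo, "PC")
  hs <- interaction_frequency(rec)
  expect_equal(sum(hs$percent), 100, tolerance = 1e-12)
  expect_equal(hs$count[hs$resid == 1L], 3L)
  expect_equal(hs$percent[hs$resid == 1L], 75)
  # zero contacts -> empty table with warning
  far <- toy_trajectory(list(rbind(c(0, 0, 0), c(5, 5, 5),
                                   c(2, 2, 2), c(8, 8, 8))), c(10, 10, 10))
  expect_warning(empty <- interaction_frequency(contact_events(far, topo, "PC")),
                 "no contacts")
  expect_equal(nrow(empty), 0L)
})

test_that("pooling sums equivalent residues across monomers before percents", {
  sys <- generate_system(synthetic_spec(n_frames = 60L, seed = 13L))
  rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
  pooled <- interaction_frequency(rec, pool_monomers = TRUE)
  split <- interaction_frequency(rec, pool_monomers = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(dplyr::as_tibble(split),
                                          .data$pooled_key),
                          count = sum(.data$count), .groups = "drop")
  m <- match(pooled$pooled_key, agg$pooled_key)
  expect_equal(pooled$count, agg$count[m])
  expect_equal(sum(split$percent), 100, tolerance = 1e-9)
})

test_that("a planted single site carries the bulk of its species' contacts", {
  spec <- synthetic_spec(
    n_frames = 150L,
    sites = list(list(residues = 1:3, leaflet = "inner",
                      affinity = list(PIP2 = c(k_on = 0.6, k_off = 0.03)))),
    seed = 21L
  )
  sys <- generate_system(spec)
  rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
  hs <- interaction_frequency(rec)
  site_share <- sum(hs$percent[hs$pooled_key %in% sys$truth$sites$residues[[1L]]])
  expect_gt(site_share, 90)
})

test_that("display flagging uses a strict threshold and descending order", {
  tab <- structure(
    tibble::tibble(resid = 1:3, resname = c("ALA", "ARG", "ASN"),
                   pooled_key = c("ALA1", "ARG2", "ASN3"),
                   count = c(75L, 23L, 2L), percent = c(75, 23, 2.5)),
    class = c("hotspot_table", class(tibble::tibble()))
  )
  expect_equal(flag_display_residues(tab, 2.5)$pooled_key, c("ALA1", "ARG2"))
  expect_equal(nrow(flag_display_residues(tab, 75)), 0L)
  expect_equal(flag_display_residues(tab, 6)$percent, c(75, 23))
})

test_that("simultaneous contact histograms match direct enumeration", {
  topo <- toy_topology(3L, 1L)
  # lipid touches all 3 residues every frame (residues clustered)
  prot <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0))
  frames <- lapply(1:4, function(f) rbind(prot, c(0.15, 0.15, 0)))
  rec <- contact_events(toy_trajectory(frames, c(10, 10, 10)), topo, "PC")
  site <- c("ALA1", "ARG2", "ASN3")
  h <- simultaneous_contact_counts(rec, site)
  expect_equal(h$fraction, c(0, 0, 1))
  # random occupancy vs enumeration oracle
  set.seed(31)
  for (rep in 1:20) {
    s <- random_contact_system(1000L + rep, n_res = 6L, n_lipids = 10L,
                               n_frames = 5L)
    rec <- contact_events(s$trajectory, s$topology, "PC")
    if (nrow(rec) == 0L) next
    site <- unique(rec$pooled_key)[1:min(3L, length(unique(rec$pooled_key)))]
    h <- simultaneous_contact_counts(rec, site)
    df <- dplyr::as_tibble(rec)[dplyr::as_tibble(rec)$pooled_key %in% site, ]
    ev <- table(paste(df$frame, df$lipid_id))
    oracle <- tabulate(ev, nbins = length(site)) / length(ev)
    expect_equal(h$fraction, oracle)
  }
})

test_that("site occupancy marks exactly the contact frames", {
  topo <- toy_topology(1L, 1L)
  frames <- lapply(0:5, function(f) {
    lipid <- if (f %in% 2:4) c(0.3, 0, 0) else c(5, 5, 5)
    rbind(c(0, 0, 0), lipid)
  })
  rec <- contact_events(toy_trajectory(frames, c(10, 10, 10)), topo, "PC")
  occ <- site_occupancy(rec, "ALA1")
  expect_equal(as.vector(unclass(occ)[1L, ]),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(simultaneous_contact_counts(rec, character(0)), "no residues")
})

test_that("occupancy from contacts equals the generator's planted intervals", {
  sys <- generate_system(synthetic_spec(n_frames = 150L, seed = 11L))
  truth <- sys$truth
  for (sn in seq_len(nrow(truth$sites))) {
    site <- truth$sites$residues[[sn]]
    for (sp in c("PIP2", "PS")) {
      rec <- contact_events(sys$trajectory, sys$topology, sp)
      occ <- site_occupancy(rec, site)
      iv <- truth$intervals[truth$intervals$species == sp &
                              truth$intervals$site == sn, ]
      if (nrow(occ) == 0L) {
        expect_equal(nrow(iv), 0L)
        next
      }
      planted <- matrix(FALSE, nrow(occ), ncol(occ),
                        dimnames = dimnames(occ))
      for (r in seq_len(nrow(iv))) {
        l <- as.character(iv$lipid_id[r])
        expect_true(l %in% rownames(planted))
        planted[l, (iv$start_frame[r]:iv$end_frame[r]) + 1L] <- TRUE
      }
      got <- unclass(occ)
      attributes(got) <- attributes(got)["dim" == names(attributes(got))]
      dimnames(got) <- dimnames(planted)
      expect_identical(got, planted)
    }
  }
})

test_that("hotspot PDB writer encodes percents as B-factors", {
  sys <- generate_system(synthetic_spec(n_frames = 30L, seed = 41L))
  rec <- contact_events(sys$trajectory, sys$topology, "PIP2")
  hs <- interaction_frequency(rec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_hotspot_pdb(sys$topology, sys$trajectory, hs, path)
  pdb <- bio3d::read.pdb(path)
  top_key <- hs$pooled_key[1L]
  top_resid <- hs$resid[1L]
  bf <- pdb$atom$b[pdb$atom$resno == top_resid &
                     pdb$atom$resid == hs$resname[1L]]
  expect_equal(max(bf), min(hs$percent[1L], 99.99), tolerance = 0.01)
})
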
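records_from_events <- function(events, n_frames) {
  # events: tibble(frame, pooled_key, lipid_id)
  out <- tibble::tibble(
    frame = events$frame, copy = 1L, monomer = 1L,
    resid = as.integer(factor(events$pooled_key)),
    resname = "ALA", pooled_key = events$pooled_key,
    lipid_id = events$lipid_id
  )
  lipidsites:::new_contact_records(out, species = "PC", cutoff = 0.65,
                                   n_frames = n_frames, frame_interval = 1)
}

test_that("co-interaction edges enumerate simultaneous residue pairs", {
  ev <- tibble::tibble(frame = 0L, pooled_key = c("A", "B", "C"),
                       lipid_id = 10L)
  g <- build_interaction_graph(records_from_events(ev, 1L))
  expect_equal(nrow(g), 3L)
  expect_true(all(g$weight == 1))
  expect_equal(sort(paste(g$from, g$to)), c("A B", "A C", "B C"))
  # two lipids, one residue each: no simultaneous pairs
  ev2 <- tibble::tibble(frame = 0L, pooled_key = c("A", "B"),
                        lipid_id = c(1L, 2L))
  expect_equal(nrow(build_interaction_graph(records_from_events(ev2, 1L))), 0L)
})

test_that("edge weights match enumeration and conserve total pair count", {
  set.seed(404)
  for (rep in 1:20) {
    nf <- 6L
    ev <- tibble::tibble(
      frame = sample(0:(nf - 1L), 60L, replace = TRUE),
      pooled_key = sample(LETTERS[1:7], 60L, replace = TRUE),
      lipid_id = sample(1:5, 60L, replace = TRUE)
    )
    ev <- dplyr::distinct(ev)
    g <- build_interaction_graph(records_from_events(ev, nf))
    # oracle: per (frame, lipid) enumerate C(k, 2) pairs
    want <- list()
    for (grp in split(ev$pooled_key, paste(ev$frame, ev$lipid_id))) {
      ks <- sort(unique(grp))
      if (length(ks) >= 2L) {
        prs <- t(utils::combn(ks, 2L))
        for (i in seq_len(nrow(prs))) {
          key <- paste(prs[i, 1L], prs[i, 2L])
          want[[key]] <- (want[[key]] %||% 0) + 1
        }
      }
    }
    got <- stats::setNames(g$weight, paste(g$from, g$to))
    expect_mapequal(as.list(got), want)
    # conservation: total weight = sum over events of choose(k, 2)
    k_per_event <- vapply(split(ev$pooled_key, paste(ev$frame, ev$lipid_id)),
                          function(x) length(unique(x)), integer(1L))
    expect_equal(sum(g$weight), sum(choose(k_per_event, 2L)))
  }
})

test_that("two planted cliques joined weakly give exactly two sites", {
  n <- 8L
  W <- matrix(0, n, n)
  W[1:4, 1:4] <- 10
  W[5:8, 5:8] <- 10
  diag(W) <- 0
  W[4L, 5L] <- W[5L, 4L] <- 0.1
  parts <- detect_sites(graph_from_matrix(W), seed = 42L)
  expect_equal(nrow(parts), 2L)
  expect_setequal(parts$residues[[1L]], sprintf("RES%02d", 1:4))
  expect_setequal(parts$residues[[2L]], sprintf("RES%02d", 5:8))
  # uniform complete graph collapses to one community
  U <- matrix(1, 5L, 5L)
  diag(U) <- 0
  one <- detect_sites(graph_from_matrix(U), seed = 42L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_residues, 5L)
})

test_that("site detection is deterministic given the seed", {
  W <- random_weight_matrix(808L)
  g <- graph_from_matrix(W)
  a <- detect_sites(g, seed = 7L)
  b <- detect_sites(g, seed = 7L)
  expect_identical(a$residues, b$residues)
  expect_identical(attr(a, "modularity"), attr(b, "modularity"))
  # the partition covers every non-isolated node exactly once
  all_res <- sort(unlist(a$residues))
  expect_identical(all_res, sort(unique(c(g$from, g$to))))
})

test_that("edge pruning and empty graphs follow the contract", {
  W <- matrix(0, 4L, 4L)
  W[1L, 2L] <- W[2L, 1L] <- 10
  W[3L, 4L] <- W[4L, 3L] <- 0.5
  g <- graph_from_matrix(W)
  pruned <- detect_sites(g, seed = 1L, min_weight_fraction = 0.2)
  expect_equal(nrow(pruned), 1L)
  expect_setequal(pruned$residues[[1L]], c("RES01", "RES02"))
  empty <- graph_from_matrix(matrix(0, 3L, 3L))
  expect_error(detect_sites(empty[0L, ], seed = 1L), "no edges")
})

test_that("Louvain attains the exhaustive maximum modularity on small graphs", {
  for (seed in 1:12) {
    W <- random_weight_matrix(3000L + seed)
    parts <- detect_sites(graph_from_matrix(W), seed = 42L)
    expect_gte(attr(parts, "modularity"), exact_max_modularity(W) - 1e-9)
  }
})

test_that("consensus merging keeps residues shared across copies", {
  # identical sites in all copies -> consensus equals each copy
  p <- list(list(c("A", "B", "C")), list(c("A", "B", "C")),
            list(c("A", "B", "C")))
  cons <- merge_equivalent_sites(p)
  expect_equal(cons$residues[[1L]], c("A", "B", "C"))
  expect_equal(cons$n_support, 3L)
  # one jittering residue present in 3 of 4 matched sites survives at 0.5
  p2 <- list(list(c("A", "B", "C")), list(c("A", "B", "C")),
             list(c("A", "B", "C", "D")), list(c("A", "B")))
  cons2 <- merge_equivalent_sites(p2, min_fraction = 0.5)
  expect_setequal(cons2$residues[[1L]], c("A", "B", "C"))
  # per-copy detection on generated data converges to the planted sets
  sys <- generate_system(synthetic_spec(n_frames = 300L, seed = 19L))
  rec <- contact_events(sys$trajectory, sys$topology, "PS")
  per_copy <- lapply(1:4, function(mn) {
    sub <- lipidsites:::new_contact_records(
      dplyr::as_tibble(rec)[rec$monomer == mn, ],
      species = "PS", cutoff = 0.65,
      n_frames = attr(rec, "n_frames"),
      frame_interval = attr(rec, "frame_interval")
    )
    g <- build_interaction_graph(sub)
    if (nrow(g) == 0L) return(NULL)
    detect_sites(g, seed = 42L)
  })
  per_copy <- per_copy[!vapply(per_copy, is.null, logical(1L))]
  expect_gte(length(per_copy), 3L)
  cons3 <- merge_equivalent_sites(per_copy)
  planted <- sys$truth$sites$residues
  for (site in planted) {
    best <- max(vapply(cons3$residues, function(r) jaccard(r, site),
                       numeric(1L)))
    expect_gte(best, 0.9)
  }
})

test_that("interaction_site accessor exposes one community", {
  W <- matrix(0, 4L, 4L)
  W[1:2, 1:2] <- 5
  W[3:4, 3:4] <- 3
  diag(W) <- 0
  parts <- detect_sites(graph_from_matrix(W), seed = 2L)
  s <- interaction_site(parts, 1L)
  expect_s3_class(s, "interaction_site")
  expect_equal(s$residues, parts$residues[[1L]])
  expect_error(interaction_site(parts, 99L), "no site")
})
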
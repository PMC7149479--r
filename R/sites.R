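#' Build the residue co-interaction graph
#'
#' Nodes are protein residues; an edge joins two residues each time they
#' contact the same lipid molecule in the same frame, so the edge weight is
#' the number of (frame, lipid) events in which the pair co-interacts.
#' With `pool = TRUE` (default) equivalent residues across monomers and
#' copies share a node (pooled residue keys), which pools the statistics of
#' all site instances of a symmetric multimer into one graph.
#'
#' @param records A `contact_records` from [contact_events()].
#' @param pool Pool equivalent residues across monomers/copies.
#' @param normalize Divide weights by the number of frames (the Louvain
#'   partition is invariant to this global factor).
#' @return An `interaction_graph` tibble of undirected edges: `from`, `to`
#'   (residue keys, `from < to`), `weight`.
#' @export
build_interaction_graph <- function(records, pool = TRUE,
                                    normalize = FALSE) {
  hits <- dplyr::as_tibble(records)
  key <- if (pool) {
    hits$pooled_key
  } else {
    sprintf("c%d.m%d:%s", hits$copy, hits$monomer, hits$pooled_key)
  }
  event <- paste(hits$frame, hits$lipid_id)
  groups <- split(key, event)
  pair_list <- lapply(groups, function(ks) {
    ks <- sort(unique(ks))
    if (length(ks) < 2L) return(NULL)
    t(utils::combn(ks, 2L))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  } else {
    edges <- dplyr::count(
      tibble::tibble(from = pairs[, 1L], to = pairs[, 2L]),
      .data$from, .data$to, name = "weight"
    )
    edges$weight <- as.numeric(edges$weight)
    if (normalize) edges$weight <- edges$weight / attr(records, "n_frames")
  }
  structure(
    edges,
    species = attr(records, "species"),
    n_frames = attr(records, "n_frames"),
    pooled = pool, normalized = normalize,
    class = c("interaction_graph", class(tibble::tibble()))
  )
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(as.data.frame(graph)[, c("from", "to")],
                                directed = FALSE) |>
    igraph::set_edge_attr("weight", value = graph$weight)
}

#' Detect lipid interaction sites by community analysis
#'
#' Partitions the residue co-interaction graph with the weighted Louvain
#' (multilevel modularity) algorithm; every community is an interaction
#' site. Edges lighter than `min_weight_fraction` of the heaviest edge are
#' removed first (default: none). Because greedy Louvain is sensitive to
#' vertex order, a small number of seeded restarts with shuffled vertex
#' order is run and the maximum-modularity partition kept; the result is
#' deterministic given `seed`. Singleton communities with no internal
#' weight are discarded.
#'
#' @param graph An `interaction_graph`.
#' @param seed Integer seed controlling the restarts.
#' @param resolution Louvain resolution; >1 favours smaller communities.
#' @param min_weight_fraction Prune edges below this fraction of the
#'   maximum edge weight before partitioning.
#' @param n_restarts Number of shuffled-order restarts.
#' @return A `site_partition` tibble ordered by descending internal weight:
#'   `site_id`, `n_residues`, `total_weight` (sum of internal edge
#'   weights), `residues` (list column of residue keys). Attributes:
#'   `modularity`, `seed`, `resolution`, `species`.
#' @export
detect_sites <- function(graph, seed = 42L, resolution = 1.0,
                         min_weight_fraction = 0, n_restarts = 8L) {
  if (nrow(graph) == 0L) {
    stop("interaction graph has no edges; cannot detect sites",
         call. = FALSE)
  }
  edges <- dplyr::as_tibble(graph)
  if (min_weight_fraction > 0) {
    edges <- edges[edges$weight >= min_weight_fraction * max(edges$weight), ]
    if (nrow(edges) == 0L) {
      stop("all edges pruned by min_weight_fraction", call. = FALSE)
    }
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges)[, c("from", "to")], directed = FALSE
  )
  igraph::E(g)$weight <- edges$weight

  nodes <- igraph::V(g)$name
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes)
    j <- match(edges$to[r], nodes)
    W[i, j] <- W[i, j] + edges$weight[r]
    W[j, i] <- W[j, i] + edges$weight[r]
  }

  best <- NULL
  best_q <- -Inf
  seeds <- derive_seeds(seed, n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    perm <- sample(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = resolution)
    # membership is named by vertex; realign to g's vertex order
    memb <- igraph::membership(cl)[nodes]
    memb <- refine_partition(W, as.integer(memb), resolution)
    # iterated local search: seeded kicks out of residual local optima
    q_r <- modularity_of(W, memb, resolution)
    for (kick in 1:6) {
      trial <- memb
      move <- sample(seq_along(trial), min(2L, length(trial)))
      trial[move] <- sample(c(unique(trial), max(trial) + 1L),
                            length(move), replace = TRUE)
      trial <- refine_partition(W, trial, resolution)
      q_t <- modularity_of(W, trial, resolution)
      if (q_t > q_r + 1e-12) {
        memb <- trial
        q_r <- q_t
      }
    }
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                            resolution = resolution)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- stats::setNames(memb, nodes)
    }
  }

  comm <- split(names(best), as.integer(best))
  wt <- vapply(comm, function(res) {
    sum(edges$weight[edges$from %in% res & edges$to %in% res])
  }, numeric(1L))
  keep <- !(lengths(comm) == 1L & wt <= 0)
  comm <- comm[keep]
  wt <- wt[keep]
  ord <- order(-wt, vapply(comm, min, character(1L)))
  out <- tibble::tibble(
    site_id = seq_along(ord),
    n_residues = unname(lengths(comm)[ord]),
    total_weight = unname(wt[ord]),
    residues = unname(lapply(comm[ord], function(r) sort(unname(r))))
  )
  structure(out,
            modularity = best_q, seed = seed, resolution = resolution,
            min_weight_fraction = min_weight_fraction,
            species = attr(graph, "species"),
            class = c("site_partition", class(tibble::tibble())))
}

# Greedy post-refinement of a Louvain partition: single-node moves and
# whole-community merges accepted while they increase modularity. The
# greedy multilevel pass is order-sensitive and can stall in local optima
# on small weighted graphs; this polish step is deterministic and never
# decreases modularity.
refine_partition <- function(W, memb, resolution = 1.0) {
  n <- length(memb)
  k <- rowSums(W)
  m2 <- sum(W)               # 2m
  if (m2 <= 0) return(memb)
  q_now <- modularity_of(W, memb, resolution)
  repeat {
    improved <- FALSE
    # single-node moves, best-improvement per node, exact evaluation
    for (i in seq_len(n)) {
      for (cand in setdiff(unique(memb), memb[i])) {
        trial <- memb
        trial[i] <- cand
        q_trial <- modularity_of(W, trial, resolution)
        if (q_trial > q_now + 1e-12) {
          memb <- trial
          q_now <- q_trial
          improved <- TRUE
        }
      }
    }
    # pairwise exchanges across communities (Kernighan-Lin style): each
    # individual move can decrease Q even when the swap increases it
    if (n <= 40L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (memb[i] == memb[j]) next
          trial <- memb
          trial[c(i, j)] <- memb[c(j, i)]
          q_trial <- modularity_of(W, trial, resolution)
          if (q_trial > q_now + 1e-12) {
            memb <- trial
            q_now <- q_trial
            improved <- TRUE
          }
        }
      }
    }
    # two-way community splits: exhaustive for small communities,
    # spectral (modularity-matrix leading vector) for large ones
    for (cc in unique(memb)) {
      members <- which(memb == cc)
      s <- length(members)
      if (s < 2L) next
      if (s <= 14L) {
        for (mask in seq_len(2^(s - 1L) - 1L)) {
          side <- as.logical(bitwAnd(mask, 2^(seq_len(s) - 1L)))
          trial <- memb
          trial[members[side]] <- max(memb) + 1L
          q_trial <- modularity_of(W, trial, resolution)
          if (q_trial > q_now + 1e-12) {
            memb <- trial
            q_now <- q_trial
            improved <- TRUE
            break
          }
        }
      } else {
        B <- W[members, members, drop = FALSE]
        kk <- k[members]
        Bmod <- B - resolution * outer(kk, kk) / m2
        ev <- eigen(Bmod, symmetric = TRUE)$vectors[, 1L]
        side <- ev > 0
        if (any(side) && !all(side)) {
          trial <- memb
          trial[members[side]] <- max(memb) + 1L
          q_trial <- modularity_of(W, trial, resolution)
          if (q_trial > q_now + 1e-12) {
            memb <- trial
            q_now <- q_trial
            improved <- TRUE
          }
        }
      }
    }
    # whole-community merges
    comms <- sort(unique(memb))
    for (a_i in seq_along(comms)) {
      for (b_i in seq_along(comms)) {
        if (a_i >= b_i) next
        if (!all(c(comms[a_i], comms[b_i]) %in% memb)) next
        trial <- memb
        trial[trial == comms[b_i]] <- comms[a_i]
        q_trial <- modularity_of(W, trial, resolution)
        if (q_trial > q_now + 1e-12) {
          memb <- trial
          q_now <- q_trial
          improved <- TRUE
        }
      }
    }
    if (!improved) return(memb)
  }
}

modularity_of <- function(W, memb, resolution = 1.0) {
  m2 <- sum(W)
  q <- 0
  k <- rowSums(W)
  for (c in unique(memb)) {
    inC <- memb == c
    q <- q + sum(W[inC, inC]) / m2 -
      resolution * (sum(k[inC]) / m2)^2
  }
  q
}

#' One interaction site from a partition
#'
#' @param partition A `site_partition`.
#' @param site_id Which site.
#' @return An `interaction_site`: list with `site_id`, `residues` (pooled
#'   keys), `species`, `total_weight`.
#' @export
interaction_site <- function(partition, site_id = 1L) {
  row <- dplyr::as_tibble(partition)[partition$site_id == site_id, ]
  if (nrow(row) == 0L) stop("no site with id ", site_id, call. = FALSE)
  structure(
    list(site_id = site_id, residues = row$residues[[1L]],
         species = attr(partition, "species"),
         total_weight = row$total_weight),
    class = "interaction_site"
  )
}

#' @export
print.interaction_site <- function(x, ...) {
  cat("<interaction_site> #", x$site_id, " (", x$species %||% "?", "): ",
      paste(x$residues, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Consensus sites across protein copies
#'
#' Matches per-copy site partitions (residues expressed as pooled,
#' within-monomer keys) by maximal Jaccard overlap against the partition
#' with the most sites, and keeps in each consensus site the residues
#' present in at least `min_fraction` of its matched sites. Jaccard ties
#' break deterministically towards the candidate containing the
#' lexicographically smallest residue key.
#'
#' @param partitions A list of `site_partition` objects (or plain lists of
#'   residue-key vectors), one per protein copy.
#' @param min_fraction Fraction of matched sites a residue must appear in.
#' @return A tibble: `site_id`, `n_support` (sites merged), `residues`
#'   (list column).
#' @export
merge_equivalent_sites <- function(partitions, min_fraction = 0.5) {
  site_sets <- lapply(partitions, function(p) {
    if (inherits(p, "site_partition") || is.data.frame(p)) {
      p$residues
    } else {
      p
    }
  })
  if (!length(site_sets)) stop("no partitions given", call. = FALSE)
  ref_idx <- which.max(lengths(site_sets))
  groups <- lapply(site_sets[[ref_idx]], list)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (p in seq_along(site_sets)) {
    if (p == ref_idx) next
    for (s in site_sets[[p]]) {
      sims <- vapply(groups, function(g) jaccard(s, g[[1L]]), numeric(1L))
      if (!length(sims) || max(sims) == 0) {
        groups[[length(groups) + 1L]] <- list(s)
        next
      }
      hit <- which(sims == max(sims))
      if (length(hit) > 1L) {
        firsts <- vapply(hit, function(h) min(groups[[h]][[1L]]),
                         character(1L))
        hit <- hit[order(firsts)][1L]
        message("tied Jaccard match broken towards site containing ",
                min(groups[[hit]][[1L]]))
      }
      groups[[hit]] <- c(groups[[hit]], list(s))
    }
  }
  consensus <- lapply(groups, function(g) {
    tab <- table(unlist(lapply(g, unique)))
    sort(names(tab)[tab >= min_fraction * length(g)])
  })
  keep <- lengths(consensus) > 0L
  tibble::tibble(
    site_id = seq_len(sum(keep)),
    n_support = lengths(groups)[keep],
    residues = consensus[keep]
  )
}

#' Exhaustive maximum modularity of a small graph
#'
#' Enumerates every set partition of the nodes (restricted-growth strings)
#' and returns the maximum Newman-Girvan weighted modularity. Exponential
#' in node count; limited to 13 nodes. Intended as an independent oracle
#' for community-detection results.
#'
#' @param graph An `interaction_graph` (edge tibble) or a symmetric weight
#'   matrix with zero diagonal.
#' @return Maximum modularity (numeric scalar).
#' @export
exact_max_modularity <- function(graph) {
  if (is.matrix(graph)) {
    W <- graph
  } else {
    nodes <- sort(unique(c(graph$from, graph$to)))
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(graph))) {
      i <- match(graph$from[r], nodes)
      j <- match(graph$to[r], nodes)
      W[i, j] <- W[i, j] + graph$weight[r]
      W[j, i] <- W[j, i] + graph$weight[r]
    }
  }
  best_partition_modularity_cpp(W)
}
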
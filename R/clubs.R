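#' Detect bacterial clubs in a co-occurrence network
#'
#' A *club* is a group of at least `min_size` OTUs with strong mutual
#' positive correlations. Clubs are found by Markov clustering of the
#' FDR-masked correlation matrix; because MCL needs non-negative input, the
#' negative correlations are either clamped to zero (`negative = "clamp"`,
#' the default, appropriate for plain club detection) or replaced by their
#' absolute values (`negative = "abs"`, the first phase of rival-club
#' detection). MCL clusters smaller than `min_size` are not clubs; their
#' nodes are reported as unassigned.
#'
#' @param net a `cooccurrence_network` from [build_network()].
#' @param params an [mcl_params] object.
#' @param min_size minimum club size (default 3).
#' @param negative how negative correlations enter the clustering:
#'   `"clamp"` (drop them) or `"abs"` (use magnitudes).
#' @return a `club_partition`: list with `clubs` (list of character vectors
#'   of OTU ids, ordered by decreasing size), `leaders` (character, per
#'   club), `unassigned` (character vector), `membership` (integer per
#'   network node, NA = unassigned), and the underlying `mcl` result.
#' @export
find_clubs <- function(net, params = mcl_params(), min_size = 3,
                       negative = c("clamp", "abs")) {
  stopifnot(inherits(net, "cooccurrence_network"))
  negative <- match.arg(negative)
  w <- net$r_masked
  diag(w) <- 0
  w <- if (negative == "abs") abs(w) else pmax(w, 0)
  if (all(w == 0))
    warning("edgeless network: all nodes unassigned")
  res <- mcl_cluster(w, params)
  partition_from_mcl(res, net$nodes$otu_id, min_size)
}

# turn an mcl_result into a club_partition (size filter + deterministic
# ordering: decreasing size, ties by first member's node index)
partition_from_mcl <- function(res, ids, min_size) {
  sizes <- lengths(res$clusters)
  keep <- which(sizes >= min_size)
  ord <- keep[order(-sizes[keep],
                    vapply(res$clusters[keep], min, integer(1)))]
  clubs <- lapply(res$clusters[ord], function(ix) ids[ix])
  leaders <- ids[res$leaders[ord]]
  member_idx <- unlist(res$clusters[ord], use.names = FALSE)
  membership <- rep(NA_integer_, length(ids))
  for (ci in seq_along(ord)) membership[res$clusters[[ord[ci]]]] <- ci
  structure(
    list(clubs = clubs, leaders = leaders,
         unassigned = ids[setdiff(seq_along(ids), member_idx)],
         membership = membership, mcl = res),
    class = "club_partition")
}

#' @export
print.club_partition <- function(x, ...) {
  cat(sprintf("club_partition: %d clubs, %d unassigned nodes\n",
              length(x$clubs), length(x$unassigned)))
  for (i in seq_along(x$clubs))
    cat(sprintf("  club %d (n=%d, leader %s)\n", i, length(x$clubs[[i]]),
                x$leaders[i]))
  invisible(x)
}

#' Intra- and inter-club correlation summaries
#'
#' Mean and sample SD of the *nonzero* (significance-retained) correlations
#' within each club, and between each pair of clubs. Pairs whose
#' cross-correlations were all masked are reported as `NA`, not 0.
#'
#' @param net a `cooccurrence_network`.
#' @param partition a `club_partition`.
#' @return list with data frames `intra` (club, n_members, n_edges, mean,
#'   sd) and `inter` (club_a, club_b, n_edges, n_negative, mean, sd,
#'   neg_fraction).
#' @export
club_stats <- function(net, partition) {
  stopifnot(inherits(net, "cooccurrence_network"),
            inherits(partition, "club_partition"))
  ids <- net$nodes$otu_id
  bad <- setdiff(unlist(partition$clubs), ids)
  if (length(bad))
    stop("club member(s) not in network: ", paste(bad, collapse = ", "))
  R <- net$r_masked
  k <- length(partition$clubs)
  summarize <- function(v) {
    v <- v[v != 0]
    if (!length(v)) return(c(n = 0, neg = 0, mean = NA_real_, sd = NA_real_))
    c(n = length(v), neg = sum(v < 0), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0)
  }
  intra <- do.call(rbind, lapply(seq_len(k), function(i) {
    ix <- match(partition$clubs[[i]], ids)
    sub <- R[ix, ix, drop = FALSE]
    s <- summarize(sub[upper.tri(sub)])
    data.frame(club = i, n_members = length(ix), n_edges = s["n"],
               mean = s["mean"], sd = s["sd"], row.names = NULL)
  }))
  inter <- NULL
  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      sub <- R[match(partition$clubs[[i]], ids),
               match(partition$clubs[[j]], ids), drop = FALSE]
      s <- summarize(as.vector(sub))
      data.frame(club_a = i, club_b = j, n_edges = s["n"],
                 n_negative = s["neg"], mean = s["mean"], sd = s["sd"],
                 neg_fraction = if (s["n"] > 0) s["neg"] / s["n"] else NA_real_,
                 row.names = NULL)
    }))
  }
  list(intra = intra, inter = inter)
}

#' Detect rival clubs via the two-phase algorithm
#'
#' Rival clubs are pairs of clubs whose members are predominantly
#' negatively correlated with each other — candidate competing communities.
#' Phase 1 clusters the absolute-value masked correlation matrix, yielding
#' *super-clubs*: groups with strong correlations of either sign. Phase 2
#' re-clusters each super-club using only its positive correlations,
#' splitting it into sub-clubs. Two sub-clubs of the same super-club are
#' held together by strong |r| but share few positive edges, so their
#' cross-edges must be largely negative; a pair is reported as rivals when
#' its mean nonzero inter-correlation is negative and at least
#' `neg_fraction` of those nonzero inter-correlations are negative.
#'
#' @param net a `cooccurrence_network`.
#' @param params an [mcl_params] for both phases.
#' @param min_size minimum sub-club size (default 3).
#' @param neg_fraction minimum fraction of nonzero inter-correlations that
#'   must be negative (default 0.5).
#' @return a `rival_result`: list with `rivals` (data frame: club_a,
#'   club_b, super_club, inter_mean, inter_sd, n_edges, neg_fraction —
#'   club ids index into `partition$clubs`), `partition` (the phase-2
#'   `club_partition` over all nodes), and `super_membership` (phase-1
#'   cluster id per node).
#' @export
find_rival_clubs <- function(net, params = mcl_params(), min_size = 3,
                             neg_fraction = 0.5) {
  stopifnot(inherits(net, "cooccurrence_network"))
  ids <- net$nodes$otu_id
  R <- net$r_masked
  diag(R) <- 0

  # phase 1: super-clubs on |r|
  super <- mcl_cluster(abs(R), params)

  # phase 2: positive-only MCL within each super-club
  pos <- pmax(R, 0)
  sub_clubs <- list(); sub_leaders <- character(0); sub_super <- integer(0)
  for (sc in seq_along(super$clusters)) {
    ix <- super$clusters[[sc]]
    if (length(ix) == 1) {
      sub_clubs <- c(sub_clubs, list(ix)); sub_leaders <- c(sub_leaders, ids[ix])
      sub_super <- c(sub_super, sc); next
    }
    res2 <- mcl_cluster(pos[ix, ix, drop = FALSE], params)
    for (cl in seq_along(res2$clusters)) {
      sub_clubs <- c(sub_clubs, list(ix[res2$clusters[[cl]]]))
      sub_leaders <- c(sub_leaders, ids[ix[res2$leaders[cl]]])
      sub_super <- c(sub_super, sc)
    }
  }

  # package phase-2 clusters as a club_partition (size >= min_size)
  sizes <- lengths(sub_clubs)
  keep <- which(sizes >= min_size)
  ord <- keep[order(-sizes[keep], vapply(sub_clubs[keep], min, integer(1)))]
  clubs <- lapply(sub_clubs[ord], function(ix) ids[ix])
  membership <- rep(NA_integer_, length(ids))
  for (ci in seq_along(ord)) membership[sub_clubs[[ord[ci]]]] <- ci
  partition <- structure(
    list(clubs = clubs, leaders = sub_leaders[ord],
         unassigned = ids[is.na(membership)], membership = membership,
         mcl = super),
    class = "club_partition")
  club_super <- sub_super[ord]

  rivals <- data.frame(club_a = integer(0), club_b = integer(0),
                       super_club = integer(0), inter_mean = numeric(0),
                       inter_sd = numeric(0), n_edges = integer(0),
                       neg_fraction = numeric(0))
  k <- length(clubs)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (club_super[i] != club_super[j]) next
      sub <- R[match(clubs[[i]], ids), match(clubs[[j]], ids), drop = FALSE]
      v <- sub[sub != 0]
      if (!length(v)) next
      nf <- mean(v < 0)
      if (mean(v) < 0 && nf >= neg_fraction) {
        rivals <- rbind(rivals, data.frame(
          club_a = i, club_b = j, super_club = club_super[i],
          inter_mean = mean(v),
          inter_sd = if (length(v) > 1) stats::sd(v) else 0,
          n_edges = length(v), neg_fraction = nf))
      }
    }
  }
  rownames(rivals) <- NULL
  structure(list(rivals = rivals, partition = partition,
                 super_membership = super$membership),
            class = "rival_result")
}

#' @export
print.rival_result <- function(x, ...) {
  cat(sprintf("rival_result: %d rival pair(s) among %d clubs\n",
              nrow(x$rivals), length(x$partition$clubs)))
  if (nrow(x$rivals)) print(x$rivals)
  invisible(x)
}

#' Club membership table with top members
#'
#' Summary table in the style of the five-most-abundant-members-per-club
#' listing: for each club, the `top_k` members with the highest mean
#' abundance, the leader flagged.
#'
#' @param net a `cooccurrence_network`.
#' @param partition a `club_partition`.
#' @param top_k members listed per club (default 5).
#' @return data frame: club, otu_id, mean_abundance, is_leader.
#' @export
club_summary_table <- function(net, partition, top_k = 5) {
  stopifnot(inherits(partition, "club_partition"))
  ab <- stats::setNames(net$nodes$mean_abundance, net$nodes$otu_id)
  do.call(rbind, lapply(seq_along(partition$clubs), function(i) {
    members <- partition$clubs[[i]]
    members <- members[order(-ab[members])]
    members <- utils::head(members, top_k)
    data.frame(club = i, otu_id = members,
               mean_abundance = unname(ab[members]),
               is_leader = members == partition$leaders[i],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write club and rival tables as TSV
#'
#' @param partition a `club_partition`.
#' @param path output TSV path (otu_id, club_id, is_attractor, is_leader).
#' @return `path`, invisibly.
#' @export
write_clubs_tsv <- function(partition, path) {
  ids_all <- c(unlist(partition$clubs), partition$unassigned)
  mcl <- partition$mcl
  attractor_ids <- mcl$node_names[unlist(mcl$attractors)]
  rows <- do.call(rbind, lapply(seq_along(partition$clubs), function(i) {
    data.frame(otu_id = partition$clubs[[i]], club_id = i,
               stringsAsFactors = FALSE)
  }))
  if (length(partition$unassigned))
    rows <- rbind(rows, data.frame(otu_id = partition$unassigned,
                                   club_id = NA_integer_))
  rows$is_attractor <- rows$otu_id %in% attractor_ids
  rows$is_leader <- rows$otu_id %in% partition$leaders & !is.na(rows$club_id)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clubs_tsv
#' @param rr a `rival_result`.
#' @export
write_rivals_tsv <- function(rr, path) {
  stopifnot(inherits(rr, "rival_result"))
  utils::write.table(rr$rivals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
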
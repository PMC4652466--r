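test_that("clusters below min_size become unassigned nodes", {
  # blocks of 5, 4 and 2 fully connected at r = 0.8: MCL returns them as
  # clusters; only the first two are clubs
  net <- net_from_masked(block_corr(c(5, 4, 2)))
  p <- find_clubs(net)
  expect_length(p$clubs, 2)
  expect_equal(lengths(p$clubs), c(5L, 4L))
  expect_length(p$unassigned, 2)
  expect_true(all(is.na(p$membership[10:11])))
})

test_that("an edgeless network yields zero clubs with a warning", {
  net <- net_from_masked(diag(5))
  expect_warning(p <- find_clubs(net), "edgeless")
  expect_length(p$clubs, 0)
  expect_length(p$unassigned, 5)
})

test_that("planted positive blocks are recovered exactly (ARI = 1)", {
  sim <- generate_community(community_spec(
    seed = 101, clubs = rep(list(list(size = 8, rho = 0.6)), 3),
    n_background = 0))
  nm <- normalize_and_log(filter_otus(subset_group(sim$abundance, "A")))
  net <- build_network(correlation_with_significance(nm),
                       colMeans(nm$values))
  p <- find_clubs(net)
  truth <- sim$truth$otus$club[match(nm$otu_ids, sim$truth$otus$otu_id)]
  got <- ifelse(is.na(p$membership), 0L, p$membership)
  expect_equal(ari(truth, got), 1)
})

test_that("club_stats honors the only-significant-correlations rule", {
  R <- diag(6)
  dimnames(R) <- list(paste0("T", 1:6), paste0("T", 1:6))
  # club {1,2,3}: r = {0.2, 0.4, masked 0}; club {4,5,6}: all 0.5
  R[1, 2] <- R[2, 1] <- 0.2
  R[1, 3] <- R[3, 1] <- 0.4
  R[4, 5] <- R[5, 4] <- R[4, 6] <- R[6, 4] <- R[5, 6] <- R[6, 5] <- 0.5
  net <- net_from_masked(R)
  partition <- structure(
    list(clubs = list(c("T1", "T2", "T3"), c("T4", "T5", "T6")),
         leaders = c("T1", "T4"), unassigned = character(0),
         membership = c(1L, 1L, 1L, 2L, 2L, 2L),
         mcl = NULL),
    class = "club_partition")
  st <- club_stats(net, partition)
  expect_equal(st$intra$mean[1], 0.3)          # mean over the two nonzero r
  expect_equal(st$intra$n_edges[1], 2)
  expect_equal(st$intra$mean[2], 0.5)
  expect_equal(st$intra$sd[2], 0)
  # no nonzero inter correlations: undefined, not zero
  expect_true(is.na(st$inter$mean[1]))
  expect_equal(st$inter$n_edges[1], 0)
})

test_that("uniform inter-correlations give exact inter stats", {
  R <- block_corr(c(3, 3), intra = 0.6)
  R[1:3, 4:6] <- -0.1
  R[4:6, 1:3] <- -0.1
  net <- net_from_masked(R)
  p <- find_clubs(net)
  st <- club_stats(net, p)
  expect_equal(st$inter$mean[1], -0.1)
  expect_equal(st$inter$sd[1], 0)
  expect_equal(st$inter$neg_fraction[1], 1)
})

test_that("club_stats validates membership against the network", {
  net <- net_from_masked(block_corr(c(3, 3)))
  p <- find_clubs(net)
  p$clubs[[1]] <- c(p$clubs[[1]], "GHOST")
  expect_error(club_stats(net, p), "GHOST")
})

test_that("all-positive networks produce no rivals", {
  net <- net_from_masked(block_corr(c(4, 4), intra = 0.7))
  rr <- find_rival_clubs(net)
  expect_equal(nrow(rr$rivals), 0)
})

test_that("negating inter-block correlations creates exactly one rival pair", {
  R <- block_corr(c(5, 5), intra = 0.7)
  # strong positive inter edges: still not rivals
  R[1:5, 6:10] <- 0.45
  R[6:10, 1:5] <- 0.45
  expect_equal(nrow(find_rival_clubs(net_from_masked(R))$rivals), 0)
  # sign-flip the inter block: the pair becomes a rivalry
  R[1:5, 6:10] <- -0.45
  R[6:10, 1:5] <- -0.45
  rr <- find_rival_clubs(net_from_masked(R))
  expect_equal(nrow(rr$rivals), 1)
  expect_equal(rr$rivals$inter_mean, -0.45)
  expect_equal(rr$rivals$neg_fraction, 1)
  a <- rr$partition$clubs[[rr$rivals$club_a]]
  b <- rr$partition$clubs[[rr$rivals$club_b]]
  expect_setequal(c(a, b), paste0("T", sprintf("%02d", 1:10)))
})

test_that("reported rivals always have negative inter mean and same super-club", {
  set.seed(77)
  all_rivals <- list()
  for (rep in 1:5) {
    n <- 14
    vals <- runif(n * n, -0.6, 0.6) * (runif(n * n) < 0.4)
    M <- matrix(vals, n); M <- (M + t(M)) / 2
    R <- M; diag(R) <- 1
    dimnames(R) <- list(sprintf("T%02d", 1:n), sprintf("T%02d", 1:n))
    all_rivals[[rep]] <- find_rival_clubs(net_from_masked(R))$rivals
  }
  # a constructed rivalry guarantees the property is exercised at least once
  R <- block_corr(c(4, 4), intra = 0.7)
  R[1:4, 5:8] <- -0.5; R[5:8, 1:4] <- -0.5
  all_rivals$constructed <- find_rival_clubs(net_from_masked(R))$rivals
  rivals <- do.call(rbind, all_rivals)
  expect_gte(nrow(rivals), 1)
  expect_true(all(rivals$inter_mean < 0))
  expect_true(all(rivals$neg_fraction >= 0.5))
})

test_that("phase 2 equals plain club detection when one super-club spans the network", {
  R <- block_corr(c(4, 4), intra = 0.7)
  R[1:4, 5:8] <- -0.5
  R[5:8, 1:4] <- -0.5
  net <- net_from_masked(R)
  plain <- find_clubs(net)            # clamp negatives: two positive cliques
  rr <- find_rival_clubs(net)         # phase 1 joins all; phase 2 splits
  expect_equal(length(plain$clubs), length(rr$partition$clubs))
  for (k in seq_along(plain$clubs))
    expect_setequal(plain$clubs[[k]], rr$partition$clubs[[k]])
})

test_that("planted rival pair is recovered from generated data", {
  sim <- generate_community(community_spec(
    seed = 202, rival_pairs = list(list(pair = c(1, 2), rho = -0.3))))
  nm <- normalize_and_log(filter_otus(subset_group(sim$abundance, "A")))
  net <- build_network(correlation_with_significance(nm),
                       colMeans(nm$values))
  rr <- find_rival_clubs(net)
  expect_equal(nrow(rr$rivals), 1)
  tr <- sim$truth$otus
  lab <- function(members) {
    t <- table(tr$club[match(members, tr$otu_id)])
    as.integer(names(which.max(t)))
  }
  got <- sort(c(lab(rr$partition$clubs[[rr$rivals$club_a]]),
                lab(rr$partition$clubs[[rr$rivals$club_b]])))
  expect_equal(got, c(1L, 2L))
})

test_that("summary table lists top-abundance members with leader flag", {
  R <- block_corr(c(4, 3), intra = 0.8)
  cr <- fake_corr(R)
  net <- build_network(cr, mean_abundance = c(7, 1, 2, 3, 6, 5, 4))
  p <- find_clubs(net)
  tab <- club_summary_table(net, p, top_k = 2)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$otu_id[tab$club == 1], c("T01", "T04"))
  expect_equal(sum(tab$is_leader), sum(p$leaders %in% tab$otu_id))
})

test_that("clubs and rivals TSV exports round-trip", {
  net <- net_from_masked(block_corr(c(4, 3)))
  p <- find_clubs(net)
  rr <- find_rival_clubs(net)
  dir <- withr::local_tempdir()
  write_clubs_tsv(p, file.path(dir, "clubs.tsv"))
  write_rivals_tsv(rr, file.path(dir, "rivals.tsv"))
  clubs <- read.delim(file.path(dir, "clubs.tsv"))
  expect_setequal(clubs$otu_id, net$nodes$otu_id)
  expect_equal(sum(clubs$is_leader), 2)
  rivals <- read.delim(file.path(dir, "rivals.tsv"))
  expect_identical(colnames(rivals),
                   c("club_a", "club_b", "super_club", "inter_mean",
                     "inter_sd", "n_edges", "neg_fraction"))
})
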
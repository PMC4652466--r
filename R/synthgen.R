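#' Specification of a synthetic microbial community
#'
#' Describes the statistical world the generator samples from: a
#' latent-factor log-normal abundance model with planted positively
#' correlated OTU blocks (clubs), optional anti-correlated block pairs
#' (rivals), a boosted-loading leader per club, uncorrelated background
#' OTUs, fixed-depth multinomial read sampling, and random structural
#' zeros. Correlation targets are on the log-abundance scale — the scale on
#' which the analysis pipeline computes correlations.
#'
#' The defaults mirror the planted-recovery setting used throughout the
#' test suite: 100 samples, four clubs of eight OTUs with intra-club
#' correlation 0.6, twenty background OTUs, 50,000 reads per sample.
#'
#' @param n_samples samples per group (default 100).
#' @param clubs list of `list(size =, rho =)` entries: club size (>= 3) and
#'   target intra-club correlation in (0, 1). Default: four clubs of size 8
#'   at rho 0.6.
#' @param rival_pairs list of `list(pair = c(i, j), rho =)` entries: indices
#'   of two clubs and their target inter-club correlation in (-1, 0).
#'   Default: none.
#' @param leader_boost extra factor loading given to each club's designated
#'   leader (first member), >= 0 (default 0.2), making the leader a hub with
#'   clearly dominant correlations to its club.
#' @param n_background uncorrelated background OTUs (default 20).
#' @param depth reads per sample (default 50000).
#' @param sparsity probability that an abundance cell is a structural zero
#'   on top of the sampling zeros the multinomial produces anyway (default
#'   0). Structural zeros land on the pseudocount floor after the log
#'   transform and attenuate planted correlations quickly; see the vignette.
#' @param base_sd SD of per-OTU baseline log10 abundance (default 0.4),
#'   giving abundances spanning several orders of magnitude.
#' @param latent_sd SD of the latent log10 fluctuation (default 0.6).
#' @param model_fraction expected fraction of each sample's reads taken by
#'   the modeled OTUs (default 0.10). The remaining reads belong to a
#'   stable unmodeled community remainder that is sampled and discarded;
#'   modeling the OTUs as a minority of the community keeps the
#'   relative-abundance denominator nearly constant, so log-scale
#'   correlation targets survive the compositional closure.
#' @param groups group labels; one full sample set is generated per group
#'   (default `"A"`).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return a list of class `community_spec`.
#' @export
community_spec <- function(n_samples = 100,
                           clubs = rep(list(list(size = 8, rho = 0.6)), 4),
                           rival_pairs = list(),
                           leader_boost = 0.2,
                           n_background = 20,
                           depth = 50000,
                           sparsity = 0,
                           base_sd = 0.4,
                           latent_sd = 0.6,
                           model_fraction = 0.10,
                           groups = "A",
                           seed = 1L) {
  stopifnot(n_samples >= 2, n_background >= 0, depth > 0,
            sparsity >= 0, sparsity < 1, leader_boost >= 0,
            base_sd > 0, latent_sd > 0, length(groups) >= 1,
            model_fraction > 0, model_fraction <= 1)
  for (cl in clubs) {
    if (cl$size < 3) stop("club sizes must be >= 3")
    if (cl$rho <= 0 || cl$rho >= 1) stop("intra targets must be in (0, 1)")
  }
  for (rp in rival_pairs) {
    if (length(rp$pair) != 2 || rp$pair[1] == rp$pair[2] ||
        any(rp$pair < 1) || any(rp$pair > length(clubs)))
      stop("rival pair must name two distinct clubs")
    if (rp$rho >= 0 || rp$rho <= -1) stop("inter targets must be in (-1, 0)")
  }
  structure(list(n_samples = n_samples, clubs = clubs,
                 rival_pairs = rival_pairs, leader_boost = leader_boost,
                 n_background = n_background, depth = depth,
                 sparsity = sparsity, base_sd = base_sd,
                 latent_sd = latent_sd, model_fraction = model_fraction,
                 groups = groups, seed = as.integer(seed)),
            class = "community_spec")
}

# loadings for one club: a on the club factor, b on the shared rival factor
# (0 when the club has no rival). Pairwise member correlation = a^2 + b^2.
club_loadings <- function(rho_intra, rho_inter_abs, leader_boost) {
  b <- sqrt(rho_inter_abs)
  a2 <- rho_intra - rho_inter_abs
  if (a2 <= 0)
    stop("infeasible targets: |inter| must be below intra correlation")
  a <- sqrt(a2)
  a_lead <- a + leader_boost
  if (a_lead^2 + b^2 > 1)
    stop("infeasible targets: total squared loading exceeds 1 ",
         "(reduce leader_boost or correlation targets)")
  list(a = a, a_lead = a_lead, b = b)
}

#' Generate a synthetic abundance matrix with planted structure
#'
#' Samples read counts under the model described in [community_spec()].
#' For each sample, every club draws a shared standard-normal factor; a
#' member's latent log10 abundance is its baseline plus
#' `latent_sd * (loading * factor + rival loading * shared factor + noise)`,
#' with loadings chosen so the expected pairwise log-scale correlation hits
#' the club's target and rival pairs hit their (negative) inter target
#' through a shared factor loaded with opposite signs. Latent values are
#' exponentiated to expected proportions, structural zeros are injected,
#' and counts are drawn from a multinomial at the given depth, emulating
#' fixed-depth sequencing.
#'
#' @param spec a [community_spec].
#' @return list with `abundance` (an [abundance_matrix] over all groups)
#'   and `truth` (a `planted_truth`: data frame `otus` with otu_id, club,
#'   is_leader; `rival_pairs` list; `leaders` character per club).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  k <- length(spec$clubs)
  sizes <- vapply(spec$clubs, `[[`, numeric(1), "size")
  n_otus <- sum(sizes) + spec$n_background
  otu_ids <- sprintf("OTU%03d", seq_len(n_otus))
  club_of <- rep(NA_integer_, n_otus)
  off <- 0
  leaders <- character(k)
  for (c in seq_len(k)) {
    club_of[off + seq_len(sizes[c])] <- c
    leaders[c] <- otu_ids[off + 1]        # first member is the leader
    off <- off + sizes[c]
  }

  rival_of <- rep(NA_integer_, k)          # rival-pair index per club
  rival_sign <- rep(0, k)
  for (p in seq_along(spec$rival_pairs)) {
    pr <- spec$rival_pairs[[p]]$pair
    if (any(!is.na(rival_of[pr])))
      stop("a club may belong to at most one rival pair")
    rival_of[pr] <- p
    rival_sign[pr] <- c(1, -1)
  }
  loads <- lapply(seq_len(k), function(c) {
    ria <- if (is.na(rival_of[c])) 0 else abs(spec$rival_pairs[[rival_of[c]]]$rho)
    club_loadings(spec$clubs[[c]]$rho, ria, spec$leader_boost)
  })

  n_total <- spec$n_samples * length(spec$groups)
  counts <- with_local_seed(spec$seed, {
    mu <- stats::rnorm(n_otus, 0, spec$base_sd)   # baseline log10 abundance
    z <- matrix(0, n_total, n_otus)
    fac_club <- matrix(stats::rnorm(n_total * max(k, 1)), n_total)
    fac_riv <- matrix(stats::rnorm(n_total * max(length(spec$rival_pairs), 1)),
                      n_total)
    for (j in seq_len(n_otus)) {
      c <- club_of[j]
      if (is.na(c)) { z[, j] <- stats::rnorm(n_total); next }
      ld <- loads[[c]]
      a <- if (otu_ids[j] == leaders[c]) ld$a_lead else ld$a
      noise_sd <- sqrt(1 - a^2 - ld$b^2)
      z[, j] <- a * fac_club[, c] + noise_sd * stats::rnorm(n_total)
      if (!is.na(rival_of[c]))
        z[, j] <- z[, j] + rival_sign[c] * ld$b * fac_riv[, rival_of[c]]
    }
    lat <- sweep(spec$latent_sd * z, 2, mu, "+")   # log10 latent abundance
    props <- 10^lat
    if (spec$sparsity > 0) {
      zero <- matrix(stats::runif(length(props)) < spec$sparsity,
                     nrow(props))
      props[zero] <- 0
    }
    # the modeled OTUs are a minority of the community: reads are drawn
    # jointly with a stable unmodeled remainder (then discarded), so the
    # per-sample denominator barely fluctuates and log-scale correlation
    # targets are approximately preserved under closure
    remainder <- (1 - spec$model_fraction) / spec$model_fraction *
      mean(rowSums(props))
    draw_depth <- round(spec$depth / spec$model_fraction)
    cnt <- matrix(0L, n_total, n_otus)
    for (s in seq_len(n_total)) {
      ps <- c(props[s, ], remainder)
      if (sum(props[s, ]) == 0) ps[which.max(lat[s, ])] <- remainder / 10
      cnt[s, ] <- as.integer(
        stats::rmultinom(1, draw_depth, ps)[seq_len(n_otus)])
    }
    cnt
  })
  sample_ids <- as.vector(vapply(spec$groups, function(g)
    sprintf("%s_S%03d", g, seq_len(spec$n_samples)),
    character(spec$n_samples)))
  dimnames(counts) <- list(sample_ids, otu_ids)
  groups <- stats::setNames(rep(spec$groups, each = spec$n_samples),
                            sample_ids)
  truth <- structure(
    list(otus = data.frame(otu_id = otu_ids, club = club_of,
                           is_leader = otu_ids %in% leaders,
                           stringsAsFactors = FALSE),
         rival_pairs = lapply(spec$rival_pairs, `[[`, "pair"),
         leaders = leaders),
    class = "planted_truth")
  list(abundance = abundance_matrix(counts, groups), truth = truth)
}

#' Write generator output in the pipeline's input dialect
#'
#' @param sim result of [generate_community()].
#' @param dir output directory (created if needed).
#' @return paths of `abundance.tsv`, `metadata.tsv`, `truth.tsv`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("abundance.tsv", "metadata.tsv", "truth.tsv"))
  write_abundance_table(sim$abundance, paths[1], paths[2])
  utils::write.table(sim$truth$otus, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
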
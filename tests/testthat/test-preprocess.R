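# 10-sample matrix with OTUs engineered on the filter boundary:
# totals {99, 100} x prevalence {10%, 20%}
boundary_matrix <- function() {
  counts <- matrix(0L, nrow = 10, ncol = 4,
                   dimnames = list(paste0("S", 1:10),
                                   c("t99p10", "t99p20", "t100p10", "t100p20")))
  counts[1, "t99p10"] <- 99
  counts[1:2, "t99p20"] <- c(98, 1)
  counts[1, "t100p10"] <- 100
  counts[1:2, "t100p20"] <- c(99, 1)
  abundance_matrix(counts, setNames(rep("g", 10), paste0("S", 1:10)))
}

test_that("filter keeps exactly total >= 100 AND prevalence >= 20%", {
  f <- filter_otus(boundary_matrix())
  expect_identical(f$otu_ids, "t100p20")
  log <- attr(f, "discarded")
  expect_setequal(log$otu_id, c("t99p10", "t99p20", "t100p10"))
  expect_match(log$reason[log$otu_id == "t99p20"], "low_reads")
  expect_match(log$reason[log$otu_id == "t100p10"], "low_prevalence")
  expect_match(log$reason[log$otu_id == "t99p10"], "low_reads;low_prevalence")
})

test_that("filter decisions are per-OTU predicates: order and sample permutation irrelevant", {
  set.seed(11)
  counts <- matrix(rpois(200, 30) * rbinom(200, 1, 0.5), nrow = 10,
                   dimnames = list(paste0("S", 1:10), paste0("O", 1:20)))
  m <- abundance_matrix(counts, setNames(rep("g", 10), paste0("S", 1:10)))
  both <- filter_otus(m)
  # read-count filter then prevalence filter == joint filter
  only_reads <- filter_otus(m, min_reads = 100, min_prevalence = 0)
  seq_filtered <- filter_otus(only_reads, min_reads = 0, min_prevalence = 0.2)
  expect_identical(seq_filtered$otu_ids, both$otu_ids)
  perm <- sample(10)
  mp <- abundance_matrix(counts[perm, , drop = FALSE], m$groups)
  expect_identical(filter_otus(mp)$otu_ids, both$otu_ids)
})

test_that("normalization gives relative abundances then log10 with pseudocount", {
  counts <- matrix(c(2L, 3L, 5L,
                     4L, 6L, 10L,
                     1L, 0L, 9L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("S", 1:3), c("a", "b", "c")))
  m <- abundance_matrix(counts)
  nm <- normalize_and_log(m, pseudocount = 1e-6)
  expect_equal(unname(10^nm$values[1, ]), c(0.2, 0.3, 0.5))
  # proportional samples give identical rows
  expect_equal(nm$values[1, ], nm$values[2, ])
  # zero count -> log10(pseudocount)
  expect_equal(unname(nm$values[3, "b"]), -6)
  # rows sum to 1 before pseudocount substitution
  expect_equal(unname(rowSums(m$counts / rowSums(m$counts))), rep(1, 3))
})

test_that("auto pseudocount is half the smallest nonzero relative abundance", {
  counts <- matrix(c(1L, 99L, 0L, 50L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("a", "b")))
  nm <- normalize_and_log(abundance_matrix(counts))
  expect_equal(nm$pseudocount, (1 / 100) / 2)
})

test_that("all-zero samples are rejected by name", {
  counts <- matrix(c(1L, 2L, 0L, 0L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("a", "b")))
  expect_error(normalize_and_log(abundance_matrix(counts)), "S2")
})

test_that("differential abundance matches the Welch formula and maps to heat", {
  mk <- function(vals, ids) {
    structure(list(values = matrix(vals, ncol = 1,
                                   dimnames = list(ids, "O1")),
                   sample_ids = ids, otu_ids = "O1", groups = NULL,
                   pseudocount = 1e-6), class = "normalized_matrix")
  }
  a <- mk(c(1, 2, 3), paste0("A", 1:3))
  b <- mk(c(2, 3, 4), paste0("B", 1:3))
  da <- differential_abundance(a, b)
  expect_equal(da$p, welch_p_oracle(c(1, 2, 3), c(2, 3, 4)), tolerance = 1e-12)
  expect_equal(da$heat, 1 - da$p)

  # identical values: no difference, heat 0
  same <- differential_abundance(mk(c(1, 1, 2), paste0("A", 1:3)),
                                 mk(c(1, 1, 2), paste0("B", 1:3)))
  expect_equal(same$p, 1)
  expect_equal(same$heat, 0)

  # extreme separation with tiny jitter: p near 0, heat near 1
  set.seed(1)
  far <- differential_abundance(mk(1 + rnorm(4, 0, 1e-4), paste0("A", 1:4)),
                                mk(5 + rnorm(4, 0, 1e-4), paste0("B", 1:4)))
  expect_lt(far$p, 1e-6)
  expect_gt(far$heat, 1 - 1e-6)
})

test_that("differential abundance validates its inputs", {
  counts <- toy_counts()
  nm <- normalize_and_log(abundance_matrix(counts))
  nm2 <- nm
  nm2$otu_ids <- rev(nm2$otu_ids)
  expect_error(differential_abundance(nm, nm2), "OTU sets differ")
})

test_that("p-values are invariant to sample order", {
  set.seed(2)
  counts <- matrix(rpois(60, 50), nrow = 6,
                   dimnames = list(paste0("S", 1:6), paste0("O", 1:10)))
  a <- normalize_and_log(abundance_matrix(counts[1:3, ]))
  b <- normalize_and_log(abundance_matrix(counts[4:6, ]))
  b_perm <- normalize_and_log(abundance_matrix(counts[c(6, 4, 5), ]))
  expect_equal(differential_abundance(a, b)$p,
               differential_abundance(a, b_perm)$p)
})
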
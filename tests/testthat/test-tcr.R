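# Repertoire metrics: downsampling, diversity, clonality, edit distances,
# similarity networks.

clone_tbl <- function(seqs, counts) {
  tibble::tibble(cdr3_aa = seqs, count = counts)
}

test_that("amino-acid-identical clones are merged before any metric", {
  rep <- clone_tbl(c("CASSLGF", "CASSLGF", "CASSQEF"), c(3, 2, 5))
  merged <- merge_clones(rep)
  expect_identical(nrow(merged), 2L)
  expect_identical(sum(merged$count), 10)
  expect_equal(tcr_shannon(rep),
               -sum(c(0.5, 0.5) * log(c(0.5, 0.5))))
})

test_that("downsampling conserves totals, is seeded, and refuses upsampling", {
  withr::with_seed(3, {
    rep <- clone_tbl(replicate(40, paste(sample(LETTERS, 10, TRUE),
                                         collapse = "")),
                     sample(1:500, 40))
  })
  total <- sum(rep$count)
  expect_identical(tcr_downsample(rep, total, seed = 1),
                   merge_clones(rep))
  down <- tcr_downsample(rep, 1000, seed = 9)
  expect_identical(sum(down$count), 1000L)
  expect_true(all(down$count >= 1))
  expect_identical(down, tcr_downsample(rep, 1000, seed = 9))
  expect_false(identical(down, tcr_downsample(rep, 1000, seed = 10)))
  expect_error(tcr_downsample(rep, total + 1, seed = 1), "upsampling")
  expect_error(tcr_downsample(rep, 10), "seed")
})

test_that("downsampling preserves expected clone frequencies", {
  withr::with_seed(4, {
    rep <- clone_tbl(replicate(20, paste(sample(LETTERS, 12, TRUE),
                                         collapse = "")),
                     sample(50:2000, 20))
  })
  total <- sum(rep$count)
  n <- floor(total / 2)
  p0 <- rep$count / total
  freq_sum <- rep(0, nrow(rep))
  n_rep <- 100
  for (k in seq_len(n_rep)) {
    down <- tcr_downsample(rep, n, seed = 1000 + k)
    m <- merge_clones(rep) # canonical order used by downsample
    f <- down$count[match(m$cdr3_aa, down$cdr3_aa)]
    f[is.na(f)] <- 0
    freq_sum <- freq_sum + f[match(rep$cdr3_aa, m$cdr3_aa)] / n
  }
  mean_freq <- freq_sum / n_rep
  # hypergeometric standard error of the replicate-averaged frequency; the
  # bound is joint over all 20 clones, so allow 4 SE per clone
  se <- sqrt(p0 * (1 - p0) / n * (total - n) / (total - 1) / n_rep)
  expect_true(all(abs(mean_freq - p0) < pmax(4 * se, 1e-4)))
})

test_that("Shannon diversity closed forms", {
  expect_equal(tcr_shannon(clone_tbl(c("A", "B", "C", "D"), rep(5, 4))),
               log(4))
  expect_identical(tcr_shannon(clone_tbl("CASSF", 100)), 0)
  h <- tcr_shannon(clone_tbl(c("A", "B", "C"), c(2, 1, 1)))
  expect_lt(abs(h - 1.0397), 1e-4)
  expect_equal(h, -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("diversity is invariant to clone order and uniform count scaling", {
  rep <- clone_tbl(c("AA", "BB", "CC", "DD"), c(8, 4, 2, 1))
  expect_equal(tcr_shannon(rep), tcr_shannon(rep[4:1, ]))
  scaled <- rep
  scaled$count <- scaled$count * 17
  expect_equal(tcr_shannon(rep), tcr_shannon(scaled))
})

test_that("clonality closed forms and limits", {
  expect_equal(tcr_clonality(clone_tbl(c("A", "B", "C", "D"), rep(3, 4))), 0)
  expect_identical(tcr_clonality(clone_tbl("CASSF", 10)), 1)
  mix <- clone_tbl(c("A", "B", "C"), c(2, 1, 1))
  expect_equal(tcr_clonality(mix), 1 - tcr_shannon(mix) / log(3))
  expect_lt(abs(tcr_clonality(mix) - 0.0536), 1e-4)
})

test_that("clonality change is antisymmetric and checks patient identity", {
  base <- clone_tbl(c("A", "B", "C"), c(1, 1, 1))
  post <- clone_tbl(c("A", "B", "C"), c(8, 1, 1))
  d <- tcr_clonality_delta(base, post)
  expect_gt(d, 0) # dominance emerged on treatment
  expect_equal(tcr_clonality_delta(post, base), -d)
  expect_identical(tcr_clonality_delta(base, base), 0)
  b2 <- dplyr::mutate(base, patient_id = "P1")
  p2 <- dplyr::mutate(post, patient_id = "P2")
  expect_error(tcr_clonality_delta(b2, p2), "different patients")
})

test_that("edit-distance summary over top clones matches hand values", {
  rep <- clone_tbl(c("CASS", "CASSLG", "CASSLA"), c(5, 4, 3))
  ed <- tcr_edit_distance(rep)
  expect_equal(sort(ed$matrix[upper.tri(ed$matrix)]), c(1, 2, 2))
  expect_equal(ed$mean, 5 / 3, tolerance = 1e-12)
  expect_equal(ed$median, 2)
  two <- tcr_edit_distance(clone_tbl(c("CASSLG", "CASSLA"), c(2, 1)))
  expect_equal(two$mean, 1)
  expect_error(tcr_edit_distance(clone_tbl("CASSLG", 5)), "2 clone")
})

test_that("top-N selection breaks count ties lexicographically", {
  rep <- clone_tbl(c("CCCC", "AAAA", "BBBB", "DDDD"), c(5, 3, 3, 1))
  ed <- tcr_edit_distance(rep, top_n = 3)
  expect_identical(rownames(ed$matrix), c("CCCC", "AAAA", "BBBB"))
})

test_that("Levenshtein distances equal the DP oracle on random pairs", {
  withr::with_seed(31, {
    for (k in 1:100) {
      a <- paste(sample(c("A", "C", "S", "L", "G"), sample(1:12, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "S", "L", "G"), sample(1:12, 1), TRUE),
                 collapse = "")
      if (a == b) next
      ed <- tcr_edit_distance(clone_tbl(c(a, b), c(2, 1)))
      expect_equal(unname(ed$matrix[a, b]), levenshtein_oracle(a, b),
                   ignore_attr = TRUE)
    }
  })
})

test_that("edit-distance matrices satisfy the triangle inequality", {
  withr::with_seed(32, {
    seqs <- unique(replicate(12, paste(sample(c("C", "A", "S", "L", "G", "F"),
                                              sample(6:14, 1), TRUE),
                                       collapse = "")))
  })
  ed <- tcr_edit_distance(clone_tbl(seqs, seq_along(seqs)),
                          top_n = length(seqs))
  d <- ed$matrix
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("similarity network links equal-length sequences within 3 substitutions", {
  rep <- clone_tbl(c("CASSL", "CASTL", "CASS", "CASSLG", "WWWWL"),
                   c(5, 4, 3, 2, 1))
  net <- tcr_similarity_network(rep)
  has_edge <- function(a, b) {
    any((net$cdr3_a == a & net$cdr3_b == b) |
          (net$cdr3_a == b & net$cdr3_b == a))
  }
  expect_true(has_edge("CASSL", "CASTL"))   # 1 substitution
  expect_false(has_edge("CASS", "CASSLG"))  # unequal length
  expect_false(has_edge("CASSL", "WWWWL"))  # 4 substitutions
  expect_true(all(net$distance <= 3))
  expect_true(all(net$cdr3_a != net$cdr3_b))
  wide <- tcr_similarity_network(rep, max_subs = 4)
  expect_true(any((wide$cdr3_a == "CASSL" & wide$cdr3_b == "WWWWL") |
                    (wide$cdr3_a == "WWWWL" & wide$cdr3_b == "CASSL")))
})

test_that("metric panel combines diversity, clonality and clone count", {
  m <- tcr_metrics(clone_tbl(c("A", "B", "C", "D"), rep(2, 4)))
  expect_identical(m$n_clones, 4L)
  expect_identical(m$total_reads, 8)
  expect_equal(m$shannon, log(4))
  expect_equal(m$clonality, 0)
})
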
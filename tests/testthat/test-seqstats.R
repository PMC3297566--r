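test_that("paralog grouping weights members by inverse group size", {
  two <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  w <- group_paralogs(two)
  expect_equal(w$group, c(1L, 1L))
  expect_equal(w$weight, c(0.5, 0.5))
  # a planted group of 5 near-identical paralogs contributes 1/5 each
  base <- "ACDEFGHIKLMNPQRSTVWY"
  five <- purrr::map_chr(1:5, function(i) {
    s <- strsplit(base, "")[[1]]
    s[i] <- "A"  # one substitution each: pairwise identity >= 18/20
    paste0(s, collapse = "")
  })
  seqs <- c(setNames(five, paste0("p", 1:5)),
            lone = "YWVTSRQPNMLKIHGFEDCA")
  w5 <- group_paralogs(seqs)
  expect_equal(w5$weight[w5$id %in% paste0("p", 1:5)], rep(0.2, 5))
  expect_equal(w5$weight[w5$id == "lone"], 1)
})

test_that("grouping is single-linkage over the identity graph", {
  # A-B 60%, B-C 60%, A-C 40%: one group of 3 under single linkage
  a <- "AAAAAAAAAA"
  b <- "AAAAAACCCC"  # 6/10 vs a
  c_ <- "CCCCCCCCAA"  # b vs c_: positions 7-8 C==C ... construct carefully
  # identities: a-b = 6, b-c: compare AAAAAACCCC vs CCCCCCCCAA -> matches at
  # positions 7,8 (C) = 2 -> too low; build explicit triplet instead
  a <- "AAAAAAAAAA"
  b <- "AAAAAABBBB"           # a-b: 6/10
  c_ <- "CCCCAABBBB"          # b-c: positions 5,6 A + 7-10 B = 6/10; a-c: 2/10
  id <- pairwise_identity(c(a = a, b = b, c = c_))
  expect_equal(id["a", "b"], 0.6)
  expect_equal(id["b", "c"], 0.6)
  expect_equal(id["a", "c"], 0.2)
  w <- group_paralogs(c(a = a, b = b, c = c_), identity_cutoff = 0.5)
  expect_equal(length(unique(w$group)), 1)
  expect_equal(w$weight, rep(1 / 3, 3))
  # complete linkage splits the chain
  wc <- group_paralogs(c(a = a, b = b, c = c_), identity_cutoff = 0.5,
                       linkage = "complete")
  expect_gt(length(unique(wc$group)), 1)
})

test_that("gap handling: identity ignores gap columns, zero overlap warns", {
  id <- pairwise_identity(c(x = "AC-G", y = "ACTG"))
  expect_equal(id["x", "y"], 1)
  expect_warning(pairwise_identity(c(x = "AA--", y = "--CC")), "overlap")
})

test_that("weighted frequencies follow the inverse-group-size rule", {
  seqs <- c(s1 = "D", s2 = "A")
  w <- group_paralogs(seqs)
  expect_equal(weighted_frequency(w, 1, c("D", "E")), 0.5)
  allD <- group_paralogs(c(s1 = "D", s2 = "D", s3 = "D"))
  expect_equal(weighted_frequency(allD, 1, c("D", "E")), 1.0)
  # a 5-paralog D group and 5 singleton A's: weighted D freq = 1/6, raw 1/2
  base <- strrep("M", 19)
  grp <- setNames(rep(paste0("D", base), 5), paste0("g", 1:5))
  singles <- setNames(paste0("A", vapply(1:5, function(i) {
    paste0(sample(c("F", "W", "Y", "H", "R", "K", "N", "Q", "S", "T",
                    "C", "G", "I", "L", "V", "P", "M", "E", "A"),
                  19, replace = TRUE), collapse = "")
  }, "")), paste0("s", 1:5))
  set.seed(51)
  wmsa <- group_paralogs(c(grp, singles))
  expect_equal(weighted_frequency(wmsa, 1, "D"), 1 / 6)
  expect_error(weighted_frequency(wmsa, 999, "D"), "out of range")
})

test_that("weighted frequencies over the 20 residues sum to 1 per column", {
  msa <- gen_msa(msa_generator_spec(n_groups = 8, seed = 52))
  wmsa <- group_paralogs(msa$sequences)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (col in c(1, 25, 90)) {
    total <- sum(vapply(aa, function(r) weighted_frequency(wmsa, col, r), 0))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("merging groups can only decrease member weights", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAABBBB", c = "CCCCAABBBB")
  w_hi <- group_paralogs(seqs, identity_cutoff = 0.65)  # no links
  w_lo <- group_paralogs(seqs, identity_cutoff = 0.5)   # one big group
  expect_true(all(w_lo$weight <= w_hi$weight + 1e-12))
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  # all class residues in the loop, margins (10, 10): one 20-column sequence
  seqs <- c(only = paste0(strrep("D", 10), strrep("G", 10)))
  wmsa <- group_paralogs(seqs)
  enr <- loop_enrichment(wmsa, 1:10)
  expect_equal(unname(enr$table[1, ]), c(10L, 0L))
  expect_equal(enr$p_value, hyper_tail(10, 10, 10, 10), tolerance = 1e-12)
  expect_equal(enr$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  # balanced table: no enrichment signal; p carries the point mass of the
  # observed table and matches enumeration exactly
  seqs2 <- c(s = paste0("DDDDDGGGGG", "DDDDDGGGGG"))
  enr2 <- loop_enrichment(group_paralogs(seqs2), 1:10)
  expect_equal(enr2$p_value, hyper_tail(5, 10, 10, 10), tolerance = 1e-12)
  expect_gt(enr2$p_value, 0.5)
})

test_that("Fisher P matches enumeration for every table with margins up to 30", {
  worst <- 0
  n_tables <- 0L
  for (n in 2:30) {
    for (r1 in 1:(n - 1)) {
      r2 <- n - r1
      for (c1 in 1:(n - 1)) {
        for (a in max(0, c1 - r2):min(r1, c1)) {
          tab <- matrix(c(a, r1 - a, c1 - a, r2 - (c1 - a)), 2,
                        byrow = TRUE)
          p_fisher <- stats::fisher.test(tab,
                                         alternative = "greater")$p.value
          worst <- max(worst, abs(p_fisher - hyper_tail(a, r1, r2, c1)))
          n_tables <- n_tables + 1L
        }
      }
    }
  }
  expect_gt(n_tables, 40000)
  expect_lt(worst, 1e-9)
})

test_that("planted loop enrichment is detected on synthetic alignments", {
  msa <- gen_msa(msa_generator_spec(
    n_groups = 50, group_sizes = 2, loop_enrichment_factor = 2, seed = 53))
  expect_equal(length(msa$sequences), 100)
  wmsa <- group_paralogs(msa$sequences)
  enr <- loop_enrichment(wmsa, msa$loop_columns)
  expect_lt(enr$p_value, 0.01)
  expect_gt(enr$freq_loop_weighted, enr$freq_overall_weighted)
})

test_that("degenerate enrichment tables are rejected", {
  wmsa <- group_paralogs(c(s = "DDDDDDDDDD"))
  expect_error(loop_enrichment(wmsa, 1:5), "empty margin")
  expect_error(loop_enrichment(wmsa, 1:10), "proper")
})

test_that("propensity profiles zero-pad truncated proteins and weight paralogs", {
  seqs <- c(d1 = "IMMM", d2 = "AMMM", d3 = "IMMM")
  wmsa <- group_paralogs(seqs, identity_cutoff = 0.9)
  # flat 0.6 for d1 over all 20 positions -> constant profile
  flat <- tibble::tibble(domain_id = "d1", position = 1:20,
                         propensity = 0.6)
  # d2 ends exactly at the domain C-terminus: zero everywhere
  ends <- tibble::tibble(domain_id = "d2", position = 1L, propensity = 0)
  prof <- propensity_profile(dplyr::bind_rows(flat, ends), wmsa,
                             class_column = 1) |>
    suppressWarnings()  # d3 missing from the tables
  ilv <- prof[prof$class == "ILV", ]
  ala <- prof[prof$class == "ALA", ]
  expect_equal(ilv$mean_propensity, rep(0.6, 20))
  expect_equal(ala$mean_propensity, rep(0, 20))
  expect_warning(
    propensity_profile(dplyr::bind_rows(flat, ends), wmsa, 1), "d3")
  # truncation after position 8: zeros from position 9 on
  part <- tibble::tibble(domain_id = "d1", position = 1:8, propensity = 0.5)
  prof2 <- suppressWarnings(
    propensity_profile(dplyr::bind_rows(part, ends), wmsa, 1))
  ilv2 <- prof2[prof2$class == "ILV", ]
  expect_equal(ilv2$mean_propensity, c(rep(0.5, 8), rep(0, 12)))
})

test_that("planted class contrast is recovered with paralog weighting", {
  msa <- gen_msa(msa_generator_spec(n_groups = 60, group_sizes = 1,
                                    seed = 54))
  wmsa <- group_paralogs(msa$sequences)
  # plant the class column deterministically: half I, half A
  m <- do.call(rbind, strsplit(unname(msa$sequences), ""))
  m[, 10] <- rep(c("I", "A"), length.out = nrow(m))
  seqs <- setNames(apply(m, 1, paste0, collapse = ""), names(msa$sequences))
  wmsa <- group_paralogs(seqs)
  tabs <- gen_propensity_tables(
    setNames(ifelse(m[, 10] == "I", "ILV", "ALA"), names(seqs)),
    class_means = c(ILV = 0.5, ALA = 0.25), noise_sd = 0.05, seed = 55)
  prof <- propensity_profile(tabs, wmsa, class_column = 10)
  m_ilv <- mean(prof$mean_propensity[prof$class == "ILV"])
  m_ala <- mean(prof$mean_propensity[prof$class == "ALA"])
  # 3 SE of the ratio via the per-class SEs (n = 30 domains, sd = 0.05)
  se_ratio <- 2 * 0.05 / sqrt(30) / 0.25
  expect_lt(abs(m_ilv / m_ala - 2), 3 * se_ratio)
})

test_that("group-level permutation p-values behave at the null and under effects", {
  # identical values in both classes: p = 1 at any permutation count
  ids <- paste0("d", 1:20)
  wmsa <- singleton_wmsa(ids)
  vals <- setNames(rep(0.4, 20), ids)
  labs <- setNames(rep(c(TRUE, FALSE), 10), ids)
  res <- reshuffle_pvalue(vals, wmsa, labs, n_perm = 199, seed = 61)
  expect_equal(res$p_value, 1)
  # a planted strong effect is significant
  vals2 <- setNames(c(rep(0.8, 10), rep(0.2, 10)), ids)
  labs2 <- setNames(rep(c(TRUE, FALSE), each = 10), ids)
  res2 <- reshuffle_pvalue(vals2, wmsa, labs2, n_perm = 999, seed = 62)
  expect_lte(res2$p_value, 0.01)
  expect_gt(res2$p_value, 0)
  expect_error(reshuffle_pvalue(vals2, wmsa, setNames(rep(TRUE, 20), ids),
                                n_perm = 999), "non-empty")
  expect_error(reshuffle_pvalue(vals2, wmsa, labs2, n_perm = 10), "100")
})

test_that("permutation shuffling respects paralog groups", {
  # two groups of 5 with opposite labels and values: group-level shuffling
  # can only produce the observed statistic or its negative, so p is 0.5-ish
  ids <- paste0("d", 1:10)
  wmsa <- singleton_wmsa(ids)
  wmsa$group <- rep(1:2, each = 5)
  wmsa$weight <- 0.2
  vals <- setNames(c(rep(0.9, 5), rep(0.1, 5)), ids)
  labs <- setNames(rep(c(TRUE, FALSE), each = 5), ids)
  res <- reshuffle_pvalue(vals, wmsa, labs, n_perm = 500, seed = 63)
  expect_gt(res$p_value, 0.2)  # only two distinguishable label patterns
  res_member <- reshuffle_pvalue(vals, wmsa, labs, n_perm = 500, seed = 63,
                                 unit = "member")
  expect_lt(res_member$p_value, 0.05)
})

test_that("family summary reports weighted frequencies and enrichment", {
  msa <- gen_msa(msa_generator_spec(n_groups = 30, group_sizes = c(1, 5),
                                    loop_enrichment_factor = 2, seed = 56))
  out <- pdz_family_summary(msa$sequences, msa$loop_columns,
                            hydrophobic_column = 50)
  expect_true(out$de_freq_loop > out$de_freq_overall)
  expect_true(out$fisher_p > 0 && out$fisher_p <= 1)
  expect_true(out$hydrophobic_freq >= 0 && out$hydrophobic_freq <= 1)
})
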
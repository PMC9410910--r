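fake_summary <- function(genome, variants, base_counts, nt = sum(base_counts)) {
  structure(list(sample_id = "s", variants = variants,
                 error_corrected_nt = nt, base_counts = base_counts,
                 context_counts = NULL, depth = NULL, n_offtarget = 0L),
            class = "sample_summary")
}

test_that("overall frequency is unique variants over error-corrected nt", {
  g <- mito_genome(rand_dna(300, seed = 71))
  v5 <- data.frame(position = c(10L, 20L, 30L, 40L, 50L),
                   ref = g$bases[c(11, 21, 31, 41, 51)], alt = "N")
  v5$alt <- vapply(v5$ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  s <- fake_summary(g, v5, c(A = 2.5e6, C = 2.5e6, G = 2.5e6, T = 2.5e6))
  expect_equal(overall_frequency(s), 5e-7)
  s0 <- fake_summary(g, v5[0, ], c(A = 2.5e6, C = 2.5e6, G = 2.5e6, T = 2.5e6))
  expect_equal(overall_frequency(s0), 0)
  s_bad <- fake_summary(g, v5, c(A = 0, C = 0, G = 0, T = 0))
  expect_error(overall_frequency(s_bad), "zero")
})

test_that("class frequencies pool complements over matched denominators", {
  g <- mito_genome(rand_dna(300, seed = 72))
  # 3 C>A plus 1 G>T among 2e6 C + 2e6 G sequenced -> C:G->A:T = 1e-6
  cpos <- which(g$bases == "C")[1:3] - 1L
  gpos <- which(g$bases == "G")[1] - 1L
  v <- data.frame(position = c(cpos, gpos),
                  ref = c(rep("C", 3), "G"), alt = c(rep("A", 3), "T"))
  s <- fake_summary(g, v, c(A = 1e6, C = 2e6, G = 2e6, T = 1e6))
  sp <- class_frequencies(s)
  expect_equal(sp$class_counts[["C>A"]], 4L)
  expect_equal(sp$class_frequencies[["C>A"]], 1e-6)
  expect_equal(sum(sp$class_counts), nrow(v))
  # strand counts collapse pairwise onto the pooled classes
  collapsed <- sp$strand_counts[c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")] +
    sp$strand_counts[c("G>T", "G>C", "G>A", "A>T", "A>G", "A>C")]
  expect_equal(unname(collapsed), unname(sp$class_counts))
  # doubling depth with the same counts halves every frequency
  s2 <- fake_summary(g, v, 2 * c(A = 1e6, C = 2e6, G = 2e6, T = 1e6))
  expect_equal(class_frequencies(s2)$class_frequencies,
               sp$class_frequencies / 2)
  # all-zero counts -> all-zero frequencies
  expect_true(all(class_frequencies(fake_summary(g, v[0, ],
    c(A = 1e6, C = 2e6, G = 2e6, T = 1e6)))$class_frequencies == 0))
})

test_that("overall frequency recombines from class counts algebraically", {
  g <- generate_synthetic_genome(4000, seed = 73)
  for (s in 1:5) {
    tr <- simulate_lineage(g, flat_rate_model(8e-5),
                           population_params(generations = 20), seed = 700 + s)
    if (!nrow(tr$variants)) next
    sm <- summary_from_truth(tr, g, depth = 100)
    sp <- class_frequencies(sm)
    expect_equal(sum(sp$class_counts) / sm$error_corrected_nt,
                 overall_frequency(sm))
  }
})

test_that("strand asymmetry uses the exact two-sided binomial", {
  g <- mito_genome(rand_dna(500, seed = 74))
  mkv <- function(cls, n) {
    ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
    pos <- which(g$bases == ref)[seq_len(n)] - 1L
    data.frame(position = pos, ref = ref, alt = alt)
  }
  bc <- c(A = 1e5, C = 1e5, G = 1e5, T = 1e5)
  # (10, 10) -> p = 1
  s <- fake_summary(g, rbind(mkv("C>T", 10), mkv("G>A", 10)), bc)
  res <- strand_asymmetry(s)
  expect_equal(res$p[res$pair == "C>T vs G>A"], 1)
  # empty pairs are skipped with a note
  expect_equal(res$note[res$pair == "T>A vs A>T"], "no observations")
  expect_true(is.na(res$p[res$pair == "T>A vs A>T"]))
  # (15, 5) matches the direct summation oracle
  s2 <- fake_summary(g, rbind(mkv("C>T", 15), mkv("G>A", 5)), bc)
  res2 <- strand_asymmetry(s2)
  expect_equal(res2$p[res2$pair == "C>T vs G>A"],
               oracle_binom_two_sided(15, 20), tolerance = 1e-12)
  # Bonferroni never decreases p
  expect_true(all(res2$p_adj >= res2$p - 1e-15, na.rm = TRUE))
})

test_that("trinucleotide signatures count, normalize and compare correctly", {
  # single C>T in a C_T flanking context -> exactly one nonzero raw entry
  g <- toy_genome("AGCCT")  # position 3 is C flanked by C and T
  s <- fake_summary(g, data.frame(position = 3L, ref = "C", alt = "T"),
                    c(A = 10, C = 10, G = 10, T = 10))
  sig <- trinuc_signature(s, g, mode = "raw")
  expect_equal(sum(sig$contributions), 1)
  expect_equal(unname(sig$contributions["C[C>T]T"]), 1)

  # raw signatures sum to the classified variant count on simulated truth
  g2 <- generate_synthetic_genome(4000, seed = 75)
  tr <- simulate_lineage(g2, flat_rate_model(1e-4),
                         population_params(generations = 20), seed = 76)
  sm <- summary_from_truth(tr, g2, depth = 50)
  expect_equal(sum(trinuc_signature(sm, g2, mode = "raw")$contributions),
               nrow(sm$variants))

  # relative mode: zeros in the baseline propagate as NA, not imputed
  base <- rep(2, 96); base[5] <- 0
  rel <- trinuc_signature(s, g, mode = "relative", baseline = base)
  expect_true(is.na(rel$contributions[5]))
  expect_equal(unname(rel$contributions["C[C>T]T"]), 0.5)
})

test_that("cosine similarity handles identity, disjointness and NA exclusion", {
  a <- c(1, 1, rep(0, 94)); b <- c(1, 0, 1, rep(0, 93))
  expect_equal(cosine_similarity(a, a), 1, ignore_attr = TRUE)
  expect_equal(cosine_similarity(c(1, 0, rep(0, 94)), c(0, 1, rep(0, 94))), 0,
               ignore_attr = TRUE)
  expect_equal(cosine_similarity(a, b), 0.5, ignore_attr = TRUE)
  expect_error(cosine_similarity(a, rep(0, 96)), "zero vector")
  # NA entries excluded pairwise with reported effective dimension
  b_na <- b; b_na[4] <- NA
  cs <- cosine_similarity(a, b_na)
  expect_equal(attr(cs, "effective_dim"), 95)
})

test_that("a C>A-dominated rate model yields a C:G->A:T-dominated spectrum", {
  g <- generate_synthetic_genome(8000, gc_fraction = 0.3, seed = 77)
  rmod <- rate_model(c("C>A" = 3e-4, "G>T" = 3e-4,
                       "C>T" = 2e-5, "G>A" = 2e-5,
                       "T>C" = 2e-5, "A>G" = 2e-5,
                       "C>G" = 1e-5, "G>C" = 1e-5))
  pop <- population_params(copy_number = 30, generations = 25)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    vars <- list()
    for (k in 1:6) {
      tr <- simulate_lineage(g, rmod, pop, seed = 9000 + 10 * r + k)
      vars[[k]] <- tr$variants
    }
    v <- do.call(rbind, vars)
    expect_gte(nrow(v), 300)
    cls <- collapse6 <- table(factor(ifelse(v$ref %in% c("C", "T"),
                                            paste0(v$ref, ">", v$alt),
                                            paste0(c(A = "T", C = "G", G = "C",
                                                     T = "A")[v$ref], ">",
                                                   c(A = "T", C = "G", G = "C",
                                                     T = "A")[v$alt])),
                                     levels = c("C>A", "C>G", "C>T",
                                                "T>A", "T>C", "T>G")))
    if (names(which.max(cls)) == "C>A") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("a 5x context multiplier is recovered from occurrence-normalized rates", {
  g <- generate_synthetic_genome(8000, gc_fraction = 0.3, seed = 78)
  boosted <- "A[C>T]A"
  rmod <- rate_model(c("C>T" = 6e-5, "G>A" = 6e-5),
                     context_multiplier = setNames(5, boosted))
  pop <- population_params(copy_number = 30, generations = 25)
  counts <- numeric(96); names(counts) <- trinuc_channels()
  for (k in 1:40) {
    tr <- simulate_lineage(g, rmod, pop, seed = 8100 + k)
    if (!nrow(tr$variants)) next
    sm <- summary_from_truth(tr, g, depth = 10)
    counts <- counts + trinuc_signature(sm, g, mode = "raw")$contributions
  }
  occ <- context_occurrences(g)
  ct_chans <- grep("\\[C>T\\]", trinuc_channels(), value = TRUE)
  rate_of <- function(ch) {
    ctx <- paste0(substr(ch, 1, 1), "C", substr(ch, 7, 7))
    counts[ch] / as.numeric(occ[ctx])
  }
  r_boost <- rate_of(boosted)
  others <- setdiff(ct_chans, boosted)
  r_others <- mean(vapply(others, rate_of, numeric(1)))
  expect_gt(counts[boosted], 30)
  ratio <- r_boost / r_others
  # Poisson error on the boosted count dominates
  tol <- 3 / sqrt(counts[boosted])
  expect_lt(abs(log(ratio / 5)), 3 * tol)
})
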
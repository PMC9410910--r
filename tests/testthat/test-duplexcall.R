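mk_reads <- function(seqs, strands, umi_a = "AAAAA", umi_b = "CCCCC",
                     start = 0L, mol = "m1") {
  data.table::data.table(
    molecule_id = mol, umi_a = umi_a, umi_b = umi_b, strand = strands,
    start = start, len = nchar(seqs[1]), sequence = seqs,
    read_id = sprintf("%s.%d", mol, seq_along(seqs))
  )
}

test_that("family grouping keys on canonical UMI pair plus fragment coords", {
  r <- mk_reads(rep("ACGTACGT", 6), rep(c("ab", "ba"), each = 3))
  g <- group_families(r)
  expect_equal(length(unique(g$family_key)), 1L)
  expect_equal(as.vector(table(g$cstrand)), c(3L, 3L))

  # same UMI pair, different fragment start -> distinct keys
  r2 <- rbind(r, mk_reads(rep("ACGTACGT", 2), c("ab", "ba"), start = 10L))
  expect_equal(length(unique(group_families(r2)$family_key)), 2L)

  # swapped UMI pair with flipped strand labels collapses onto the same
  # canonical key and strand assignment
  ra <- mk_reads(rep("ACGTACGT", 2), c("ab", "ab"),
                 umi_a = "AAAAA", umi_b = "CCCCC")
  rb <- mk_reads(rep("ACGTACGT", 2), c("ba", "ba"),
                 umi_a = "CCCCC", umi_b = "AAAAA")
  gg <- group_families(rbind(ra, rb))
  expect_equal(length(unique(gg$family_key)), 1L)
  expect_true(all(gg$cstrand == "ab"))
})

test_that("SSCS applies the minimum-family-size and 70% consensus rules", {
  # a minimum of three reads is required
  expect_null(call_sscs(rep("ACGT", 2)))
  expect_false(is.null(call_sscs(rep("ACGT", 3))))

  base <- strrep("A", 20)
  alt_at5 <- paste0(strrep("A", 4), "T", strrep("A", 15))
  # 6/10 = 60% < 70% -> masked
  s <- call_sscs(c(rep(alt_at5, 6), rep(base, 4)))
  expect_equal(rawToChar(s$seq[5]), "N")
  # 7/10 = 70% -> called (inclusive threshold)
  s2 <- call_sscs(c(rep(alt_at5, 7), rep(base, 3)))
  expect_equal(rawToChar(s2$seq[5]), "T")
  expect_error(call_sscs(c("ACGT", "ACGTA", "ACGT")), "length-discordant")
})

test_that("DCS requires duplex agreement and masks the clipped ends", {
  base <- strrep("A", 40)
  one_err <- paste0(strrep("A", 19), "G", strrep("A", 20))
  sa <- call_sscs(rep(one_err, 5))   # e.g. a PCR error at 100% of one strand
  sb <- call_sscs(rep(base, 5))
  d <- call_dcs(sa, sb, clip = 12, start = 0L, len = 40L)
  expect_equal(rawToChar(d$seq[20]), "N")  # strand-confined -> never an alt
  # true variant present in both strand families survives
  d2 <- call_dcs(call_sscs(rep(one_err, 5)), call_sscs(rep(one_err, 5)),
                 clip = 12, start = 0L, len = 40L)
  expect_equal(rawToChar(d2$seq[20]), "G")
  # clip masks both ends
  expect_true(all(rawToChar(d2$seq[1:12], multiple = TRUE) == "N"))
  expect_true(all(rawToChar(d2$seq[29:40], multiple = TRUE) == "N"))
  expect_error(call_dcs(call_sscs(rep(base, 3)), call_sscs(rep("AAA", 3))),
               "mismatch")
})

test_that("variant calling deduplicates, clips and accounts denominators", {
  g <- mito_genome(rand_dna(300, seed = 61))
  ref <- substr(g$sequence, 1, 60)
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 30, 30))[1]
  mut <- ref
  substr(mut, 30, 30) <- alt
  mk_dcs <- function(seqstr, start = 0L) {
    sa <- call_sscs(rep(seqstr, 3)); call_dcs(sa, sa, clip = 12,
                                              start = start, len = nchar(seqstr))
  }
  # two DCS carrying the same alt at position 29 (0-based) -> one variant,
  # support 2
  s <- call_variants(list(mk_dcs(mut), mk_dcs(mut), mk_dcs(ref)), g)
  expect_equal(nrow(s$variants), 1L)
  expect_equal(s$variants$position, 29L)
  expect_equal(s$variants$alt, alt)
  expect_equal(s$variants$dcs_support, 2L)
  expect_equal(s$variants$duplex_depth, 3L)

  # a variant 5 bp from the fragment end is clipped away
  mut_end <- ref
  alt_end <- setdiff(c("A", "C", "G", "T"), substr(ref, 56, 56))[1]
  substr(mut_end, 56, 56) <- alt_end
  s2 <- call_variants(list(mk_dcs(mut_end)), g)
  expect_equal(nrow(s2$variants), 0L)

  # zero-error library: no variants, error_corrected_nt equals summed depth
  ref100 <- substr(g$sequence, 101, 160)
  s3 <- call_variants(list(mk_dcs(ref), mk_dcs(ref100, start = 100L)), g)
  expect_equal(nrow(s3$variants), 0L)
  expect_equal(s3$error_corrected_nt, sum(s3$depth))
  expect_equal(s3$error_corrected_nt, 2 * (60 - 24))
})

test_that("per-base sequenced counts conserve the error-corrected total", {
  g <- mito_genome(rand_dna(1500, seed = 62))
  sim <- simulate_reads(g, make_truth(g, data.frame()), error_model(),
                        n_molecules = 150, seed = 8,
                        fragment_len_dist = function(n) rep(120L, n))
  s <- call_sample(sim$reads, g)
  expect_equal(sum(s$base_counts), s$error_corrected_nt)
  expect_equal(sum(s$context_counts), s$error_corrected_nt)
  expect_equal(s$error_corrected_nt, sum(s$depth))
})

test_that("pipeline SSCS/DCS match the brute-force oracle byte-for-byte", {
  g <- mito_genome(rand_dna(800, seed = 63))
  em <- error_model(seq_error_rate = 0.01, pcr_error_rate = 0.002,
                    end_artifact_rate = 0.01)
  sim <- simulate_reads(g, make_truth(g, data.frame()), em,
                        n_molecules = 25, seed = 9,
                        fragment_len_dist = function(n) rep(60L, n))
  gr <- group_families(sim$reads)
  fams <- split(seq_len(nrow(gr)), gr$family_key)
  expect_lte(length(fams), 50)
  n_dcs <- 0L
  for (fam in fams) {
    ab <- fam[gr$cstrand[fam] == "ab"]
    ba <- fam[gr$cstrand[fam] == "ba"]
    sa <- call_sscs(gr$sequence[ab])
    sb <- call_sscs(gr$sequence[ba])
    oa <- oracle_sscs(gr$sequence[ab])
    ob <- oracle_sscs(gr$sequence[ba])
    expect_identical(is.null(sa), is.null(oa))
    expect_identical(is.null(sb), is.null(ob))
    if (is.null(sa) || is.null(sb)) next
    expect_identical(rawToChar(sa$seq), oa)
    expect_identical(rawToChar(sb$seq), ob)
    d <- call_dcs(sa, sb, clip = 12, start = gr$start[fam[1]],
                  len = gr$len[fam[1]])
    expect_identical(rawToChar(d$seq), oracle_dcs(oa, ob, clip = 12))
    n_dcs <- n_dcs + 1L
  }
  expect_gt(n_dcs, 5)
})

test_that("an injected variant is recovered at its heteroplasmy", {
  g <- mito_genome(rand_dna(400, seed = 64))
  h <- 0.2
  alt <- setdiff(c("A", "C", "G", "T"), g$bases[201])[1]
  truth <- make_truth(g, data.frame(position = 200L, alt = alt,
                                    heteroplasmy = h))
  sim <- simulate_reads(g, truth, error_model(), n_molecules = 400,
                        seed = 10,
                        fragment_len_dist = function(n) rep(400L, n))
  s <- call_sample(sim$reads, g)
  v <- s$variants[s$variants$position == 200L & s$variants$alt == alt, ]
  expect_equal(nrow(v), 1L)
  ci <- stats::binom.test(v$dcs_support, v$duplex_depth,
                          conf.level = 0.99)$conf.int
  expect_gte(h, ci[1])
  expect_lte(h, ci[2])
})

test_that("fixed polymorphisms are removed only when fixed in all samples", {
  g <- mito_genome(rand_dna(300, seed = 65))
  mk_sum <- function(vars, id) {
    structure(list(sample_id = id, variants = vars,
                   error_corrected_nt = 1e4,
                   base_counts = c(A = 2500, C = 2500, G = 2500, T = 2500),
                   context_counts = NULL, depth = NULL, n_offtarget = 0L),
              class = "sample_summary")
  }
  vfix <- data.frame(position = 10L, ref = "A", alt = "G",
                     dcs_support = 100L, duplex_depth = 100L)
  vlow <- data.frame(position = 10L, ref = "A", alt = "G",
                     dcs_support = 5L, duplex_depth = 100L)
  vother <- data.frame(position = 20L, ref = "C", alt = "T",
                       dcs_support = 3L, duplex_depth = 80L)

  # fixed everywhere -> removed everywhere
  out <- filter_fixed_polymorphisms(list(mk_sum(rbind(vfix, vother), "s1"),
                                         mk_sum(vfix, "s2")))
  expect_equal(out$fixed$position, 10L)
  expect_equal(out$summaries[[1]]$variants$position, 20L)
  expect_equal(nrow(out$summaries[[2]]$variants), 0L)

  # fixed in one sample only -> retained
  out2 <- filter_fixed_polymorphisms(list(mk_sum(vfix, "s1"),
                                          mk_sum(vlow, "s2")))
  expect_equal(nrow(out2$fixed), 0L)
  expect_equal(nrow(out2$summaries[[1]]$variants), 1L)

  # no shared variants -> identity
  out3 <- filter_fixed_polymorphisms(list(mk_sum(vfix, "s1"),
                                          mk_sum(vother, "s2")))
  expect_equal(nrow(out3$fixed), 0L)

  expect_warning(filter_fixed_polymorphisms(list(mk_sum(vfix, "s1"))),
                 ">= 2 samples")
})

test_that("VCF output is 1-based with DCS support and depth", {
  g <- mito_genome(rand_dna(300, seed = 66))
  s <- structure(list(
    sample_id = "s", variants = data.frame(
      position = 29L, ref = g$bases[30], alt = setdiff(c("A", "C", "G", "T"),
                                                       g$bases[30])[1],
      dcs_support = 2L, duplex_depth = 7L),
    error_corrected_nt = 100), class = "sample_summary")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(s, g, vcf)
  body <- grep("^[^#]", readLines(vcf), value = TRUE)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(as.integer(f[2]), 30L)
  expect_equal(f[8], "DCS_SUPPORT=2;DEPTH=7")
})

test_that("the naive mapper places error-free reads at their origin", {
  g <- mito_genome(rand_dna(600, seed = 67))
  sim <- simulate_reads(g, make_truth(g, data.frame()),
                        error_model(seq_error_rate = 0, pcr_error_rate = 0,
                                    end_artifact_rate = 0),
                        n_molecules = 10, seed = 11,
                        fragment_len_dist = function(n) rep(100L, n))
  got <- map_reads_naive(sim$reads$sequence[1:10], g)
  expect_equal(got, sim$reads$start[1:10])
})
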
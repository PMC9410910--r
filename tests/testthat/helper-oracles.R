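# Independent long-hand oracles. These deliberately avoid the package's
# code paths (and Biostrings): the genetic code is hand-assembled from the
# standard code string plus the four documented invertebrate-mitochondrial
# differences; consensus, Welch, binomial and Fisher oracles are direct
# enumerations.

# Standard genetic code in TCAG codon order, then table-5 differences:
# TGA=Trp, AGA=Ser, AGG=Ser, ATA=Met.
oracle_table5 <- function() {
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  code <- setNames(aa, codons)
  code["TGA"] <- "W"; code["AGA"] <- "S"; code["AGG"] <- "S"; code["ATA"] <- "M"
  code
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# classify one substitution on a single-gene toy genome by direct codon walk
oracle_classify <- function(seqstr, gene_start, gene_end, strand, pos, alt) {
  code <- oracle_table5()
  ch <- strsplit(seqstr, "")[[1]]
  if (pos < gene_start || pos >= gene_end) return("noncoding")
  if (strand == "+") {
    cds <- paste(ch[(gene_start + 1):gene_end], collapse = "")
    k <- pos - gene_start
  } else {
    cds <- oracle_revcomp(paste(ch[(gene_start + 1):gene_end], collapse = ""))
    k <- (gene_end - 1) - pos
    alt <- c(A = "T", C = "G", G = "C", T = "A")[alt]
  }
  ci <- k %/% 3
  codon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
  if (nchar(codon) < 3) return("noncoding")
  new <- codon
  substr(new, k %% 3 + 1, k %% 3 + 1) <- unname(alt)
  a0 <- code[codon]; a1 <- code[new]
  if (a0 == a1) "synonymous" else if (a1 == "*") "nonsense" else "nonsynonymous"
}

# naive per-position consensus by character tabulation
oracle_sscs <- function(seqs, min_reads = 3, frac = 0.70) {
  if (length(seqs) < min_reads) return(NULL)
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) >= frac - 1e-12) names(tab)[1] else "N"
  })
  paste(cons, collapse = "")
}

oracle_dcs <- function(sa, sb, clip = 12) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  out <- ifelse(a == b & a != "N", a, "N")
  n <- length(out)
  out[seq_len(min(clip, n))] <- "N"
  out[seq.int(max(1, n - clip + 1), n)] <- "N"
  paste(out, collapse = "")
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# two-sided exact binomial p at p0 = 1/2 by direct summation (minlike rule)
oracle_binom_two_sided <- function(x, n) {
  probs <- choose(n, 0:n) * 0.5^n
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# 2x2 Fisher exact two-sided p by hypergeometric enumeration with choose()
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  pr <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# toy single-gene genome builder used across test files
toy_genome <- function(seqstr, gene_start = NULL, gene_end = NULL,
                       strand = "+", target = NULL) {
  ann <- NULL
  if (!is.null(gene_start)) {
    ann <- data.frame(name = "toy", start = gene_start, end = gene_end,
                      strand = strand, frame_offset = 0L, genetic_code_id = 5L)
  }
  mito_genome(seqstr, annotations = ann, target_region = target)
}

# deterministic random DNA string for fixtures
rand_dna <- function(n, seed, gc = 0.4) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
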
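## Duplex consensus formation and ultra-rare variant calling.
##
## The error-correction ladder: reads -> per-strand-family consensus (SSCS;
## needs >= min_reads reads and a >= consensus_frac within-family majority
## per position, else N) -> duplex consensus (DCS; base emitted only where
## the two SSCS agree and neither is N; the first and last `clip` bp of the
## fragment are always masked) -> unique variant calls with duplex-depth
## denominators.

#' Group reads into duplex families
#'
#' The family key is (canonical UMI pair, fragment start, fragment length);
#' the two strand families of one molecule share a key with opposite strand
#' labels. Canonicalization orders the UMI pair lexicographically and flips
#' the strand label when the pair is swapped, so (a,b,ab) and (b,a,ba)
#' collapse to one key. Including fragment coordinates in the key prevents
#' UMI collisions across loci.
#'
#' @param reads reads data.table (from [simulate_reads()] or
#'   [read_fastq()]).
#' @return the reads table with `family_key` and canonical `cstrand`
#'   columns added (a copy; the input is not modified).
#' @export
group_families <- function(reads) {
  r <- data.table::copy(reads)
  swap <- r$umi_a > r$umi_b
  ua <- ifelse(swap, r$umi_b, r$umi_a)
  ub <- ifelse(swap, r$umi_a, r$umi_b)
  r[, cstrand := ifelse(swap, ifelse(strand == "ab", "ba", "ab"), strand)]
  r[, family_key := paste(ua, ub, start, len, sep = "|")]
  r
}

#' Single-strand consensus of one strand family
#'
#' @param seqs character vector of same-length read sequences from one
#'   strand family.
#' @param min_reads minimum reads to emit an SSCS (default 3).
#' @param consensus_frac within-family fraction a base needs to be called,
#'   inclusive (default 0.70); positions below threshold are masked N.
#' @return list with `seq` (raw vector, N-masked) and `n_reads`, or `NULL`
#'   if the family is rejected.
#' @export
call_sscs <- function(seqs, min_reads = 3L, consensus_frac = 0.70) {
  n <- length(seqs)
  if (n < min_reads) return(NULL)
  l <- nchar(seqs[1])
  if (any(nchar(seqs) != l)) stop("length-discordant reads within a family")
  m <- matrix(charToRaw(paste0(seqs, collapse = "")), nrow = l)
  cons <- m[, 1]
  ## count >= frac * n, inclusive at the boundary (tolerant of fp rounding)
  need <- ceiling(consensus_frac * n - 1e-9)
  if (n > 1L) {
    disc <- which(rowSums(m != cons) > 0L)
    for (i in disc) {
      tab <- table(as.integer(m[i, ]))
      top <- which.max(tab)
      cons[i] <- if (tab[top] >= need) as.raw(as.integer(names(tab)[top])) else RAW_N
    }
  } else if (need > 1L) {
    cons[] <- RAW_N
  }
  list(seq = cons, n_reads = n)
}

#' Duplex consensus of a molecule's two strand consensi
#'
#' @param sscs_a,sscs_b SSCS lists from [call_sscs()]; both must be present
#'   and derived from the same fragment coordinates.
#' @param clip bp masked at each fragment end (default 12).
#' @param start,len fragment coordinates carried onto the result.
#' @return list with `start`, `len`, `seq` (raw, N-masked), `n_reads_a`,
#'   `n_reads_b`.
#' @export
call_dcs <- function(sscs_a, sscs_b, clip = 12L, start = NA_integer_,
                     len = NA_integer_) {
  a <- sscs_a$seq; b <- sscs_b$seq
  if (length(a) != length(b)) stop("SSCS coordinate/length mismatch")
  out <- a
  out[a != b | a == RAW_N | b == RAW_N] <- RAW_N
  l <- length(out)
  clip <- min(clip, l)
  if (clip > 0L) {
    out[seq_len(clip)] <- RAW_N
    out[(l - clip + 1L):l] <- RAW_N
  }
  list(start = start, len = l, seq = out,
       n_reads_a = sscs_a$n_reads, n_reads_b = sscs_b$n_reads)
}

#' Form duplex consensus sequences for every family in a read set
#'
#' @param reads reads data.table.
#' @param min_reads,consensus_frac,clip filter parameters (defaults 3,
#'   0.70, 12 — the standard Duplex-Seq settings).
#' @return list with `dcs` (list of DCS objects), and counts:
#'   `n_families`, `n_sscs_rejected`, `n_single_strand` (families missing a
#'   usable mate SSCS).
#' @export
duplex_consensus <- function(reads, min_reads = 3L, consensus_frac = 0.70,
                             clip = 12L) {
  g <- group_families(reads)
  idx <- split(seq_len(nrow(g)), g$family_key)
  dcs <- vector("list", length(idx))
  n_dcs <- 0L; n_rej <- 0L; n_single <- 0L
  strands <- g$cstrand; seqs <- g$sequence
  starts <- g$start; lens <- g$len
  for (fam in idx) {
    ab <- fam[strands[fam] == "ab"]
    ba <- fam[strands[fam] == "ba"]
    sa <- if (length(ab)) call_sscs(seqs[ab], min_reads, consensus_frac) else NULL
    sb <- if (length(ba)) call_sscs(seqs[ba], min_reads, consensus_frac) else NULL
    if (is.null(sa) || is.null(sb)) {
      if (is.null(sa) != is.null(sb)) n_single <- n_single + 1L
      if (length(ab) && is.null(sa)) n_rej <- n_rej + 1L
      if (length(ba) && is.null(sb)) n_rej <- n_rej + 1L
      next
    }
    n_dcs <- n_dcs + 1L
    dcs[[n_dcs]] <- call_dcs(sa, sb, clip = clip,
                             start = starts[fam[1]], len = lens[fam[1]])
  }
  list(dcs = dcs[seq_len(n_dcs)], n_families = length(idx),
       n_sscs_rejected = n_rej, n_single_strand = n_single)
}

#' Call unique single-nucleotide variants from duplex consensus sequences
#'
#' Every unmasked DCS base differing from the reference yields an
#' observation; observations are deduplicated to unique (position, alt)
#' pairs per sample (set `strict_per_position = TRUE` for the stricter
#' once-per-position reading). Duplex depth and the per-reference-base /
#' per-context sequencing denominators accumulate over unmasked positions
#' of on-target DCS only; DCS touching any non-targeted position are
#' dropped and counted.
#'
#' @param dcs_set list of DCS objects (from [duplex_consensus()]).
#' @param genome a `mito_genome`.
#' @param sample_id sample identifier.
#' @param strict_per_position collapse multi-allelic sites to one variant
#'   (highest support wins; default FALSE).
#' @return object of class `sample_summary`: `variants` data.frame
#'   (`position` 0-based, `ref`, `alt`, `dcs_support`, `duplex_depth`),
#'   `error_corrected_nt`, `base_counts` (sequenced A/C/G/T),
#'   `context_counts` (sequenced pyrimidine-centered 3-mers), `depth`
#'   (per-position unmasked duplex depth), `n_offtarget`.
#' @export
call_variants <- function(dcs_set, genome, sample_id = "sample1",
                          strict_per_position = FALSE) {
  L <- genome$length
  mask2 <- c(genome$target_mask, genome$target_mask)
  cs <- c(0L, cumsum(mask2))
  depth_diff <- numeric(L + 1L)
  obs_pos <- integer(0); obs_alt <- character(0)
  refraw2 <- charToRaw(paste0(genome$sequence, genome$sequence))
  n_off <- 0L
  for (d in dcs_set) {
    s <- d$start; l <- d$len
    if (cs[s + l + 1L] - cs[s + 1L] < l) { n_off <- n_off + 1L; next }
    unm <- which(d$seq != RAW_N)
    if (!length(unm)) next
    mism <- unm[d$seq[unm] != refraw2[s + unm]]
    if (length(mism)) {
      obs_pos <- c(obs_pos, (s + mism - 1L) %% L)
      obs_alt <- c(obs_alt, rawToChar(d$seq[mism], multiple = TRUE))
    }
    ## depth: contiguous unmasked run is [clip, len-clip); interior Ns are
    ## rare, subtract them individually
    lo <- unm[1]; hi <- unm[length(unm)]
    a <- (s + lo - 1L) %% L; b <- (s + hi - 1L) %% L
    if (a <= b) {
      depth_diff[a + 1L] <- depth_diff[a + 1L] + 1
      depth_diff[b + 2L] <- depth_diff[b + 2L] - 1
    } else { # run crosses the origin
      depth_diff[a + 1L] <- depth_diff[a + 1L] + 1
      depth_diff[L + 1L] <- depth_diff[L + 1L] - 1
      depth_diff[1L] <- depth_diff[1L] + 1
      depth_diff[b + 2L] <- depth_diff[b + 2L] - 1
    }
    inner_n <- setdiff(seq.int(lo, hi), unm)
    for (i in inner_n) {
      p <- (s + i - 1L) %% L
      depth_diff[p + 1L] <- depth_diff[p + 1L] - 1
      depth_diff[p + 2L] <- depth_diff[p + 2L] + 1
    }
  }
  depth <- as.integer(cumsum(depth_diff[seq_len(L)]))
  if (length(obs_pos)) {
    dt <- data.table::data.table(position = obs_pos, alt = obs_alt)
    agg <- dt[, list(dcs_support = .N), by = c("position", "alt")]
    variants <- data.frame(
      position = agg$position,
      ref = genome$bases[agg$position + 1L],
      alt = agg$alt,
      dcs_support = agg$dcs_support,
      duplex_depth = depth[agg$position + 1L],
      stringsAsFactors = FALSE
    )
    if (strict_per_position && anyDuplicated(variants$position)) {
      variants <- variants[order(variants$position, -variants$dcs_support), ]
      variants <- variants[!duplicated(variants$position), ]
    }
    variants <- variants[order(variants$position, variants$alt), ]
    rownames(variants) <- NULL
  } else {
    variants <- data.frame(position = integer(0), ref = character(0),
                           alt = character(0), dcs_support = integer(0),
                           duplex_depth = integer(0), stringsAsFactors = FALSE)
  }
  base_counts <- vapply(BASES, function(b) sum(depth[genome$bases == b]),
                        numeric(1))
  ctx <- genome$ctx32
  okc <- !is.na(ctx) & depth > 0L
  context_counts <- tapply(depth[okc], ctx[okc], sum)
  context_counts <- context_counts[!is.na(context_counts)]
  structure(list(sample_id = sample_id, variants = variants,
                 error_corrected_nt = sum(as.numeric(depth)),
                 base_counts = base_counts,
                 context_counts = as.numeric(context_counts) |>
                   setNames(names(context_counts)),
                 depth = depth, n_offtarget = n_off),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary '%s'> %d unique variants over %.3g error-corrected nt\n",
              x$sample_id, nrow(x$variants), x$error_corrected_nt))
  invisible(x)
}

#' Run reads -> consensus -> variants in one call
#'
#' @param reads reads data.table.
#' @param genome a `mito_genome`.
#' @param sample_id sample identifier.
#' @param min_reads,consensus_frac,clip consensus parameters.
#' @return a `sample_summary` with consensus counters attached as
#'   attribute `"consensus_stats"`.
#' @export
call_sample <- function(reads, genome, sample_id = "sample1",
                        min_reads = 3L, consensus_frac = 0.70, clip = 12L) {
  cons <- duplex_consensus(reads, min_reads = min_reads,
                           consensus_frac = consensus_frac, clip = clip)
  s <- call_variants(cons$dcs, genome, sample_id = sample_id)
  attr(s, "consensus_stats") <- cons[c("n_families", "n_sscs_rejected",
                                       "n_single_strand")]
  s
}

#' Remove polymorphisms fixed in every sample
#'
#' Variants present at per-sample allele fraction >= `af` in ALL samples
#' are removed from every sample and returned separately (the strain-level
#' fixed differences from the reference that are not de novo mutations).
#'
#' @param summaries list of `sample_summary` objects (>= 2; a single
#'   sample triggers a warning and no filtering).
#' @param af allele-fraction threshold (default 0.99).
#' @return list with `summaries` (filtered) and `fixed` (data.frame of
#'   removed position/alt pairs).
#' @export
filter_fixed_polymorphisms <- function(summaries, af = 0.99) {
  no_fixed <- data.frame(position = integer(0), alt = character(0))
  if (length(summaries) < 2L) {
    warning("fixed-polymorphism filtering needs >= 2 samples; input unchanged")
    return(list(summaries = summaries, fixed = no_fixed))
  }
  keysets <- lapply(summaries, function(s) {
    v <- s$variants
    frac <- ifelse(v$duplex_depth > 0, v$dcs_support / v$duplex_depth, 0)
    paste(v$position, v$alt)[frac >= af]
  })
  shared <- Reduce(intersect, keysets)
  if (!length(shared)) return(list(summaries = summaries, fixed = no_fixed))
  out <- lapply(summaries, function(s) {
    v <- s$variants
    keep <- !(paste(v$position, v$alt) %in% shared)
    s$variants <- v[keep, , drop = FALSE]
    rownames(s$variants) <- NULL
    s
  })
  parts <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  list(summaries = out,
       fixed = data.frame(position = as.integer(parts[, 1]), alt = parts[, 2]))
}

#' Write sample variants as minimal VCF 4.2 (1-based positions)
#' @param summary a `sample_summary`.
#' @param genome a `mito_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(summary, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$name, genome$length),
    "##INFO=<ID=DCS_SUPPORT,Number=1,Type=Integer,Description=\"Supporting duplex consensus sequences\">",
    "##INFO=<ID=DEPTH,Number=1,Type=Integer,Description=\"Duplex depth at position\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  v <- summary$variants
  if (nrow(v)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDCS_SUPPORT=%d;DEPTH=%d",
                       genome$name, v$position + 1L, v$ref, v$alt,
                       v$dcs_support, v$duplex_depth), con)
  }
  invisible(path)
}

#' Serialize a sample summary (denominators included) as JSON
#' @param summary a `sample_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  v <- summary$variants
  obj <- list(
    sample_id = summary$sample_id,
    n_unique_variants = nrow(v),
    error_corrected_nt = summary$error_corrected_nt,
    base_counts = as.list(summary$base_counts),
    context_counts = as.list(summary$context_counts),
    variants = v
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Naive circular-aware ungapped mapper for external FASTQ
#'
#' Exact 31-mer seed from the read start, looked up in a reference index,
#' then ungapped extension (best diagonal by mismatch count). Intended only
#' to place externally produced reads; simulated reads carry their origin
#' coordinates and bypass mapping.
#'
#' @param seqs character vector of read sequences.
#' @param genome a `mito_genome`.
#' @param k seed length (default 31).
#' @param max_mismatch_frac maximum mismatch fraction to accept (default
#'   0.1).
#' @return integer vector of 0-based start positions (NA = unmapped).
#' @export
map_reads_naive <- function(seqs, genome, k = 31L, max_mismatch_frac = 0.1) {
  L <- genome$length
  ref2 <- paste0(genome$sequence, genome$sequence)
  starts <- substring(ref2, seq_len(L), seq_len(L) + k - 1L)
  index <- split(seq_len(L) - 1L, starts)
  vapply(seqs, function(s) {
    if (nchar(s) < k || nchar(s) > L) return(NA_integer_)
    hits <- index[[substr(s, 1L, k)]]
    if (is.null(hits)) return(NA_integer_)
    best <- NA_integer_; bestmm <- Inf
    sraw <- charToRaw(s)
    r2raw <- charToRaw(ref2)
    for (h in hits) {
      mm <- sum(sraw != r2raw[(h + 1L):(h + length(sraw))])
      if (mm < bestmm) { bestmm <- mm; best <- h }
    }
    if (bestmm <= max_mismatch_frac * nchar(s)) best else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}
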
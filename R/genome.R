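## Circular mitochondrial reference genome: sequence, CDS annotations under
## the invertebrate mitochondrial genetic code, and the capture target mask.
## All coordinates are 0-based half-open internally; exporters convert to
## 1-based where the file format demands it.

genetic_code_5 <- function() Biostrings::getGeneticCode("5")

#' Normalize (possibly origin-wrapping) intervals on a circular genome
#'
#' An interval with `start >= end` is taken to wrap the origin and is split
#' into two non-wrapping pieces. Overlapping pieces are merged.
#'
#' @param intervals data.frame with 0-based half-open `start`, `end`.
#' @param length genome length in bp.
#' @return data.frame of disjoint, sorted, non-wrapping intervals.
#' @export
normalize_intervals <- function(intervals, length) {
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (any(intervals$start < 0 | intervals$end > length)) {
    stop("interval endpoints must lie in [0, genome length]")
  }
  pieces <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (s < e) {
      pieces[[length(pieces) + 1L]] <- c(s, e)
    } else { # wraps the origin
      if (e > 0) pieces[[length(pieces) + 1L]] <- c(0, e)
      if (s < length) pieces[[length(pieces) + 1L]] <- c(s, length)
    }
  }
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) {
      out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
    } else out[[length(out) + 1L]] <- m[i, ]
  }
  m <- do.call(rbind, out)
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Construct a MitoGenome object
#'
#' @param sequence single uppercase DNA string over ACGTN; treated as
#'   circular.
#' @param annotations data.frame of CDS annotations with columns
#'   `name`, `start`, `end` (0-based half-open, non-wrapping), `strand`
#'   (`"+"`/`"-"`), `frame_offset` (0/1/2) and `genetic_code_id` (5 for
#'   everything bundled here). May be empty.
#' @param target_region data.frame of 0-based half-open intervals included
#'   in the capture panel; wrapping intervals are split at the origin.
#'   Defaults to the whole genome minus any N runs.
#' @param name genome name used in output files.
#' @return object of class `mito_genome`.
#' @export
mito_genome <- function(sequence, annotations = NULL, target_region = NULL,
                        name = "mtDNA") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("empty genome sequence")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c(BASES, "N"))) stop("sequence must be over ACGTN")
  if (is.null(annotations)) {
    annotations <- data.frame(
      name = character(0), start = integer(0), end = integer(0),
      strand = character(0), frame_offset = integer(0),
      genetic_code_id = integer(0)
    )
  }
  if (nrow(annotations)) {
    with_ann <- annotations
    if (any(with_ann$start < 0 | with_ann$end > L | with_ann$start >= with_ann$end)) {
      stop("gene annotations must be non-wrapping and within the genome")
    }
    if (!all(with_ann$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  }
  n_pos <- which(bases == "N") - 1L
  if (is.null(target_region)) {
    target_region <- data.frame(start = 0L, end = L)
  }
  target_region <- normalize_intervals(target_region, L)
  ## N bases are never targeted
  mask <- rep(FALSE, L)
  for (i in seq_len(nrow(target_region))) {
    mask[(target_region$start[i] + 1L):target_region$end[i]] <- TRUE
  }
  if (length(n_pos)) mask[n_pos + 1L] <- FALSE
  g <- structure(list(
    sequence = sequence,
    length = L,
    bases = bases,
    annotations = annotations,
    target_region = mask_to_intervals(mask),
    target_mask = mask,
    name = name
  ), class = "mito_genome")
  g$gene_index <- gene_index_vector(g)
  ctx <- all_contexts(g)
  g$ctx32 <- ctx$ctx
  g$ctx_flip <- ctx$flip
  cod <- codon_cache(g)
  g$cod_b1 <- cod$b1; g$cod_b2 <- cod$b2; g$cod_b3 <- cod$b3
  g$cod_off <- cod$off; g$cod_strand <- cod$strand
  g
}

## Per-position codon lookup over complete codons: codon bases in coding
## orientation, the position's offset within its codon, and gene strand.
## Built gene-by-gene in reverse file order so the first annotation wins.
codon_cache <- function(genome) {
  L <- genome$length
  b1 <- b2 <- b3 <- strand <- rep(NA_character_, L)
  off <- rep(NA_integer_, L)
  ann <- genome$annotations
  for (i in rev(seq_len(nrow(ann)))) {
    fr <- ann$frame_offset[i]
    ncod <- (ann$end[i] - ann$start[i] - fr) %/% 3L
    if (ncod < 1L) next
    if (ann$strand[i] == "+") {
      p0 <- ann$start[i] + fr + 3L * (seq_len(ncod) - 1L)
      pos <- c(p0, p0 + 1L, p0 + 2L)
      offs <- rep(0:2, each = ncod)
      c1 <- genome$bases[p0 + 1L]
      c2 <- genome$bases[p0 + 2L]
      c3 <- genome$bases[p0 + 3L]
    } else {
      p0 <- ann$end[i] - 1L - fr - 3L * (seq_len(ncod) - 1L)
      pos <- c(p0, p0 - 1L, p0 - 2L)
      offs <- rep(0:2, each = ncod)
      c1 <- unname(COMP[genome$bases[p0 + 1L]])
      c2 <- unname(COMP[genome$bases[p0]])
      c3 <- unname(COMP[genome$bases[p0 - 1L]])
    }
    b1[pos + 1L] <- rep(c1, 3L)
    b2[pos + 1L] <- rep(c2, 3L)
    b3[pos + 1L] <- rep(c3, 3L)
    off[pos + 1L] <- offs
    strand[pos + 1L] <- ann$strand[i]
  }
  list(b1 = b1, b2 = b2, b3 = b3, off = off, strand = strand)
}

mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = as.integer(starts[r$values]),
             end = as.integer(ends[r$values]))
}

## First annotation (file order) covering each position; NA = noncoding.
gene_index_vector <- function(genome) {
  idx <- rep(NA_integer_, genome$length)
  ann <- genome$annotations
  for (i in rev(seq_len(nrow(ann)))) {
    span <- (ann$start[i] + 1L):ann$end[i]
    if (i < nrow(ann) && any(!is.na(idx[span]))) {
      warning(sprintf("overlapping gene annotations at '%s'; first in file order wins",
                      ann$name[i]))
    }
    idx[span] <- i
  }
  idx
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome '%s'> %d bp circular, %d CDS, %d bp targeted\n",
              x$name, x$length, nrow(x$annotations), sum(x$target_mask)))
  invisible(x)
}

#' Number of targeted positions
#' @param genome a `mito_genome`.
#' @return integer count of targeted bp.
#' @export
targeted_length <- function(genome) sum(genome$target_mask)

#' Load a circular mitochondrial genome from single-record FASTA
#'
#' @param path FASTA file with exactly one record over ACGTN (case folded
#'   to upper). N bases are recorded and excluded from the target region.
#' @param annotations,target_region as in [mito_genome()].
#' @return a `mito_genome`.
#' @export
load_fasta <- function(path, annotations = NULL, target_region = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop(sprintf("expected a single-record FASTA, found %d records", length(ss)))
  }
  seqstr <- toupper(as.character(ss[[1]]))
  if (nchar(seqstr) == 0L) stop("empty sequence in FASTA")
  mito_genome(seqstr, annotations = annotations, target_region = target_region,
              name = sub("\\s.*$", "", names(ss)[1]))
}

#' Write a genome to FASTA
#' @param genome a `mito_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read CDS annotations from BED6+1 (7th column = frame offset)
#'
#' Standard BED: 0-based half-open, columns chrom/start/end/name/score/strand
#' plus a 7th frame-offset column.
#' @param path BED file path.
#' @return annotation data.frame suitable for [mito_genome()].
#' @export
load_annotations_bed <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(b) < 7L) stop("annotation BED needs 7 columns (BED6 + frame)")
  data.frame(name = as.character(b[[4]]), start = as.integer(b[[2]]),
             end = as.integer(b[[3]]), strand = as.character(b[[6]]),
             frame_offset = as.integer(b[[7]]),
             genetic_code_id = 5L)
}

#' Read a target region from BED3
#' @param path BED file path (0-based half-open).
#' @return data.frame of intervals.
#' @export
load_targets_bed <- function(path) {
  b <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(start = as.integer(b[[2]]), end = as.integer(b[[3]]))
}

#' Generate a synthetic circular mitochondrial genome
#'
#' Emulates the organisation of an animal mtDNA: a compact, AT-rich circular
#' molecule tiled by protein-coding genes (invertebrate mitochondrial code)
#' plus one non-coding AT-rich interval that the capture panel excludes.
#'
#' @param length genome size in bp (>= 300).
#' @param gc_fraction target GC content in (0,1); *C. elegans* mtDNA is
#'   about 0.24.
#' @param n_genes number of CDS annotations to tile (0 allowed; dN/dS is
#'   then undefined downstream).
#' @param seed RNG seed; output is deterministic for a fixed seed.
#' @param at_rich_width width of the excluded non-coding region (default
#'   500 bp, commensurate with the *C. elegans* AT-rich region).
#' @param coding_fraction fraction of the genome the genes must tile
#'   (default 0.8).
#' @param minus_strand_fraction fraction of genes annotated on the minus
#'   strand (default 0.25).
#' @return a `mito_genome` whose target region excludes the AT-rich
#'   interval.
#' @export
generate_synthetic_genome <- function(length, gc_fraction = 0.24, n_genes = 12,
                                      seed = 1L, at_rich_width = 500L,
                                      coding_fraction = 0.8,
                                      minus_strand_fraction = 0.25) {
  if (length < 300) stop("length must be >= 300")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0,1)")
  at_rich_width <- min(at_rich_width, length %/% 10L)
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(BASES, length, replace = TRUE, prob = p)
    ## AT-rich excluded region at the far end of the circle
    at_start <- length - at_rich_width
    if (at_rich_width > 0) {
      bases[(at_start + 1L):length] <-
        sample(c("A", "T"), at_rich_width, replace = TRUE)
    }
    ann <- NULL
    if (n_genes > 0) {
      avail <- at_start
      need <- ceiling(coding_fraction * length)
      glen <- (need %/% n_genes %/% 3L + 1L) * 3L
      gap <- max(0L, (avail - glen * n_genes) %/% n_genes)
      if (glen * n_genes > avail) {
        stop("infeasible gene tiling: coding_fraction too large for this length")
      }
      starts <- as.integer((glen + gap) * (seq_len(n_genes) - 1L))
      strands <- ifelse(runif(n_genes) < minus_strand_fraction, "-", "+")
      ann <- data.frame(
        name = sprintf("CDS%02d", seq_len(n_genes)),
        start = starts, end = starts + glen,
        strand = strands, frame_offset = 0L, genetic_code_id = 5L
      )
    }
    target <- data.frame(start = 0L, end = at_start)
    mito_genome(paste0(bases, collapse = ""), annotations = ann,
                target_region = target,
                name = sprintf("synthetic_mtDNA_%dbp", length))
  })
}

## ---- trinucleotide contexts ------------------------------------------------

## Per-position pyrimidine-centered 3-mer (32 possibilities) with a flag for
## reverse-complement flips; circular neighbours wrap the origin.
all_contexts <- function(genome) {
  b <- genome$bases
  L <- genome$length
  left <- b[c(L, seq_len(L - 1L))]
  right <- b[c(seq_len(L)[-1L], 1L)]
  flip <- b %in% c("A", "G")
  ctx <- character(L)
  keep <- !flip
  ctx[keep] <- paste0(left[keep], b[keep], right[keep])
  comp <- c(COMP, N = "N")
  ctx[flip] <- paste0(comp[right[flip]], comp[b[flip]], comp[left[flip]])
  hasN <- b == "N" | left == "N" | right == "N"
  ctx[hasN] <- NA_character_
  list(ctx = ctx, flip = flip)
}

#' Pyrimidine-centered trinucleotide context at a position
#'
#' The circular genome wraps: positions 0 and `length - 1` use the bases at
#' the other end of the sequence as neighbours. If the reference base is a
#' purine the reverse-complement context is returned with `flipped = TRUE`,
#' so the central base of the result is always C or T.
#'
#' @param genome a `mito_genome`.
#' @param position 0-based position.
#' @return list with `context` (3-mer) and `flipped` (logical).
#' @export
trinucleotide_context <- function(genome, position) {
  if (position < 0 || position >= genome$length) stop("position out of range")
  list(context = genome$ctx32[position + 1L],
       flipped = genome$ctx_flip[position + 1L])
}

## vectorized 96-channel labels; NA where the context is undefined
channel_many <- function(genome, positions, alts) {
  i <- positions + 1L
  ref <- genome$bases[i]
  ctx <- genome$ctx32[i]
  flip <- genome$ctx_flip[i]
  cl <- ifelse(flip, paste0(unname(COMP[ref]), ">", unname(COMP[alts])),
               paste0(ref, ">", alts))
  out <- paste0(substr(ctx, 1, 1), "[", cl, "]", substr(ctx, 3, 3))
  out[is.na(ctx)] <- NA_character_
  out
}

#' Map a substitution to its 96-channel label
#'
#' @param genome a `mito_genome`.
#' @param position 0-based position.
#' @param alt alternate base (differs from the reference base).
#' @return channel label such as `"A[C>A]A"`.
#' @export
substitution_channel <- function(genome, position, alt) {
  ref <- genome$bases[position + 1L]
  if (alt == ref) stop("alt equals the reference base")
  ctx <- genome$ctx32[position + 1L]
  if (is.na(ctx)) stop("context undefined (N base in window)")
  if (genome$ctx_flip[position + 1L]) {
    cl <- paste0(COMP[ref], ">", COMP[alt])
  } else {
    cl <- paste0(ref, ">", alt)
  }
  paste0(substr(ctx, 1, 1), "[", cl, "]", substr(ctx, 3, 3))
}

## ---- coding classification -------------------------------------------------

## Vectorized classification over positions/alts using the codon cache.
classify_many <- function(genome, positions, alts) {
  i <- positions + 1L
  if (any(alts == genome$bases[i])) stop("alt equals the reference base")
  out <- rep("noncoding", length(positions))
  cod <- !is.na(genome$cod_off[i])
  if (!any(cod)) return(out)
  ic <- i[cod]
  sub <- ifelse(genome$cod_strand[ic] == "+", alts[cod],
                unname(COMP[alts[cod]]))
  b1 <- genome$cod_b1[ic]; b2 <- genome$cod_b2[ic]; b3 <- genome$cod_b3[ic]
  off <- genome$cod_off[ic]
  old <- paste0(b1, b2, b3)
  new <- paste0(ifelse(off == 0L, sub, b1),
                ifelse(off == 1L, sub, b2),
                ifelse(off == 2L, sub, b3))
  code <- genetic_code_5()
  aa0 <- unname(code[old]); aa1 <- unname(code[new])
  cls <- ifelse(is.na(aa0) | is.na(aa1), "noncoding",   # N in codon
                ifelse(aa0 == aa1, "synonymous",
                       ifelse(aa1 == "*", "nonsense", "nonsynonymous")))
  out[cod] <- cls
  out
}

#' Classify a single-nucleotide substitution
#'
#' Uses the first annotation covering the position (strand-aware codon
#' extraction) and the invertebrate mitochondrial genetic code (translation
#' table 5). Positions outside any complete codon are `"noncoding"`.
#' Substitutions creating a stop are `"nonsense"`; stop-loss counts as
#' nonsynonymous.
#'
#' @param genome a `mito_genome`.
#' @param position 0-based position.
#' @param alt alternate base, different from the reference base.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"noncoding"`.
#' @export
classify_substitution <- function(genome, position, alt) {
  if (position < 0 || position >= genome$length) stop("position out of range")
  if (!alt %in% BASES) stop("alt must be one of A/C/G/T")
  classify_many(genome, position, alt)
}

#' GC fraction of a genome
#' @param genome a `mito_genome`.
#' @return numeric in \[0,1\].
#' @export
gc_fraction <- function(genome) {
  mean(genome$bases %in% c("G", "C"))
}

#' Occurrence counts of the 32 pyrimidine-centered contexts over the target
#'
#' @param genome a `mito_genome`.
#' @return named integer vector over the contexts present.
#' @export
context_occurrences <- function(genome) {
  ctx <- genome$ctx32[genome$target_mask]
  table(ctx[!is.na(ctx)])
}
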
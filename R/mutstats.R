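## Mutation frequency, six-class spectrum, strand asymmetry, and 96-channel
## trinucleotide signatures with their normalizations.

#' Overall mutation frequency of a sample
#'
#' `[number of unique mutations] / [error-corrected nucleotides sequenced]`.
#'
#' @param summary a `sample_summary`.
#' @return frequency (mutations per duplex bp).
#' @export
overall_frequency <- function(summary) {
  if (summary$error_corrected_nt <= 0) stop("zero error-corrected nucleotides")
  nrow(summary$variants) / summary$error_corrected_nt
}

## strand-resolved class of each variant, reference-strand ref>alt
variant_strand_classes <- function(summary) {
  v <- summary$variants
  paste0(v$ref, ">", v$alt)
}

## collapse a strand class to its pyrimidine representative
collapse_class <- function(cls) {
  ref <- substr(cls, 1, 1)
  ifelse(ref %in% c("C", "T"), cls,
         paste0(COMP[ref], ">", COMP[substr(cls, 3, 3)]))
}

#' Six-class mutation spectrum with sequenced-base denominators
#'
#' Pools each substitution class with its complement (C:G -> A:T etc.) and
#' divides by the matching sequenced reference-base counts: C-class
#' frequencies by (sequenced C + sequenced G), T-class frequencies by
#' (sequenced T + sequenced A).
#'
#' @param summary a `sample_summary` with `base_counts` denominators.
#' @return object of class `mutation_spectrum`: `class_counts` and
#'   `class_frequencies` over the 6 pyrimidine-collapsed classes, and
#'   `strand_counts` over the 12 strand-resolved classes.
#' @export
class_frequencies <- function(summary) {
  if (is.null(summary$base_counts) || !all(summary$base_counts >= 0)) {
    stop("sequenced-base denominators missing")
  }
  sc <- variant_strand_classes(summary)
  strand_counts <- table(factor(sc, levels = STRAND_CLASSES))
  class_counts <- table(factor(collapse_class(sc), levels = PYR_CLASSES))
  bc <- summary$base_counts
  denom <- c(rep(bc["C"] + bc["G"], 3), rep(bc["T"] + bc["A"], 3))
  if (any(denom <= 0 & class_counts > 0)) stop("zero denominator for a nonzero class")
  freq <- ifelse(denom > 0, as.numeric(class_counts) / denom, 0)
  structure(list(
    class_counts = setNames(as.integer(class_counts), PYR_CLASSES),
    class_frequencies = setNames(freq, PYR_CLASSES),
    strand_counts = setNames(as.integer(strand_counts), STRAND_CLASSES)
  ), class = "mutation_spectrum")
}

#' Strand asymmetry of the six complementary substitution pairs
#'
#' For each pair (e.g. C>T vs G>A) reports both strand counts and a
#' two-sided exact binomial test against equal occurrence, with Bonferroni
#' adjustment over the pairs actually tested.
#'
#' @param summary a `sample_summary`.
#' @param adjust multiple-testing method (default `"bonferroni"`).
#' @return data.frame with `pair`, `n_pyr`, `n_pur`, `p`, `p_adj`; pairs
#'   with zero total are reported with NA p and a note column.
#' @export
strand_asymmetry <- function(summary, adjust = "bonferroni") {
  sc <- variant_strand_classes(summary)
  counts <- table(factor(sc, levels = STRAND_CLASSES))
  res <- lapply(PYR_CLASSES, function(cl) {
    comp_cl <- paste0(COMP[substr(cl, 1, 1)], ">", COMP[substr(cl, 3, 3)])
    a <- as.integer(counts[cl]); b <- as.integer(counts[comp_cl])
    if (a + b == 0L) {
      data.frame(pair = sprintf("%s vs %s", cl, comp_cl), n_pyr = 0L,
                 n_pur = 0L, p = NA_real_, note = "no observations")
    } else {
      p <- binom.test(a, a + b, 0.5)$p.value
      data.frame(pair = sprintf("%s vs %s", cl, comp_cl), n_pyr = a,
                 n_pur = b, p = p, note = "")
    }
  })
  out <- do.call(rbind, res)
  m <- sum(!is.na(out$p))
  out$p_adj <- pmin(1, out$p * if (adjust == "bonferroni") m else 1)
  out
}

#' 96-channel trinucleotide mutation signature
#'
#' @param summary a `sample_summary`.
#' @param genome a `mito_genome` (contexts wrap the circular origin).
#' @param mode `"raw"` (counts per channel), `"occurrence"` (counts divided
#'   by the targeted genome's context occurrence counts), or `"relative"`
#'   (elementwise ratio to a baseline vector; baseline zeros propagate as
#'   NA, reported rather than imputed).
#' @param baseline 96-vector for `"relative"` mode, e.g. from
#'   [baseline_signature()].
#' @return object of class `trinuc_signature`: `contributions` named
#'   96-vector and `normalization_mode`.
#' @export
trinuc_signature <- function(summary, genome,
                             mode = c("raw", "occurrence", "relative"),
                             baseline = NULL) {
  mode <- match.arg(mode)
  v <- summary$variants
  if (nrow(v) && (any(v$position < 0) || any(v$position >= genome$length))) {
    stop("variant outside the genome")
  }
  chans <- if (nrow(v)) channel_many(genome, v$position, v$alt) else character(0)
  counts <- table(factor(chans, levels = trinuc_channels()))
  x <- setNames(as.numeric(counts), trinuc_channels())
  if (mode == "occurrence") {
    occ <- context_occurrences(genome)
    ctx_of_chan <- paste0(substr(trinuc_channels(), 1, 1),
                          substr(trinuc_channels(), 3, 3),
                          substr(trinuc_channels(), 7, 7))
    denom <- as.numeric(occ[ctx_of_chan])
    x <- ifelse(!is.na(denom) & denom > 0, x / denom, NA_real_)
    names(x) <- trinuc_channels()
  } else if (mode == "relative") {
    if (is.null(baseline) || length(baseline) != 96L) {
      stop("relative mode needs a 96-element baseline")
    }
    x <- ifelse(baseline > 0, x / as.numeric(baseline), NA_real_)
    names(x) <- trinuc_channels()
  }
  structure(list(contributions = x, normalization_mode = mode,
                 sample_id = summary$sample_id),
            class = "trinuc_signature")
}

#' Mean raw context counts of a control group (relative-mode baseline)
#'
#' The arithmetic mean of per-sample raw 96-channel counts over the
#' designated control samples.
#'
#' @param summaries list of `sample_summary` objects (the control group).
#' @param genome a `mito_genome`.
#' @return named 96-vector.
#' @export
baseline_signature <- function(summaries, genome) {
  mats <- vapply(summaries, function(s) {
    trinuc_signature(s, genome, mode = "raw")$contributions
  }, numeric(96))
  rowMeans(mats)
}

#' Cosine similarity of two signatures
#'
#' Standard inner-product cosine. Entries undefined (NA) in either vector
#' are excluded pairwise; the effective dimension is attached as attribute
#' `"effective_dim"`.
#'
#' @param sig_a,sig_b `trinuc_signature` objects (same normalization mode)
#'   or bare numeric vectors of equal length.
#' @return cosine similarity in \[0, 1\] (nonnegative vectors).
#' @export
cosine_similarity <- function(sig_a, sig_b) {
  va <- if (inherits(sig_a, "trinuc_signature")) sig_a$contributions else sig_a
  vb <- if (inherits(sig_b, "trinuc_signature")) sig_b$contributions else sig_b
  if (inherits(sig_a, "trinuc_signature") && inherits(sig_b, "trinuc_signature") &&
      sig_a$normalization_mode != sig_b$normalization_mode) {
    stop("signatures have different normalization modes")
  }
  if (length(va) != length(vb)) stop("signature lengths differ")
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  out <- sum(va * vb) / (na * nb)
  attr(out, "effective_dim") <- sum(ok)
  out
}

#' Write a signature as labelled TSV (96 rows)
#' @param sig a `trinuc_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(sig, path) {
  write.table(data.frame(channel = names(sig$contributions),
                         contribution = sig$contributions),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a sample summary directly from a lineage truth
#'
#' Treats every truth variant as observed once at a uniform duplex depth
#' over the target — the idealized deep-sequencing limit, useful for
#' studying the spectrum/signature machinery without read simulation.
#'
#' @param truth a `lineage_truth`.
#' @param genome a `mito_genome`.
#' @param depth uniform duplex depth (default 1000).
#' @return a `sample_summary`.
#' @export
summary_from_truth <- function(truth, genome, depth = 1000L) {
  v <- truth$variants
  keep <- genome$target_mask[v$position + 1L]
  v <- v[keep, , drop = FALSE]
  d <- integer(genome$length)
  d[genome$target_mask] <- depth
  variants <- data.frame(position = v$position, ref = v$ref, alt = v$alt,
                         dcs_support = pmax(1L, as.integer(round(v$heteroplasmy * depth))),
                         duplex_depth = depth, stringsAsFactors = FALSE)
  base_counts <- vapply(BASES, function(b) sum(as.numeric(d[genome$bases == b])),
                        numeric(1))
  ctx <- genome$ctx32
  okc <- !is.na(ctx) & d > 0L
  context_counts <- tapply(d[okc], ctx[okc], sum)
  structure(list(sample_id = truth$line_id, variants = variants,
                 error_corrected_nt = sum(as.numeric(d)),
                 base_counts = base_counts,
                 context_counts = setNames(as.numeric(context_counts),
                                           names(context_counts)),
                 depth = d, n_offtarget = 0L),
            class = "sample_summary")
}
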
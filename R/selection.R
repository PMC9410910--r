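## Spectrum-aware dN/dS under the invertebrate mitochondrial genetic code.
## A transparent counting estimator: expected nonsynonymous and synonymous
## totals come from exhaustive enumeration of every possible coding
## substitution (site opportunities), optionally weighted by the sample's
## per-channel mutation rates, so a biased mutation spectrum does not
## masquerade as selection.

#' Enumerate synonymous/nonsynonymous site opportunities
#'
#' Walks every coding position of the genome and classifies all three
#' possible substitutions under translation table 5, tallying by 96-channel
#' (substitution class x trinucleotide context). Nonsense counts as
#' nonsynonymous.
#'
#' @param genome a `mito_genome` with CDS annotations.
#' @return object of class `site_opportunity`: data.frame `table`
#'   (`channel`, `syn`, `nonsyn`) plus totals `n_syn`, `n_nonsyn`,
#'   `coding_length`.
#' @export
site_opportunities <- function(genome) {
  if (nrow(genome$annotations) == 0L) stop("genome has no CDS annotations")
  coding <- which(!is.na(genome$cod_off)) - 1L
  if (!length(coding)) stop("annotations contain no complete codon")
  pos3 <- rep(coding, each = 3L)
  refs <- genome$bases[coding + 1L]
  alt3 <- unlist(lapply(refs, function(b) setdiff(BASES, b)), use.names = FALSE)
  kinds <- classify_many(genome, pos3, alt3)
  chans <- channel_many(genome, pos3, alt3)
  ok <- kinds != "noncoding" & !is.na(chans) # N-containing codons/contexts
  kinds <- ifelse(kinds[ok] == "synonymous", "syn", "nonsyn")
  chans <- chans[ok]
  lev <- trinuc_channels()
  syn <- table(factor(chans[kinds == "syn"], levels = lev))
  non <- table(factor(chans[kinds == "nonsyn"], levels = lev))
  structure(list(
    table = data.frame(channel = lev, syn = as.integer(syn),
                       nonsyn = as.integer(non)),
    n_syn = sum(syn), n_nonsyn = sum(non),
    coding_length = length(coding)
  ), class = "site_opportunity")
}

#' @export
print.site_opportunity <- function(x, ...) {
  cat(sprintf("<site_opportunity> %d coding bp: %d syn / %d nonsyn opportunities\n",
              x$coding_length, x$n_syn, x$n_nonsyn))
  invisible(x)
}

#' Spectrum-weighted counting dN/dS with a bootstrap confidence interval
#'
#' `ratio = (observed nonsyn / expected nonsyn) / (observed syn / expected
#' syn)` where the expected totals weight the site opportunities by
#' per-channel mutation rates. With `spectrum_weights = NULL` the weights
#' are uniform (every possible substitution equally likely). The CI is a
#' seeded percentile bootstrap over variants.
#'
#' @param variants data.frame with `position` (0-based) and `alt`;
#'   noncoding variants are ignored (their count is reported).
#' @param genome a `mito_genome` with CDS annotations.
#' @param spectrum_weights optional named vector of per-channel relative
#'   mutation rates (96-channel labels); e.g. channel counts divided by
#'   context occurrences from the same sample set.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param conf CI level (default 0.95).
#' @param opp precomputed [site_opportunities()] for `genome` (recomputed
#'   when NULL; pass it when calling repeatedly).
#' @return object of class `dnds_result`: `ratio` (NA when no synonymous
#'   observations), `ci`, counts `dn_obs`, `ds_obs`, expected `dn_exp`,
#'   `ds_exp`, `n_noncoding`.
#' @export
dnds <- function(variants, genome, spectrum_weights = NULL, n_boot = 1000L,
                 seed = 1L, conf = 0.95, opp = NULL) {
  if (is.null(opp)) opp <- site_opportunities(genome)
  w <- rep(1, 96)
  names(w) <- trinuc_channels()
  if (!is.null(spectrum_weights)) {
    if (is.null(names(spectrum_weights))) stop("spectrum_weights must be named")
    w[] <- 0
    w[names(spectrum_weights)] <- spectrum_weights
    if (all(w == 0)) stop("all spectrum weights are zero")
  }
  dn_exp <- sum(w * opp$table$nonsyn)
  ds_exp <- sum(w * opp$table$syn)
  if (ds_exp == 0) stop("zero expected synonymous sites under these weights")
  cls <- classify_many(genome, variants$position, variants$alt)
  coding <- cls != "noncoding"
  is_non <- cls[coding] %in% c("nonsynonymous", "nonsense")
  n <- sum(coding)
  if (n < 1L) stop("need at least one classified coding variant")
  dn_obs <- sum(is_non); ds_obs <- n - dn_obs
  point <- function(dn, ds) {
    if (ds == 0L) return(NA_real_)
    (dn / dn_exp) / (ds / ds_exp)
  }
  ratio <- point(dn_obs, ds_obs)
  ci <- c(NA_real_, NA_real_)
  if (!is.na(ratio) && n_boot > 0L) {
    boots <- with_seed(seed, {
      dn_star <- rbinom(n_boot, n, dn_obs / n) # resample variants with replacement
      vapply(dn_star, function(d) point(d, n - d), numeric(1))
    })
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- unname(quantile(boots, probs, na.rm = TRUE))
  }
  structure(list(ratio = ratio, ci = ci, conf = conf,
                 dn_obs = dn_obs, ds_obs = ds_obs,
                 dn_exp = dn_exp, ds_exp = ds_exp,
                 n_noncoding = sum(!coding)),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  if (is.na(x$ratio)) {
    cat(sprintf("<dnds_result> undefined (dn_obs=%d, ds_obs=0)\n", x$dn_obs))
  } else {
    cat(sprintf("<dnds_result> dN/dS = %.3f [%.3f, %.3f] (dn=%d, ds=%d)\n",
                x$ratio, x$ci[1], x$ci[2], x$dn_obs, x$ds_obs))
  }
  invisible(x)
}

#' Sample substitutions uniformly over all possible coding changes
#'
#' The neutral null for the counting estimator: every (coding position,
#' alternate base) pair is equally likely.
#'
#' @param genome a `mito_genome` with CDS annotations.
#' @param n number of substitutions to draw.
#' @param seed RNG seed.
#' @return data.frame with `position` (0-based), `ref`, `alt`.
#' @export
sample_neutral_coding <- function(genome, n, seed = 1L) {
  coding <- which(!is.na(genome$cod_off)) - 1L
  if (!length(coding)) stop("genome has no CDS annotations")
  with_seed(seed, {
    pos <- sample(coding, n, replace = TRUE)
    ref <- genome$bases[pos + 1L]
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
    data.frame(position = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  })
}
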
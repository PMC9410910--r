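## Germline mutation-accumulation simulator: each generation every genome
## copy acquires Poisson-distributed new mutations at class- and
## context-resolved rates, then the next generation's pool is a multinomial
## resample of the same size (neutral Wright-Fisher drift through a
## single-individual bottleneck).

#' Construct a strand-resolved substitution rate model
#'
#' @param per_class_rate named numeric vector of per-site per-generation
#'   probabilities over the 12 strand-resolved classes (`"C>A"`, `"G>T"`,
#'   ...). Missing classes default to 0.
#' @param context_multiplier optional named nonnegative numeric vector over
#'   96-channel labels (`"A[C>A]A"`); channels absent default to 1.
#' @return object of class `rate_model`.
#' @export
rate_model <- function(per_class_rate, context_multiplier = NULL) {
  rates <- setNames(rep(0, 12), STRAND_CLASSES)
  if (!all(names(per_class_rate) %in% STRAND_CLASSES)) {
    stop("per_class_rate names must be strand-resolved classes like 'C>A'")
  }
  rates[names(per_class_rate)] <- per_class_rate
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (sum(rates) >= 0.1) stop("total per-site per-generation rate must be < 0.1")
  if (!is.null(context_multiplier)) {
    if (!all(names(context_multiplier) %in% trinuc_channels())) {
      stop("context_multiplier names must be 96-channel labels like 'A[C>A]A'")
    }
    if (any(context_multiplier < 0)) stop("context multipliers must be nonnegative")
  }
  structure(list(per_class_rate = rates, context_multiplier = context_multiplier),
            class = "rate_model")
}

#' A flat rate model with equal rates in all 12 classes
#' @param per_site_total total per-site per-generation mutation probability;
#'   each of the 12 classes gets `per_site_total / 3` so that every site has
#'   the same total rate regardless of its reference base.
#' @return a `rate_model`.
#' @export
flat_rate_model <- function(per_site_total) {
  rate_model(setNames(rep(per_site_total / 3, 12), STRAND_CLASSES))
}

#' Population parameters for the bottleneck simulation
#'
#' @param copy_number mtDNA copies transmitted through the bottleneck
#'   (default 60, the cited effective number in *C. elegans*).
#' @param generations single-individual bottleneck generations (default 50,
#'   the MA design).
#' @return object of class `population_params`.
#' @export
population_params <- function(copy_number = 60L, generations = 50L) {
  if (copy_number < 1) stop("copy_number must be >= 1")
  if (generations < 0) stop("generations must be >= 0")
  structure(list(copy_number = as.integer(copy_number),
                 generations = as.integer(generations),
                 bottleneck_individuals = 1L),
            class = "population_params")
}

## Per-targeted-site mutation sampling distribution: for every targeted
## position and each of its 3 alternate bases, the per-generation rate
## (class rate x context multiplier). Returns flattened vectors.
site_rate_table <- function(genome, rmod) {
  keep <- which(genome$target_mask & genome$bases %in% BASES)
  refs <- genome$bases[keep]
  pos <- rep(keep - 1L, each = 3L)
  ref3 <- rep(refs, each = 3L)
  alt3 <- unlist(lapply(refs, function(b) setdiff(BASES, b)), use.names = FALSE)
  cls <- paste0(ref3, ">", alt3)
  rate <- unname(rmod$per_class_rate[cls])
  if (!is.null(rmod$context_multiplier)) {
    flip <- genome$ctx_flip[pos + 1L]
    ctx <- genome$ctx32[pos + 1L]
    pyr_cls <- ifelse(flip, paste0(COMP[ref3], ">", COMP[alt3]), cls)
    chan <- paste0(substr(ctx, 1, 1), "[", pyr_cls, "]", substr(ctx, 3, 3))
    mult <- rmod$context_multiplier[chan]
    mult[is.na(mult)] <- 1
    rate <- rate * unname(mult)
  }
  ok <- !is.na(rate) & rate > 0
  list(pos = pos[ok], alt = alt3[ok], rate = rate[ok],
       lambda = sum(rate[ok]))
}

#' Expected mutation events per transmitted lineage
#'
#' Returns the expected number of mutation events along one line of descent
#' over the experiment: the sum over targeted sites of the per-site
#' per-generation rate, times generations. With a flat rate model this is
#' the textbook `L * mu_total * G`.
#'
#' @param rmod a `rate_model`.
#' @param pop a `population_params`.
#' @param genome a `mito_genome`.
#' @return expected event count (numeric).
#' @export
expected_mutation_count <- function(rmod, pop, genome) {
  srt <- site_rate_table(genome, rmod)
  srt$lambda * pop$generations
}

#' Simulate one mutation-accumulation lineage through the germline bottleneck
#'
#' Each generation, the pool of `copy_number` genome copies acquires
#' Poisson-distributed new mutations at class- and context-resolved rates,
#' then is resampled multinomially to `copy_number` copies (the neutral
#' drift of the single-individual bottleneck). Variants lost from the pool
#' are dropped; fixed variants are retained and flagged. Rates are keyed to
#' the reference base; a second hit at a mutated site replaces the allele.
#'
#' @param genome a `mito_genome`; only targeted positions mutate.
#' @param rmod a `rate_model`.
#' @param pop a `population_params`.
#' @param seed RNG seed; the run is deterministic for a fixed seed.
#' @param line_id identifier recorded in the truth table.
#' @param init_variants optional data.frame (`position` 0-based, `alt`,
#'   `heteroplasmy`) of variants segregating at generation 0; each is
#'   assigned to `round(h * copy_number)` randomly chosen copies.
#' @return object of class `lineage_truth`: `$variants` data.frame
#'   (`position`, `ref`, `alt`, `heteroplasmy`, `generation`, `fixed`),
#'   plus `$n_events`, the total mutation events injected into the pool.
#' @export
simulate_lineage <- function(genome, rmod, pop, seed, line_id = "line1",
                             init_variants = NULL) {
  srt <- site_rate_table(genome, rmod)
  N <- pop$copy_number
  with_seed(seed, {
    ## event registry
    ev_pos <- integer(0); ev_alt <- character(0); ev_gen <- integer(0)
    ## genotypes: list of integer event-id vectors; counts: copies per genotype
    genotypes <- list(integer(0))
    counts <- N
    if (!is.null(init_variants) && nrow(init_variants)) {
      copy_sets <- replicate(N, integer(0), simplify = FALSE)
      for (i in seq_len(nrow(init_variants))) {
        h <- init_variants$heteroplasmy[i]
        k <- round(h * N)
        ev_pos <- c(ev_pos, init_variants$position[i])
        ev_alt <- c(ev_alt, init_variants$alt[i])
        ev_gen <- c(ev_gen, 0L)
        for (cp in sample.int(N, k)) {
          copy_sets[[cp]] <- c(copy_sets[[cp]], length(ev_pos))
        }
      }
      keys <- vapply(copy_sets, function(s) paste(sort(s), collapse = ","),
                     character(1))
      uk <- unique(keys)
      genotypes <- lapply(uk, function(k) {
        s <- copy_sets[[match(k, keys)]]
        sort(s)
      })
      counts <- as.integer(table(factor(keys, levels = uk)))
    }
    n_events <- 0L
    if (pop$generations > 0 && (srt$lambda > 0 || length(ev_pos))) {
      for (g in seq_len(pop$generations)) {
        ## mutation phase
        if (srt$lambda > 0) {
          K <- rpois(1, N * srt$lambda)
          if (K > 0) {
            hits <- sample.int(length(srt$pos), K, replace = TRUE,
                               prob = srt$rate)
            for (h in hits) {
              gt <- sample.int(length(counts), 1, prob = counts)
              pos <- srt$pos[h]; alt <- srt$alt[h]
              ev_pos <- c(ev_pos, pos); ev_alt <- c(ev_alt, alt)
              ev_gen <- c(ev_gen, g)
              id <- length(ev_pos)
              newg <- genotypes[[gt]]
              prior <- newg[ev_pos[newg] == pos]
              if (length(prior)) newg <- setdiff(newg, prior)
              newg <- c(newg, id)
              counts[gt] <- counts[gt] - 1L
              genotypes[[length(genotypes) + 1L]] <- newg
              counts <- c(counts, 1L)
              n_events <- n_events + 1L
            }
          }
        }
        ## drift phase: one multinomial bottleneck resample
        if (length(counts) > 1L) {
          counts <- as.integer(stats::rmultinom(1, N, counts))
        }
        live <- counts > 0L
        if (!all(live)) {
          genotypes <- genotypes[live]
          counts <- counts[live]
        }
      }
    }
    ## tally surviving (position, alt) with copy counts
    if (length(ev_pos)) {
      carrier <- integer(length(ev_pos))
      for (i in seq_along(genotypes)) {
        ids <- genotypes[[i]]
        if (length(ids)) carrier[ids] <- carrier[ids] + counts[i]
      }
      alive <- which(carrier > 0L)
      if (length(alive)) {
        dt <- data.table::data.table(
          position = ev_pos[alive], alt = ev_alt[alive],
          gen = ev_gen[alive], n = carrier[alive]
        )
        agg <- dt[, list(n = sum(n), generation = min(gen)),
                  by = c("position", "alt")]
        variants <- data.frame(
          position = agg$position,
          ref = genome$bases[agg$position + 1L],
          alt = agg$alt,
          heteroplasmy = agg$n / N,
          generation = agg$generation,
          fixed = agg$n == N,
          stringsAsFactors = FALSE
        )
      } else {
        variants <- empty_variants()
      }
    } else variants <- empty_variants()
    structure(list(variants = variants, line_id = line_id, seed = seed,
                   n_events = n_events, copy_number = N),
              class = "lineage_truth")
  })
}

empty_variants <- function() {
  data.frame(position = integer(0), ref = character(0), alt = character(0),
             heteroplasmy = numeric(0), generation = integer(0),
             fixed = logical(0), stringsAsFactors = FALSE)
}

#' Build a lineage truth from a hand-specified variant table
#'
#' Convenience constructor for injection experiments where heteroplasmy
#' fractions are chosen directly rather than simulated.
#'
#' @param genome a `mito_genome`.
#' @param variants data.frame with `position` (0-based), `alt`,
#'   `heteroplasmy`; `ref` is filled from the genome.
#' @param line_id identifier.
#' @return a `lineage_truth`.
#' @export
make_truth <- function(genome, variants, line_id = "line1") {
  if (nrow(variants)) {
    variants$ref <- genome$bases[variants$position + 1L]
    if (any(variants$ref == variants$alt)) stop("alt equals ref for some variant")
    if (any(variants$heteroplasmy <= 0 | variants$heteroplasmy > 1)) {
      stop("heteroplasmy must be in (0, 1]")
    }
    if (is.null(variants$generation)) variants$generation <- NA_integer_
    variants$fixed <- variants$heteroplasmy == 1
    variants <- variants[, c("position", "ref", "alt", "heteroplasmy",
                             "generation", "fixed")]
  } else variants <- empty_variants()
  structure(list(variants = variants, line_id = line_id, seed = NA_integer_,
                 n_events = nrow(variants), copy_number = NA_integer_),
            class = "lineage_truth")
}

#' Write a lineage truth table as TSV (1-based positions)
#' @param truth a `lineage_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  v <- truth$variants
  out <- data.frame(line_id = rep(truth$line_id, nrow(v)), pos = v$position + 1L,
                    ref = v$ref, alt = v$alt, heteroplasmy = v$heteroplasmy,
                    generation = v$generation)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lineage truth table written by [write_truth_tsv()]
#' @param path TSV path.
#' @param genome a `mito_genome` (for reference-base checks).
#' @return a `lineage_truth`.
#' @export
read_truth_tsv <- function(path, genome) {
  t <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  v <- data.frame(position = t$pos - 1L, alt = t$alt,
                  heteroplasmy = t$heteroplasmy, generation = t$generation)
  tr <- make_truth(genome, v,
                   line_id = if (nrow(t)) t$line_id[1] else "line1")
  if (nrow(t) && !all(tr$variants$ref == t$ref)) {
    stop("truth table ref bases disagree with the genome")
  }
  tr
}

#' @export
print.lineage_truth <- function(x, ...) {
  cat(sprintf("<lineage_truth '%s'> %d segregating variants (%d events)\n",
              x$line_id, nrow(x$variants), x$n_events))
  invisible(x)
}
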
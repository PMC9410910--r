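## End-to-end orchestration: simulate -> reads -> consensus -> stats ->
## compare, with derived per-stage seeds, a checksum manifest and a
## worked-example verifier for the motivating mutation-accumulation
## experiment's printed arithmetic.

#' Assemble a run configuration
#'
#' @param seed global seed; per-stage child seeds derive from it via
#'   [derive_seed()] with a running counter, so stages can be rerun in
#'   isolation.
#' @param outdir output directory.
#' @param genome a `mito_genome`, or a list of [generate_synthetic_genome()]
#'   arguments under `$synthetic`, or `$fasta`/`$annotations_bed`/
#'   `$targets_bed` paths.
#' @param groups data.frame with `strain`, `treatment`, `n_lines`.
#' @param rates a `rate_model`.
#' @param pop a `population_params`.
#' @param errors an `error_model`.
#' @param n_molecules duplex molecules per line.
#' @param consensus list of `min_reads`, `consensus_frac`, `clip`.
#' @param write_fastq also write per-line FASTQ files (default FALSE; they
#'   dominate run size).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed, outdir, genome, groups, rates, pop, errors,
                       n_molecules,
                       consensus = list(min_reads = 3L, consensus_frac = 0.70,
                                        clip = 12L),
                       write_fastq = FALSE) {
  structure(list(seed = as.integer(seed), outdir = outdir, genome = genome,
                 groups = groups, rates = rates, pop = pop, errors = errors,
                 n_molecules = as.integer(n_molecules), consensus = consensus,
                 write_fastq = isTRUE(write_fastq)),
            class = "run_config")
}

resolve_genome <- function(genome) {
  if (inherits(genome, "mito_genome")) return(genome)
  if (!is.null(genome$synthetic)) {
    return(do.call(generate_synthetic_genome, genome$synthetic))
  }
  ann <- if (!is.null(genome$annotations_bed)) load_annotations_bed(genome$annotations_bed)
  tgt <- if (!is.null(genome$targets_bed)) load_targets_bed(genome$targets_bed)
  load_fasta(genome$fasta, annotations = ann, target_region = tgt)
}

#' Run the full simulate -> sequence -> call -> summarize experiment
#'
#' Deterministic for a fixed config seed. Any stage failure aborts with the
#' stage name; completed artifacts are listed in the manifest with MD5
#' checksums.
#'
#' @param config a `run_config`.
#' @return (invisibly) list with `summaries`, `frequencies` (per-line
#'   table), `manifest` path.
#' @export
run_experiment <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$outdir, "run.log")
  logline <- function(stage, msg) {
    cat(sprintf("[%s] seed=%d %s\n", stage, config$seed, msg),
        file = logf, append = TRUE)
  }
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)
  stage <- "genome"
  res <- tryCatch({
    genome <- resolve_genome(config$genome)
    gp <- file.path(config$outdir, "genome.fasta")
    write_genome_fasta(genome, gp); add(gp)
    logline(stage, sprintf("%d bp, %d bp targeted", genome$length,
                           targeted_length(genome)))
    ctr <- 0L
    summaries <- list()
    rows <- list()
    for (gi in seq_len(nrow(config$groups))) {
      grp <- config$groups[gi, ]
      for (li in seq_len(grp$n_lines)) {
        line_id <- sprintf("%s_%s_L%02d", grp$strain, grp$treatment, li)
        stage <- paste0("simulate:", line_id)
        truth <- simulate_lineage(genome, config$rates, config$pop,
                                  seed = derive_seed(config$seed, ctr),
                                  line_id = line_id)
        ctr <- ctr + 1L
        tp <- file.path(config$outdir, paste0(line_id, ".truth.tsv"))
        write_truth_tsv(truth, tp); add(tp)
        stage <- paste0("reads:", line_id)
        sim <- simulate_reads(genome, truth, config$errors,
                              n_molecules = config$n_molecules,
                              seed = derive_seed(config$seed, ctr))
        ctr <- ctr + 1L
        if (config$write_fastq) {
          fp <- file.path(config$outdir, paste0(line_id, ".fastq"))
          write_fastq(sim$reads, fp); add(fp)
        }
        stage <- paste0("consensus:", line_id)
        s <- call_sample(sim$reads, genome, sample_id = line_id,
                         min_reads = config$consensus$min_reads,
                         consensus_frac = config$consensus$consensus_frac,
                         clip = config$consensus$clip)
        cst <- attr(s, "consensus_stats")
        logline(stage, sprintf("%d families, %d SSCS rejected, %d single-strand",
                               cst$n_families, cst$n_sscs_rejected,
                               cst$n_single_strand))
        vp <- file.path(config$outdir, paste0(line_id, ".vcf"))
        write_vcf(s, genome, vp); add(vp)
        jp <- file.path(config$outdir, paste0(line_id, ".summary.json"))
        write_summary_json(s, jp); add(jp)
        summaries[[line_id]] <- s
        spec <- class_frequencies(s)
        rows[[line_id]] <- data.frame(
          line_id = line_id, strain = grp$strain, treatment = grp$treatment,
          n_variants = nrow(s$variants),
          error_corrected_nt = s$error_corrected_nt,
          frequency = overall_frequency(s),
          t(spec$class_counts), check.names = FALSE
        )
      }
    }
    stage <- "stats"
    if (length(summaries) >= 2L) {
      summaries <- filter_fixed_polymorphisms(summaries)$summaries
    }
    freq <- do.call(rbind, rows); rownames(freq) <- NULL
    fp <- file.path(config$outdir, "frequencies.tsv")
    write.table(freq, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    add(fp)
    stage <- "compare"
    n_strain <- length(unique(freq$strain))
    n_treat <- length(unique(freq$treatment))
    if (n_strain >= 2L || n_treat >= 2L) {
      fac <- c("strain", "treatment")[c(n_strain, n_treat) >= 2L]
      cmp <- anova_tukey(freq, "frequency", fac)
      cp <- file.path(config$outdir, "comparison.tsv")
      av <- cmp$anova
      av$p <- format(av$p, scientific = TRUE)
      write.table(av, cp, sep = "\t", quote = FALSE, row.names = FALSE)
      add(cp)
    }
    stage <- "manifest"
    mf <- file.path(config$outdir, "manifest.json")
    sums <- tools::md5sum(artifacts)
    jsonlite::write_json(
      list(seed = config$seed,
           artifacts = data.frame(path = basename(names(sums)),
                                  md5 = unname(sums))),
      mf, auto_unbox = TRUE)
    list(summaries = summaries, frequencies = freq, manifest = mf)
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s [completed: %s]", stage,
                 conditionMessage(e), paste(basename(artifacts), collapse = ", ")),
         call. = FALSE)
  })
  invisible(res)
}

#' Printed reference constants of the motivating MA experiment
#'
#' The published counts and rates this package's worked-example verifier
#' recomputes: per-group single-nucleotide-mutation totals for three strains
#' (wild-type, dct-1, pink-1) under three conditions (control, CdCl2,
#' AfB1), the per-group line counts, the printed grand total, the design's
#' generation arithmetic and the nuclear-rate fold change.
#'
#' @return named list of constants.
#' @export
ma_study_constants <- function() {
  list(
    snm_totals = c(
      "wild-type:control" = 760, "wild-type:CdCl2" = 874, "wild-type:AfB1" = 636,
      "dct-1:control" = 491, "dct-1:CdCl2" = 727, "dct-1:AfB1" = 574,
      "pink-1:control" = 530, "pink-1:CdCl2" = 696, "pink-1:AfB1" = 752
    ),
    grand_total = 6040,
    wt_control_lines = 11,
    wt_control_mean_printed = 70,
    lines_sequenced = 96,
    generations_per_line = 50,
    total_generations_printed = 4800,
    sublines_per_group = 50,
    generations_per_group_printed = 2500,
    nuclear_rate_control = 9.45e-9,
    nuclear_rate_afb1 = 15e-9,
    afb1_fold_printed = 1.6
  )
}

#' Recompute the study's in-print arithmetic worked examples
#'
#' Each row recomputes one printed quantity from the other printed inputs
#' and compares at the printed precision. The per-line average is printed
#' as the round figure 70 for 760/11 = 69.1, so that row carries an
#' explicit tolerance of 1 mutation/line; every other comparison is exact.
#'
#' @return data.frame with `check`, `computed`, `printed`, `tolerance`,
#'   `pass`.
#' @export
verify_worked_examples <- function() {
  k <- ma_study_constants()
  rows <- list(
    data.frame(check = "nine per-group SNM totals sum to the grand total",
               computed = sum(k$snm_totals), printed = k$grand_total,
               tolerance = 0),
    data.frame(check = "wild-type control total over 11 lines gives the printed per-line average",
               computed = round(k$snm_totals[["wild-type:control"]] / k$wt_control_lines, 1),
               printed = k$wt_control_mean_printed, tolerance = 1),
    data.frame(check = "96 lines x 50 generations give the printed generation total",
               computed = k$lines_sequenced * k$generations_per_line,
               printed = k$total_generations_printed, tolerance = 0),
    data.frame(check = "50 sublines x 50 generations give the printed per-group generation total",
               computed = k$sublines_per_group * k$generations_per_line,
               printed = k$generations_per_group_printed, tolerance = 0),
    data.frame(check = "AfB1/control nuclear-rate ratio gives the printed fold change",
               computed = round(k$nuclear_rate_afb1 / k$nuclear_rate_control, 1),
               printed = k$afb1_fold_printed, tolerance = 0)
  )
  out <- do.call(rbind, rows)
  out$pass <- abs(out$computed - out$printed) <= out$tolerance
  rownames(out) <- NULL
  out
}
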
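## UMI-tagged duplex read-family simulator. Each original molecule yields two
## strand families (labelled ab / ba). True variants are sampled per molecule
## by Bernoulli(heteroplasmy); PCR errors are injected once per strand family
## and propagate to all of its reads; sequencing errors are independent per
## read; end artifacts only occur within `end_window` bp of fragment ends.
## Reads are emitted in reference orientation (the post-mapping convention),
## full fragment length by default.

RAW_N <- charToRaw("N")

#' Construct a read-level error model
#'
#' @param seq_error_rate per-base per-read substitution probability
#'   (default 1e-3, typical Illumina raw error).
#' @param pcr_error_rate per-base per-strand-family probability of an early
#'   PCR error shared by every read of that strand family (default 1e-5).
#' @param end_artifact_rate per-base probability of an artifactual
#'   substitution, applied only within `end_window` bp of fragment ends
#'   (default 1e-4).
#' @param end_window width in bp of the fragment-end artifact zone
#'   (default 12, the window the consensus caller clips).
#' @param umi_error_rate per-base UMI error probability (default 0; family
#'   collision/merging is out of scope).
#' @return object of class `error_model`.
#' @export
error_model <- function(seq_error_rate = 1e-3, pcr_error_rate = 1e-5,
                        end_artifact_rate = 1e-4, end_window = 12L,
                        umi_error_rate = 0) {
  r <- c(seq_error_rate, pcr_error_rate, end_artifact_rate, umi_error_rate)
  if (any(r < 0 | r > 0.25)) stop("error rates must lie in [0, 0.25]")
  structure(list(seq_error_rate = seq_error_rate,
                 pcr_error_rate = pcr_error_rate,
                 end_artifact_rate = end_artifact_rate,
                 end_window = as.integer(end_window),
                 umi_error_rate = umi_error_rate),
            class = "error_model")
}

#' Default fragment length sampler
#'
#' Normal(mean, sd) rounded, floored at `min_len`; emulates Covaris-sheared
#' duplex inserts.
#' @param mean,sd,min_len distribution parameters.
#' @return function(n) returning integer lengths.
#' @export
fragment_length_sampler <- function(mean = 300, sd = 30, min_len = 25L) {
  function(n) pmax(as.integer(min_len), as.integer(round(rnorm(n, mean, sd))))
}

#' Default strand-family size sampler
#'
#' Zero-truncated negative binomial, mean about `mu`; the realized family
#' size distribution of a duplex library is tuning-dependent, so this is a
#' documented free choice.
#' @param mu mean family size (default 6).
#' @param size NB dispersion (default 3).
#' @return function(n) returning integer counts >= 1.
#' @export
family_size_sampler <- function(mu = 6, size = 3) {
  function(n) {
    x <- rnbinom(n, mu = mu, size = size)
    while (any(x == 0L)) {
      z <- x == 0L
      x[z] <- rnbinom(sum(z), mu = mu, size = size)
    }
    as.integer(x)
  }
}

## alt-base lookup: for byte of base i, three substitute bytes
ALT_RAW <- lapply(BASES, function(b) vapply(setdiff(BASES, b), charToRaw, raw(1)))
names(ALT_RAW) <- BASES

## substitute k entries of raw vector x at idx with random different bases
inject_subs <- function(x, idx) {
  if (!length(idx)) return(x)
  cur <- x[idx]
  pick <- sample.int(3L, length(idx), replace = TRUE)
  x[idx] <- vapply(seq_along(idx),
                   function(i) ALT_RAW[[rawToChar(cur[i])]][pick[i]],
                   raw(1))
  x
}

#' Simulate UMI-tagged duplex read families
#'
#' @param genome a `mito_genome`; fragments are sampled with uniform starts
#'   over positions where the whole fragment is targeted (circular wrap
#'   allowed when the target permits it).
#' @param truth a `lineage_truth` (may carry zero variants for a
#'   reference-only library).
#' @param emod an `error_model`.
#' @param n_molecules number of original duplex molecules (> 0).
#' @param fragment_len_dist function(n) -> fragment lengths; default
#'   [fragment_length_sampler()].
#' @param family_size_dist function(n) -> per-strand-family read counts
#'   (0 allowed: lost strand family); default [family_size_sampler()].
#' @param seed RNG seed.
#' @param umi_length UMI tag length (default 10).
#' @return list with `reads` (data.table: `read_id`, `molecule_id`,
#'   `umi_a`, `umi_b`, `strand` ab/ba, `start` 0-based, `len`, `sequence`)
#'   and `families` (the ground-truth family table: per-molecule fragment,
#'   UMIs, per-strand read counts, carried variants and injected PCR
#'   errors as `offset:alt` lists, 0-based offsets).
#' @export
simulate_reads <- function(genome, truth, emod, n_molecules,
                           fragment_len_dist = fragment_length_sampler(),
                           family_size_dist = family_size_sampler(),
                           seed = 1L, umi_length = 10L) {
  if (n_molecules <= 0) stop("n_molecules must be > 0")
  L <- genome$length
  mask2 <- c(genome$target_mask, genome$target_mask)
  cs <- c(0L, cumsum(mask2))
  targeted <- which(genome$target_mask) - 1L
  if (!length(targeted)) stop("genome has no targeted positions")
  seq2raw <- charToRaw(paste0(genome$sequence, genome$sequence))
  tv <- truth$variants
  with_seed(seed, {
    lens <- fragment_len_dist(n_molecules)
    if (any(lens < 2L * emod$end_window + 1L)) {
      stop("fragment lengths must be >= 2*end_window + 1")
    }
    if (any(lens > L)) stop("fragment length exceeds genome length")
    starts <- sample(targeted, n_molecules, replace = TRUE)
    ## resample starts until the whole fragment is targeted
    repeat {
      bad <- which(cs[starts + lens + 1L] - cs[starts + 1L] < lens)
      if (!length(bad)) break
      starts[bad] <- sample(targeted, length(bad), replace = TRUE)
    }
    umis <- matrix(
      replicate(2L * n_molecules,
                paste0(sample(BASES, umi_length, replace = TRUE), collapse = "")),
      ncol = 2L
    )
    n_ab <- family_size_dist(n_molecules)
    n_ba <- family_size_dist(n_molecules)

    read_rows <- vector("list", n_molecules)
    fam_rows <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      s <- starts[m]; l <- lens[m]
      frag <- seq2raw[(s + 1L):(s + l)]
      carried <- character(0)
      if (nrow(tv)) {
        off <- (tv$position - s) %% L
        infrag <- which(off < l)
        if (length(infrag)) {
          hit <- infrag[runif(length(infrag)) < tv$heteroplasmy[infrag]]
          if (length(hit)) {
            frag[off[hit] + 1L] <- vapply(tv$alt[hit], charToRaw, raw(1))
            carried <- paste0(off[hit], ":", tv$alt[hit])
          }
        }
      }
      pcr_rec <- list(ab = character(0), ba = character(0))
      strand_reads <- list(ab = NULL, ba = NULL)
      for (st in c("ab", "ba")) {
        nr <- if (st == "ab") n_ab[m] else n_ba[m]
        if (nr == 0L) next
        tmpl <- frag
        kp <- rbinom(1L, l, emod$pcr_error_rate)
        if (kp > 0L) {
          ip <- sample.int(l, kp)
          tmpl <- inject_subs(tmpl, ip)
          pcr_rec[[st]] <- paste0(ip - 1L, ":", rawToChar(tmpl[ip], multiple = TRUE))
        }
        mat <- matrix(tmpl, nrow = l, ncol = nr)
        ks <- rbinom(1L, nr * l, emod$seq_error_rate)
        if (ks > 0L) {
          sel <- sample.int(nr * l, ks)
          mat[sel] <- inject_subs_mat(mat, sel)
        }
        if (emod$end_artifact_rate > 0) {
          w <- emod$end_window
          widx <- c(seq_len(w), (l - w + 1L):l)
          full <- as.vector(outer(widx, (seq_len(nr) - 1L) * l, "+"))
          ke <- rbinom(1L, length(full), emod$end_artifact_rate)
          if (ke > 0L) {
            sel <- sample(full, ke)
            mat[sel] <- vapply(sel, function(i) {
              ALT_RAW[[rawToChar(mat[i])]][sample.int(3L, 1L)]
            }, raw(1))
          }
        }
        strand_reads[[st]] <- vapply(seq_len(nr),
                                     function(j) rawToChar(mat[, j]),
                                     character(1))
      }
      nr_tot <- length(strand_reads$ab) + length(strand_reads$ba)
      if (nr_tot > 0L) {
        read_rows[[m]] <- data.table::data.table(
          molecule_id = sprintf("mol%06d", m),
          umi_a = umis[m, 1], umi_b = umis[m, 2],
          strand = rep(c("ab", "ba"),
                       c(length(strand_reads$ab), length(strand_reads$ba))),
          start = s, len = l,
          sequence = c(strand_reads$ab, strand_reads$ba)
        )
      }
      fam_rows[[m]] <- data.table::data.table(
        molecule_id = sprintf("mol%06d", m),
        start = s, len = l,
        umi_a = umis[m, 1], umi_b = umis[m, 2],
        reads_ab = n_ab[m], reads_ba = n_ba[m],
        carried_variants = paste(carried, collapse = ";"),
        pcr_ab = paste(pcr_rec$ab, collapse = ";"),
        pcr_ba = paste(pcr_rec$ba, collapse = ";")
      )
    }
    reads <- data.table::rbindlist(read_rows)
    if (nrow(reads)) {
      reads[, read_id := sprintf("%s.%s.%d", molecule_id, strand,
                                 seq_len(.N)), by = c("molecule_id", "strand")]
    } else reads[, read_id := character(0)]
    list(reads = reads, families = data.table::rbindlist(fam_rows))
  })
}

## random different-base substitutes for matrix entries at linear idx
inject_subs_mat <- function(mat, idx) {
  vapply(idx, function(i) ALT_RAW[[rawToChar(mat[i])]][sample.int(3L, 1L)],
         raw(1))
}

#' Write simulated reads as FASTQ (Phred+33, constant Q30)
#'
#' Read names encode the UMI pair and strand family as
#' `name#umiA+umiB/strand start=<s> len=<l>` so the pipeline is testable
#' from FASTQ alone. `paired = TRUE` additionally trims each fragment to
#' `read_len` bases from each end and writes an R1/R2 pair (interoperability
#' mode; the consensus caller consumes the full-fragment default).
#'
#' @param reads reads data.table from [simulate_reads()].
#' @param path output FASTQ path (R1 when paired).
#' @param paired emit trimmed read pairs instead of full fragments.
#' @param path2 R2 path (required when paired).
#' @param read_len paired-end read length (default 150).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, paired = FALSE, path2 = NULL,
                        read_len = 150L) {
  hdr <- sprintf("@%s#%s+%s/%s start=%d len=%d", reads$read_id,
                 reads$umi_a, reads$umi_b, reads$strand, reads$start,
                 reads$len)
  if (!paired) {
    qual <- strrep("?", nchar(reads$sequence))
    writeLines(as.vector(rbind(hdr, reads$sequence, "+", qual)), path)
  } else {
    if (is.null(path2)) stop("paired output needs path2")
    r1 <- substr(reads$sequence, 1L, pmin(read_len, nchar(reads$sequence)))
    full <- nchar(reads$sequence)
    r2 <- revcomp(substr(reads$sequence, pmax(1L, full - read_len + 1L), full))
    writeLines(as.vector(rbind(paste0(hdr, " 1"), r1, "+",
                               strrep("?", nchar(r1)))), path)
    writeLines(as.vector(rbind(paste0(hdr, " 2"), r2, "+",
                               strrep("?", nchar(r2)))), path2)
  }
  invisible(path)
}

#' Read a full-fragment FASTQ written by [write_fastq()]
#'
#' Reads whose names do not carry a parseable UMI/strand label are dropped;
#' the dropped count is reported via a message and an attribute.
#'
#' @param path FASTQ path.
#' @return reads data.table in [simulate_reads()] layout, with attribute
#'   `dropped` (count of unparseable reads).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ")
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  m <- regmatches(hdr, regexec(
    "^@(\\S+)#([ACGT]+)\\+([ACGT]+)/(ab|ba) start=(\\d+) len=(\\d+)", hdr))
  ok <- lengths(m) == 7L
  if (any(!ok)) message(sum(!ok), " reads with unparseable labels dropped")
  mm <- do.call(rbind, m[ok])
  reads <- data.table::data.table(
    molecule_id = sub("\\.(ab|ba)\\.\\d+$", "", mm[, 2]),
    umi_a = mm[, 3], umi_b = mm[, 4], strand = mm[, 5],
    start = as.integer(mm[, 6]), len = as.integer(mm[, 7]),
    sequence = seqs[ok], read_id = mm[, 2]
  )
  data.table::setattr(reads, "dropped", sum(!ok))
  reads
}

#' Write the ground-truth family table as TSV (1-based fragment starts)
#' @param families family table from [simulate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_truth_tsv <- function(families, path) {
  out <- data.table::copy(families)
  out[, start := start + 1L]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
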
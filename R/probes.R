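#' Tile oligo probes over a target sequence
#'
#' Greedy left-to-right placement of `probe_len`-mers with an exact
#' `gap`-bp space between consecutive probes (stride `probe_len + gap`),
#' starting at position 0. Probes containing N are skipped but the
#' placement grid still advances, so coordinates stay on the fixed stride.
#' For an N-free sequence of length `L >= probe_len` the probe count is
#' `floor((L - probe_len) / (probe_len + gap)) + 1`; the assay's standard
#' design (30-mers, 20-bp gaps) therefore yields 50 probes over 2.5 kb.
#'
#' @param sequence target as a character string or
#'   [Biostrings::DNAString-class] over A/C/G/T/N.
#' @param probe_len probe (core) length in bp, >= 10; default 30.
#' @param gap inter-probe gap in bp; default 20.
#' @param target_name name recorded in the probe set.
#' @return object of class `probe_set`: list with `target_name`,
#'   `region_length`, `tail` (initially `""`) and `probes` (data frame:
#'   0-based half-open `start` / `end`, `strand`, `core`, `full_seq`).
#' @export
tile_probes <- function(sequence, probe_len = 30L, gap = 20L,
                        target_name = "target") {
  if (inherits(sequence, "DNAString") || inherits(sequence, "BString"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            probe_len >= 10, gap >= 0)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence must contain only A, C, G, T or N")
  L <- nchar(sequence)
  probe_len <- as.integer(probe_len); gap <- as.integer(gap)
  if (L < probe_len) {
    warning(sprintf("sequence (%d nt) shorter than probe_len (%d): no probes",
                    L, probe_len))
    return(.probe_set(target_name, L, .empty_probes()))
  }
  starts <- seq.int(0L, L - probe_len, by = probe_len + gap)
  cores <- substring(sequence, starts + 1L, starts + probe_len)
  keep <- !grepl("N", cores, fixed = TRUE)
  probes <- data.frame(start = starts[keep],
                       end = starts[keep] + probe_len,
                       strand = "+",
                       core = cores[keep],
                       full_seq = cores[keep],
                       stringsAsFactors = FALSE)
  .probe_set(target_name, L, probes)
}

.empty_probes <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             core = character(0), full_seq = character(0),
             stringsAsFactors = FALSE)
}

.probe_set <- function(target_name, region_length, probes, tail = "") {
  structure(list(target_name = target_name,
                 region_length = as.integer(region_length),
                 tail = tail, probes = probes),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set '%s': %d probes over %d bp%s\n", x$target_name,
              nrow(x$probes), x$region_length,
              if (nzchar(x$tail)) paste0(", 3' tail ", x$tail) else ""))
  invisible(x)
}

#' Filter problematic probes
#'
#' Removes probes that would behave badly in hybridization: low-complexity
#' sequences (dinucleotide Shannon entropy below `min_entropy` bits or a
#' homopolymer run longer than `max_run`), probes sharing a k-mer with
#' multiple genomic sites (exact `kmer`-mer occurrence count in the
#' background sequences reaching `max_hits`; supply a background that
#' includes the target locus, whose own site accounts for one hit), and
#' optionally probes with GC fraction outside `gc_bounds`. Removal reasons
#' are recorded in the `filtered` attribute. The operation is idempotent.
#'
#' @param ps a [tile_probes()] result.
#' @param background optional character vector (or `DNAStringSet`) of
#'   background sequences for the uniqueness rule.
#' @param min_entropy dinucleotide entropy threshold in bits (default 1.5);
#'   `NULL` disables the rule.
#' @param max_run maximum homopolymer run (default 8); `NULL` disables.
#' @param kmer k-mer length for the uniqueness rule (default 16).
#' @param max_hits background k-mer count at which a probe is removed
#'   (default 2, i.e. one site beyond the target's own).
#' @param gc_bounds optional `c(min, max)` GC fraction bounds; `NULL`
#'   (default) disables the rule.
#' @return the filtered `probe_set`, with attribute `filtered` (data
#'   frame: `start`, `core`, `reason`).
#' @export
filter_probes <- function(ps, background = NULL, min_entropy = 1.5,
                          max_run = 8L, kmer = 16L, max_hits = 2L,
                          gc_bounds = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  pr <- ps$probes
  if (nrow(pr) == 0L) {
    attr(ps, "filtered") <- data.frame(start = integer(0),
                                       core = character(0),
                                       reason = character(0))
    return(ps)
  }
  reason <- rep(NA_character_, nrow(pr))

  if (!is.null(min_entropy) || !is.null(max_run)) {
    for (i in seq_len(nrow(pr))) {
      core <- pr$core[i]
      if (!is.null(max_run) &&
          max(rle(strsplit(core, "")[[1]])$lengths) > max_run) {
        reason[i] <- "homopolymer"
        next
      }
      if (!is.null(min_entropy) &&
          .dinucleotide_entropy(core) < min_entropy)
        reason[i] <- "low_complexity"
    }
  }

  if (!is.null(background) && !is.null(kmer)) {
    counts <- .kmer_counts(background, as.integer(kmer))
    for (i in which(is.na(reason))) {
      kms <- .seq_kmers(pr$core[i], as.integer(kmer))
      hits <- counts[kms]; hits[is.na(hits)] <- 0L
      if (any(hits >= max_hits)) reason[i] <- "non_unique_kmer"
    }
  }

  if (!is.null(gc_bounds)) {
    gc <- vapply(pr$core, function(s)
      mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1))
    bad <- is.na(reason) & (gc < gc_bounds[1] | gc > gc_bounds[2])
    reason[bad] <- "gc_out_of_bounds"
  }

  removed <- !is.na(reason)
  out <- .probe_set(ps$target_name, ps$region_length,
                    pr[!removed, , drop = FALSE], tail = ps$tail)
  rownames(out$probes) <- NULL
  attr(out, "filtered") <- data.frame(start = pr$start[removed],
                                      core = pr$core[removed],
                                      reason = reason[removed])
  out
}

.seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

.kmer_counts <- function(background, k) {
  if (inherits(background, "DNAStringSet"))
    background <- as.character(background)
  all <- unlist(lapply(toupper(background), .seq_kmers, k = k))
  tb <- table(all)
  setNames(as.integer(tb), names(tb))
}

## Shannon entropy (bits) of the overlapping-dinucleotide composition
.dinucleotide_entropy <- function(s) {
  di <- .seq_kmers(s, 2L)
  p <- table(di) / length(di)
  -sum(p * log2(p))
}

#' Append the common 3' detection tail
#'
#' Every probe carries the same 3' common sequence, the landing site for
#' the fluorescent detection oligos; the default is the assay's standard
#' 20-mer `TAGTTTCAGCTTTCCGCAAC`, giving 50-nt full oligos from 30-nt
#' cores.
#'
#' @param ps a `probe_set`.
#' @param tail nonempty A/C/G/T string appended at the 3' end of each
#'   core.
#' @return the `probe_set` with `full_seq = core + tail`.
#' @export
append_common_tail <- function(ps, tail = "TAGTTTCAGCTTTCCGCAAC") {
  stopifnot(inherits(ps, "probe_set"))
  if (!is.character(tail) || length(tail) != 1L || !nzchar(tail))
    stop("tail must be a nonempty sequence")
  tail <- toupper(tail)
  if (grepl("[^ACGT]", tail)) stop("tail must contain only A, C, G or T")
  ps$tail <- tail
  if (nrow(ps$probes) > 0)
    ps$probes$full_seq <- paste0(ps$probes$core, tail)
  ps
}

#' Write a probe set as FASTA and TSV
#'
#' FASTA headers are `target|start-end`; the TSV carries coordinates,
#' core and full sequences.
#'
#' @param ps a `probe_set`.
#' @param fasta_path,tsv_path output paths (`NULL` skips that output).
#' @return invisibly, a list of the written paths.
#' @export
write_probes <- function(ps, fasta_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(ps, "probe_set"))
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(ps$probes$full_seq)
    names(seqs) <- sprintf("%s|%d-%d", ps$target_name,
                           ps$probes$start, ps$probes$end)
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(tsv_path))
    write.table(ps$probes, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}
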
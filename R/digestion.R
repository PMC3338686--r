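#' Read clone sequences from a FASTA file
#'
#' @param path FASTA file of cloned marker-gene amplicons (IUPAC nucleotide
#'   alphabet; degenerate codes allowed).
#' @return data.frame with `clone_id` and `sequence` (uppercase character).
#' @export
read_clones <- function(path) {
  .check(file.exists(path), "FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  data.frame(clone_id = names(ss), sequence = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' amoA primer pair
#'
#' The standard amoA amplicon primers; the forward primer carries the
#' fluorescent label in T-RFLP, so terminal fragments are measured from its
#' first base. The reverse primer contains the degenerate IUPAC codes K
#' (G/T) and S (G/C).
#'
#' @format character scalars.
#' @export
AMOA_FWD_PRIMER <- "GGGGTTTCTACTGGTGGT"

#' @rdname AMOA_FWD_PRIMER
#' @export
AMOA_REV_PRIMER <- "CCCCTCKGSAAAGCCTTCTTC"

#' Orient a clone sequence by its labeled forward primer
#'
#' Searches for the forward (labeled) primer on both strands with IUPAC-aware
#' matching (degenerate codes in primer or template match their base sets)
#' allowing up to `max_mismatch` mismatches, and returns the amplicon written
#' 5' to 3' starting at the first base of the forward primer. Cloned inserts
#' can sit in the vector in either orientation, so a hit on the minus strand
#' returns the reverse complement.
#'
#' The amplicon runs from the forward primer to the binding site of the
#' reverse primer; when the reverse primer's complement is found downstream
#' (IUPAC-aware, e.g. K matching G/T and S matching G/C), the returned
#' amplicon is trimmed there, removing any flanking vector sequence from
#' cloned inserts. If it is absent the sequence is kept to its end.
#'
#' @param sequence nucleotide string (IUPAC codes allowed).
#' @param fwd_primer labeled forward primer (default the amoA forward
#'   primer).
#' @param rev_primer reverse primer, written 5' to 3' on the opposite strand
#'   (default the amoA reverse primer).
#' @param max_mismatch mismatches tolerated in the primer match (default 1,
#'   allowing for PCR/cloning errors).
#' @return list with `amplicon` (character, starting at the primer's first
#'   base) and `orientation` (`"forward"` or `"reverse-complemented"`).
#' @export
orient_by_primer <- function(sequence, fwd_primer = AMOA_FWD_PRIMER,
                             rev_primer = AMOA_REV_PRIMER,
                             max_mismatch = 1) {
  seq_fwd <- Biostrings::DNAString(toupper(sequence))
  seq_rc <- Biostrings::reverseComplement(seq_fwd)
  hit <- function(subject, pattern) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatch, fixed = FALSE)
    if (length(m) == 0) NULL else m
  }
  pos_f <- hit(seq_fwd, fwd_primer)
  pos_r <- hit(seq_rc, fwd_primer)
  if (is.null(pos_f) && is.null(pos_r)) {
    stop("forward primer not found on either strand", call. = FALSE)
  }
  if (!is.null(pos_f) && !is.null(pos_r)) {
    stop("forward primer found on both strands: orientation ambiguous", call. = FALSE)
  }
  oriented <- if (!is.null(pos_f)) seq_fwd else seq_rc
  start <- Biostrings::start(if (!is.null(pos_f)) pos_f else pos_r)[1]
  amp <- oriented[start:length(oriented)]
  # trim at the reverse primer's binding site (its reverse complement on
  # this strand), if present downstream of the forward primer
  rc_rev <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  mrev <- hit(amp, as.character(rc_rev))
  if (!is.null(mrev)) {
    amp <- amp[1:Biostrings::end(mrev)[length(mrev)]]
  }
  list(amplicon = as.character(amp),
       orientation = if (!is.null(pos_f)) "forward" else "reverse-complemented")
}

#' Predict the terminal restriction fragment length of an amplicon
#'
#' Scans the oriented amplicon 5' to 3' for the first exact occurrence of the
#' restriction recognition site and returns the length of the labeled
#' terminal fragment: the 0-based start index of the site plus `cut_offset`
#' (TaqI recognizes TCGA and cleaves after the T, so `cut_offset = 1`). The
#' labeled primer bases count toward the fragment length. If no site occurs,
#' the fragment is the whole amplicon and `cut_found` is `FALSE`. A site
#' window containing degenerate IUPAC codes counts only if every expansion of
#' the window contains the site (which requires the exact bases); when an
#' earlier degenerate-compatible window is skipped, a warning is issued.
#'
#' @param amplicon oriented sequence (labeled end first).
#' @param enzyme_site recognition sequence (default `"TCGA"`, TaqI).
#' @param cut_offset bases between the site start and the cut on the labeled
#'   strand (default 1 for T^CGA).
#' @return list with `predicted_trf` (integer bp) and `cut_found` (logical).
#' @export
predict_trf <- function(amplicon, enzyme_site = "TCGA", cut_offset = 1) {
  amplicon <- toupper(amplicon)
  exact_pos <- as.integer(regexpr(enzyme_site, amplicon, fixed = TRUE))
  # IUPAC-compatible hits that are not exact are uncertain sites: flag them
  subj <- Biostrings::DNAString(amplicon)
  compat <- Biostrings::matchPattern(enzyme_site, subj, fixed = FALSE)
  compat_pos <- if (length(compat) > 0) Biostrings::start(compat)[1] else NA_integer_
  if (!is.na(compat_pos) && (exact_pos == -1L || compat_pos < exact_pos)) {
    warning(sprintf("degenerate bases form a possible %s site at position %d; counted only as uncertain (conservative rule)",
                    enzyme_site, compat_pos), call. = FALSE)
  }
  if (exact_pos == -1L) {
    list(predicted_trf = nchar(amplicon), cut_found = FALSE)
  } else {
    list(predicted_trf = as.integer(exact_pos - 1L + cut_offset), cut_found = TRUE)
  }
}

#' Assign predicted clone T-RFs to observed profile bins
#'
#' Each clone is matched to the nearest bin within `tolerance_bp`; the
#' default of 3 bp sits in the middle of the 1-7 bp discrepancy commonly
#' reported between sequence-predicted and electrophoretically observed
#' fragment lengths. Exact ties between two bins are broken toward the
#' smaller bin with a warning; clones with no bin in range are flagged
#' unmatched (`matched_bin = NA`).
#'
#' @param results data.frame with at least `clone_id` and `predicted_trf`
#'   (as produced by [digest_clones()]).
#' @param bins numeric vector of observed T-RF bin labels (bp).
#' @param tolerance_bp matching tolerance (bp).
#' @return `results` with columns `matched_bin` and `offset_bp`
#'   (predicted - matched) appended.
#' @export
assign_clones <- function(results, bins, tolerance_bp = 3) {
  .check(length(bins) > 0, "bins must be non-empty")
  bins <- sort(as.numeric(bins))
  matched <- offset <- rep(NA_real_, nrow(results))
  for (i in seq_len(nrow(results))) {
    d <- abs(results$predicted_trf[i] - bins)
    if (min(d) > tolerance_bp) next
    hits <- which(d == min(d))
    if (length(hits) > 1) {
      warning(sprintf("clone %s: tie between bins %s; matched to the smaller",
                      results$clone_id[i], paste(bins[hits], collapse = " and ")),
              call. = FALSE)
    }
    matched[i] <- bins[hits[1]]
    offset[i] <- results$predicted_trf[i] - matched[i]
  }
  results$matched_bin <- matched
  results$offset_bp <- offset
  results
}

#' In-silico clone T-RFLP: orient, digest, and assign
#'
#' End-to-end surrogate for clone T-RFLP: each clone is oriented by the
#' labeled forward primer, the terminal fragment length predicted from the
#' first restriction site, and the prediction matched to the observed
#' community bins.
#'
#' @param clones data.frame with `clone_id`, `sequence` (see
#'   [read_clones()]).
#' @param bins observed T-RF bin labels; `NULL` skips assignment.
#' @param fwd_primer,rev_primer,max_mismatch passed to [orient_by_primer()].
#' @param enzyme_site,cut_offset passed to [predict_trf()].
#' @param tolerance_bp passed to [assign_clones()].
#' @return data.frame with `clone_id`, `orientation`, `predicted_trf`,
#'   `cut_found` and, if bins were given, `matched_bin`, `offset_bp`.
#' @export
digest_clones <- function(clones, bins = NULL,
                          fwd_primer = AMOA_FWD_PRIMER,
                          rev_primer = AMOA_REV_PRIMER, max_mismatch = 1,
                          enzyme_site = "TCGA", cut_offset = 1,
                          tolerance_bp = 3) {
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    ori <- orient_by_primer(clones$sequence[i], fwd_primer, rev_primer, max_mismatch)
    dg <- predict_trf(ori$amplicon, enzyme_site, cut_offset)
    data.frame(clone_id = clones$clone_id[i], orientation = ori$orientation,
               predicted_trf = dg$predicted_trf, cut_found = dg$cut_found,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(bins)) res <- assign_clones(res, bins, tolerance_bp)
  res
}
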
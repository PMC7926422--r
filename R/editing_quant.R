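# Quantification of C-to-U editing from per-position nucleotide counts and
# differential editing calls between two genotypes.
#
# Editing is read out as apparent C-to-T conversion in reads from the
# transcript strand: at a reference C on a forward-strand transcript, edited
# reads carry T; on a reverse-strand transcript the reference shows G and
# edited reads carry A. The denominator is restricted to the two bases that
# can arise from the edited/unedited states; other bases are treated as
# sequencing noise (an all-bases denominator is available via `denominator`).

#' Construct an editing observation from edited/total read counts
#'
#' @param edited number of reads carrying the edited base.
#' @param total edited + unedited reads. When 0 the extent is undefined and
#'   the observation is flagged (`defined = FALSE`), not an error.
#' @return object of class `editing_obs`: `edited`, `total`, `extent`
#'   (fraction in \[0,1\]), `defined`.
#' @export
editing_observation <- function(edited, total) {
  edited <- as.numeric(edited); total <- as.numeric(total)
  if (is.na(edited) || is.na(total) || edited < 0 || total < 0 || edited > total)
    stopf("need 0 <= edited <= total (got edited=%s, total=%s)", edited, total)
  structure(list(edited = edited, total = total,
                 extent = if (total > 0) edited / total else NA_real_,
                 defined = total > 0),
            class = "editing_obs")
}

#' @export
print.editing_obs <- function(x, ...) {
  if (x$defined)
    cat(sprintf("editing: %g/%g reads (%.2f%%)\n", x$edited, x$total,
                100 * x$extent))
  else cat("editing: undefined (no informative reads)\n")
  invisible(x)
}

#' Editing extent at one position from its nucleotide counts
#'
#' @param counts named numeric vector (or one-row data frame) with entries
#'   `A`, `C`, `G`, `T` — read counts on the forward reference strand.
#' @param strand transcript strand: `"+"` counts `edited = T`,
#'   `total = C + T`; `"-"` counts `edited = A`, `total = G + A` (the
#'   reference shows G where the transcript has C).
#' @param denominator `"edited_unedited"` (default, the two informative
#'   bases) or `"all"` (all four bases).
#' @return an [editing_observation()].
#' @export
editing_extent <- function(counts, strand = c("+", "-"),
                           denominator = c("edited_unedited", "all")) {
  strand <- match.arg(strand)
  denominator <- match.arg(denominator)
  if (is.data.frame(counts)) counts <- unlist(counts[1, c("A", "C", "G", "T")])
  counts <- counts[c("A", "C", "G", "T")]
  if (any(is.na(counts)) || any(counts < 0))
    stopf("counts must be non-negative A/C/G/T values")
  edited <- if (strand == "+") counts[["T"]] else counts[["A"]]
  unedited <- if (strand == "+") counts[["C"]] else counts[["G"]]
  total <- if (denominator == "all") sum(counts) else edited + unedited
  editing_observation(edited, total)
}

#' Two-sided Fisher exact test for differential editing
#'
#' Tests association in the 2x2 table
#' `[[edited_a, unedited_a], [edited_b, unedited_b]]` by exact hypergeometric
#' enumeration in log space (no normal approximation). Two-sidedness follows
#' the minimum-likelihood convention: the p-value sums the probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (within a 1 + 1e-7 relative guard against
#' floating-point ties).
#'
#' @param obs_a,obs_b [editing_observation()]s (or lists with `edited` and
#'   `total`).
#' @return the two-sided p-value.
#' @export
fisher_differential <- function(obs_a, obs_b) {
  a <- obs_a$edited; b <- obs_a$total - obs_a$edited
  c_ <- obs_b$edited; d <- obs_b$total - obs_b$edited
  if (any(c(a, b, c_, d) < 0)) stopf("negative counts in 2x2 table")
  if (obs_a$total == 0 || obs_b$total == 0)
    stopf("both groups need total > 0")
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs_logp <- logp[support == a]
  min(1, sum(exp(logp[logp <= obs_logp + log(1 + 1e-7)])))
}

#' Simes-Hochberg step-up adjustment of p-values
#'
#' Wraps `stats::p.adjust(method = "hochberg")`: with p-values sorted
#' ascending, adjusted p(i) = min over j >= i of (m - j + 1) p(j), clipped
#' at 1 and returned in input order. Controls family-wise error under
#' non-negative dependence.
#'
#' @param p numeric vector of raw p-values in \[0,1\].
#' @return adjusted p-values, same order and length.
#' @export
adjust_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "hochberg")
}

#' Pseudocounted odds ratio between two editing observations
#'
#' @inheritParams fisher_differential
#' @param pseudocount added to all four cells before forming the ratio so it
#'   stays finite and positive with zero cells (default 0.5).
#' @return `((edited_a + p)(unedited_b + p)) / ((unedited_a + p)(edited_b + p))`.
#' @export
odds_ratio <- function(obs_a, obs_b, pseudocount = 0.5) {
  ua <- obs_a$total - obs_a$edited
  ub <- obs_b$total - obs_b$edited
  ((obs_a$edited + pseudocount) * (ub + pseudocount)) /
    ((ua + pseudocount) * (obs_b$edited + pseudocount))
}

check_count_matrix <- function(x, label) {
  need <- c("position", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stopf("count matrix %s lacks column(s): %s", label,
          paste(miss, collapse = ", "))
  if (is.null(x$strand)) x$strand <- "+"
  if (any(x[, c("A", "C", "G", "T")] < 0)) stopf("negative counts in %s", label)
  x
}

#' Read (or normalise) a per-position nucleotide count table
#'
#' Accepts the pre-tabulated pileup-count TSV the pipeline prefers:
#' columns `sample_id` (optional), `position`, `ref`, `A`, `C`, `G`, `T`,
#' optional `strand`. Duplicate `(sample, position)` rows are summed with a
#' warning. This is the "identity ingest" path; see
#' [count_from_alignments()] for the optional alignment adapter.
#'
#' @param x TSV path or data frame.
#' @return data frame of class `site_count_matrix`, one row per position
#'   (per sample if `sample_id` present).
#' @export
count_from_pileup <- function(x) {
  df <- if (is.data.frame(x)) x else {
    out <- tryCatch(utils::read.delim(x, comment.char = "#",
                                      stringsAsFactors = FALSE),
                    error = function(e) stopf("malformed count table '%s': %s",
                                              x, conditionMessage(e)))
    out
  }
  df <- check_count_matrix(df, "input")
  key <- if (!is.null(df$sample_id)) paste(df$sample_id, df$position)
         else as.character(df$position)
  if (anyDuplicated(key)) {
    warning("duplicate (sample, position) rows summed", call. = FALSE)
    first <- !duplicated(key)
    agg <- rowsum(df[, c("A", "C", "G", "T")], key, reorder = FALSE)
    df2 <- df[first, , drop = FALSE]
    df2[, c("A", "C", "G", "T")] <- agg[match(key[first], rownames(agg)), ]
    df <- df2
  }
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_count_matrix", "data.frame")
  df
}

#' Count nucleotides per reference position from a SAM/BAM alignment
#'
#' Optional adapter around `Rsamtools::pileup()` for coordinate-sorted
#' alignments over a supplied reference; applies mapping- and base-quality
#' filters (these defaults are recorded in the result's attributes).
#'
#' @param file SAM or BAM path (SAM is converted on the fly).
#' @param reference FASTA path for the reference (used for the `ref` column).
#' @param min_mapq,min_baseq quality filters (defaults 10 and 20).
#' @return a `site_count_matrix` data frame.
#' @export
count_from_alignments <- function(file, reference, min_mapq = 10,
                                  min_baseq = 20) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stopf("count_from_alignments() needs the Rsamtools package")
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(file, ".bai"))) {
    Rsamtools::indexBam(file)
  }
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- vapply(strsplit(names(ref), "\\s+"), `[`, character(1), 1L)
  bam_contigs <- Rsamtools::scanBamHeader(file)[[1]]$targets
  missing_ctg <- setdiff(names(bam_contigs), names(ref))
  if (length(missing_ctg) > 0)
    stopf("alignment contig(s) not in reference: %s",
          paste(missing_ctg, collapse = ", "))
  pp <- Rsamtools::PileupParam(min_mapq = min_mapq,
                               min_base_quality = min_baseq,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               max_depth = 1e6, min_nucleotide_depth = 1)
  p <- Rsamtools::pileup(file, pileupParam = pp)
  p <- p[p$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  wide <- data.frame(position = sort(unique(p$pos)))
  for (b in c("A", "C", "G", "T")) {
    sel <- p[p$nucleotide == b, , drop = FALSE]
    wide[[b]] <- 0L
    wide[[b]][match(sel$pos, wide$position)] <- sel$count
  }
  ctg <- as.character(p$seqnames[match(wide$position, p$pos)])
  wide$ref <- vapply(seq_len(nrow(wide)), function(i)
    as.character(Biostrings::subseq(ref[[ctg[i]]], wide$position[i],
                                    wide$position[i])), character(1))
  wide$strand <- "+"
  wide <- wide[, c("position", "ref", "strand", "A", "C", "G", "T")]
  attr(wide, "filters") <- c(min_mapq = min_mapq, min_baseq = min_baseq)
  class(wide) <- c("site_count_matrix", "data.frame")
  wide
}

#' Call differentially edited sites between two genotypes
#'
#' Candidate positions are those whose reference base can be edited on the
#' annotated strand (C on `+`, G on `-`) and that show C/U variation (at
#' least one edited read) in at least one of the two count matrices. Each
#' candidate covered by at least `min_total` informative reads in both
#' matrices is tested with [fisher_differential()]; p-values are
#' Simes-Hochberg adjusted over the whole tested family. A site is
#' `significant` when `p_adj <= alpha` and the absolute extent change is at
#' least `delta_min`; significant sites are classified `"lost"` when the
#' second genotype retains at most `lost_factor` of the first genotype's
#' extent (a dramatic collapse of editing), otherwise `"down"`/`"up"` by the
#' direction of change.
#'
#' @param matrix_a,matrix_b `site_count_matrix` data frames (e.g. wild type
#'   and mutant) sharing positions.
#' @param alpha family-wise significance level (default 0.05).
#' @param min_total minimum informative reads per genotype (default 10).
#' @param delta_min minimum absolute change in editing extent (default 0.10).
#' @param lost_factor residual-extent fraction below which a significant
#'   decrease is called `"lost"` (default 0.05).
#' @param pseudocount passed to [odds_ratio()] (default 0.5).
#' @return data frame of class `differential_editing`, one row per tested
#'   site: counts, extents, `p_raw`, `p_adj`, `odds_ratio`, `direction`,
#'   `significant`, `call`. Positions skipped for low coverage are recorded
#'   in `attr(, "skipped")`.
#' @export
call_differential_sites <- function(matrix_a, matrix_b, alpha = 0.05,
                                    min_total = 10, delta_min = 0.10,
                                    lost_factor = 0.05, pseudocount = 0.5) {
  matrix_a <- check_count_matrix(as.data.frame(matrix_a), "A")
  matrix_b <- check_count_matrix(as.data.frame(matrix_b), "B")
  shared <- intersect(matrix_a$position, matrix_b$position)
  if (length(shared) == 0) stopf("count matrices share no positions")
  a <- matrix_a[match(shared, matrix_a$position), , drop = FALSE]
  b <- matrix_b[match(shared, matrix_b$position), , drop = FALSE]
  if (any(a$ref != b$ref))
    stopf("reference base mismatch at position(s) %s",
          paste(utils::head(shared[a$ref != b$ref], 3), collapse = ", "))

  editable <- (a$strand == "+" & a$ref == "C") | (a$strand == "-" & a$ref == "G")
  obs_a <- lapply(which(editable), function(i)
    editing_extent(a[i, ], strand = a$strand[i]))
  obs_b <- lapply(which(editable), function(i)
    editing_extent(b[i, ], strand = b$strand[i]))
  pos <- shared[editable]
  varying <- vapply(seq_along(pos), function(i)
    obs_a[[i]]$edited + obs_b[[i]]$edited > 0, logical(1))
  covered <- vapply(seq_along(pos), function(i)
    obs_a[[i]]$total >= min_total && obs_b[[i]]$total >= min_total, logical(1))
  skipped <- pos[varying & !covered]
  if (length(skipped) > 0)
    message(length(skipped), " position(s) below min_total skipped")
  keep <- which(varying & covered)
  if (length(keep) == 0) {
    res <- data.frame(position = integer(0))
  } else {
    p_raw <- vapply(keep, function(i)
      fisher_differential(obs_a[[i]], obs_b[[i]]), numeric(1))
    p_adj <- adjust_pvalues(p_raw)
    ea <- vapply(keep, function(i) obs_a[[i]]$extent, numeric(1))
    eb <- vapply(keep, function(i) obs_b[[i]]$extent, numeric(1))
    or <- vapply(keep, function(i)
      odds_ratio(obs_a[[i]], obs_b[[i]], pseudocount), numeric(1))
    significant <- p_adj <= alpha & abs(eb - ea) >= delta_min
    call <- rep("ns", length(keep))
    call[significant & eb < ea] <- "down"
    call[significant & eb > ea] <- "up"
    call[significant & eb <= lost_factor * ea] <- "lost"
    res <- data.frame(
      position = pos[keep],
      strand = a$strand[editable][keep],
      edited_a = vapply(keep, function(i) obs_a[[i]]$edited, numeric(1)),
      total_a = vapply(keep, function(i) obs_a[[i]]$total, numeric(1)),
      extent_a = ea,
      edited_b = vapply(keep, function(i) obs_b[[i]]$edited, numeric(1)),
      total_b = vapply(keep, function(i) obs_b[[i]]$total, numeric(1)),
      extent_b = eb,
      p_raw = p_raw, p_adj = p_adj, odds_ratio = or,
      direction = sign(eb - ea), significant = significant, call = call,
      stringsAsFactors = FALSE)
  }
  attr(res, "skipped") <- skipped
  attr(res, "params") <- list(alpha = alpha, min_total = min_total,
                              delta_min = delta_min, lost_factor = lost_factor,
                              pseudocount = pseudocount)
  class(res) <- c("differential_editing", "data.frame")
  res
}

#' @export
print.differential_editing <- function(x, digits = 3, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "differential editing: %d site(s) tested, %d significant (alpha=%g, min_total=%g, delta_min=%g)\n",
    nrow(x), sum(x$significant), p$alpha, p$min_total, p$delta_min))
  if (nrow(x) > 0) print(as.data.frame(x), digits = digits)
  invisible(x)
}

#' @export
summary.differential_editing <- function(object, ...) {
  tab <- table(factor(object$call, levels = c("lost", "down", "up", "ns")))
  structure(list(n_tested = nrow(object), n_significant = sum(object$significant),
                 calls = tab, n_skipped = length(attr(object, "skipped")),
                 params = attr(object, "params")),
            class = "summary.differential_editing")
}

#' @export
print.summary.differential_editing <- function(x, ...) {
  cat(sprintf("%d site(s) tested, %d significant, %d skipped for coverage\n",
              x$n_tested, x$n_significant, x$n_skipped))
  print(x$calls)
  invisible(x)
}

#' Consequence of a C-to-U edit on the encoded protein
#'
#' Substitutes U (read as T in the DNA frame) at a CDS position, translates
#' the affected codon with the standard genetic code and reports whether the
#' change is synonymous.
#'
#' @param cds in-frame coding sequence (DNA or RNA string, length a multiple
#'   of 3 at least up to the edited codon).
#' @param position 1-based position of the edited C within the CDS; the base
#'   there must be C.
#' @return list: `ref_codon`, `ref_aa`, `edited_codon`, `edited_aa`,
#'   `synonymous`.
#' @export
codon_effect <- function(cds, position) {
  bases <- strsplit(toupper(gsub("U", "T", cds)), "", fixed = TRUE)[[1]]
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > length(bases))
    stopf("edit position %s outside the CDS (length %d)", position,
          length(bases))
  if (bases[position] != "C")
    stopf("base at CDS position %d is %s, not C", position, bases[position])
  codon_i <- (position - 1L) %/% 3L
  idx <- codon_i * 3L + 1:3
  if (max(idx) > length(bases))
    stopf("CDS truncated inside the edited codon")
  ref_codon <- paste(bases[idx], collapse = "")
  edited <- bases; edited[position] <- "T"
  edited_codon <- paste(edited[idx], collapse = "")
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  edited_aa <- unname(Biostrings::GENETIC_CODE[edited_codon])
  list(ref_codon = ref_codon, ref_aa = ref_aa,
       edited_codon = edited_codon, edited_aa = edited_aa,
       synonymous = identical(ref_aa, edited_aa))
}
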
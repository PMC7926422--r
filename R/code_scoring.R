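# The PPR-RNA recognition code as a set of empirical log-ratio scoring
# tables, trained from alignments of known editing factors to their target
# sites, plus the alignment/scoring/ranking machinery built on top of them.

#' Build PPR-code scoring tables from factor-target alignment observations
#'
#' For each motif type independently, observations are tabulated as a
#' (aa5/aa_last pair) x (nucleotide) contingency table of summed weights.
#' The score for a cell is
#' \deqn{\log\frac{p + \mathrm{observed}}{p + \mathrm{expected}}}
#' (natural log, pseudocount \eqn{p = 10} by default), where the expected
#' count is the two-way independence expectation computed from the training
#' observations themselves: row total x column total / grand total. A pair
#' never seen in training has observed = expected = 0 for every base, hence
#' score 0; the pseudocount keeps rare observations from dominating.
#'
#' @param observations data frame with columns `motif_type`, `aa5`,
#'   `aa_last`, `nucleotide` (A/C/G/U; T read as U) and optionally `weight`
#'   (non-negative, default 1).
#' @param pseudocount positive real added to both observed and expected
#'   counts (default 10).
#' @return an object of class `ppr_code`: per-motif-type score matrices
#'   (rows = `aa5|aa_last` pairs, columns A/C/G/U) plus training metadata.
#'   Use [score_protein_site()] or [predict.ppr_code()] to apply it.
#' @seealso [score_lookup()], [write_scoring_tables()]
#' @export
build_scoring_tables <- function(observations, pseudocount = 10) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stopf("pseudocount must be a single positive number")
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0) stopf("empty observation set")
  need <- c("motif_type", "aa5", "aa_last", "nucleotide")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0)
    stopf("observations lack column(s): %s", paste(miss, collapse = ", "))
  if (is.null(observations$weight)) observations$weight <- 1
  if (any(observations$weight < 0)) stopf("weights must be >= 0")
  observations$nucleotide <- as_rna(observations$nucleotide)
  bad <- setdiff(unique(observations$nucleotide), RNA_ALPHABET)
  if (length(bad) > 0)
    stopf("invalid nucleotide(s): %s", paste(bad, collapse = ","))
  observations$aa5 <- check_aa(observations$aa5, "aa5")
  observations$aa_last <- check_aa(observations$aa_last, "aa_last")

  tables <- lapply(split(observations, observations$motif_type), function(obs) {
    pair <- paste(obs$aa5, obs$aa_last, sep = "|")
    counts <- matrix(0, nrow = length(unique(pair)), ncol = 4,
                     dimnames = list(sort(unique(pair)), RNA_ALPHABET))
    agg <- stats::aggregate(obs$weight,
                            by = list(pair = pair, nuc = obs$nucleotide), FUN = sum)
    counts[cbind(agg$pair, agg$nuc)] <- agg$x
    grand <- sum(counts)
    expected <- if (grand > 0)
      outer(rowSums(counts), colSums(counts)) / grand
    else counts
    list(scores = log((pseudocount + counts) / (pseudocount + expected)),
         n_obs = grand)
  })

  structure(list(
    tables = lapply(tables, `[[`, "scores"),
    n_obs = vapply(tables, `[[`, numeric(1), "n_obs"),
    pseudocount = pseudocount),
    class = "ppr_code")
}

#' @export
print.ppr_code <- function(x, ...) {
  cat(sprintf("PPR-code scoring tables (pseudocount %g)\n", x$pseudocount))
  for (mt in names(x$tables))
    cat(sprintf("  %-4s %4d aa5/aa_last pair(s), %g observation(s)\n",
                mt, nrow(x$tables[[mt]]), x$n_obs[[mt]]))
  invisible(x)
}

#' Look up PPR-code scores
#'
#' Vectorised lookup of `(motif_type, aa5, aa_last, nucleotide)` tuples.
#' Unseen pairs and gap residues score 0 (the formula's value for an
#' observed count of 0 with an expected count of 0).
#'
#' @param code a `ppr_code` object.
#' @param motif_type,aa5,aa_last,nucleotide parallel character vectors.
#' @param coarsen map fine motif-type labels (P1, S2, ...) onto coarse ones
#'   (P, S, ...) before lookup; useful when the tables carry coarse types.
#' @return numeric vector of scores.
#' @export
score_lookup <- function(code, motif_type, aa5, aa_last, nucleotide,
                         coarsen = FALSE) {
  stopifnot(inherits(code, "ppr_code"))
  if (coarsen) motif_type <- coarsen_motif_types(motif_type)
  nucleotide <- as_rna(nucleotide)
  pair <- paste(aa5, aa_last, sep = "|")
  out <- numeric(length(motif_type))
  gap <- aa5 == GAP | aa_last == GAP | is.na(nucleotide)
  for (mt in unique(motif_type[!gap])) {
    tab <- code$tables[[mt]]
    if (is.null(tab)) next  # motif type untrained: score 0
    sel <- which(motif_type == mt & !gap)
    ri <- match(pair[sel], rownames(tab))
    ok <- !is.na(ri)
    if (any(ok))
      out[sel[ok]] <- tab[cbind(ri[ok], match(nucleotide[sel[ok]], RNA_ALPHABET))]
  }
  out
}

#' Align the motifs of a PPR protein to an editing-site window
#'
#' The anchoring convention follows the geometry of PLS editing factors: the
#' E2 motif faces the nucleotide two positions upstream of the edited C
#' (offset -2, the C itself being offset 0), E1 faces -3, the C-terminal-most
#' P/L/S motif faces -4, and each step toward the protein's N terminus moves
#' one base further 5'. A protein without an E2 motif anchors its
#' C-terminal-most motif at `no_e2_anchor` (default -4). Motifs whose offset
#' falls 5' of the window start get `NA` positions (and later score 0).
#'
#' @param protein a `ppr_protein` with at least one motif.
#' @param site an `editing_site`.
#' @param anchor_offset offset of the E2 motif relative to the edited C
#'   (default -2).
#' @param no_e2_anchor offset of the C-terminal-most motif when E2 is absent
#'   (default -4).
#' @return data frame with one row per motif: `index`, `motif_type`, `aa5`,
#'   `aa_last`, `offset`, `window_pos` (1-based within the window, `NA` if
#'   off-window) and `nucleotide` (`NA` if off-window).
#' @export
align_motifs_to_site <- function(protein, site, anchor_offset = -2L,
                                 no_e2_anchor = -4L) {
  stopifnot(inherits(protein, "ppr_protein"), inherits(site, "editing_site"))
  m <- protein$motifs
  if (nrow(m) == 0) stopf("protein '%s' has no motifs", protein$protein_id)
  i_e2 <- match("E2", m$motif_type)
  if (is.na(i_e2)) {
    anchor_row <- nrow(m)
    anchor_off <- as.integer(no_e2_anchor)
  } else {
    anchor_row <- i_e2
    anchor_off <- as.integer(anchor_offset)
  }
  offsets <- anchor_off - (anchor_row - seq_len(nrow(m)))
  len <- nchar(site$window)
  pos <- len + offsets            # window index, 1-based; edited C at offset 0
  pos[pos < 1L | pos > len] <- NA_integer_
  bases <- strsplit(site$window, "", fixed = TRUE)[[1]]
  data.frame(index = m$index, motif_type = m$motif_type,
             aa5 = m$aa5, aa_last = m$aa_last,
             offset = offsets, window_pos = pos,
             nucleotide = ifelse(is.na(pos), NA_character_, bases[pos]),
             stringsAsFactors = FALSE)
}

#' Score a PPR protein against an editing site
#'
#' Aligns the protein's motifs to the site window (see
#' [align_motifs_to_site()]), looks up each motif-nucleotide pairing in the
#' scoring tables and sums the scores. Gap-residue motifs, motifs aligned
#' off the 5' end of the window, and (by default) the E1/E2/DYW C-terminal
#' motifs contribute exactly 0.
#'
#' @inheritParams align_motifs_to_site
#' @param code a `ppr_code` object.
#' @param score_terminal also score E1/E2/DYW motifs if the tables carry
#'   those motif types (default `FALSE`: they only anchor the alignment).
#' @param coarsen passed to [score_lookup()].
#' @return object of class `site_score`: list with `protein_id`, `site_id`,
#'   `total` and a `per_motif` data frame.
#' @export
score_protein_site <- function(protein, site, code, score_terminal = FALSE,
                               coarsen = FALSE, anchor_offset = -2L,
                               no_e2_anchor = -4L) {
  aln <- align_motifs_to_site(protein, site, anchor_offset = anchor_offset,
                              no_e2_anchor = no_e2_anchor)
  scored <- !is.na(aln$window_pos) & aln$aa5 != GAP & aln$aa_last != GAP
  if (!score_terminal) scored <- scored & aln$motif_type %in% PLS_TYPES
  aln$score <- 0
  if (any(scored))
    aln$score[scored] <- score_lookup(code, aln$motif_type[scored],
                                      aln$aa5[scored], aln$aa_last[scored],
                                      aln$nucleotide[scored], coarsen = coarsen)
  aln$scored <- scored
  structure(list(protein_id = protein$protein_id, site_id = site$site_id,
                 total = sum(aln$score), per_motif = aln),
            class = "site_score")
}

#' @export
print.site_score <- function(x, digits = 3, ...) {
  cat(sprintf("score of '%s' at site '%s': %.*f (%d of %d motifs scored)\n",
              x$protein_id, x$site_id, digits, x$total,
              sum(x$per_motif$scored), nrow(x$per_motif)))
  print(x$per_motif, digits = digits)
  invisible(x)
}

#' Predict binding scores from a fitted PPR code
#'
#' Convenience method: `predict(code, protein, site)` is
#' [score_protein_site()]; with a list of proteins it returns
#' [rank_candidates()] output.
#'
#' @param object a `ppr_code`.
#' @param protein a `ppr_protein` or list of them.
#' @param site an `editing_site`.
#' @param ... passed on to [score_protein_site()]/[rank_candidates()].
#' @return a `site_score`, or a ranking data frame for a protein list.
#' @export
predict.ppr_code <- function(object, protein, site, ...) {
  if (inherits(protein, "ppr_protein"))
    score_protein_site(protein, site, object, ...)
  else
    rank_candidates(site, protein, object, ...)
}

#' Rank candidate editing factors at a site
#'
#' Scores every protein against the site and ranks them in descending score
#' order with competition ranking: a protein that scores strictly better
#' than k others has rank k + 1, and ties share the smaller rank.
#'
#' @param site an `editing_site`.
#' @param proteins list of `ppr_protein` objects.
#' @param code a `ppr_code`.
#' @param ... passed to [score_protein_site()].
#' @return data frame `protein_id`, `total`, `rank`, sorted by rank.
#' @export
rank_candidates <- function(site, proteins, code, ...) {
  if (length(proteins) == 0) stopf("no proteins to rank")
  totals <- vapply(proteins, function(p)
    score_protein_site(p, site, code, ...)$total, numeric(1))
  ids <- vapply(proteins, `[[`, character(1), "protein_id")
  res <- data.frame(protein_id = ids, total = totals,
                    rank = rank(-totals, ties.method = "min"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$rank, res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarise the score distribution of a candidate set at a site
#'
#' @inheritParams rank_candidates
#' @param protein_id optional protein whose score (and rank) to report; if it
#'   is not among the candidates the result carries `found = FALSE` rather
#'   than an error.
#' @return list with `n`, `min`, `max`, `quantiles` (25/50/75%), and when
#'   `protein_id` is given: `protein_id`, `found`, `score`, `rank`.
#' @export
score_distribution <- function(site, proteins, code, protein_id = NULL, ...) {
  ranking <- rank_candidates(site, proteins, code, ...)
  out <- list(site_id = site$site_id, n = nrow(ranking),
              min = min(ranking$total), max = max(ranking$total),
              quantiles = stats::quantile(ranking$total, c(.25, .5, .75),
                                          names = TRUE))
  if (!is.null(protein_id)) {
    i <- match(protein_id, ranking$protein_id)
    out$protein_id <- protein_id
    out$found <- !is.na(i)
    out$score <- if (out$found) ranking$total[i] else NA_real_
    out$rank <- if (out$found) ranking$rank[i] else NA_integer_
  }
  out
}

#' Write scoring tables to a directory of TSV files
#'
#' One file per motif type (`<type>.tsv`), columns `aa5`, `aa_last`, `A`,
#' `C`, `G`, `U`. A small `metadata.tsv` records the pseudocount and per-type
#' observation totals so [read_scoring_tables()] can round-trip the object.
#'
#' @param code a `ppr_code`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scoring_tables <- function(code, dir) {
  stopifnot(inherits(code, "ppr_code"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mt in names(code$tables)) {
    tab <- code$tables[[mt]]
    pairs <- do.call(rbind, strsplit(rownames(tab), "|", fixed = TRUE))
    df <- data.frame(aa5 = pairs[, 1], aa_last = pairs[, 2],
                     tab, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(mt, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(motif_type = names(code$tables),
               n_obs = unname(code$n_obs),
               pseudocount = code$pseudocount),
    file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read scoring tables written by [write_scoring_tables()]
#'
#' @param dir directory containing `<motif_type>.tsv` files.
#' @return a `ppr_code` object.
#' @export
read_scoring_tables <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  files <- files[basename(files) != "metadata.tsv"]
  if (length(files) == 0) stopf("no scoring-table TSVs in %s", dir)
  tables <- lapply(files, function(f) {
    df <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, RNA_ALPHABET, drop = FALSE])
    rownames(m) <- paste(df$aa5, df$aa_last, sep = "|")
    m
  })
  names(tables) <- sub("\\.tsv$", "", basename(files))
  pseudocount <- 10
  n_obs <- stats::setNames(rep(NA_real_, length(tables)), names(tables))
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    pseudocount <- meta$pseudocount[1]
    n_obs[meta$motif_type] <- meta$n_obs
  }
  structure(list(tables = tables, n_obs = n_obs, pseudocount = pseudocount),
            class = "ppr_code")
}
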
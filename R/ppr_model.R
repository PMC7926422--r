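# Domain model for PLS-class PPR proteins.
#
# A PLS editing factor is a tandem array of degenerate 35-aa helical repeats
# (P, L and S variants) followed by C-terminal E1/E2 motifs and, in DYW-class
# factors, a DYW deaminase domain. RNA recognition is read off two "code"
# residues per motif: the amino acids at motif position 5 and at the motif's
# last position.

#' Recognised PPR motif type labels
#'
#' Coarse (`P`, `L`, `S`), fine (`P1`, `P2`, `L1`, `L2`, `S1`, `S2`, `SS`)
#' and C-terminal (`E1`, `E2`, `DYW`) labels are accepted. Scoring tables are
#' keyed by the label as given; [coarsen_motif_types()] maps fine labels onto
#' coarse ones when a table set only carries coarse types.
#'
#' @export
PPR_MOTIF_TYPES <- c("P", "L", "S", "SS",
                     "P1", "P2", "L1", "L2", "S1", "S2",
                     "E1", "E2", "DYW")

# motif types that participate in the P/L/S tract (everything that is not
# C-terminal machinery)
PLS_TYPES <- c("P", "L", "S", "SS", "P1", "P2", "L1", "L2", "S1", "S2")

#' Map fine motif-type labels onto coarse ones
#'
#' `P1`/`P2` become `P`, `L1`/`L2` become `L`, `S1`/`S2`/`SS` become `S`;
#' all other labels pass through unchanged.
#'
#' @param types character vector of motif type labels.
#' @return character vector of the same length.
#' @export
coarsen_motif_types <- function(types) {
  map <- c(P1 = "P", P2 = "P", L1 = "L", L2 = "L",
           S1 = "S", S2 = "S", SS = "S")
  out <- unname(map[types])
  ifelse(is.na(out), types, out)
}

#' Construct a PPR motif
#'
#' @param index 1-based position of the motif in the array.
#' @param motif_type one of [PPR_MOTIF_TYPES].
#' @param aa5 single-letter amino acid at motif position 5, or `"-"` for an
#'   unannotatable (gap) residue.
#' @param aa_last single-letter amino acid at the motif's last position, or
#'   `"-"`.
#' @return a list of class `ppr_motif`.
#' @export
ppr_motif <- function(index, motif_type, aa5, aa_last) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L) stopf("motif index must be >= 1")
  if (!motif_type %in% PPR_MOTIF_TYPES)
    stopf("unknown motif type '%s' (expected one of %s)", motif_type,
          paste(PPR_MOTIF_TYPES, collapse = ", "))
  structure(list(index = index, motif_type = motif_type,
                 aa5 = check_aa(aa5, "aa5"),
                 aa_last = check_aa(aa_last, "aa_last")),
            class = "ppr_motif")
}

#' Code residues of a PPR motif
#'
#' Returns the (aa5, aa_last) pair that all scoring lookups use, together
#' with a `scorable` flag: a motif carrying a gap residue cannot be looked up
#' in a scoring table and contributes a score of 0.
#'
#' @param motif a `ppr_motif` (or any list with `aa5`/`aa_last` fields).
#' @return list with `aa5`, `aa_last`, `scorable`.
#' @export
code_residues <- function(motif) {
  list(aa5 = motif$aa5, aa_last = motif$aa_last,
       scorable = motif$aa5 != GAP && motif$aa_last != GAP)
}

derive_cterm <- function(types) {
  has <- c(E1 = "E1" %in% types, E2 = "E2" %in% types, DYW = "DYW" %in% types)
  if (!any(has)) return("none")
  paste(names(has)[has], collapse = "-")
}

#' Construct a PPR protein from its motif table
#'
#' @param protein_id identifier string.
#' @param motifs data frame with columns `index`, `motif_type`, `aa5`,
#'   `aa_last` (rows need not be pre-sorted).
#' @return an object of class `ppr_protein`: list with `protein_id`, `motifs`
#'   (sorted data frame) and `cterm` (derived label such as `"E1-E2-DYW"` or
#'   `"none"`).
#' @export
ppr_protein <- function(protein_id, motifs) {
  stopifnot(is.data.frame(motifs))
  need <- c("index", "motif_type", "aa5", "aa_last")
  miss <- setdiff(need, names(motifs))
  if (length(miss) > 0)
    stopf("motif table for '%s' lacks column(s): %s", protein_id,
          paste(miss, collapse = ", "))
  motifs <- motifs[order(motifs$index), need, drop = FALSE]
  motifs$index <- as.integer(motifs$index)
  motifs$motif_type <- as.character(motifs$motif_type)
  motifs$aa5 <- check_aa(as.character(motifs$aa5), "aa5")
  motifs$aa_last <- check_aa(as.character(motifs$aa_last), "aa_last")
  rownames(motifs) <- NULL

  if (nrow(motifs) > 0) {
    if (any(motifs$index < 1L)) stopf("'%s': motif indices must be >= 1", protein_id)
    if (anyDuplicated(motifs$index))
      stopf("'%s': duplicate motif index %s", protein_id,
            motifs$index[duplicated(motifs$index)][1])
    unknown <- setdiff(unique(motifs$motif_type), PPR_MOTIF_TYPES)
    if (length(unknown) > 0)
      stopf("'%s': unknown motif type '%s'", protein_id, unknown[1])
    for (e in c("E1", "E2")) {
      if (sum(motifs$motif_type == e) > 1L)
        stopf("'%s': more than one %s motif", protein_id, e)
    }
    i_e1 <- match("E1", motifs$motif_type)
    i_e2 <- match("E2", motifs$motif_type)
    if (!is.na(i_e1) && !is.na(i_e2) && i_e1 > i_e2)
      stopf("'%s': E1 must precede E2", protein_id)
    i_pls <- which(motifs$motif_type %in% PLS_TYPES)
    if (length(i_pls) > 0) {
      last_pls <- max(i_pls)
      if ((!is.na(i_e1) && i_e1 < last_pls) || (!is.na(i_e2) && i_e2 < last_pls))
        stopf("'%s': E1/E2 must follow all P/L/S motifs", protein_id)
    }
  }

  structure(list(protein_id = as.character(protein_id), motifs = motifs,
                 cterm = derive_cterm(motifs$motif_type)),
            class = "ppr_protein")
}

#' @export
print.ppr_protein <- function(x, ...) {
  n_pls <- sum(x$motifs$motif_type %in% PLS_TYPES)
  cat(sprintf("PPR protein '%s': %d motif(s) (%d P/L/S), C-terminus: %s\n",
              x$protein_id, nrow(x$motifs), n_pls, x$cterm))
  if (nrow(x$motifs) > 0) {
    cat(" array:", paste(x$motifs$motif_type, collapse = "-"), "\n")
    cat(" code residues:",
        paste(paste0(x$motifs$aa5, x$motifs$aa_last), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.ppr_protein <- function(x) nrow(x$motifs)

#' Parse a PPR motif annotation table
#'
#' Reads a motif annotation TSV (columns `protein_id`, `motif_index`,
#' `motif_type`, `aa5`, `aa_last`; `#` comment lines ignored) or an
#' equivalent data frame, and returns one [ppr_protein()] per protein with
#' motifs in ascending index order. Motif boundaries are taken as annotated;
#' they are never inferred from protein sequence.
#'
#' @param x path to a TSV file, or a data frame.
#' @return named list of `ppr_protein` objects (possibly empty).
#' @export
parse_ppr_annotation <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(structure(list(), names = character(0)))
  need <- c("protein_id", "motif_index", "motif_type", "aa5", "aa_last")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stopf("annotation lacks column(s): %s", paste(miss, collapse = ", "))
  out <- lapply(split(x, x$protein_id), function(rows) {
    ppr_protein(rows$protein_id[1],
                data.frame(index = rows$motif_index,
                           motif_type = rows$motif_type,
                           aa5 = rows$aa5, aa_last = rows$aa_last,
                           stringsAsFactors = FALSE))
  })
  out[unique(as.character(x$protein_id))]
}

#' Serialise PPR proteins back to the annotation table format
#'
#' Inverse of [parse_ppr_annotation()]: writing then re-parsing is lossless.
#'
#' @param proteins list of `ppr_protein` objects.
#' @param file optional path; when `NULL` the data frame is returned only.
#' @return the annotation data frame, invisibly when written to `file`.
#' @export
write_ppr_annotation <- function(proteins, file = NULL) {
  rows <- lapply(proteins, function(p) {
    if (nrow(p$motifs) == 0) return(NULL)
    data.frame(protein_id = p$protein_id, motif_index = p$motifs$index,
               motif_type = p$motifs$motif_type, aa5 = p$motifs$aa5,
               aa_last = p$motifs$aa_last, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- data.frame(protein_id = character(0),
                                    motif_index = integer(0),
                                    motif_type = character(0),
                                    aa5 = character(0), aa_last = character(0))
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Truncate a PPR protein at a premature stop
#'
#' Models a loss-of-function allele in which translation terminates inside
#' the motif at `stop_motif_index`: that motif and everything downstream
#' (including E1/E2/DYW) are removed.
#'
#' @param protein a `ppr_protein`.
#' @param stop_motif_index motif index (1-based) containing the stop; must
#'   lie within the protein's motif index range.
#' @return the truncated `ppr_protein` (its `cterm` is re-derived).
#' @export
truncate_protein <- function(protein, stop_motif_index) {
  stopifnot(inherits(protein, "ppr_protein"))
  stop_motif_index <- as.integer(stop_motif_index)
  n <- nrow(protein$motifs)
  if (is.na(stop_motif_index) || stop_motif_index < 1L ||
      stop_motif_index > max(protein$motifs$index, 0L))
    stopf("stop_motif_index %s out of range 1..%d", stop_motif_index,
          max(protein$motifs$index, 0L))
  keep <- protein$motifs[protein$motifs$index < stop_motif_index, , drop = FALSE]
  ppr_protein(protein$protein_id, keep)
}
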
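# Editing sites: a genome position plus the upstream RNA window a PPR
# protein is aligned against. The edited C is always the last base of the
# window, so alignment offsets are counted back from the window's 3' end.

#' Construct an editing site
#'
#' @param site_id identifier, conventionally `<gene>-<cds position>` (e.g.
#'   `nad1-493`).
#' @param window RNA sequence ending at the edited C; `T` is transparently
#'   read as `U` and case is ignored. For sites used in scoring, the window
#'   should extend at least `n_motifs + 2` nt so every motif can face a base.
#' @param genome_position 1-based position of the edited C on the forward
#'   reference strand (optional bookkeeping; scoring never uses it).
#' @param strand `"+"` or `"-"`, the transcript strand.
#' @param require_edited_c enforce that the last window base is `C`. Set to
#'   `FALSE` for non-editable orthologue sites, where the genome already
#'   carries `U`(T), `A` or `G` at the homologous position.
#' @return object of class `editing_site`.
#' @export
editing_site <- function(site_id, window, genome_position = NA_integer_,
                         strand = c("+", "-"), require_edited_c = TRUE) {
  strand <- match.arg(strand)
  bases <- rna_chars(window, sprintf("window of site '%s'", site_id))
  if (length(bases) < 1L) stopf("site '%s': empty window", site_id)
  if (require_edited_c && bases[length(bases)] != "C")
    stopf("site '%s': last window base must be the edited C (got %s)",
          site_id, bases[length(bases)])
  structure(list(site_id = as.character(site_id),
                 genome_position = as.integer(genome_position),
                 strand = strand,
                 window = paste(bases, collapse = ""),
                 edited_offset = length(bases)),
            class = "editing_site")
}

#' @export
print.editing_site <- function(x, ...) {
  cat(sprintf("editing site '%s' (%s%s): 5'-%s-3' (site base %s, window %d nt)\n",
              x$site_id,
              if (is.na(x$genome_position)) "pos ?" else paste0("pos ", x$genome_position),
              paste0(", ", x$strand),
              x$window, substr(x$window, nchar(x$window), nchar(x$window)),
              nchar(x$window)))
  invisible(x)
}

#' Read editing sites from a TSV table
#'
#' Expected columns: `site_id`, `position`, `strand`, `window`; `#` comments
#' ignored.
#'
#' @param file path, or a data frame with those columns.
#' @param require_edited_c passed to [editing_site()].
#' @return named list of `editing_site` objects.
#' @export
read_sites_tsv <- function(file, require_edited_c = TRUE) {
  df <- if (is.data.frame(file)) file else
    utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("site_id", "position", "strand", "window")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("sites table lacks column(s): %s", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    editing_site(df$site_id[i], df$window[i], df$position[i],
                 strand = df$strand[i], require_edited_c = require_edited_c))
  names(out) <- df$site_id
  out
}

#' Read editing-site windows from a FASTA file
#'
#' Each record id becomes the site id; the sequence is the window ending at
#' the edited C. DNA (`T`) and RNA (`U`) alphabets are both accepted.
#'
#' @param file FASTA path.
#' @param require_edited_c passed to [editing_site()].
#' @return named list of `editing_site` objects.
#' @export
read_sites_fasta <- function(file, require_edited_c = TRUE) {
  seqs <- Biostrings::readBStringSet(file)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(seqs), function(i)
    editing_site(ids[i], as.character(seqs[[i]]),
                 require_edited_c = require_edited_c))
  names(out) <- ids
  out
}
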
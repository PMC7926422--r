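# Cross-species comparison: do putative orthologues of an editing factor
# still score well against a site in species where the site is editable
# (genomic C) versus species where it is not (genomic T, rarely A or G)?

#' Construct a species/site record for the orthologue comparison
#'
#' @param species species label.
#' @param site_id which tracked site this record refers to.
#' @param window sequence upstream of (and including) the homologous
#'   position in that species' organellar genome.
#' @param editable `TRUE` when the site base is C (editing possible). When
#'   omitted it is derived from the window's last base.
#' @param protein the species' putative orthologue, a `ppr_protein`.
#' @return list of class `species_site_record`.
#' @export
species_site_record <- function(species, site_id, window, protein,
                                editable = NULL) {
  site_base <- substr(as_rna(window), nchar(window), nchar(window))
  if (is.null(editable)) editable <- site_base == "C"
  if (editable != (site_base == "C"))
    stopf("record %s/%s: editable flag inconsistent with site base '%s'",
          species, site_id, site_base)
  structure(list(
    species = species, site_id = site_id, editable = editable,
    site = editing_site(site_id, window, require_edited_c = FALSE),
    protein = protein), class = "species_site_record")
}

#' Score a panel of orthologues against their species' site sequences
#'
#' @param records list of [species_site_record()]s.
#' @param code a `ppr_code`.
#' @param ... passed to [score_protein_site()].
#' @return data frame `species`, `site_id`, `editable`, `score`, grouped by
#'   site. Scoring errors are re-raised with the species/site attached.
#' @export
score_orthologue_set <- function(records, code, ...) {
  rows <- lapply(records, function(r) {
    sc <- tryCatch(score_protein_site(r$protein, r$site, code, ...),
                   error = function(e)
                     stopf("scoring failed for %s at %s: %s", r$species,
                           r$site_id, conditionMessage(e)))
    data.frame(species = r$species, site_id = r$site_id,
               editable = r$editable, score = sc$total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$site_id, !out$editable, out$species), , drop = FALSE]
}

welch_onesided <- function(x, y, var_equal = FALSE) {
  # alternative: mean(x) > mean(y)
  if (stats::sd(c(x, y)) == 0 || (stats::sd(x) == 0 && stats::sd(y) == 0)) {
    d <- mean(x) - mean(y)
    return(list(statistic = sign(d) * if (d == 0) 0 else Inf,
                p.value = if (d > 0) 0 else if (d < 0) 1 else 0.5))
  }
  ht <- stats::t.test(x, y, alternative = "greater", var.equal = var_equal)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' One-sided t-test of editable versus non-editable site scores
#'
#' For each site, tests whether orthologue binding scores are higher in
#' species where the site is editable than in species where it is not
#' (alternative: mean(editable) > mean(non-editable)). The Welch
#' unequal-variance form is the default since group sizes and variances
#' across species panels are typically unbalanced; `var_equal = TRUE` gives
#' the pooled form. A site with fewer than 2 observations in either group is
#' returned flagged `testable = FALSE` rather than raising an error.
#'
#' @param scores data frame as returned by [score_orthologue_set()]
#'   (columns `site_id`, `editable`, `score`).
#' @param var_equal use the pooled-variance t-test (default `FALSE`, Welch).
#' @return data frame of class `ortho_comparison`, one row per site:
#'   group sizes and means, `t`, `p_one_sided`, `testable`.
#' @export
editable_vs_noneditable_test <- function(scores, var_equal = FALSE) {
  stopifnot(is.data.frame(scores),
            all(c("site_id", "editable", "score") %in% names(scores)))
  rows <- lapply(split(scores, scores$site_id), function(g) {
    e <- g$score[g$editable]
    ne <- g$score[!g$editable]
    out <- data.frame(site_id = g$site_id[1],
                      n_editable = length(e), n_noneditable = length(ne),
                      mean_editable = if (length(e)) mean(e) else NA_real_,
                      mean_noneditable = if (length(ne)) mean(ne) else NA_real_,
                      t = NA_real_, p_one_sided = NA_real_,
                      testable = length(e) >= 2 && length(ne) >= 2,
                      stringsAsFactors = FALSE)
    if (out$testable) {
      ht <- welch_onesided(e, ne, var_equal = var_equal)
      out$t <- ht$statistic
      out$p_one_sided <- ht$p.value
    }
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(res, "var_equal") <- var_equal
  class(res) <- c("ortho_comparison", "data.frame")
  res
}

#' @export
print.ortho_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("editable vs non-editable site scores (%s one-sided t-test)\n",
              if (attr(x, "var_equal")) "pooled" else "Welch"))
  print(as.data.frame(x), digits = digits)
  invisible(x)
}
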
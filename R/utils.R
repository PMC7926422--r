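# Internal helpers shared across modules.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
GAP <- "-"
RNA_ALPHABET <- c("A","C","G","U")

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Normalise a nucleotide string to uppercase RNA (T read as U).
#' @noRd
as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Split an RNA string into single bases, validating the alphabet.
#' @noRd
rna_chars <- function(x, what = "sequence") {
  ch <- strsplit(as_rna(x), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), RNA_ALPHABET)
  if (length(bad) > 0)
    stopf("invalid base(s) %s in %s (alphabet is A/C/G/U, T read as U)",
          paste(bad, collapse = ","), what)
  ch
}

check_aa <- function(x, field) {
  x <- toupper(x)
  bad <- setdiff(unique(x), c(AA_ALPHABET, GAP))
  if (length(bad) > 0)
    stopf("invalid amino acid(s) %s in %s (20-letter alphabet or '-')",
          paste(bad, collapse = ","), field)
  x
}

# Derive an independent 32-bit seed for a generator substream, so adding a
# new generator never perturbs the draws of an existing one.
substream_seed <- function(seed, stream) {
  offsets <- c(training = 11L, protein = 23L, counts = 37L, ortho = 53L,
               panel = 71L)
  if (!stream %in% names(offsets)) stopf("unknown substream '%s'", stream)
  as.integer((abs(as.numeric(seed)) * 2654435761 + offsets[[stream]] * 40503) %%
               2147483647)
}
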
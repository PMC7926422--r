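# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the code paths they are used to check.

# Exhaustive two-sided Fisher p-value: enumerate every table with the
# observed margins, compute each probability from binomial coefficients and
# sum those no more probable than the observed table.
fisher_enum_oracle <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_
  support <- max(0, k - r2):min(k, r1)
  lp <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(r1 + r2, k)
  prob <- exp(lp)
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Hochberg step-up from the definition: sort ascending, adjusted
# p(i) = min over j >= i of (m - j + 1) * p(j), clipped at 1, input order.
hochberg_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, (m - i + 1) * ps[i])
    adj[i] <- min(1, run)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# One-sided (mean(x) > mean(y)) permutation p-value on the mean difference.
perm_test_oracle <- function(x, y, n_perm = 4000L) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- mean(x) - mean(y)
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pooled), nx)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

# Minimal protein builder: P/L/S types with given code residues, optional
# E1/E2 appended.
make_protein <- function(aa5, aa_last, types = NULL, id = "p", e_term = TRUE) {
  n <- length(aa5)
  if (is.null(types)) types <- rep(c("P", "L", "S"), length.out = n)
  if (e_term) {
    types <- c(types, "E1", "E2")
    aa5 <- c(aa5, "G", "G")
    aa_last <- c(aa_last, "N", "N")
  }
  ppr_protein(id, data.frame(index = seq_along(types), motif_type = types,
                             aa5 = aa5, aa_last = aa_last,
                             stringsAsFactors = FALSE))
}

# Hand-built scoring-table object honouring the documented lookup contract:
# score `value` whenever pair i faces `bases[i]`, 0 otherwise.
make_planted_code <- function(aa5, aa_last, bases, types, value = 1,
                              pseudocount = 10) {
  tabs <- list()
  for (mt in unique(types)) {
    sel <- types == mt
    pairs <- unique(paste(aa5[sel], aa_last[sel], sep = "|"))
    m <- matrix(0, nrow = length(pairs), ncol = 4,
                dimnames = list(pairs, c("A", "C", "G", "U")))
    for (i in which(sel))
      m[paste(aa5[i], aa_last[i], sep = "|"), bases[i]] <- value
    tabs[[mt]] <- m
  }
  structure(list(tables = tabs,
                 n_obs = stats::setNames(rep(0, length(tabs)), names(tabs)),
                 pseudocount = pseudocount),
            class = "ppr_code")
}

# The worked 5-pair training design used for the scoring-table tests:
# four pairs observed 40x with one base each (orthogonal), one pair with a
# uniform 10/10/10/10 profile.
worked_training_set <- function(motif_type = "P") {
  rbind(
    data.frame(motif_type = motif_type, aa5 = "T", aa_last = "N",
               nucleotide = "U", weight = 40),
    data.frame(motif_type = motif_type, aa5 = "T", aa_last = "D",
               nucleotide = "A", weight = 40),
    data.frame(motif_type = motif_type, aa5 = "N", aa_last = "D",
               nucleotide = "C", weight = 40),
    data.frame(motif_type = motif_type, aa5 = "S", aa_last = "N",
               nucleotide = "G", weight = 40),
    data.frame(motif_type = motif_type, aa5 = "N", aa_last = "N",
               nucleotide = c("A", "C", "G", "U"), weight = 10))
}

# Independent expected/score computation for a single-motif-type training
# table, written as plain loops over a dense pair x base count array.
scoring_oracle <- function(obs, pseudocount = 10) {
  pairs <- sort(unique(paste(obs$aa5, obs$aa_last, sep = "|")))
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0, length(pairs), 4, dimnames = list(pairs, bases))
  for (i in seq_len(nrow(obs))) {
    pr <- paste(obs$aa5[i], obs$aa_last[i], sep = "|")
    counts[pr, obs$nucleotide[i]] <- counts[pr, obs$nucleotide[i]] + obs$weight[i]
  }
  grand <- sum(counts)
  scores <- counts * 0
  for (pr in pairs) for (b in bases) {
    e <- sum(counts[pr, ]) * sum(counts[, b]) / grand
    scores[pr, b] <- log((pseudocount + counts[pr, b]) / (pseudocount + e))
  }
  scores
}
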
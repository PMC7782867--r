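## Ancestral-reconstruction post-processing: turn per-site posterior
## probability tables into maximum-likelihood (ML) and AltAll sequences.
##
## The AltAll ("alternative residue at all ambiguous positions") sequence
## is the worst-case-scenario ancestor: at every site where the posterior
## probability of the ML residue falls below a threshold (0.8 by default,
## strict inequality) the residue with the second-highest probability is
## substituted. Comparing the ML and AltAll proteins experimentally tests
## how robust conclusions are to reconstruction uncertainty.

pp_matrix <- function(pp) {
  stopifnot(inherits(pp, "evb_pp"))
  as.matrix(pp[, amino_acids()])
}

## Index of max / second max per row, ties broken alphabetically
## (columns are in alphabetical order, so "first" = alphabetical).
row_top_two <- function(m) {
  best <- max.col(m, ties.method = "first")
  m2 <- m
  m2[cbind(seq_len(nrow(m)), best)] <- -Inf
  second <- max.col(m2, ties.method = "first")
  list(best = best, second = second,
       p_best = m[cbind(seq_len(nrow(m)), best)],
       p_second = m[cbind(seq_len(nrow(m)), second)])
}

#' Maximum-likelihood ancestral sequence
#'
#' Per site, the residue with the highest posterior probability; exact
#' ties are broken alphabetically (a deterministic documented rule — real
#' reconstructions essentially never tie).
#'
#' @param pp A posterior table from [posterior_table()].
#' @return Single residue string.
#' @export
#' @examples
#' pp <- posterior_table(diag(20)[match(c("Y","K","Q"), amino_acids()), ,
#'                                drop = FALSE] |>
#'                         `colnames<-`(amino_acids()))
#' ml_sequence(pp)
ml_sequence <- function(pp) {
  m <- pp_matrix(pp)
  paste0(amino_acids()[row_top_two(m)$best], collapse = "")
}

#' AltAll (worst-case) ancestral sequence
#'
#' Sites where the ML residue's posterior probability is strictly below
#' `threshold` receive the second-highest-probability residue instead;
#' all other sites keep the ML residue.
#'
#' @param pp A posterior table.
#' @param threshold Posterior-probability cutoff in (0, 1]; default 0.8.
#'   A site is substituted iff `PP(ML) < threshold` (strict). `threshold = 0`
#'   therefore returns the ML sequence unchanged.
#' @return A list with `sequence` (residue string) and `flagged` — a tibble
#'   with columns `site`, `ml`, `alt`, `pp_ml` listing every substitution.
#' @export
altall_sequence <- function(pp, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single probability in [0, 1]")
  }
  m <- pp_matrix(pp)
  tt <- row_top_two(m)
  swap <- tt$p_best < threshold
  res <- amino_acids()[ifelse(swap, tt$second, tt$best)]
  flagged <- tibble(
    site = pp$site[swap],
    ml = amino_acids()[tt$best[swap]],
    alt = amino_acids()[tt$second[swap]],
    pp_ml = tt$p_best[swap]
  )
  list(sequence = paste0(res, collapse = ""), flagged = flagged)
}

#' Fraction of confidently reconstructed sites
#'
#' @param pp A posterior table.
#' @param threshold Confidence cutoff; a site counts as confident when the
#'   ML residue's posterior probability is `>= threshold`.
#' @return Fraction in \[0, 1\].
#' @export
pp_summary <- function(pp, threshold = 0.8) {
  m <- pp_matrix(pp)
  mean(row_top_two(m)$p_best >= threshold)
}

#' Percent identity and similarity between two aligned sequences
#'
#' Positions where either sequence has a gap (`-`) are excluded from the
#' denominator. Identity counts exact matches; similarity counts position
#' pairs whose substitution-matrix score is positive (identical residues
#' always score positive in standard log-odds matrices, so identity <=
#' similarity).
#'
#' @param seq_a,seq_b Aligned residue strings of equal length.
#' @param matrix 20x20 (or larger) scoring matrix with amino-acid dimnames;
#'   default BLOSUM62.
#' @return Tibble with `identity_pct`, `similarity_pct`, `n_compared`.
#' @export
#' @examples
#' identity_similarity("YKQTSV", "YKQSSV")
identity_similarity <- function(seq_a, seq_b, matrix = NULL) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) {
    abort(sprintf("aligned sequences must have equal length (%d vs %d)",
                  length(a), length(b)))
  }
  if (is.null(matrix)) matrix <- blosum62_matrix()
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) abort("no comparable (gap-free) positions")
  scores <- matrix[cbind(a, b)]
  tibble(
    identity_pct = 100 * sum(a == b) / n,
    similarity_pct = 100 * sum(scores > 0) / n,
    n_compared = n
  )
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}
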
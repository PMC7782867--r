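## C-terminal PDZ-binding-motif (PBM) classification.
##
## PBM positions are numbered from the C-terminus: P0 is the last residue,
## P-1 the one before, P-2 the third from the end. The canonical classes:
##   type I   : P-2 in {T, S}   and P0 hydrophobic
##   type II  : P-2 hydrophobic and P0 hydrophobic
##   type III : P-2 in {D, E}   and P0 hydrophobic
## "Hydrophobic" here is the large-hydrophobic set Phi = {V, I, L, M, F}:
## small residues (A, G, C) and polar residues at P0 do not support the
## canonical groove interaction, which is why e.g. ...SSA, ...SST and
## ...TSC C-termini are left unclassified. Phi is configurable because the
## literature draws the line differently for some domains.

PHI_DEFAULT <- c("V", "I", "L", "M", "F")

#' Classify C-terminal PDZ-binding motifs
#'
#' Classifies each sequence by its last three residues into type I
#' (T/S-X-Phi), type II (Phi-X-Phi), type III (D/E-X-Phi) or `undefined`.
#' When a configurable `phi` makes predicates overlap, precedence is
#' I > III > II. Only the final three residues matter: prepending any
#' prefix never changes the class.
#'
#' @param sequences Character vector of residue strings (each of length
#'   >= 3), optionally named, or a tibble with `id` and `seq` columns as
#'   returned by [read_fasta()].
#' @param phi Character vector: the hydrophobic residue set Phi.
#' @return Tibble with one row per sequence: `id`, `c_terminal` (last three
#'   residues), `p0`, `p_minus1`, `p_minus2`, `motif_class`.
#' @export
#' @examples
#' classify_pbm(c(human_cript = "YKQTSV", fly_cript = "YRQSST"))
classify_pbm <- function(sequences, phi = PHI_DEFAULT) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    seqs <- sequences$seq
  } else {
    seqs <- unname(sequences)
    ids <- names(sequences) %||% paste0("seq", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 3)) {
    abort("every sequence must have at least 3 residues to carry a PBM")
  }
  n <- nchar(seqs)
  p0 <- substr(seqs, n, n)
  p1 <- substr(seqs, n - 1, n - 1)
  p2 <- substr(seqs, n - 2, n - 2)
  cls <- dplyr::case_when(
    p2 %in% c("T", "S") & p0 %in% phi ~ "type_I",
    p2 %in% c("D", "E") & p0 %in% phi ~ "type_III",
    p2 %in% phi & p0 %in% phi ~ "type_II",
    TRUE ~ "undefined"
  )
  tibble(
    id = ids,
    c_terminal = substr(seqs, n - 2, n),
    p0 = p0, p_minus1 = p1, p_minus2 = p2,
    motif_class = cls
  )
}

#' Annotate a tree with PBM classes and list class transitions
#'
#' Classifies the sequence attached to every named node of the tree (leaf
#' sequences plus, optionally, ancestral sequences for internal nodes) and
#' reports the edges along which the motif class changed.
#'
#' @param tree An [ape::phylo] tree with unique tip labels; internal nodes
#'   that should be annotated must carry labels.
#' @param sequences Named character vector (or `id`/`seq` tibble) mapping
#'   node labels to residue strings. Every leaf, and every labelled
#'   internal node, must be present.
#' @param phi Hydrophobic set passed to [classify_pbm()].
#' @return A list of class `motif_annotation`: `tree`, `calls` (the
#'   [classify_pbm()] tibble plus a `node_type` column), `transitions`
#'   (tibble `parent`, `child`, `from`, `to` for every edge whose ends are
#'   both annotated and differ in class).
#' @export
annotate_tree_motifs <- function(tree, sequences, phi = PHI_DEFAULT) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$seq, sequences$id)
  }
  n_tip <- length(tree$tip.label)
  labels <- node_labels_in_order(tree)
  named <- which(nzchar(labels))
  missing <- setdiff(labels[named], names(sequences))
  if (length(missing) > 0) {
    abort(sprintf("no sequence supplied for node(s): %s",
                  paste(missing, collapse = ", ")))
  }
  calls <- classify_pbm(sequences[labels[named]], phi = phi)
  calls$node_type <- ifelse(named <= n_tip, "leaf", "internal")
  class_of <- setNames(calls$motif_class, calls$id)
  edge <- tree$edge
  pl <- labels[edge[, 1]]
  cl <- labels[edge[, 2]]
  both <- nzchar(pl) & nzchar(cl)
  trans <- tibble(parent = pl[both], child = cl[both],
                  from = unname(class_of[pl[both]]),
                  to = unname(class_of[cl[both]]))
  trans <- dplyr::filter(trans, .data$from != .data$to)
  structure(list(tree = tree, calls = calls, transitions = trans),
            class = "motif_annotation")
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat(sprintf("<motif annotation: %d nodes classified, %d transition(s)>\n",
              nrow(x$calls), nrow(x$transitions)))
  print(dplyr::count(x$calls, .data$motif_class))
  invisible(x)
}

#' Write a motif-annotated tree as newick with comments
#'
#' @param x A `motif_annotation` object.
#' @param path Output newick path.
#' @export
write_motif_tree <- function(x, path) {
  stopifnot(inherits(x, "motif_annotation"))
  ann <- tibble(node = x$calls$id, motif = x$calls$motif_class)
  write_annotated_newick(x$tree, ann, path)
}
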
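## Sequence, alignment, tree and posterior-table io.

#' Read and write FASTA files of amino-acid sequences
#'
#' `read_fasta()` validates as it reads: every sequence character must be
#' one of the 20 amino acids or the gap symbol `-`, ids must be unique, and
#' parse errors name the offending line. `write_fasta()` writes records in
#' order; the pair round-trips modulo line wrapping.
#'
#' @param path File path.
#' @param width Line-wrap width for writing.
#' @return `read_fasta()` returns a tibble with columns `id` and `seq`
#'   (one row per record, order preserved).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "YKQTSV"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(id = character(), seq = character()))
  }
  idx <- which(keep)
  first <- idx[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf("%s:%d: expected FASTA header ('>') before sequence data",
                  path, first))
  }
  ok <- paste0(c(amino_acids(), "-"), collapse = "")
  ids <- character()
  seqs <- character()
  cur <- NULL
  for (i in idx) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        abort(sprintf("%s:%d: empty FASTA header", path, i))
      }
      if (id %in% ids) {
        abort(sprintf("%s:%d: duplicate record id '%s'", path, i, id))
      }
      ids <- c(ids, id)
      seqs <- c(seqs, "")
      cur <- length(ids)
    } else {
      chunk <- toupper(gsub("\\s", "", ln))
      bad <- !strsplit(chunk, "")[[1]] %in% strsplit(ok, "")[[1]]
      if (any(bad)) {
        abort(sprintf(
          "%s:%d: illegal sequence character '%s' (allowed: %s)",
          path, i, strsplit(chunk, "")[[1]][which(bad)[1]], ok))
      }
      seqs[cur] <- paste0(seqs[cur], chunk)
    }
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("%s: record '%s' has an empty sequence",
                  path, ids[which(!nzchar(seqs))[1]]))
  }
  tibble(id = ids, seq = seqs)
}

#' @param x A tibble with columns `id` and `seq` (as from [read_fasta()]),
#'   or a named character vector of sequences.
#' @export
#' @rdname read_fasta
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble(id = names(x), seq = unname(x))
  }
  if (!all(c("id", "seq") %in% names(x))) {
    abort("`x` must have columns `id` and `seq`")
  }
  aa <- Biostrings::AAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Read a Clustal-format alignment
#'
#' @param path Clustal file path.
#' @return Tibble with columns `id` and `seq` (aligned, gaps as `-`).
#' @export
read_clustal <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
  s <- as.character(Biostrings::unmasked(aln))
  tibble(id = names(s), seq = unname(toupper(s)))
}

#' Read and write newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Leaf names must be unique; parse failures are reported as errors rather
#' than `NULL` returns.
#'
#' @param path File path.
#' @return `read_newick()` returns an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(sprintf("%s: not a parseable newick tree (unbalanced parentheses?)",
                  path))
  }
  if (anyDuplicated(tree$tip.label)) {
    abort(sprintf("%s: duplicate leaf names", path))
  }
  tree
}

#' @param tree An [ape::phylo] tree.
#' @export
#' @rdname read_newick
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

## --- annotated newick ------------------------------------------------------
## Per-node annotations are carried as [&key=value,...] comments after the
## node label, a convention lossless under round-trip. ape neither writes
## nor reads such comments, so serialisation is done here on top of it.

node_labels_in_order <- function(tree) {
  n_tip <- length(tree$tip.label)
  nl <- tree$node.label %||% rep("", tree$Nnode)
  c(tree$tip.label, nl)
}

format_annotation <- function(ann_row) {
  vals <- ann_row[!vapply(ann_row, is.na, logical(1))]
  if (length(vals) == 0) return("")
  paste0("[&", paste(names(vals), vals, sep = "=", collapse = ","), "]")
}

#' Write a tree with per-node comment annotations
#'
#' Annotations are appended to node labels as `[&key=value,...]` newick
#' comments. `read_annotated_newick()` strips and re-attaches them.
#'
#' @param tree An [ape::phylo] tree with unique, non-empty names for every
#'   annotated node.
#' @param annotations Tibble with a `node` column (matching tip or internal
#'   node labels) plus one column per annotation key; values are coerced to
#'   character.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_newick <- function(tree, annotations, path) {
  stopifnot(inherits(tree, "phylo"))
  labels <- node_labels_in_order(tree)
  unknown <- setdiff(annotations$node, labels)
  if (length(unknown) > 0) {
    abort(sprintf("annotation refers to unknown node(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  keys <- setdiff(names(annotations), "node")
  decorated <- labels
  for (i in seq_len(nrow(annotations))) {
    j <- match(annotations$node[i], labels)
    row <- lapply(annotations[i, keys, drop = FALSE], as.character)
    decorated[j] <- paste0(labels[j], format_annotation(unlist(row)))
  }
  t2 <- tree
  n_tip <- length(tree$tip.label)
  t2$tip.label <- decorated[seq_len(n_tip)]
  t2$node.label <- decorated[-seq_len(n_tip)]
  ## ape would mangle the comment brackets; serialise from the decorated
  ## labels with a plain recursive writer.
  writeLines(phylo_to_newick(t2), path)
  invisible(path)
}

phylo_to_newick <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  rec <- function(node) {
    lab <- if (node <= n_tip) tree$tip.label[node] else {
      (tree$node.label %||% rep("", tree$Nnode))[node - n_tip]
    }
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(lab)
    parts <- vapply(rows, function(r) {
      s <- rec(tree$edge[r, 2])
      if (!is.null(bl)) s <- paste0(s, ":", format(bl[r], digits = 15)) else s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(rec(root), ";")
}

#' @export
#' @rdname write_annotated_newick
read_annotated_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  comments <- stringr::str_match_all(txt, "([A-Za-z0-9_.|-]+)\\[&([^\\]]*)\\]")[[1]]
  clean <- gsub("\\[&[^\\]]*\\]", "", txt)
  tree <- suppressWarnings(ape::read.tree(text = clean))
  if (is.null(tree)) abort(sprintf("%s: not a parseable newick tree", path))
  ann <- NULL
  if (nrow(comments) > 0) {
    rows <- purrr::map2_dfr(comments[, 2], comments[, 3], function(node, body) {
      kv <- strsplit(strsplit(body, ",")[[1]], "=")
      vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      as_tibble(c(list(node = node), as.list(vals)))
    })
    ann <- rows
  }
  list(tree = tree, annotations = ann %||% tibble(node = character()))
}

## --- posterior probability tables ------------------------------------------

#' Construct a per-node posterior-probability table
#'
#' One row per alignment site, one column per amino acid (alphabetical
#' order as in [amino_acids()]), values the marginal posterior probability
#' of each residue at that site for one internal node of the tree.
#'
#' Row sums are required to be 1: deviations up to `1e-3` are accepted and
#' renormalised (the band `1e-6`..`1e-3` accommodates rounding in files
#' written with few digits); larger deviations are a validation error.
#'
#' @param probs Data frame or matrix with a `site` column/rownames and the
#'   20 amino-acid columns.
#' @param node_id Identifier of the tree node the table belongs to.
#' @return Tibble of class `evb_pp` with attribute `node_id`.
#' @export
posterior_table <- function(probs, node_id = "node") {
  probs <- as_tibble(as.data.frame(probs))
  if (!"site" %in% names(probs)) {
    probs <- dplyr::mutate(probs, site = dplyr::row_number(), .before = 1)
  }
  missing_aa <- setdiff(amino_acids(), names(probs))
  if (length(missing_aa) > 0) {
    abort(sprintf("posterior table missing amino-acid column(s): %s",
                  paste(missing_aa, collapse = ", ")))
  }
  probs <- dplyr::select(probs, "site", dplyr::all_of(amino_acids()))
  probs <- dplyr::arrange(probs, .data$site)
  m <- as.matrix(probs[, amino_acids()])
  if (any(m < 0)) abort("posterior probabilities must be >= 0")
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off > 1e-3)) {
    abort(sprintf("site %d: probabilities sum to %.4f (must be 1 within 1e-3)",
                  probs$site[which.max(off)], rs[which.max(off)]))
  }
  probs[, amino_acids()] <- m / rs
  structure(probs, node_id = node_id, class = c("evb_pp", class(probs)))
}

#' @export
#' @rdname posterior_table
#' @param x An `evb_pp` object.
pp_node_id <- function(x) attr(x, "node_id", exact = TRUE)

#' Read / write posterior tables as TSV
#'
#' Dialect: one file per node; header `site` followed by the 20 amino
#' acids in alphabetical order; sites 1-based. `node_id` defaults to the
#' file name without extension.
#'
#' @param path File path.
#' @param node_id Node identifier; default from the file name.
#' @return `read_posterior_table()` returns an `evb_pp` tibble.
#' @export
read_posterior_table <- function(path, node_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  node_id <- node_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  posterior_table(df, node_id = node_id)
}

#' @export
#' @rdname read_posterior_table
write_posterior_table <- function(x, path) {
  stopifnot(inherits(x, "evb_pp"))
  readr::write_tsv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}
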
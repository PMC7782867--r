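## Assembly of per-node results into the study's summary artifacts: an
## affinity-annotated species tree and a consolidated per-node table.

#' Assemble per-node results into an annotated tree and a summary table
#'
#' Takes a species tree and a tibble of per-node results (motif class,
#' native-ligand and reference-ligand affinities, stability) and produces
#' the consolidated report: a newick string with structured per-node
#' comment annotations and a deterministic CSV-ready table. Affinities
#' from flagged or absent fits are reported as `"N.D."` (not determined).
#'
#' @param tree [ape::phylo] tree whose tip/internal labels cover every
#'   `node_id`.
#' @param node_results Tibble with columns `node_id` and any of
#'   `motif_class`, `K_d_native_uM`, `K_d_reference_uM`, `dG_kcal_mol`,
#'   `provenance`. Numeric columns may be `NA` (rendered `"N.D."`).
#' @return Object of class `evb_report`: `table` (tibble, one row per
#'   supplied result, stable column order), `tree` (input tree),
#'   `annotations` (tibble used for the newick comments) and `newick`
#'   (annotated newick string).
#' @export
build_report <- function(tree, node_results) {
  stopifnot(inherits(tree, "phylo"))
  node_results <- as_tibble(node_results)
  cols <- c("node_id", "motif_class", "K_d_native_uM", "K_d_reference_uM",
            "dG_kcal_mol", "provenance")
  for (cn in setdiff(cols, names(node_results))) {
    node_results[[cn]] <- if (cn %in% c("motif_class", "provenance")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  labels <- node_labels_in_order(tree)
  bad <- setdiff(node_results$node_id, labels)
  if (length(bad) > 0) {
    abort(sprintf("node_id(s) not found in the tree: %s",
                  paste(bad, collapse = ", ")))
  }
  fmt <- function(x) ifelse(is.na(x), "N.D.", sprintf("%.4g", x))
  table <- dplyr::transmute(
    node_results,
    node_id = .data$node_id,
    motif_class = dplyr::coalesce(.data$motif_class, "undefined"),
    K_d_native_uM = fmt(.data$K_d_native_uM),
    K_d_reference_uM = fmt(.data$K_d_reference_uM),
    dG_kcal_mol = fmt(.data$dG_kcal_mol),
    provenance = dplyr::coalesce(.data$provenance, "")
  )
  ann <- tibble(
    node = table$node_id,
    motif = table$motif_class,
    Kd_native = table$K_d_native_uM,
    Kd_ref = table$K_d_reference_uM,
    dG = table$dG_kcal_mol
  )
  tmp <- tempfile(fileext = ".nwk")
  on.exit(unlink(tmp))
  write_annotated_newick(tree, ann, tmp)
  structure(list(table = table, tree = tree, annotations = ann,
                 newick = paste(readLines(tmp), collapse = "\n")),
            class = "evb_report")
}

#' @export
print.evb_report <- function(x, ...) {
  cat(sprintf("<report: %d node(s)>\n", nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Write a report to disk
#'
#' @param x An `evb_report`.
#' @param csv_path,newick_path Output paths (either may be `NULL` to
#'   skip). The CSV is byte-deterministic for identical inputs.
#' @export
write_report <- function(x, csv_path = NULL, newick_path = NULL) {
  stopifnot(inherits(x, "evb_report"))
  if (!is.null(csv_path)) readr::write_csv(x$table, csv_path)
  if (!is.null(newick_path)) writeLines(x$newick, newick_path)
  invisible(x)
}

#' Affinity fold change
#'
#' Ratio of two dissociation constants, e.g. to quantify how much an
#' extension or mutation changed binding.
#'
#' @param K_d_a,K_d_b Dissociation constants (> 0), same units.
#' @return `K_d_a / K_d_b`.
#' @export
#' @examples
#' fold_change(17, 1.64)  # ~10-fold
fold_change <- function(K_d_a, K_d_b) {
  if (any(K_d_a <= 0) || any(K_d_b <= 0)) {
    abort("both dissociation constants must be > 0")
  }
  K_d_a / K_d_b
}
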
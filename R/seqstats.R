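#' Read an aligned FASTA file
#' @param path Aligned FASTA; gaps as `-`.
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- stats::setNames(as.character(seqs), names(seqs))
  if (length(unique(nchar(out))) > 1) {
    stop("sequences in ", path, " are not aligned (unequal lengths)",
         call. = FALSE)
  }
  out
}

#' Write an aligned FASTA file
#' @param seqs Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

aln_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise sequence identity on an alignment
#'
#' Identity is the fraction of identical residues over the aligned positions
#' where neither sequence has a gap. A pair with no gap-free overlap gets
#' identity 0 (with a warning).
#'
#' @param seqs Named character vector of aligned sequences.
#' @return Symmetric identity matrix in `[0, 1]`.
#' @export
pairwise_identity <- function(seqs) {
  m <- aln_matrix(seqs)
  n <- nrow(m)
  id <- diag(1, n)
  rownames(id) <- colnames(id) <- names(seqs)
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        if (!warned) {
          warning("sequence pair(s) with no gap-free overlap; identity set to 0")
          warned <- TRUE
        }
        id[i, j] <- id[j, i] <- 0
      } else {
        id[i, j] <- id[j, i] <- mean(m[i, ok] == m[j, ok])
      }
    }
  }
  id
}

#' Group paralogs and assign inverse-group-size weights
#'
#' Close paralogs bias family-wide frequencies, so sequences are grouped at
#' an identity cutoff (default 50%) and each member of a group of size k is
#' weighted 1/k. Groups are the connected components of the graph linking
#' pairs at or above the cutoff (single linkage); `linkage = "complete"`
#' instead cuts a complete-linkage dendrogram at the cutoff.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param identity_cutoff Fraction in `(0, 1]`; default 0.5.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return An object of class `"weighted_msa"`: tibble with columns `id`,
#'   `sequence`, `group`, `weight`; attribute `n_columns`.
#' @export
group_paralogs <- function(seqs, identity_cutoff = 0.5,
                           linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 1) {
    comp <- 1L
  } else {
    id <- pairwise_identity(seqs)
    if (linkage == "single") {
      adj <- id >= identity_cutoff
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      comp <- igraph::components(g)$membership
    } else {
      hc <- stats::hclust(stats::as.dist(1 - id), method = "complete")
      comp <- stats::cutree(hc, h = 1 - identity_cutoff)
    }
  }
  sizes <- table(comp)
  out <- tibble::tibble(
    id = names(seqs),
    sequence = unname(seqs),
    group = as.integer(comp),
    weight = 1 / as.numeric(sizes[as.character(comp)]))
  attr(out, "n_columns") <- nchar(seqs[[1]])
  class(out) <- c("weighted_msa", class(out))
  out
}

#' Paralog-weighted residue-class frequency
#'
#' Sums the weights of (sequence, column) cells whose residue belongs to the
#' class, over the weights of all non-gap cells in the given columns.
#'
#' @param wmsa A [group_paralogs()] result.
#' @param columns 1-based alignment column indices.
#' @param residue_class Character vector of one-letter residues, e.g.
#'   `c("D", "E")`.
#' @return Fraction in `[0, 1]`.
#' @export
weighted_frequency <- function(wmsa, columns, residue_class) {
  ncol_aln <- attr(wmsa, "n_columns")
  if (any(columns < 1 | columns > ncol_aln)) {
    stop("column index out of range 1..", ncol_aln, call. = FALSE)
  }
  m <- aln_matrix(stats::setNames(wmsa$sequence, wmsa$id))
  sub <- m[, columns, drop = FALSE]
  w <- matrix(rep(wmsa$weight, length(columns)), ncol = length(columns))
  nongap <- sub != "-"
  if (!any(nongap)) stop("all cells in the requested columns are gaps",
                         call. = FALSE)
  sum(w[nongap & matrix(sub %in% residue_class, nrow = nrow(sub))]) /
    sum(w[nongap])
}

#' Residue-class enrichment in loop columns (Fisher exact test)
#'
#' Tests over-representation of a residue class (by default the negatively
#' charged D/E) in the loop columns relative to the rest of the alignment.
#' The 2x2 table uses unweighted integer residue counts
#' (class/other x loop/non-loop, gaps excluded) and the one-sided Fisher
#' exact (hypergeometric) P-value for over-representation; paralog-weighted
#' class frequencies in the loop and over the whole alignment are reported
#' alongside, as the headline percentages are weighted.
#'
#' @param wmsa A [group_paralogs()] result.
#' @param loop_columns 1-based loop column indices (a proper non-empty
#'   subset of the alignment columns).
#' @param residue_class Residue class; default `c("D", "E")`.
#' @return An object of class `"enrichment_result"`: list with `table`
#'   (2x2), `p_value`, `freq_loop_weighted`, `freq_overall_weighted`,
#'   `freq_loop_raw`, `freq_overall_raw`.
#' @export
loop_enrichment <- function(wmsa, loop_columns, residue_class = c("D", "E")) {
  ncol_aln <- attr(wmsa, "n_columns")
  if (length(loop_columns) == 0 || length(loop_columns) >= ncol_aln) {
    stop("loop_columns must be a proper non-empty subset of the columns",
         call. = FALSE)
  }
  m <- aln_matrix(stats::setNames(wmsa$sequence, wmsa$id))
  in_loop <- matrix(FALSE, nrow(m), ncol(m))
  in_loop[, loop_columns] <- TRUE
  nongap <- m != "-"
  is_class <- matrix(m %in% residue_class, nrow(m)) & nongap
  tab <- matrix(c(
    sum(is_class & in_loop), sum(is_class & !in_loop),
    sum(nongap & !is_class & in_loop), sum(nongap & !is_class & !in_loop)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("class", "other"), c("loop", "non_loop")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (empty margin)", call. = FALSE)
  }
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(
    list(table = tab, p_value = p,
         freq_loop_weighted = weighted_frequency(wmsa, loop_columns,
                                                 residue_class),
         freq_overall_weighted = weighted_frequency(wmsa, seq_len(ncol_aln),
                                                    residue_class),
         freq_loop_raw = tab["class", "loop"] / sum(tab[, "loop"]),
         freq_overall_raw = sum(tab["class", ]) / sum(tab),
         residue_class = residue_class),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> class {%s}: %.1f%% in loop vs %.1f%% overall (weighted); one-sided Fisher P = %.3g\n",
    paste(x$residue_class, collapse = ","), 100 * x$freq_loop_weighted,
    100 * x$freq_overall_weighted, x$p_value))
  invisible(x)
}

#' Read per-domain helix-propensity tables
#'
#' Plain TSV with columns `domain_id`, `position` (1..20, counted downstream
#' of the domain C-terminus) and `propensity` in `[0, 1]`, as produced by an
#' external secondary-structure predictor.
#'
#' @param path TSV path.
#' @return Tibble (`domain_id`, `position`, `propensity`).
#' @export
read_propensity_tables <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("domain_id", "position", "propensity")
  if (!all(req %in% names(tab))) {
    stop("propensity TSV needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tab
}

residue_class_of <- function(res, classes) {
  hit <- names(classes)[vapply(classes, function(set) res %in% set, TRUE)]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Helical-propensity profile of C-terminal extensions, by residue class
#'
#' Partitions domains by the residue they carry at a chosen alignment
#' position (by default ILE/LEU/VAL vs ALA at the position aligned to 328
#' of PSD95-PDZ3) and averages, with paralog weights, the per-position helix
#' propensity of the 20 residues downstream of each domain's C-terminus.
#' Positions beyond a protein's C-terminus carry propensity 0 (zero
#' padding); domains absent from the propensity tables are dropped from both
#' classes with a warning.
#'
#' @param tables Propensity tibble from [read_propensity_tables()].
#' @param wmsa A [group_paralogs()] result whose ids match `domain_id`.
#' @param class_column 1-based alignment column defining the classes.
#' @param classes Named list of residue sets; default
#'   `list(ILV = c("I","L","V"), ALA = "A")`.
#' @return A tibble of class `"propensity_profile"`: columns `class`,
#'   `position` (1..20), `mean_propensity`, `n_domains`.
#' @export
propensity_profile <- function(tables, wmsa, class_column,
                               classes = list(ILV = c("I", "L", "V"),
                                              ALA = "A")) {
  m <- aln_matrix(stats::setNames(wmsa$sequence, wmsa$id))
  res_at <- m[, class_column]
  cls <- vapply(res_at, residue_class_of, "", classes = classes)
  if (any(tables$position < 1 | tables$position > 20)) {
    stop("propensity positions must lie in 1..20", call. = FALSE)
  }
  known <- unique(tables$domain_id)
  missing <- setdiff(wmsa$id[!is.na(cls)], known)
  if (length(missing) > 0) {
    warning("domain(s) missing from propensity tables, excluded: ",
            paste(missing, collapse = ", "))
  }
  # Dense 20-position matrix per domain with zero padding past the
  # C-terminus (absent positions are zeros by construction).
  rows <- list()
  for (k in seq_len(nrow(wmsa))) {
    if (is.na(cls[k]) || !(wmsa$id[k] %in% known)) next
    dom <- tables[tables$domain_id == wmsa$id[k], ]
    prop <- numeric(20)
    prop[dom$position] <- dom$propensity
    rows[[length(rows) + 1]] <- tibble::tibble(
      class = cls[k], position = 1:20, propensity = prop,
      weight = wmsa$weight[k])
  }
  if (length(rows) == 0) stop("no domains left to profile", call. = FALSE)
  long <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$class, .data$position),
    mean_propensity = sum(.data$propensity * .data$weight) /
      sum(.data$weight),
    n_domains = dplyr::n(), .groups = "drop")
  class(out) <- c("propensity_profile", class(out))
  out
}

#' Group-level permutation p-value for a class contrast
#'
#' Tests whether the difference of class means of a per-domain value (e.g.
#' helix propensity at a given downstream position) exceeds chance, by
#' reshuffling the class labels. To respect paralog weighting, labels are
#' shuffled at the paralog-group level by default (every member of a group
#' carries its group's label); `unit = "member"` shuffles individual
#' sequences instead. The p-value uses add-one smoothing,
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`, so it is never 0.
#'
#' @param values Named numeric vector of per-domain values (names = ids).
#' @param wmsa A [group_paralogs()] result supplying groups and weights.
#' @param is_class_a Named logical vector over the same ids: `TRUE` for
#'   class A, `FALSE` for class B. Ids with `NA` are dropped.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param unit `"group"` (default) or `"member"`.
#' @return List with `p_value`, `observed` (A mean minus B mean, weighted)
#'   and `n_perm`.
#' @export
reshuffle_pvalue <- function(values, wmsa, is_class_a, n_perm = 999,
                             seed = 1, unit = c("group", "member")) {
  unit <- match.arg(unit)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  ids <- intersect(names(values), wmsa$id)
  ids <- ids[!is.na(is_class_a[ids])]
  lab <- is_class_a[ids]
  if (!any(lab) || all(lab)) stop("both classes must be non-empty",
                                  call. = FALSE)
  w <- stats::setNames(wmsa$weight, wmsa$id)[ids]
  grp <- stats::setNames(wmsa$group, wmsa$id)[ids]
  v <- values[ids]
  stat <- function(labels) {
    a <- labels; b <- !labels
    sum(w[a] * v[a]) / sum(w[a]) - sum(w[b] * v[b]) / sum(w[b])
  }
  observed <- stat(lab)
  set.seed(seed)
  exceed <- 0L
  if (unit == "group") {
    groups <- unique(grp)
    # A group's label is its members' majority label (groups are near-
    # identical paralogs, so labels rarely split within a group).
    glab <- vapply(groups, function(g) mean(lab[grp == g]) >= 0.5, TRUE)
    for (b in seq_len(n_perm)) {
      perm <- sample(glab)
      plab <- stats::setNames(perm, groups)[as.character(grp)]
      if (!any(plab) || all(plab)) next
      if (stat(plab) >= observed) exceed <- exceed + 1L
    }
  } else {
    for (b in seq_len(n_perm)) {
      plab <- sample(lab)
      if (stat(plab) >= observed) exceed <- exceed + 1L
    }
  }
  list(p_value = (1 + exceed) / (1 + n_perm), observed = observed,
       n_perm = n_perm)
}

#' Family-wide summary for a curated PDZ alignment
#'
#' Convenience wrapper reproducing the family-level numbers from a curated
#' alignment: paralog grouping, weighted D/E frequency over whole domains
#' and over the loop columns with the Fisher enrichment P, and the weighted
#' fraction of aliphatic/aromatic residues at a stated alignment column
#' (position 337 in PSD95-PDZ3 numbering).
#'
#' @param seqs Named character vector of aligned sequences (e.g. from
#'   [read_alignment()]).
#' @param loop_columns 1-based loop column indices.
#' @param hydrophobic_column Optional 1-based column for the
#'   aliphatic/aromatic fraction (class A/V/I/L/M/F/W/Y).
#' @param identity_cutoff Paralog grouping cutoff; default 0.5.
#' @return Tibble with `de_freq_overall`, `de_freq_loop`, `fisher_p` and
#'   (when `hydrophobic_column` is given) `hydrophobic_freq`.
#' @export
pdz_family_summary <- function(seqs, loop_columns, hydrophobic_column = NULL,
                               identity_cutoff = 0.5) {
  wmsa <- group_paralogs(seqs, identity_cutoff = identity_cutoff)
  enr <- loop_enrichment(wmsa, loop_columns)
  out <- tibble::tibble(
    de_freq_overall = enr$freq_overall_weighted,
    de_freq_loop = enr$freq_loop_weighted,
    fisher_p = enr$p_value)
  if (!is.null(hydrophobic_column)) {
    out$hydrophobic_freq <- weighted_frequency(
      wmsa, hydrophobic_column,
      c("A", "V", "I", "L", "M", "F", "W", "Y"))
  }
  out
}
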
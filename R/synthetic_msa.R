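AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background residue composition used by the alignment generator: a
# smoothed natural-abundance table (values renormalised over the 20
# standard residues).
default_composition <- function() {
  w <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
         I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
         R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  w / sum(w)
}

#' Specification for a synthetic PDZ-like alignment
#'
#' Generates an aligned family with planted paralog groups (members are
#' point mutants of a common ancestor, so within-group identity stays above
#' the grouping cutoff by construction) and a planted enrichment of a
#' residue class in designated loop columns.
#'
#' @param n_groups Number of paralog groups.
#' @param group_sizes Integer vector (recycled) of members per group.
#' @param n_columns Alignment length (default 90, a typical PDZ domain).
#' @param loop_columns Column indices forming the loop (default 25:31, a
#'   7-column loop).
#' @param loop_enrichment_factor Multiplier on the D/E probability in loop
#'   columns (other residues renormalised); 1 = no enrichment.
#' @param mutation_rate Per-position substitution probability within groups
#'   (must keep expected pairwise identity above 0.5; capped at 0.2).
#' @param composition Named background probability vector over the 20
#'   residues.
#' @param seed Integer seed.
#' @return An object of class `"msa_generator_spec"`.
#' @export
msa_generator_spec <- function(n_groups = 40, group_sizes = c(1, 1, 2, 5),
                               n_columns = 90, loop_columns = 25:31,
                               loop_enrichment_factor = 2,
                               mutation_rate = 0.1,
                               composition = default_composition(),
                               seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-8 || any(composition < 0)) {
    stop("composition must be a probability vector", call. = FALSE)
  }
  if (!all(names(composition) %in% AA20) || length(composition) != 20) {
    stop("composition must cover the 20 standard residues", call. = FALSE)
  }
  if (mutation_rate > 0.2) {
    stop("mutation_rate above 0.2 no longer guarantees within-group ",
         "identity > 50%", call. = FALSE)
  }
  de <- sum(composition[c("D", "E")])
  if (de * loop_enrichment_factor >= 1) {
    stop("enrichment factor pushes the D/E probability to 1 or above",
         call. = FALSE)
  }
  if (any(loop_columns < 1 | loop_columns > n_columns)) {
    stop("loop_columns out of range", call. = FALSE)
  }
  structure(
    list(n_groups = n_groups,
         group_sizes = rep_len(group_sizes, n_groups),
         n_columns = n_columns, loop_columns = loop_columns,
         loop_enrichment_factor = loop_enrichment_factor,
         mutation_rate = mutation_rate, composition = composition,
         seed = as.integer(seed)),
    class = "msa_generator_spec"
  )
}

#' Generate a synthetic aligned family with planted structure
#'
#' @param spec An [msa_generator_spec()].
#' @return List with `sequences` (named character vector), `groups` (list of
#'   id vectors, the planted partition), `loop_columns` and `spec`.
#' @export
gen_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_generator_spec"))
  set.seed(spec$seed)
  comp <- spec$composition
  loop_comp <- comp
  loop_comp[c("D", "E")] <- loop_comp[c("D", "E")] * spec$loop_enrichment_factor
  others <- setdiff(names(comp), c("D", "E"))
  loop_comp[others] <- loop_comp[others] *
    (1 - sum(loop_comp[c("D", "E")])) / sum(comp[others])
  stopifnot(abs(sum(loop_comp) - 1) < 1e-8)
  seqs <- character(0)
  groups <- list()
  sid <- 0
  for (g in seq_len(spec$n_groups)) {
    anc <- character(spec$n_columns)
    for (j in seq_len(spec$n_columns)) {
      p <- if (j %in% spec$loop_columns) loop_comp else comp
      anc[j] <- sample(names(p), 1, prob = p)
    }
    ids <- character(spec$group_sizes[g])
    for (m in seq_len(spec$group_sizes[g])) {
      sid <- sid + 1
      member <- anc
      mut <- stats::runif(spec$n_columns) < spec$mutation_rate
      if (any(mut)) {
        for (j in which(mut)) {
          p <- if (j %in% spec$loop_columns) loop_comp else comp
          member[j] <- sample(names(p), 1, prob = p)
        }
      }
      id <- sprintf("dom%03d_g%02d", sid, g)
      ids[m] <- id
      seqs[id] <- paste0(member, collapse = "")
    }
    groups[[g]] <- ids
  }
  list(sequences = seqs, groups = groups,
       loop_columns = spec$loop_columns, spec = spec)
}

#' Generate per-domain helix-propensity tables
#'
#' Emulates the output of a secondary-structure predictor on the 20 residues
#' downstream of each domain's C-terminus: each domain draws its 20-position
#' propensities from a Gaussian around its class mean, clipped to `[0, 1]`.
#' A stated fraction of domains is truncated (the protein C-terminus falls
#' within the 20-residue window); truncated domains only report positions up
#' to the truncation point, exercising the zero-padding rule downstream.
#'
#' @param domain_classes Named character vector: domain id -> class label
#'   (a name of `class_means`).
#' @param class_means Named numeric vector of per-class mean propensities in
#'   `[0, 1]`, e.g. `c(ILV = 0.5, ALA = 0.25)`.
#' @param noise_sd Gaussian noise SD (default 0.05).
#' @param truncation_fraction Fraction of domains truncated before position
#'   20 (default 0).
#' @param seed Integer seed.
#' @return Tibble (`domain_id`, `position`, `propensity`).
#' @export
gen_propensity_tables <- function(domain_classes,
                                  class_means = c(ILV = 0.5, ALA = 0.25),
                                  noise_sd = 0.05,
                                  truncation_fraction = 0,
                                  seed = 1L) {
  if (any(class_means < 0 | class_means > 1)) {
    stop("class means must lie in [0, 1]", call. = FALSE)
  }
  if (truncation_fraction < 0 || truncation_fraction > 1) {
    stop("truncation_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!all(domain_classes %in% names(class_means))) {
    stop("domain_classes contains labels absent from class_means",
         call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  for (id in names(domain_classes)) {
    mu <- class_means[[domain_classes[[id]]]]
    prop <- pmin(1, pmax(0, stats::rnorm(20, mean = mu, sd = noise_sd)))
    last <- 20L
    if (stats::runif(1) < truncation_fraction) {
      last <- sample(0:19, 1)
    }
    if (last > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain_id = id, position = seq_len(last),
        propensity = prop[seq_len(last)])
    } else {
      # Protein ends exactly at the domain C-terminus: no downstream
      # residues at all, recorded as an explicit zero at position 1 so the
      # domain is not mistaken for missing.
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain_id = id, position = 1L, propensity = 0)
    }
  }
  dplyr::bind_rows(rows)
}

#' Write per-domain propensity tables as TSV
#' @param tables Tibble from [gen_propensity_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_propensity_tables <- function(tables, path) {
  readr::write_tsv(tables, path)
  invisible(path)
}
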
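#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conformation-space network
#' @param x A `"csn"`.
#' @param ... Unused.
#' @return Node tibble (`code`, `population`, `pattern`, `fraction`).
#' @export
tidy.csn <- function(x, ...) {
  dplyr::mutate(x$nodes, fraction = .data$population / x$total_frames)
}

#' One-row summary of a conformation-space network
#' @param x A `"csn"`.
#' @param ... Unused.
#' @return Tibble with microstate, edge, frame and run counts.
#' @export
glance.csn <- function(x, ...) {
  tibble::tibble(
    n_microstates = nrow(x$nodes), n_edges = nrow(x$edges),
    total_frames = x$total_frames, n_runs = x$n_runs,
    n_self_transitions = sum(x$edges$count[x$edges$from == x$edges$to]))
}

#' Tidy a basin set
#' @param x A `"basin_set"` from [gradient_cluster()].
#' @param ... Unused.
#' @return Tibble without the list-column of members.
#' @export
tidy.basin_set <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -"members")
}

#' One-row summary of a basin set
#' @param x A `"basin_set"`.
#' @param ... Unused.
#' @return Tibble with basin count and population of the top basin.
#' @export
glance.basin_set <- function(x, ...) {
  tibble::tibble(n_basins = nrow(x), mode = attr(x, "mode"),
                 top_basin = x$basin[which.max(x$population)],
                 top_population = max(x$population))
}

#' Tidy contact records
#' @param x A `"contact_records"` tibble.
#' @param ... Unused.
#' @return Tibble (`name`, `kind`, `occupancy`) without the series column.
#' @export
tidy.contact_records <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "name", "kind", "occupancy")
}

#' Tidy an enrichment result
#' @param x An `"enrichment_result"`.
#' @param ... Unused.
#' @return One-row tibble of frequencies and the Fisher p-value.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    residue_class = paste(x$residue_class, collapse = ""),
    freq_loop_weighted = x$freq_loop_weighted,
    freq_overall_weighted = x$freq_overall_weighted,
    freq_loop_raw = x$freq_loop_raw,
    freq_overall_raw = x$freq_overall_raw,
    p_value = x$p_value)
}

#' One-row summary of an enrichment result
#' @param x An `"enrichment_result"`.
#' @param ... Unused.
#' @return Tibble with the 2x2 counts and the p-value.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    class_loop = x$table["class", "loop"],
    class_non_loop = x$table["class", "non_loop"],
    other_loop = x$table["other", "loop"],
    other_non_loop = x$table["other", "non_loop"],
    p_value = x$p_value)
}

#' Tidy a leader clustering
#' @param x A `"leader_clustering"`.
#' @param ... Unused.
#' @return Tibble (`frame`, `cluster`), 0-based as in the object.
#' @export
tidy.leader_clustering <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$assignments) - 1L,
                 cluster = x$assignments)
}

#' One-row summary of a leader clustering
#' @param x A `"leader_clustering"`.
#' @param ... Unused.
#' @return Tibble with cluster count and cutoff.
#' @export
glance.leader_clustering <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$leaders), cutoff = x$cutoff,
                 fitted = x$fit, n_frames = length(x$assignments))
}
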
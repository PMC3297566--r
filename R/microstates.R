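#' Leader clustering of peptide conformations
#'
#' Single-pass clustering on a backbone atom selection: frames are scanned in
#' time order; a frame founds a new cluster (becomes a leader) iff its RMSD
#' to every existing leader exceeds the cutoff, otherwise it is assigned to
#' the FIRST leader within the cutoff. By default the RMSD is computed after
#' optimal superposition (Kabsch); `fit = FALSE` gives the raw-coordinate
#' variant.
#'
#' @param traj A [trajectory()].
#' @param selection Integer vector of 1-based atom indices (e.g. from
#'   [select_backbone()]).
#' @param cutoff RMSD cutoff in Angstrom (default 2).
#' @param fit Superpose before computing RMSD (default `TRUE`).
#' @return An object of class `"leader_clustering"`: list with `cutoff`,
#'   `leaders` (0-based frame indices) and `assignments` (length-F 0-based
#'   cluster ids).
#' @export
leader_cluster <- function(traj, selection, cutoff = 2.0, fit = TRUE) {
  if (length(selection) == 0) stop("selection must be non-empty", call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames", call. = FALSE)
  leaders <- integer(0)
  leader_xyz <- list()
  assignments <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[selection, , drop = FALSE]
    hit <- NA_integer_
    for (k in seq_along(leaders)) {
      if (rmsd_fit(xyz, leader_xyz[[k]], fit = fit) <= cutoff) {
        hit <- k
        break
      }
    }
    if (is.na(hit)) {
      leaders <- c(leaders, f - 1L)
      leader_xyz[[length(leaders)]] <- xyz
      hit <- length(leaders)
    }
    assignments[f] <- hit - 1L
  }
  structure(
    list(cutoff = cutoff, leaders = leaders, assignments = assignments,
         fit = fit, selection = selection),
    class = "leader_clustering"
  )
}

#' @export
print.leader_clustering <- function(x, ...) {
  cat(sprintf("<leader_clustering> %d frames -> %d clusters (cutoff %.2f A)\n",
              length(x$assignments), length(x$leaders), x$cutoff))
  invisible(x)
}

#' Encode each frame as a microstate code
#'
#' Every frame is labelled by a code concatenating D binary contact digits
#' (one per monitored contact, in the order of `records`) and the
#' conformation-cluster id from leader clustering, e.g. `"110|2"`. The
#' contact part alone (`"110"`) is the compact binding-mode label used in
#' reporting; the delimited form keeps cluster ids above 9 unambiguous.
#'
#' @param records A [contact_timeseries()] result (the monitored contacts,
#'   ordered).
#' @param clustering A [leader_cluster()] result over the same frames.
#' @return Character vector of per-frame codes.
#' @export
encode_microstates <- function(records, clustering) {
  nf <- length(clustering$assignments)
  lens <- vapply(records$formed, length, 0L)
  if (any(lens != nf)) {
    stop("contact records cover ", paste(unique(lens), collapse = "/"),
         " frames but the clustering covers ", nf, call. = FALSE)
  }
  bits <- vapply(records$formed, function(x) as.integer(x), integer(nf))
  if (nf == 1) bits <- matrix(bits, nrow = 1)
  pattern <- apply(bits, 1, paste0, collapse = "")
  paste0(pattern, "|", clustering$assignments)
}

#' Contact pattern part of microstate codes
#' @param codes Character vector of `"bits|cluster"` codes.
#' @return Character vector of the binary contact patterns.
#' @export
contact_pattern <- function(codes) sub("\\|.*$", "", codes)

#' Build the conformation-space network
#'
#' Nodes are microstates with populations equal to their frame counts; a
#' directed edge `(u, v)` counts transitions between consecutive frames
#' within one run (self-transitions included). No edges are placed across
#' run boundaries.
#'
#' @param codes A character vector of per-frame codes, or a list of such
#'   vectors (one per run).
#' @return An object of class `"csn"`: list with tibbles `nodes`
#'   (`code`, `population`, `pattern`), `edges` (`from`, `to`, `count`) and
#'   `total_frames`.
#' @export
build_csn <- function(codes) {
  if (!is.list(codes)) codes <- list(codes)
  codes <- purrr::map(codes, as.character)
  if (length(codes) == 0 || all(lengths(codes) == 0)) {
    stop("need at least one non-empty code sequence", call. = FALSE)
  }
  all_codes <- unlist(codes, use.names = FALSE)
  pops <- table(all_codes)
  nodes <- tibble::tibble(
    code = names(pops),
    population = as.integer(pops),
    pattern = contact_pattern(names(pops))
  ) |> dplyr::arrange(dplyr::desc(.data$population), .data$code)
  edge_rows <- purrr::map(codes, function(s) {
    if (length(s) < 2) return(NULL)
    tibble::tibble(from = s[-length(s)], to = s[-1])
  })
  edges <- dplyr::bind_rows(edge_rows)
  if (nrow(edges) > 0) {
    edges <- dplyr::count(edges, .data$from, .data$to, name = "count")
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            count = integer())
  }
  structure(
    list(nodes = nodes, edges = edges,
         total_frames = length(all_codes), n_runs = length(codes)),
    class = "csn"
  )
}

#' @export
print.csn <- function(x, ...) {
  cat(sprintf("<csn> %d microstates, %d edges, %d frames over %d run(s)\n",
              nrow(x$nodes), nrow(x$edges), x$total_frames, x$n_runs))
  invisible(x)
}

#' Gradient clustering of a conformation-space network into basins
#'
#' Each node points to the highest-population member of its closed
#' neighbourhood (itself plus its undirected neighbours, self-transitions
#' excluded from the neighbour set); following pointers reaches a fixed
#' point, a local population maximum, and nodes sharing a fixed point form
#' one basin of attraction — a metastable binding mode. Ties between
#' neighbours are broken towards the lexicographically smallest code; a node
#' whose population equals the best neighbour's points to itself, making the
#' output deterministic.
#'
#' With `mode = "transition"` the ascent is weighted by interconversion flux
#' instead: among the neighbours of strictly higher population, a node moves
#' to the one with the largest symmetrised transition count (rapid
#' interconversion partners attract first), falling back on population order
#' only to break flux ties.
#'
#' @param csn A [build_csn()] result.
#' @param mode `"population"` (default) or `"transition"`.
#' @return A tibble of class `"basin_set"`: one row per basin with columns
#'   `basin` (attractor code), `label` (contact pattern of the most populated
#'   member), `minor_patterns`, `population` (summed fraction), `n_members`,
#'   and list-column `members`.
#' @export
gradient_cluster <- function(csn, mode = c("population", "transition")) {
  mode <- match.arg(mode)
  nodes <- csn$nodes
  if (nrow(nodes) == 0) stop("empty network", call. = FALSE)
  pop <- stats::setNames(nodes$population, nodes$code)
  ed <- csn$edges[csn$edges$from != csn$edges$to, , drop = FALSE]
  und <- dplyr::bind_rows(
    tibble::tibble(a = ed$from, b = ed$to, count = ed$count),
    tibble::tibble(a = ed$to, b = ed$from, count = ed$count)
  )
  und <- dplyr::summarise(dplyr::group_by(und, .data$a, .data$b),
                          flux = sum(.data$count), .groups = "drop")
  nbrs <- split(und[, c("b", "flux")], und$a)
  target <- vapply(nodes$code, function(u) {
    nb <- nbrs[[u]]
    if (is.null(nb) || nrow(nb) == 0) return(u)
    if (mode == "population") {
      cand_pop <- pop[nb$b]
      best <- max(cand_pop)
      if (pop[u] >= best) return(u)
      cands <- sort(nb$b[cand_pop == best])
      cands[1]
    } else {
      higher <- nb[pop[nb$b] > pop[u], , drop = FALSE]
      if (nrow(higher) == 0) return(u)
      top <- higher[higher$flux == max(higher$flux), , drop = FALSE]
      top <- top[order(-pop[top$b], top$b), , drop = FALSE]
      top$b[1]
    }
  }, character(1))
  # Pointer chasing to the fixed points.
  attractor <- target
  repeat {
    nxt <- target[attractor]
    if (all(nxt == attractor)) break
    attractor <- nxt
  }
  members <- split(nodes$code, attractor)
  basins <- purrr::imap(members, function(m, att) {
    mp <- pop[m]
    major <- m[order(-mp, m)][1]
    pats <- unique(contact_pattern(m[order(-mp, m)]))
    tibble::tibble(
      basin = att,
      label = contact_pattern(major),
      minor_patterns = paste(setdiff(pats, contact_pattern(major)),
                             collapse = ","),
      population = sum(mp) / csn$total_frames,
      n_members = length(m),
      members = list(sort(m))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(basins), dplyr::desc(.data$population))
  attr(out, "mode") <- mode
  class(out) <- c("basin_set", class(out))
  out
}

#' Coarse-grained transition network between basins
#'
#' Collapses the CSN onto the basins: node weight is the summed population
#' fraction of the basin's members; the weight of a directed basin edge is
#' the total number of inter-basin transitions along it divided by the total
#' number of observed transitions. Each basin is labelled by its most
#' populated member's contact pattern with minor patterns listed alongside.
#'
#' @param csn A [build_csn()] result.
#' @param basins A [gradient_cluster()] result partitioning `csn`'s nodes.
#' @return An object of class `"coarse_network"`: list of tibbles `nodes`
#'   (`basin`, `label`, `minor_patterns`, `fraction`) and `edges`
#'   (`from`, `to`, `count`, `probability`).
#' @export
coarse_grain <- function(csn, basins) {
  membership <- stats::setNames(
    rep(basins$basin, lengths(basins$members)),
    unlist(basins$members))
  if (!setequal(names(membership), csn$nodes$code) ||
      length(membership) != nrow(csn$nodes)) {
    stop("basins do not partition the network's nodes", call. = FALSE)
  }
  total_trans <- sum(csn$edges$count)
  ed <- csn$edges
  ed$from_basin <- membership[ed$from]
  ed$to_basin <- membership[ed$to]
  inter <- ed[ed$from_basin != ed$to_basin, , drop = FALSE]
  if (nrow(inter) > 0) {
    edges <- dplyr::summarise(
      dplyr::group_by(inter, from = .data$from_basin, to = .data$to_basin),
      count = sum(.data$count), .groups = "drop")
    edges$probability <- edges$count / total_trans
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            count = integer(), probability = numeric())
  }
  nodes <- tibble::tibble(
    basin = basins$basin, label = basins$label,
    minor_patterns = basins$minor_patterns, fraction = basins$population)
  structure(list(nodes = nodes, edges = edges, total_transitions = total_trans),
            class = "coarse_network")
}

#' @export
print.coarse_network <- function(x, ...) {
  cat(sprintf("<coarse_network> %d basins, %d inter-basin edges\n",
              nrow(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$nodes))) {
    lab <- x$nodes$label[i]
    if (nzchar(x$nodes$minor_patterns[i])) {
      lab <- paste0(lab, " (", x$nodes$minor_patterns[i], ")")
    }
    cat(sprintf("  %-18s %5.1f%%\n", lab, 100 * x$nodes$fraction[i]))
  }
  invisible(x)
}

#' Export a CSN or coarse network as GraphML plus TSV tables
#'
#' Writes `<stem>.graphml` (via igraph), `<stem>_edges.tsv`
#' (source, target, count, probability) and `<stem>_nodes.tsv`.
#'
#' @param x A `"csn"` or `"coarse_network"` object.
#' @param stem Output path stem (no extension).
#' @return Paths written, invisibly.
#' @export
write_network <- function(x, stem) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "csn")) {
    nodes <- data.frame(name = x$nodes$code,
                        population = x$nodes$population,
                        pattern = x$nodes$pattern)
    total <- sum(x$edges$count)
    edges <- data.frame(from = x$edges$from, to = x$edges$to,
                        count = x$edges$count,
                        probability = if (total > 0) x$edges$count / total
                                      else numeric(0))
  } else if (inherits(x, "coarse_network")) {
    nodes <- data.frame(name = x$nodes$basin, label = x$nodes$label,
                        fraction = x$nodes$fraction)
    edges <- data.frame(from = x$edges$from, to = x$edges$to,
                        count = x$edges$count,
                        probability = x$edges$probability)
  } else {
    stop("x must be a csn or coarse_network", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  graphml <- paste0(stem, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  edges_tsv <- paste0(stem, "_edges.tsv")
  readr::write_tsv(
    tibble::as_tibble(stats::setNames(edges,
                                      c("source", "target", "count",
                                        "probability"))), edges_tsv)
  nodes_tsv <- paste0(stem, "_nodes.tsv")
  readr::write_tsv(tibble::as_tibble(nodes), nodes_tsv)
  invisible(c(graphml, edges_tsv, nodes_tsv))
}

#' Write basin membership as TSV
#' @param basins A [gradient_cluster()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_basins <- function(basins, path) {
  out <- tibble::tibble(
    code = unlist(basins$members),
    basin = rep(basins$basin, lengths(basins$members)),
    label = rep(basins$label, lengths(basins$members)))
  readr::write_tsv(out, path)
  invisible(path)
}
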
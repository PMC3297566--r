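# Small in-code fixtures shared across tests.

# Trajectory from a list of A x 3 frames over a generic atom table.
make_traj <- function(frames, atom_names = NULL, residue_numbers = NULL,
                      roles = NULL, dt = 1) {
  a <- nrow(frames[[1]])
  if (is.null(atom_names)) atom_names <- rep(c("N", "CA", "C"), length.out = a)
  if (is.null(residue_numbers)) {
    residue_numbers <- rep(seq_len(ceiling(a / 3)), each = 3)[seq_len(a)]
  }
  atoms <- tibble::tibble(
    atom_id = seq_len(a) - 1L, name = atom_names,
    residue_number = as.integer(residue_numbers),
    residue_name = "GLY", chain_id = "A")
  coords <- array(NA_real_, dim = c(length(frames), a, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(atoms, coords, frame_times = (seq_along(frames) - 1) * dt,
             roles = roles)
}

# A non-degenerate 9-atom (3-residue backbone) reference geometry.
ref_backbone <- function(n_res = 3) {
  xyz <- NULL
  for (i in seq_len(n_res)) {
    x <- 3 * (i - 1)
    xyz <- rbind(xyz,
                 c(x - 1.2, 0.6, 0.1 * i),
                 c(x, 0, -0.2 * i),
                 c(x + 1.2, 0.6, 0.15 * i))
  }
  xyz
}

# Build a csn object directly from explicit code sequences.
csn_from_seq <- function(...) build_csn(list(...))

# A random connected-ish network fixture for gradient-clustering sweeps:
# returns a csn-like structure by simulating code sequences is awkward, so
# construct the object fields directly.
random_csn <- function(n_nodes, seed) {
  set.seed(seed)
  codes <- sprintf("n%02d", seq_len(n_nodes))
  pop <- sample.int(50, n_nodes, replace = TRUE)
  # random undirected edges, each kept with prob 0.4, plus a spanning path
  edges <- NULL
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i < j && (j == i + 1 || stats::runif(1) < 0.4)) {
        cnt1 <- sample.int(5, 1)
        edges <- rbind(edges, data.frame(from = codes[i], to = codes[j],
                                         count = cnt1))
        if (stats::runif(1) < 0.7) {
          edges <- rbind(edges, data.frame(from = codes[j], to = codes[i],
                                           count = sample.int(5, 1)))
        }
      }
    }
  }
  nodes <- tibble::tibble(code = codes, population = pop,
                          pattern = substr(codes, 2, 3))
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges),
                 total_frames = sum(pop), n_runs = 1L),
            class = "csn")
}

# Singleton-group weighted MSA over arbitrary per-domain ids (used by
# permutation-test fixtures where no paralog structure is wanted).
singleton_wmsa <- function(ids, n_columns = 10) {
  out <- tibble::tibble(
    id = ids,
    sequence = strrep("A", n_columns),
    group = seq_along(ids),
    weight = 1)
  attr(out, "n_columns") <- n_columns
  class(out) <- c("weighted_msa", class(out))
  out
}
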
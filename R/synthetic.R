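#' Specification for a synthetic Markov-chain trajectory
#'
#' Defines a toy peptide+loop system whose binding mode follows a known
#' Markov chain, so that every downstream analysis (contact detection,
#' microstate encoding, network building, basin recovery) can be checked
#' against closed-form expectations. Each mode is a rigid geometry template
#' realising a stated contact pattern; frames add i.i.d. Gaussian jitter.
#'
#' With `doorway = TRUE` (default), a switch between modes routes through a
#' one-frame "doorway" sub-state in which all monitored contacts are broken
#' while the backbone still sits in the outgoing mode's conformation —
#' emulating that contacts break before the backbone moves. Doorways keep
#' mode attractors from being direct network neighbours, which is what makes
#' the modes separable basins.
#'
#' @param transition_matrix Row-stochastic matrix over the modes.
#' @param state_contact_map List (one per mode) of character subsets of the
#'   monitored contacts `c("-7:331", "-7:332", "-4:331")`.
#' @param jitter_sigma Isotropic Gaussian jitter per coordinate in Angstrom.
#' @param n_frames Number of frames to simulate.
#' @param dt_ps Frame spacing in ps.
#' @param doorway Route mode switches through unbound doorway frames.
#' @param seed Integer seed.
#' @return An object of class `"traj_generator_spec"`.
#' @export
traj_generator_spec <- function(
    transition_matrix = default_mode_matrix(),
    state_contact_map = list(c("-7:331", "-7:332"), "-4:331", "-7:331"),
    jitter_sigma = 0.15,
    n_frames = 20000L,
    dt_ps = 1,
    doorway = TRUE,
    seed = 1L) {
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-8)) {
    stop("transition_matrix must be square and row-stochastic", call. = FALSE)
  }
  if (length(state_contact_map) != nrow(tm)) {
    stop("state_contact_map must have one entry per mode", call. = FALSE)
  }
  known <- c("-7:331", "-7:332", "-4:331")
  for (s in state_contact_map) {
    if (length(s) > 0 && !all(s %in% known)) {
      stop("contact map entries must be drawn from ",
           paste(known, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_states = nrow(tm), transition_matrix = tm,
         state_contact_map = state_contact_map,
         jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
         dt_ps = dt_ps, doorway = doorway, seed = as.integer(seed)),
    class = "traj_generator_spec"
  )
}

#' Default three-mode transition matrix
#'
#' Stay probability 0.99 per frame (mean dwell 100 ps at 1 ps spacing, i.e.
#' sub-ns interconversion scaled down from the tens-of-ns regime of full
#' simulations) with asymmetric exchange so the stationary distribution is
#' non-uniform.
#' @return 3x3 row-stochastic matrix.
#' @export
default_mode_matrix <- function() {
  matrix(c(0.990, 0.006, 0.004,
           0.007, 0.990, 0.003,
           0.006, 0.004, 0.990), nrow = 3, byrow = TRUE)
}

# ---- toy geometry ------------------------------------------------------

# Atom table of the toy system: a 4-residue peptide (chain P, residues
# -7..-4, lysine-like side chains on -7 and -4) facing a 3-residue loop
# (chain L, residues 331-333, glutamate-like side chains on 331/332). Only
# the atoms the detectors and clustering need are present.
toy_atoms <- function() {
  rows <- list()
  add <- function(name, resno, resname, chain) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, residue_number = resno, residue_name = resname,
      chain_id = chain)
  }
  for (i in 0:3) {
    resno <- -7L + i
    resname <- if (resno %in% c(-7L, -4L)) "LYS" else "GLY"
    for (nm in c("N", "CA", "C")) add(nm, resno, resname, "P")
    if (resno %in% c(-7L, -4L)) {
      for (nm in c("CD", "CE", "NZ")) add(nm, resno, resname, "P")
    }
    if (resno == -4L) add("H", resno, resname, "P")
  }
  for (j in 0:2) {
    resno <- 331L + j
    resname <- if (resno < 333L) "GLU" else "GLY"
    for (nm in c("N", "CA", "C")) add(nm, resno, resname, "L")
    if (resno < 333L) for (nm in c("CG", "CD", "OE1")) add(nm, resno, resname, "L")
    if (resno == 333L) add("O", resno, resname, "L")
  }
  atoms <- dplyr::bind_rows(rows)
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  atoms[, c("atom_id", "name", "residue_number", "residue_name", "chain_id")]
}

toy_roles <- function(atoms) {
  rows <- list()
  tag <- function(sel, role, partner = NA_integer_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      atom_id = sel, role = role, partner = partner)
  }
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    if (a$chain_id == "P" && a$residue_number %in% c(-7L, -4L)) {
      if (a$name %in% c("CD", "CE")) tag(a$atom_id, "contact_carbon")
      if (a$name == "NZ") tag(a$atom_id, "charged")
    }
    if (a$chain_id == "L" && a$residue_number %in% c(331L, 332L)) {
      if (a$name %in% c("CG", "CD")) tag(a$atom_id, "contact_carbon")
      if (a$name == "OE1") {
        tag(a$atom_id, "charged")
        tag(a$atom_id, "acceptor")
      }
    }
    if (a$chain_id == "L" && a$name == "O") tag(a$atom_id, "acceptor")
    if (a$chain_id == "P" && a$residue_number == -4L && a$name == "N") {
      tag(a$atom_id, "donor")
    }
  }
  roles <- dplyr::bind_rows(rows)
  hn <- atoms$atom_id[atoms$chain_id == "P" & atoms$residue_number == -4L &
                        atoms$name == "H"]
  dn <- atoms$atom_id[atoms$chain_id == "P" & atoms$residue_number == -4L &
                        atoms$name == "N"]
  roles <- dplyr::bind_rows(roles, tibble::tibble(
    atom_id = hn, role = "hydrogen", partner = dn))
  roles
}

# Template coordinates realising a contact pattern with the backbone of
# mode `mode_index` (backbone z offset separates modes by > the 2 A leader
# cutoff). Formed contacts sit ~2.5 A inside the 5 A cutoff, broken ones
# >= 1.5 A outside it, so sub-Angstrom jitter cannot flip a digit.
toy_template <- function(atoms, contacts, mode_index) {
  xyz <- matrix(0, nrow(atoms), 3)
  place <- function(chain, resno, name, p) {
    i <- which(atoms$chain_id == chain & atoms$residue_number == resno &
                 atoms$name == name)
    xyz[i, ] <<- p
  }
  loop_x <- c(`331` = 0, `332` = 9, `333` = 18)
  for (r in c(331L, 332L, 333L)) {
    x <- loop_x[[as.character(r)]]
    place("L", r, "N", c(x - 1.2, 0, 0))
    place("L", r, "CA", c(x, 0, 0))
    place("L", r, "C", c(x + 1.2, 0, 0))
    if (r < 333L) {
      place("L", r, "CG", c(x, 1.5, 0))
      place("L", r, "CD", c(x, 3.0, 0))
      place("L", r, "OE1", c(x, 4.2, 0))
    } else {
      place("L", r, "O", c(x + 1.8, 1.0, 0))
    }
  }
  # Modes differ by an internal zig-zag deformation of the peptide backbone
  # (amplitude 3 A per mode step) plus a rigid z shift; the zig-zag survives
  # superposition, keeping inter-mode backbone RMSD well above the 2 A
  # leader cutoff.
  z_off <- 4 * (mode_index - 1)
  amp <- 3 * (mode_index - 1)
  zr <- numeric(4)
  for (i in 0:3) {
    resno <- -7L + i
    x <- 3 * i
    zr[i + 1] <- z_off + amp * (-1)^i
    place("P", resno, "N", c(x - 1.2, 10.6, zr[i + 1]))
    place("P", resno, "CA", c(x, 10, zr[i + 1]))
    place("P", resno, "C", c(x + 1.2, 10.6, zr[i + 1]))
  }
  place("P", -4L, "H", c(9 - 1.2, 9, zr[4]))
  # Side chain of -7: CE services -7:331, CD services -7:332.
  if ("-7:331" %in% contacts) {
    place("P", -7L, "CE", c(0, 5.5, 0))
  } else {
    place("P", -7L, "CE", c(0, 9.5, zr[1]))
  }
  if ("-7:332" %in% contacts) {
    place("P", -7L, "CD", c(9, 5.5, 0))
  } else {
    place("P", -7L, "CD", c(0, 10.8, zr[1]))
  }
  place("P", -7L, "NZ", c(0.6, 11.5, zr[1]))
  # Side chain of -4.
  if ("-4:331" %in% contacts) {
    place("P", -4L, "CE", c(1.0, 5.0, 0))
    place("P", -4L, "CD", c(1.0, 6.3, 0))
  } else {
    place("P", -4L, "CE", c(9, 14.2, zr[4]))
    place("P", -4L, "CD", c(9, 13.0, zr[4]))
  }
  place("P", -4L, "NZ", c(9.6, 15.0, zr[4]))
  xyz
}

#' Contact specs monitored on the toy system
#'
#' The three salt bridges of the binding-mode code, in code order:
#' `-7:331`, `-7:332`, `-4:331`.
#' @return List of [contact_spec()] objects.
#' @export
toy_contact_specs <- function() {
  list(
    contact_spec("-7:331", "ionic", "P:-7:*", "L:331:*"),
    contact_spec("-7:332", "ionic", "P:-7:*", "L:332:*"),
    contact_spec("-4:331", "ionic", "P:-4:*", "L:331:*"))
}

#' Simulate a Markov-chain trajectory of the toy system
#'
#' Simulates the mode chain, optionally expanding switches through doorway
#' frames, and emits per-frame coordinates as the mode template plus i.i.d.
#' Gaussian jitter. Fully reproducible from the spec's seed.
#'
#' @param spec A [traj_generator_spec()].
#' @return List with `trajectory` (a [trajectory()] with roles populated),
#'   `states` (per-frame hidden mode index; doorway frames carry the
#'   negative of the outgoing mode), `patterns` (per-frame ground-truth
#'   contact pattern string) and `spec`.
#' @export
gen_markov_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_frames
  k <- spec$n_states
  tm <- spec$transition_matrix
  # Hidden sequence over expanded states: 1..k are modes, k+j is the
  # doorway of mode j (entered on leaving j, left on the next frame).
  states <- integer(n)
  states[1] <- 1L
  i <- 2L
  cur <- 1L
  while (i <= n) {
    if (cur > k) {
      # doorway of mode (cur - k): exit towards a new mode
      from <- cur - k
      p <- tm[from, ]
      p[from] <- 0
      p <- p / sum(p)
      cur <- sample.int(k, 1, prob = p)
    } else {
      nxt <- sample.int(k, 1, prob = tm[cur, ])
      if (nxt != cur && spec$doorway && k > 1) {
        cur <- k + cur
      } else {
        cur <- nxt
      }
    }
    states[i] <- cur
    i <- i + 1L
  }
  atoms <- toy_atoms()
  roles <- toy_roles(atoms)
  templates <- vector("list", 2 * k)
  patterns_by_state <- character(2 * k)
  for (s in seq_len(k)) {
    templates[[s]] <- toy_template(atoms, spec$state_contact_map[[s]], s)
    patterns_by_state[s] <- pattern_of(spec$state_contact_map[[s]])
    templates[[k + s]] <- toy_template(atoms, character(0), s)
    patterns_by_state[k + s] <- "000"
  }
  coords <- array(NA_real_, dim = c(n, nrow(atoms), 3))
  for (f in seq_len(n)) {
    coords[f, , ] <- templates[[states[f]]] +
      matrix(stats::rnorm(3 * nrow(atoms), sd = spec$jitter_sigma),
             nrow(atoms), 3)
  }
  traj <- trajectory(atoms, coords,
                     frame_times = (seq_len(n) - 1) * spec$dt_ps,
                     roles = roles, run_id = sprintf("markov_seed%d", spec$seed))
  out_states <- ifelse(states > k, -(states - k), states)
  list(trajectory = traj, states = out_states,
       patterns = patterns_by_state[states], spec = spec)
}

pattern_of <- function(contacts) {
  paste0(as.integer(c("-7:331", "-7:332", "-4:331") %in% contacts),
         collapse = "")
}

#' Expanded transition matrix including doorway states
#'
#' Returns the row-stochastic matrix actually simulated by
#' [gen_markov_trajectory()]: modes `1..k` followed by their doorway states
#' `k+1..2k` (rows for unreachable doorways are kept, as self-absorbing,
#' when `doorway = FALSE`). This is the object closed-form oracles
#' (stationary distribution, autocorrelation times) are computed from.
#'
#' @param spec A [traj_generator_spec()].
#' @return `2k x 2k` row-stochastic matrix.
#' @export
expanded_transition_matrix <- function(spec) {
  k <- spec$n_states
  tm <- spec$transition_matrix
  p <- matrix(0, 2 * k, 2 * k)
  for (s in seq_len(k)) {
    if (spec$doorway && k > 1) {
      p[s, s] <- tm[s, s]
      p[s, k + s] <- 1 - tm[s, s]
      off <- tm[s, ]
      off[s] <- 0
      if (sum(off) > 0) p[k + s, seq_len(k)] <- off / sum(off)
      else p[k + s, k + s] <- 1
    } else {
      p[s, seq_len(k)] <- tm[s, ]
      p[k + s, k + s] <- 1
    }
  }
  p
}

#' Stationary distribution of a finite Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, restricted to
#' the recurrent communicating class reachable from state 1 and normalised
#' to sum to 1 (unreachable states get probability 0).
#'
#' @param p Row-stochastic matrix.
#' @return Stationary probability vector.
#' @export
markov_stationary <- function(p) {
  n <- nrow(p)
  reach <- rep(FALSE, n)
  reach[1] <- TRUE
  repeat {
    new <- reach | (colSums(p[reach, , drop = FALSE]) > 0)
    if (all(new == reach)) break
    reach <- new
  }
  sub <- p[reach, reach, drop = FALSE]
  e <- eigen(t(sub))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  pi_sub <- v / sum(v)
  out <- numeric(n)
  out[reach] <- pi_sub
  out
}

#' Standard error of an empirical state-set frequency under a Markov chain
#'
#' The naive binomial standard error understates the uncertainty of an
#' occupancy estimated from autocorrelated frames. This computes the
#' asymptotic standard error of `mean(X_t in S)` over `n` frames from the
#' chain itself, via the lag-summed autocovariance of the indicator:
#' `Var = (gamma_0 + 2 * sum_k gamma_k) / n` with
#' `gamma_k = sum_{i in S} pi_i (P^k)_{i,S} - p^2`.
#'
#' @param p Row-stochastic transition matrix.
#' @param states Indices of the state set `S`.
#' @param n Number of frames.
#' @param max_lag Truncation lag for the autocovariance sum (default 5000).
#' @return Standard error of the empirical frequency.
#' @export
markov_indicator_se <- function(p, states, n, max_lag = 5000) {
  pi_vec <- markov_stationary(p)
  prob <- sum(pi_vec[states])
  gamma0 <- prob * (1 - prob)
  acc <- gamma0
  # iterate v_k[i] = P(X_k in S | X_0 = i)
  v <- as.numeric(seq_len(nrow(p)) %in% states)
  for (k in seq_len(max_lag)) {
    v <- as.numeric(p %*% v)
    g <- sum(pi_vec[states] * v[states]) - prob^2
    acc <- acc + 2 * g
    if (abs(g) < 1e-12 * gamma0) break
  }
  sqrt(max(acc, gamma0) / n)
}
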